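test_that("campaign generation is deterministic given the configuration", {
  c1 <- generate_campaign(tiny_config(seed = 11))
  c2 <- generate_campaign(tiny_config(seed = 11))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$counting_records, c2$counting_records)
  expect_identical(c1$soil_properties, c2$soil_properties)
  c3 <- generate_campaign(tiny_config(seed = 12))
  expect_false(identical(c1$counting_records$R, c3$counting_records$R))
})

test_that("generated campaigns carry the configured structure", {
  camp <- generate_campaign(campaign_config(seed = 3))
  truth <- camp$truth
  # soil rows for every plot-year; organ sets follow the crop
  expect_equal(sum(truth$medium == "soil"), 16 * 3)
  expect_true(all(truth$organ[truth$crop_type == "maize"] %in%
                    c("root", "stem", "leaf", "grain")))
  expect_true(all(truth$organ[truth$crop_type == "winter_wheat"] %in%
                    c("root", "rest_of_plant")))
  # mechanical fractions close
  props <- camp$soil_properties
  expect_equal(rowSums(props[, c("coarse_sand", "fine_sand", "silt", "clay")]),
               rep(100, nrow(props)), tolerance = 1e-9)
  # activity decline across years on average
  yr_mean <- tapply(truth$A_true[truth$medium == "soil"],
                    truth$year[truth$medium == "soil"], mean)
  expect_gt(yr_mean[1], yr_mean[3])
  # partition ordering violated by config is rejected
  expect_error(campaign_config(organ_partition = c(root = 0.1, leaf = 0.25,
                                                   stem = 0.12, grain = 0.1,
                                                   rest_of_plant = 0.13)))
})

test_that("organ-mean TF ordering root > leaf > stem > grain holds in most replicates", {
  ok <- 0L
  for (s in 1:40) {
    camp <- generate_campaign(campaign_config(seed = 1000 + s))
    act <- reduce_counting_records(camp$counting_records, camp$config$detector)
    tf <- build_tf_table(act[act$medium == "crop", ],
                         act[act$medium == "soil", c("site_code", "year", "A")])
    m <- tapply(tf$tf[tf$defined], tf$organ[tf$defined], mean)
    ok <- ok + (m["root"] > m["leaf"] && m["leaf"] > m["stem"] &&
                  m["stem"] > m["grain"])
  }
  expect_gte(ok / 40, 0.95)
})

test_that("long counts recover the generating activities almost exactly", {
  cfg <- tiny_config(seed = 21, count_time_s = 5.4e6, background_cps = 0.002)
  camp <- generate_campaign(cfg)
  act <- reduce_counting_records(camp$counting_records, cfg$detector)
  ok <- !act$censored
  expect_gt(mean(ok), 0.9)
  rel <- abs(act$A[ok] - camp$truth$A_true[ok]) / camp$truth$A_true[ok]
  expect_lt(stats::median(rel), 0.001)
})

test_that("recovery report is exact on perfect estimates and errors on mismatch", {
  camp <- generate_campaign(tiny_config(seed = 31))
  perfect <- camp$truth[, c("site_code", "year", "medium", "crop_type", "organ")]
  perfect$A <- camp$truth$A_true
  perfect$dA <- 1e-9
  perfect$censored <- FALSE
  rep0 <- recovery_report(camp, perfect)
  expect_equal(rep0$bias[rep0$quantity %in% c("A_soil", "A_crop")], c(0, 0))
  expect_equal(rep0$rmse[rep0$quantity == "TF"], 0, tolerance = 1e-12)
  expect_equal(rep0$coverage[rep0$quantity == "A_soil"], 1)
  broken <- perfect[-1, ]
  expect_error(recovery_report(camp, broken), "mismatch")
})

test_that("pushing grain activities below the detection limit yields censored cells", {
  part <- c(root = 0.5, leaf = 0.25, stem = 0.12, grain = 0.001,
            rest_of_plant = 0.13)
  cfg <- campaign_config(n_sites = 6, years = 2014, seed = 41,
                         organ_partition = part)
  camp <- generate_campaign(cfg)
  act <- reduce_counting_records(camp$counting_records, cfg$detector)
  grain <- act$organ == "grain"
  expect_true(any(act$censored[grain]))
  expect_false(any(act$censored[act$organ == "root"]))
  # and censored cells become "/" in the TF table
  tf <- build_tf_table(act[act$medium == "crop", ],
                       act[act$medium == "soil", c("site_code", "year", "A")])
  expect_true(all(is.na(tf$tf[!tf$defined])))
  expect_equal(sum(!tf$defined), sum(act$censored[act$medium == "crop"]))
})

test_that("fully sub-detection configurations trigger the infeasibility warning", {
  expect_warning(generate_campaign(tiny_config(seed = 51, soil_A_mean = 1e-5)),
                 "infeasible")
})
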