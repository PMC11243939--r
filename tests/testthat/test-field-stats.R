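test_that("field averages reproduce every printed average row", {
  fx <- load_campaign_fixtures()
  by_field <- split(fx$soil_properties,
                    site_field(fx$soil_properties$site_code, fx$model_params))
  printed <- list(
    Radmilovac = c(coarse_sand = 6.06, fine_sand = 4.63, silt = 58.26,
                   clay = 31.06, hygroscopic_humidity = 2.50, density = 1.29,
                   pH_H2O = 6.77, pH_KCl = 7.31, CaCO3 = 1.40, humus = 2.28,
                   total_OC = 0.34, OC_humic = 0.21, OC_fulvic = 0.13),
    Rimski_Sancevi = c(coarse_sand = 11.25, fine_sand = 22.79, silt = 32.81,
                       clay = 33.15, hygroscopic_humidity = 3.02,
                       density = 1.34, pH_H2O = 7.70, pH_KCl = 6.90,
                       CaCO3 = 2.10, humus = 2.74, total_OC = 0.26,
                       OC_humic = 0.14, OC_fulvic = 0.12))
  for (f in names(printed)) {
    got <- field_averages(by_field[[f]], "zero", digits = 2)
    expect_equal(got[names(printed[[f]])], printed[[f]])
  }
  # exclude policy changes only the column with missing cells
  ns <- field_averages(by_field$Rimski_Sancevi, "exclude")
  expect_equal(round_decimal(ns["CaCO3"], 2), c(CaCO3 = 2.62))  # 21.00/8 = 2.625
  one <- field_averages(by_field$Radmilovac[1, ], "zero")
  expect_equal(unname(one["humus"]), 2.01)
})

test_that("correlation screen matches the product-moment formula and tiers", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  out <- pearson_screen(d)
  expect_equal(out$r, 0.6)                        # hand evaluation
  expect_equal(out$n, 4L)
  d2 <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = rep(1, 10))
  out2 <- pearson_screen(d2)
  xy <- out2[out2$var_x == "x" & out2$var_y == "y", ]
  expect_equal(xy$r, 1)
  expect_equal(xy$tier, "<0.001")
  expect_equal(out2$tier[out2$var_y == "z"], rep("undefined", 2))
  # affine invariance
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  r0 <- pearson_screen(data.frame(a, b))$r
  r1 <- pearson_screen(data.frame(a = 3 * a - 7, b = 0.2 * b + 11))$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("one-way ANOVA matches the hand decomposition", {
  # hand oracle for (1,2,3) vs (4,5,6): SSB = 13.5 (df 1), SSW = 4 (df 4)
  a <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, (13.5 / 1) / (4 / 4))
  expect_equal(a$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(unname(a$group_means), c(2, 5))
  # identical groups give F = 0
  expect_equal(anova_oneway(rep(c(1, 2, 3), 2),
                            rep(c("a", "b"), each = 3))$F, 0)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least two values")
})

test_that("field comparison of wheat-plot activities reproduces the printed tiers", {
  fx <- load_campaign_fixtures()
  field <- site_field(fx$crop_activity$site_code, fx$model_params)
  ww_root <- fx$crop_activity$crop_type == "winter_wheat" &
    fx$crop_activity$organ == "root"
  # root activities separate the two fields strongly
  expect_lt(anova_oneway(fx$crop_activity$A[ww_root], field[ww_root])$p, 0.001)
  # soil activities over all plot-years separate at the 1% level
  soil_field <- site_field(fx$soil_activity$site_code, fx$model_params)
  expect_lt(anova_oneway(fx$soil_activity$A, soil_field)$p, 0.01)
})

test_that("Tukey HSD agrees with the F test for two groups and flags the shifted group", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  tk <- tukey_hsd(v, g)
  expect_true(tk$significant)
  # studentized-range p for two groups equals the F-test p (up to the
  # numerical accuracy of ptukey)
  expect_equal(tk$p_adj, anova_oneway(v, g)$p, tolerance = 0.01)
  # two identical groups: no significant pair
  expect_false(tukey_hsd(rep(c(1, 2, 3), 2), g)$significant)
  # three groups, one shifted: exactly the two pairs with the shifted group
  set.seed(8)
  v3 <- c(rnorm(10), rnorm(10), rnorm(10, 8))
  g3 <- rep(c("a", "b", "c"), each = 10)
  tk3 <- tukey_hsd(v3, g3)
  expect_equal(tk3$significant[order(tk3$pair)],
               c("b-a" = FALSE, "c-a" = TRUE, "c-b" = TRUE),
               ignore_attr = TRUE)
})
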