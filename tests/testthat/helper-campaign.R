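# Shared helpers: a small deterministic campaign and a hand-rolled counting
# record for unit tests.

tiny_config <- function(seed = 42, ...) {
  campaign_config(n_sites = 4, years = 2013:2014, seed = seed, ...)
}

example_record <- function(R = 0.05, R0 = 0.01, t_sep_h = 72, eta_s = 0.7,
                           m_kg = 0.5, dR_rel = 0.05) {
  data.frame(site_code = "S1", year = 2013, medium = "soil",
             crop_type = "none", organ = "none",
             R = R, R0 = R0, tS = 5400, t0 = 5400, t_sep_h = t_sep_h,
             eta_s = eta_s, m_kg = m_kg, dR_rel = dR_rel,
             d_eta_s_rel = 0, dm_rel = 0)
}
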