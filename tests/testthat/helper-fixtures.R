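# Shared fixtures, generated in code (no data files).

# small two-stock cohort with both traits simulated from the trait models
small_trait_panel <- function(seed = 42, n_ice = 30L, n_nea = 30L,
                              span = c(1980L, 2009L)) {
  p <- cohort_params(n_fish = c(ICE = n_ice, NEA = n_nea),
                     span = list(ICE = span, NEA = span),
                     n_single_meas = 2L, seed = seed)
  panel <- generate_cohort(p)
  env <- simulate_temperature(seq(min(panel$year) - 1L, max(panel$year)),
                              seed = seed)
  panel <- simulate_widths(panel, p, env)
  panel <- simulate_d13c_lmm(panel, p)
  list(panel = panel, env = env, params = p)
}

# hand-built balanced one-way panel: n_g fish, m replicate milled increments
# each, group means mu_g; used against closed-form ANOVA/REML estimators
balanced_oneway_panel <- function(n_g = 20, m = 5, tau = 0.5, sigma2 = 1,
                                  seed = 7) {
  set.seed(seed)
  g <- rep(seq_len(n_g), each = m)
  u <- rnorm(n_g, 0, sqrt(tau))
  y <- u[g] + rnorm(n_g * m, 0, sqrt(sigma2))
  df <- data.frame(
    fish_id = sprintf("F%03d", g), stock = "ICE", sex = "F", tl_cm = 100,
    age_at_capture = m, capture_year = 2010L,
    age = rep(seq_len(m), times = n_g),
    year = 2010L - (m - rep(seq_len(m), times = n_g)),
    width_um = NA_real_, spawning_zone = FALSE, milled = TRUE,
    excluded = FALSE, d13c_permil = y, stringsAsFactors = FALSE)
  as_otolith_panel(df)
}

# closed-form balanced one-way variance-component estimators (the oracle):
# sigma2 = MSW, tau = (MSB - MSW) / m
oneway_anova_estimates <- function(y, g, m) {
  gm <- tapply(y, g, mean)
  msw <- sum((y - gm[g])^2) / (length(y) - length(gm))
  msb <- m * sum((gm - mean(y))^2) / (length(gm) - 1)
  c(sigma2 = msw, tau = (msb - msw) / m)
}
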