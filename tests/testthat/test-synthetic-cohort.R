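test_that("cohort layout honours count identities and the study design", {
  p <- cohort_params(n_fish = c(ICE = 9L), span = list(ICE = c(2000L, 2002L)),
                     ages_at_capture = 10L, age_probs = 1,
                     n_single_meas = 0L, rare_frac = 0, seed = 1)
  panel <- generate_cohort(p)
  expect_equal(length(unique(panel$fish_id)), 9L)
  expect_equal(nrow(panel), 90L)
  expect_equal(sum(!duplicated(panel$fish_id) & panel$capture_year == 2000), 3L)
  # increments = sum of ages at capture; d13c slots only at milled ages
  expect_equal(nrow(panel),
               sum(panel$age_at_capture[!duplicated(panel$fish_id)]))
  expect_true(all(panel$age[panel$milled] %in% c(3L, 8L)))
  expect_true(all(is.na(panel$d13c_permil)))

  d <- generate_cohort(cohort_params())
  fish <- d[!duplicated(d$fish_id), ]
  expect_equal(nrow(fish), 436L)
  expect_equal(sum(fish$stock == "ICE"), 213L)
  expect_equal(sum(fish$stock == "NEA"), 223L)
  expect_equal(sum(d$milled), 836L)   # 436 x 2 minus 36 single-measurement
  expect_true(all(fish$age_at_capture >= 10))
  expect_true(all(d$excluded[d$age == 1]))
})

test_that("identical seeds give byte-identical serialized panels", {
  p <- cohort_params(n_fish = c(ICE = 15L, NEA = 15L),
                     span = list(ICE = c(2000L, 2004L), NEA = c(2000L, 2004L)),
                     n_single_meas = 2L, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  env <- simulate_temperature(1985:2004, seed = 99)
  for (f in c(f1, f2)) {
    panel <- generate_cohort(p)
    panel <- simulate_widths(panel, p, env)
    panel <- simulate_d13c_lmm(panel, p)
    write_panel(panel, f)
  }
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("width simulator reduces to the fixed-effect curve at zero noise", {
  p <- cohort_params(n_fish = c(ICE = 5L, NEA = 5L),
                     span = list(ICE = c(2000L, 2004L), NEA = c(2000L, 2004L)),
                     width_var = c(sigma2 = 0, tau_fish = 0, tau_stockyear = 0),
                     n_single_meas = 0L, seed = 5)
  panel <- generate_cohort(p)
  env <- simulate_temperature(1985:2004, seed = 5)
  env$anom_t <- 0
  panel <- simulate_widths(panel, p, env)
  ctr <- attr(panel, "centers")
  nea <- as.numeric(panel$stock == "NEA")
  b <- p$width_beta
  lp <- b[["intercept"]] +
    (b[["log_age"]] + b[["log_age_nea"]] * nea) * (log(panel$age) - ctr$log_age) +
    b[["tl"]] * (panel$tl_cm - ctr$tl_cm) / 100 + b[["stock_nea"]] * nea
  expect_equal(log(panel$width_um), lp, tolerance = 1e-12)
  # negative log-age slope => widths strictly decreasing in age within fish
  for (id in unique(panel$fish_id)) {
    w <- panel$width_um[panel$fish_id == id][order(panel$age[panel$fish_id == id])]
    expect_true(all(diff(w) < 0))
  }
})

test_that("simulated random components recover their generative variances", {
  # moment recovery at >= 10,000 groups (5% relative tolerance)
  p <- cohort_params(n_fish = c(ICE = 5000L, NEA = 5100L), seed = 31)
  panel <- generate_cohort(p)
  env <- simulate_temperature(seq(min(panel$year) - 1L, max(panel$year)),
                              seed = 31)
  panel <- simulate_widths(panel, p, env)
  panel <- simulate_d13c_lmm(panel, p)
  u_w <- attr(panel, "width_ranef")$fish
  u_d <- attr(panel, "d13c_ranef")$fish
  expect_gt(length(u_w), 10000)
  expect_equal(stats::var(u_w), 0.005, tolerance = 0.05)
  expect_equal(stats::var(u_d), 0.128, tolerance = 0.05)
  sy <- attr(panel, "d13c_ranef")$stockyear
  expect_gt(length(sy), 150)  # far fewer groups; centering check only
  expect_equal(mean(c(stats::var(u_w) / 0.005, stats::var(u_d) / 0.128)), 1,
               tolerance = 0.05)
})

test_that("d13c simulator encodes the stock-specific century declines", {
  p <- cohort_params(n_fish = c(ICE = 20L, NEA = 20L),
                     span = list(ICE = c(1950L, 2015L), NEA = c(1950L, 2015L)),
                     d13c_var = c(sigma2 = 0, tau_fish = 0, tau_stockyear = 0),
                     meas_sd = 0, n_single_meas = 0L, rare_frac = 0, seed = 8)
  panel <- generate_cohort(p)
  panel <- simulate_d13c_lmm(panel, p)
  m <- panel[panel$milled & panel$age == 3, ]
  for (s in c("ICE", "NEA")) {
    ms <- m[m$stock == s, ]
    # same fixed covariates except Year: fit the slope exactly
    tlc <- (ms$tl_cm - attr(panel, "centers")$tl_cm) / 100
    resid <- ms$d13c_permil - p$d13c_beta[["tl"]] * tlc
    slope <- stats::coef(stats::lm(resid ~ ms$year))[[2]]
    expected <- if (s == "ICE") -0.007 else -0.007 + 0.004
    expect_equal(slope * 100, expected * 100, tolerance = 1e-8)
  }
})

test_that("mass-balance simulator closes algebraically", {
  src <- source_config(diet_mean = c(ICE = -18), dic_mean = c(ICE = 1),
                       diet_sd = c(ICE = 0), dic_sd = c(ICE = 0))
  p <- cohort_params(n_fish = c(ICE = 8L), span = list(ICE = c(2000L, 2003L)),
                     n_single_meas = 0L, rare_frac = 0, seed = 2)
  panel <- generate_cohort(p)
  # zero spread at p = 0.5: hand-evaluated mass balance -5.8 permil
  out <- simulate_d13c_mass_balance(panel, src, c(ICE = 0.5),
                                    sd_fish = 0, sd_year = 0, noise_sd = 0,
                                    seed = 3)
  expect_equal(unique(out$d13c_permil[out$milled]), -5.8)
  # boundary truths pin delta at the pure end members (+ epsilon)
  for (tr in c(1e-9, 1 - 1e-9)) {
    o <- simulate_d13c_mass_balance(panel, src, c(ICE = tr), 0, 0, 0, seed = 3)
    want <- if (tr > 0.5) src$diet_mean[["ICE"]] + src$epsilon
            else src$dic_mean[["ICE"]] + src$epsilon
    expect_equal(unique(round(o$d13c_permil[o$milled], 6)), want)
  }
  expect_error(simulate_d13c_mass_balance(panel, src, c(ICE = 1.2)),
               "inside")
  # noise-free round trip: algebraic inversion returns generative p exactly
  out2 <- simulate_d13c_mass_balance(panel, src, c(ICE = 0.3),
                                     sd_fish = 0.4, sd_year = 0.2,
                                     noise_sd = 0, seed = 4)
  m <- out2$milled
  p_back <- cresp_invert(out2$d13c_permil[m], src, out2$stock[m])
  expect_equal(as.numeric(p_back), unname(attr(out2, "cresp_true")[m]),
               tolerance = 1e-12)
})

test_that("temperature series center to zero anomalies", {
  env <- simulate_temperature(2000:2002, stocks = "ICE", innov_sd = 0, ar = 0)
  expect_equal(env$anom_t, rep(0, 3))
  env2 <- data.frame(stock = "ICE", year = 1:3, temp_c = c(4, 5, 6))
  env2$anom_t <- env2$temp_c - mean(env2$temp_c)
  expect_equal(env2$anom_t, c(-1, 0, 1))
  env3 <- simulate_temperature(1:10000, stocks = "NEA", seed = 6)
  expect_lt(abs(mean(env3$anom_t)), 1e-10)  # centering is exact by construction
  # AR(1) persistence shows up as positive lag-1 correlation
  expect_gt(stats::cor(env3$anom_t[-1], env3$anom_t[-10000]), 0.4)
})

test_that("panel validation catches malformed inputs", {
  s <- small_trait_panel(seed = 12, n_ice = 4L, n_nea = 4L,
                         span = c(2000L, 2003L))
  f <- tempfile(fileext = ".csv")
  write_panel(s$panel, f)
  back <- read_panel(f)
  expect_equal(back$d13c_permil, s$panel$d13c_permil)
  expect_equal(back$width_um, s$panel$width_um, tolerance = 1e-12)
  expect_equal(attr(back, "centers"), attr(s$panel, "centers"),
               tolerance = 1e-12)

  bad <- as.data.frame(s$panel); bad$width_um[3] <- -1
  expect_error(as_otolith_panel(bad), "non-positive increment width")
  bad2 <- as.data.frame(s$panel); bad2$age[2] <- bad2$age[1]
  expect_error(as_otolith_panel(bad2), "year inconsistent|duplicate")
  bad3 <- as.data.frame(s$panel)
  bad3 <- rbind(bad3, bad3[1, ])
  expect_error(as_otolith_panel(bad3), "duplicate")
})
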