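#' Generative parameters for the synthetic otolith cohort
#'
#' Bundles every constant needed to simulate a two-stock otolith sampling
#' design: cohort layout (fish per stock, capture-year spans, ages at
#' capture, milled ages), the fixed-effect coefficients and variance
#' components of the two univariate trait models, and the random seed.
#'
#' Default coefficients and variance components are the published estimates
#' of the optimal univariate models for delta-13-C and log increment width
#' (intercepts in permil and log-micrometres respectively).  Defaults
#' emulate the study design: 213 Icelandic + 223 Northeast Arctic fish,
#' up to 3 fish per capture year, ages at capture 10-14, increments milled
#' at ages 3 and 8 (rarely 2 and 7), 36 fish with a single isotope
#' measurement, and a measurement precision component of 0.3 permil (1-sigma,
#' instrument reproducibility <= 0.4) counted inside the residual variance.
#'
#' @param n_fish named integer vector, fish per stock.
#' @param span named list of `c(first, last)` capture years per stock.
#' @param ages_at_capture integer vector of possible ages at capture.
#' @param age_probs sampling probabilities for `ages_at_capture`.
#' @param milled_ages increment ages milled for isotope analysis.
#' @param rare_milled_ages fallback milled ages for a small fraction of fish.
#' @param rare_frac fraction of fish milled at the fallback ages.
#' @param n_single_meas number of fish with only one isotope measurement.
#' @param tl_mean,tl_sd total length distribution (cm).
#' @param width_beta,width_var fixed effects and variance components of the
#'   log increment-width model.
#' @param d13c_beta,d13c_var fixed effects and variance components of the
#'   delta-13-C model.
#' @param meas_sd delta-13-C measurement SD (permil), a component of
#'   `d13c_var["sigma2"]`, not additional noise.
#' @param seed integer seed; the seed fully determines all generated output.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_fish = c(ICE = 213L, NEA = 223L),
                          span = list(ICE = c(1929L, 2015L),
                                      NEA = c(1933L, 2015L)),
                          ages_at_capture = 10:14,
                          age_probs = c(0.25, 0.25, 0.20, 0.15, 0.15),
                          milled_ages = c(3L, 8L),
                          rare_milled_ages = c(2L, 7L),
                          rare_frac = 0.04,
                          n_single_meas = 36L,
                          tl_mean = 95, tl_sd = 10,
                          width_beta = c(intercept = 5.146,
                                         log_age = -0.649,
                                         log_age_nea = 0.133,
                                         tl = 0.301,
                                         stock_nea = 0.041,
                                         anomt = 0.020),
                          width_var = c(sigma2 = 0.058,
                                        tau_fish = 0.005,
                                        tau_stockyear = 0.001),
                          d13c_beta = c(intercept = -1.563,
                                        age8 = 0.036,
                                        age8_nea = 0.071,
                                        year = -0.007,
                                        year_nea = 0.004,
                                        tl = -0.203,
                                        stock_nea = -0.404),
                          d13c_var = c(sigma2 = 0.144,
                                       tau_fish = 0.128,
                                       tau_stockyear = 0.034),
                          meas_sd = 0.3,
                          seed = 1L) {
  stopifnot(all(n_fish > 0), length(ages_at_capture) == length(age_probs),
            all(width_var >= 0), all(d13c_var >= 0),
            meas_sd >= 0, meas_sd <= 0.4,
            meas_sd^2 <= d13c_var[["sigma2"]] + 1e-12)
  for (s in names(n_fish)) {
    sp <- span[[s]]
    if (is.null(sp) || sp[2] < sp[1])
      stop("invalid or empty capture-year span for stock ", s)
  }
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a synthetic otolith cohort (layout only, no trait values)
#'
#' Lays out fish and their annual increments: capture years are spread
#' round-robin over each stock's span (at most `ceiling(n/len(span))` per
#' year, emulating "3 fish caught at age 10+ per sampling year"), ages at
#' capture, sex (40/40/20 F/M/UNKNOWN) and total length are drawn per fish,
#' and one increment row per age 1..age_at_capture is created.  First and
#' last increments are flagged excluded; milled ages get `milled = TRUE`
#' with delta-13-C left NA until a trait simulator fills it.  Spawning-zone
#' flags are set with probability 0.8 at ages >= 7 and 0.05 below (no
#' generative effect on any trait).
#'
#' @param params a [cohort_params()] object.
#' @return an `otolith_panel` (widths and delta-13-C all NA).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  stocks <- names(params$n_fish)
  fish_list <- list()
  for (s in stocks) {
    n <- params$n_fish[[s]]
    yrs <- seq(params$span[[s]][1], params$span[[s]][2])
    capture_year <- sort(rep(yrs, length.out = n))
    fish_list[[s]] <- data.frame(
      fish_id = sprintf("%s_%04d", s, seq_len(n)),
      stock = s,
      capture_year = capture_year,
      age_at_capture = params$ages_at_capture[
        sample.int(length(params$ages_at_capture), n, replace = TRUE,
                   prob = params$age_probs)],
      sex = sample(c("F", "M", "UNKNOWN"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2)),
      tl_cm = pmax(40, stats::rnorm(n, params$tl_mean, params$tl_sd)),
      stringsAsFactors = FALSE
    )
  }
  fish <- do.call(rbind, fish_list)
  n_total <- nrow(fish)
  fish$rare_milled <- stats::runif(n_total) < params$rare_frac
  single <- rep(FALSE, n_total)
  if (params$n_single_meas > 0 && params$n_single_meas <= n_total)
    single[sample.int(n_total, params$n_single_meas)] <- TRUE
  # per-fish milled ages (vectorized): the rare set replaces the standard
  # one; fish with a single measurement lose one milled age at random
  lo <- ifelse(fish$rare_milled, min(params$rare_milled_ages),
               min(params$milled_ages))
  hi <- ifelse(fish$rare_milled, max(params$rare_milled_ages),
               max(params$milled_ages))
  drop_hi <- single & stats::runif(n_total) < 0.5
  drop_lo <- single & !drop_hi
  A <- fish$age_at_capture
  fidx <- rep.int(seq_len(n_total), A)
  age <- sequence(A)
  panel <- data.frame(
    fish_id = fish$fish_id[fidx], stock = fish$stock[fidx],
    sex = fish$sex[fidx], tl_cm = fish$tl_cm[fidx],
    age_at_capture = A[fidx], capture_year = fish$capture_year[fidx],
    age = age,
    year = fish$capture_year[fidx] - (A[fidx] - age),
    width_um = NA_real_,
    spawning_zone = stats::runif(length(age)) < ifelse(age >= 7, 0.8, 0.05),
    milled = (age == lo[fidx] & !drop_lo[fidx]) |
      (age == hi[fidx] & !drop_hi[fidx]),
    excluded = age == 1L | age == A[fidx],
    d13c_permil = NA_real_,
    stringsAsFactors = FALSE
  )
  # centers over width rows / milled rows; TL center over fish
  out <- as_otolith_panel(panel)
  attr(out, "params") <- params
  out
}

#' Simulate per-stock annual temperature series
#'
#' AR(1) around a stock-specific mean with an optional linear trend;
#' anomalies are computed relative to each stock's own series mean.
#'
#' @param years integer vector of calendar years to cover.
#' @param stocks stock labels.
#' @param mean_c named per-stock mean temperature (deg C).
#' @param ar AR(1) coefficient of annual anomalies.
#' @param innov_sd innovation SD (deg C).
#' @param trend linear trend (deg C per year) around the mean.
#' @param seed integer seed.
#' @return data frame `stock, year, temp_c, anom_t`.
#' @export
simulate_temperature <- function(years, stocks = c("ICE", "NEA"),
                                 mean_c = c(ICE = 5.5, NEA = 4.0),
                                 ar = 0.6, innov_sd = 0.4, trend = 0,
                                 seed = 1L) {
  set.seed(seed)
  out <- list()
  for (s in stocks) {
    n <- length(years)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, innov_sd / sqrt(1 - ar^2))
    for (t in seq_len(n - 1))
      x[t + 1] <- ar * x[t] + stats::rnorm(1, 0, innov_sd)
    temp <- mean_c[[s]] + trend * (years - mean(years)) + x
    out[[s]] <- data.frame(stock = s, year = years, temp_c = temp,
                           anom_t = temp - mean(temp),
                           stringsAsFactors = FALSE)
  }
  env <- do.call(rbind, out)
  rownames(env) <- NULL
  env
}

# linear predictor helpers ---------------------------------------------------

tl_centered_m <- function(panel) {
  (panel$tl_cm - attr(panel, "centers")$tl_cm) / 100
}

milled_age_class <- function(age, split = 5.5) ifelse(age > split, "8", "3")

lookup_anomt <- function(panel, env) {
  key <- paste(panel$stock, panel$year)
  ekey <- paste(env$stock, env$year)
  idx <- match(key, ekey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("temperature anomaly missing for stock-year(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  }
  env$anom_t[idx]
}

#' Simulate increment widths from the log-scale mixed model
#'
#' Fills `width_um` for every increment using
#' `log(width) = b0 + b_age log(age)_c + b_age:NEA log(age)_c I(NEA) +
#'  b_TL TL_c + b_NEA I(NEA) + b_T AnomT + u_fish + v_stockyear + e`,
#' with mean-centered covariates (natural log; TL centered in metres) and
#' independent normal random components at the fish, stock-year and residual
#' levels.  Widths are exponentiated back to micrometres.
#'
#' @param panel an `otolith_panel` from [generate_cohort()].
#' @param params a [cohort_params()].
#' @param env temperature series covering every stock-year in the panel.
#' @param seed integer seed (defaults to `params$seed + 1`).
#' @return the panel with `width_um` filled.
#' @export
simulate_widths <- function(panel, params = attr(panel, "params"), env,
                            seed = params$seed + 1L) {
  stopifnot(inherits(panel, "otolith_panel"))
  set.seed(seed)
  ctr <- attr(panel, "centers")
  b <- params$width_beta
  v <- params$width_var
  nea <- as.numeric(panel$stock == "NEA")
  log_age_c <- log(panel$age) - ctr$log_age
  anomt <- lookup_anomt(panel, env)
  lp <- b[["intercept"]] + b[["log_age"]] * log_age_c +
    b[["log_age_nea"]] * log_age_c * nea +
    b[["tl"]] * tl_centered_m(panel) + b[["stock_nea"]] * nea +
    b[["anomt"]] * anomt
  fid <- factor(panel$fish_id)
  syid <- factor(paste(panel$stock, panel$year))
  u <- stats::rnorm(nlevels(fid), 0, sqrt(v[["tau_fish"]]))
  w <- stats::rnorm(nlevels(syid), 0, sqrt(v[["tau_stockyear"]]))
  e <- stats::rnorm(nrow(panel), 0, sqrt(v[["sigma2"]]))
  panel$width_um <- exp(lp + u[as.integer(fid)] + w[as.integer(syid)] + e)
  attr(panel, "width_ranef") <- list(fish = stats::setNames(u, levels(fid)),
                                     stockyear = stats::setNames(w, levels(syid)))
  panel
}

#' Simulate delta-13-C at milled increments from the mixed model
#'
#' Fills `d13c_permil` at milled ages using
#' `d13C = b0 + b_age8 I(age class 8) + b_age8:NEA + b_year Year_c +
#'  b_year:NEA Year_c I(NEA) + b_TL TL_c + b_NEA I(NEA) + u_fish +
#'  v_stockyear + e` with formation year centered at the panel's milled-row
#' mean.  The negative default year slope encodes the century-scale oceanic
#' Suess decline.  The residual SD includes the instrument measurement
#' component (`params$meas_sd`).
#'
#' @inheritParams simulate_widths
#' @return the panel with `d13c_permil` filled at milled increments.
#' @export
simulate_d13c_lmm <- function(panel, params = attr(panel, "params"),
                              seed = params$seed + 2L) {
  stopifnot(inherits(panel, "otolith_panel"))
  set.seed(seed)
  ctr <- attr(panel, "centers")
  b <- params$d13c_beta
  v <- params$d13c_var
  m <- panel$milled
  nea <- as.numeric(panel$stock[m] == "NEA")
  age8 <- as.numeric(milled_age_class(panel$age[m]) == "8")
  year_c <- panel$year[m] - ctr$year
  lp <- b[["intercept"]] + b[["age8"]] * age8 + b[["age8_nea"]] * age8 * nea +
    b[["year"]] * year_c + b[["year_nea"]] * year_c * nea +
    b[["tl"]] * tl_centered_m(panel)[m] + b[["stock_nea"]] * nea
  fid <- factor(panel$fish_id[m])
  syid <- factor(paste(panel$stock[m], panel$year[m]))
  u <- stats::rnorm(nlevels(fid), 0, sqrt(v[["tau_fish"]]))
  w <- stats::rnorm(nlevels(syid), 0, sqrt(v[["tau_stockyear"]]))
  e <- stats::rnorm(sum(m), 0, sqrt(v[["sigma2"]]))
  panel$d13c_permil[m] <- lp + u[as.integer(fid)] + w[as.integer(syid)] + e
  attr(panel, "d13c_ranef") <- list(fish = stats::setNames(u, levels(fid)),
                                    stockyear = stats::setNames(w, levels(syid)))
  panel
}

#' Per-stock isotope source configuration
#'
#' Mean and SD of the two carbon end members (diet and seawater DIC,
#' permil VPDB) per stock, and the total net fractionation offset epsilon.
#' Defaults are simulation defaults consistent with the literature ranges
#' for metabolic carbon (-20 to -17 permil) and DIC (0 to 2 permil).
#'
#' @param diet_mean,diet_sd named per-stock diet delta-13-C mean/SD.
#' @param dic_mean,dic_sd named per-stock DIC delta-13-C mean/SD.
#' @param epsilon total net fractionation offset (permil), default 2.7.
#' @return list of class `source_config`.
#' @export
source_config <- function(diet_mean = c(ICE = -18.5, NEA = -18.5),
                          diet_sd = c(ICE = 0.5, NEA = 0.5),
                          dic_mean = c(ICE = 1.0, NEA = 1.0),
                          dic_sd = c(ICE = 0.3, NEA = 0.3),
                          epsilon = 2.7) {
  stopifnot(all(diet_sd >= 0), all(dic_sd >= 0))
  if (any(diet_mean >= dic_mean[names(diet_mean)]))
    stop("diet source must be 13C-depleted relative to DIC (diet mean < DIC mean)")
  structure(list(diet_mean = diet_mean, diet_sd = diet_sd,
                 dic_mean = dic_mean, dic_sd = dic_sd, epsilon = epsilon),
            class = "source_config")
}

#' Simulate delta-13-C from the two-source mass balance
#'
#' For each milled increment the respired-carbon proportion is
#' `p = plogis(qlogis(cresp_truth[stock]) + u_fish + w_stockyear)` and
#' `d13C = p d13C_diet + (1 - p) d13C_DIC + epsilon + e`, with normal
#' components of the given SDs (logit scale for u, w; permil for e).
#' Sources enter at their configured means.  The generative per-record
#' proportions are kept in `attr(panel, "cresp_true")` for round-trip
#' checks.
#'
#' @param panel an `otolith_panel`.
#' @param sources a [source_config()].
#' @param cresp_truth named per-stock true global proportion, each in (0,1).
#' @param sd_fish,sd_year logit-scale SDs of fish and stock-year deviations.
#' @param noise_sd residual SD (permil).
#' @param seed integer seed.
#' @return the panel with `d13c_permil` filled at milled increments.
#' @export
simulate_d13c_mass_balance <- function(panel, sources, cresp_truth,
                                       sd_fish = 0.3, sd_year = 0.15,
                                       noise_sd = 0.3, seed = 1L) {
  stopifnot(inherits(panel, "otolith_panel"), inherits(sources, "source_config"))
  if (any(cresp_truth <= 0 | cresp_truth >= 1))
    stop("cresp_truth must be strictly inside (0, 1)")
  set.seed(seed)
  m <- panel$milled
  stock <- as.character(panel$stock[m])
  fid <- factor(panel$fish_id[m])
  syid <- factor(paste(stock, panel$year[m]))
  u <- stats::rnorm(nlevels(fid), 0, sd_fish)
  w <- stats::rnorm(nlevels(syid), 0, sd_year)
  p <- stats::plogis(stats::qlogis(cresp_truth[stock]) +
                       u[as.integer(fid)] + w[as.integer(syid)])
  delta <- p * sources$diet_mean[stock] + (1 - p) * sources$dic_mean[stock] +
    sources$epsilon + stats::rnorm(sum(m), 0, noise_sd)
  panel$d13c_permil[m] <- as.numeric(delta)
  cr <- rep(NA_real_, nrow(panel)); cr[m] <- p
  attr(panel, "cresp_true") <- cr
  panel
}

#' Build a 2x2 covariance matrix from SDs and a correlation
#' @param sd1,sd2 standard deviations.
#' @param r correlation in `[-1, 1]`.
#' @export
make_cov2 <- function(sd1, sd2, r = 0) {
  stopifnot(sd1 >= 0, sd2 >= 0, abs(r) <= 1)
  matrix(c(sd1^2, r * sd1 * sd2, r * sd1 * sd2, sd2^2), 2, 2)
}

#' Simulate a bivariate trait panel for correlation-recovery experiments
#'
#' Draws standardized bivariate traits (delta-13-C-like, log-width-like)
#' with correlated normal components at the residual, fish and year levels:
#' `y_i = u_fish(i) + w_year(i) + e_i`.  Each fish occupies a contiguous
#' run of `n_increments` formation years placed uniformly inside the year
#' window.  Optionally deletes a fraction of trait-1 values completely at
#' random to exercise missing-response augmentation.
#'
#' @param n_fish number of fish.
#' @param n_increments increments (rows) per fish.
#' @param n_years number of distinct formation years available.
#' @param Sigma_resid,Sigma_fish,Sigma_year 2x2 level covariance matrices
#'   (see [make_cov2()]).
#' @param missing_frac fraction of trait-1 values set missing (MCAR).
#' @param seed integer seed.
#' @return data frame `fish_id, year, y1, y2` with attribute `truth`.
#' @export
simulate_bivariate_traits <- function(n_fish = 400, n_increments = 10,
                                      n_years = 80,
                                      Sigma_resid = make_cov2(1, 1, 0),
                                      Sigma_fish = make_cov2(0.5, 0.5, 0),
                                      Sigma_year = make_cov2(0.3, 0.3, 0),
                                      missing_frac = 0, seed = 1L) {
  stopifnot(n_years >= n_increments)
  set.seed(seed)
  rmvn2 <- function(n, S) {
    L <- chol(S)
    matrix(stats::rnorm(2 * n), n, 2) %*% L
  }
  U <- rmvn2(n_fish, Sigma_fish)
  W <- rmvn2(n_years, Sigma_year)
  start <- sample.int(n_years - n_increments + 1L, n_fish, replace = TRUE)
  fish <- rep(seq_len(n_fish), each = n_increments)
  year <- start[fish] + rep(seq_len(n_increments) - 1L, times = n_fish)
  E <- rmvn2(n_fish * n_increments, Sigma_resid)
  Y <- U[fish, , drop = FALSE] + W[year, , drop = FALSE] + E
  y1 <- Y[, 1]
  if (missing_frac > 0)
    y1[stats::runif(length(y1)) < missing_frac] <- NA_real_
  out <- data.frame(fish_id = sprintf("F%04d", fish), year = year,
                    y1 = y1, y2 = Y[, 2], stringsAsFactors = FALSE)
  attr(out, "truth") <- list(Sigma_resid = Sigma_resid,
                             Sigma_fish = Sigma_fish,
                             Sigma_year = Sigma_year, U = U, W = W)
  out
}
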