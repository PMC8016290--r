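#' Suess-effect correction of otolith delta-13-C
#'
#' Removes the century-scale decline in seawater delta-13-C (oceanic Suess
#' effect) using the stock-specific linear year slope estimated by the
#' univariate delta-13-C model:
#' `corrected = observed - slope_stock * (year - reference_year)`.
#' By default the reference year is the most recent formation year carrying
#' a measurement, so corrected values are present-day equivalents; note the
#' reference year shifts all corrected values (and hence C_resp) by a
#' constant.
#'
#' @param panel an `otolith_panel` with delta-13-C filled.
#' @param slopes named per-stock slope (permil per year), e.g.
#'   `c(ICE = -0.007, NEA = -0.003)`; every stock present must be named.
#' @param reference_year reference calendar year (default: latest milled
#'   formation year in the panel).
#' @return panel with column `d13c_suess` and attribute `suess`.
#' @export
suess_correct <- function(panel, slopes, reference_year = NULL) {
  stopifnot(inherits(panel, "otolith_panel"))
  m <- panel$milled & !is.na(panel$d13c_permil)
  present <- unique(as.character(panel$stock[m]))
  if (!all(present %in% names(slopes)))
    stop("missing Suess slope for stock(s): ",
         paste(setdiff(present, names(slopes)), collapse = ", "))
  if (is.null(reference_year)) reference_year <- max(panel$year[m])
  panel$d13c_suess <- NA_real_
  panel$d13c_suess[m] <- panel$d13c_permil[m] -
    slopes[as.character(panel$stock[m])] * (panel$year[m] - reference_year)
  attr(panel, "suess") <- list(slopes = slopes,
                               reference_year = reference_year)
  panel
}

#' Predict seawater delta-13-C of DIC from apparent oxygen utilization
#'
#' Linear helper `d13C_DIC = a - b * AOU`; the regression coefficients must
#' be supplied by configuration (no literature defaults are asserted).
#'
#' @param aou apparent oxygen utilization values (umol/kg).
#' @param a intercept (permil).
#' @param b slope (permil per umol/kg), positive for the usual decrease of
#'   d13C_DIC with AOU.
#' @export
estimate_dic_from_aou <- function(aou, a, b) a - b * aou

#' Algebraic inversion of the two-source mass balance
#'
#' `p = (d13C_corrected - epsilon - d13C_DIC) / (d13C_diet - d13C_DIC)`
#' per record, with stock-specific source means.  Values outside [0, 1]
#' are returned as-is with an `out_of_range` attribute, never clipped.
#'
#' @param d13c_corrected numeric vector of Suess-corrected delta-13-C.
#' @param sources a [source_config()].
#' @param stock character vector of stock labels, recycled to the data.
#' @return numeric proportions with logical attribute `out_of_range`.
#' @export
cresp_invert <- function(d13c_corrected, sources, stock) {
  stopifnot(inherits(sources, "source_config"))
  stock <- rep_len(as.character(stock), length(d13c_corrected))
  diet <- sources$diet_mean[stock]
  dic <- sources$dic_mean[stock]
  if (any(abs(diet - dic) < 1e-12))
    stop("diet and DIC source means are equal: mixture unidentifiable")
  p <- as.numeric((d13c_corrected - sources$epsilon - dic) / (diet - dic))
  attr(p, "out_of_range") <- !is.na(p) & (p < 0 | p > 1)
  p
}

#' MCMC settings for the mixing model
#'
#' Defaults are the test-scale settings (10,000 iterations, 5,000 burn-in,
#' thinning 5, 2 chains); the full-scale analysis setting is
#' 100,000 / 50,000 / 50.
#'
#' @param iterations,burn_in,thinning,chains run-length settings.
#' @export
mixing_mcmc <- function(iterations = 10000L, burn_in = 5000L,
                        thinning = 5L, chains = 2L) {
  stopifnot(iterations > burn_in, thinning >= 1, chains >= 1)
  list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
       thinning = as.integer(thinning), chains = as.integer(chains))
}

# one chain of the hierarchical logit-link mixing sampler (one stock)
mixing_chain <- function(d, fi, yi, FN, YN, src, mcmc, seed, init_spread = 0) {
  set.seed(seed)
  dm <- src$diet; cm <- src$dic; ds2 <- src$diet_sd^2; cs2 <- src$dic_sd^2
  eps <- src$epsilon
  # method-of-moments start: algebraic inversion of the mean delta-13-C
  p_hat <- min(0.98, max(0.02, (mean(d) - eps - cm) / (dm - cm)))
  # log density up to an additive constant (constants cancel in MH ratios)
  ll_rows <- function(eta, sr) {
    p <- 1 / (1 + exp(-eta))
    mu <- p * dm + (1 - p) * cm + eps
    va <- sr * sr + p * p * ds2 + (1 - p) * (1 - p) * cs2
    -0.5 * (log(va) + (d - mu)^2 / va)
  }
  lp_sd <- function(s) stats::dnorm(s, 0, 1, log = TRUE) + log(2) + log(s)
  # state (overdispersed across chains through init_spread)
  alpha <- stats::qlogis(p_hat) + init_spread
  u <- numeric(FN); w <- numeric(YN)
  su <- 0.3; sw <- 0.15; sr <- 0.3
  steps <- c(alpha = 0.1, u = 0.3, w = 0.2, su = 0.3, sw = 0.3, sr = 0.2,
             shift_u = 0.1, shift_w = 0.1)
  acc <- steps * 0
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  keep <- list(alpha = numeric(n_keep), su = numeric(n_keep),
               sw = numeric(n_keep), sr = numeric(n_keep),
               w = matrix(NA_real_, n_keep, YN))
  kept <- 0L
  cur_ll <- ll_rows(alpha + u[fi] + w[yi], sr)
  for (it in seq_len(mcmc$iterations)) {
    # alpha
    a2 <- alpha + stats::rnorm(1, 0, steps["alpha"])
    new_ll <- ll_rows(a2 + u[fi] + w[yi], sr)
    if (log(stats::runif(1)) < sum(new_ll) - sum(cur_ll) +
        stats::dnorm(a2, 0, 10, log = TRUE) - stats::dnorm(alpha, 0, 10, log = TRUE)) {
      alpha <- a2; cur_ll <- new_ll; acc["alpha"] <- acc["alpha"] + 1
    }
    # fish deviations, element-wise in one vectorized pass
    u2 <- u + stats::rnorm(FN, 0, steps["u"])
    new_ll <- ll_rows(alpha + u2[fi] + w[yi], sr)
    dll <- rowsum(new_ll - cur_ll, fi, reorder = TRUE)[, 1] -
      0.5 * (u2 * u2 - u * u) / (su * su)
    ok <- log(stats::runif(FN)) < dll
    if (any(ok)) {
      u[ok] <- u2[ok]
      rows <- ok[fi]           # proposal rows of accepted fish are current
      cur_ll[rows] <- new_ll[rows]
      acc["u"] <- acc["u"] + mean(ok)
    }
    # year deviations
    w2 <- w + stats::rnorm(YN, 0, steps["w"])
    new_ll <- ll_rows(alpha + u[fi] + w2[yi], sr)
    dll <- rowsum(new_ll - cur_ll, yi, reorder = TRUE)[, 1] -
      0.5 * (w2 * w2 - w * w) / (sw * sw)
    ok <- log(stats::runif(YN)) < dll
    if (any(ok)) {
      w[ok] <- w2[ok]
      rows <- ok[yi]
      cur_ll[rows] <- new_ll[rows]
      acc["w"] <- acc["w"] + mean(ok)
    }
    # translation moves along the intercept/random-effect ridge: shifting
    # alpha and all deviations in opposite directions leaves the likelihood
    # unchanged, so acceptance depends on the priors only
    mshift <- stats::rnorm(1, 0, steps["shift_u"])
    if (log(stats::runif(1)) <
        stats::dnorm(alpha + mshift, 0, 10, log = TRUE) -
        stats::dnorm(alpha, 0, 10, log = TRUE) -
        0.5 * (sum((u - mshift)^2) - sum(u * u)) / (su * su)) {
      alpha <- alpha + mshift; u <- u - mshift
      acc["shift_u"] <- acc["shift_u"] + 1
    }
    mshift <- stats::rnorm(1, 0, steps["shift_w"])
    if (log(stats::runif(1)) <
        stats::dnorm(alpha + mshift, 0, 10, log = TRUE) -
        stats::dnorm(alpha, 0, 10, log = TRUE) -
        0.5 * (sum((w - mshift)^2) - sum(w * w)) / (sw * sw)) {
      alpha <- alpha + mshift; w <- w - mshift
      acc["shift_w"] <- acc["shift_w"] + 1
    }
    # SD hyperparameters (log-scale random walks, half-normal(1) priors)
    s2 <- su * exp(stats::rnorm(1, 0, steps["su"]))
    ssq_u <- sum(u * u)
    if (log(stats::runif(1)) < FN * log(su / s2) -
        0.5 * ssq_u * (1 / (s2 * s2) - 1 / (su * su)) + lp_sd(s2) - lp_sd(su)) {
      su <- s2; acc["su"] <- acc["su"] + 1
    }
    s2 <- sw * exp(stats::rnorm(1, 0, steps["sw"]))
    ssq_w <- sum(w * w)
    if (log(stats::runif(1)) < YN * log(sw / s2) -
        0.5 * ssq_w * (1 / (s2 * s2) - 1 / (sw * sw)) + lp_sd(s2) - lp_sd(sw)) {
      sw <- s2; acc["sw"] <- acc["sw"] + 1
    }
    s2 <- sr * exp(stats::rnorm(1, 0, steps["sr"]))
    new_ll <- ll_rows(alpha + u[fi] + w[yi], s2)
    if (log(stats::runif(1)) < sum(new_ll) - sum(cur_ll) + lp_sd(s2) - lp_sd(sr)) {
      sr <- s2; cur_ll <- new_ll; acc["sr"] <- acc["sr"] + 1
    }
    # step-size adaptation, frozen at the end of burn-in
    if (it <= mcmc$burn_in && it %% 50 == 0) {
      rate <- acc / 50
      steps[] <- pmin(5, pmax(0.01, steps * exp(rate - 0.3)))
      acc[] <- 0
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0) {
      kept <- kept + 1L
      keep$alpha[kept] <- alpha
      keep$su[kept] <- su; keep$sw[kept] <- sw; keep$sr[kept] <- sr
      keep$w[kept, ] <- w
    }
  }
  keep
}

#' Hierarchical Bayesian estimation of C_resp
#'
#' Two-source isotope mixing model with crossed fish and year random
#' effects, fitted separately per stock:
#' `d13C_i ~ Normal(p_i mu_diet + (1 - p_i) mu_DIC + epsilon,
#'  sigma_r^2 + p_i^2 sigma_diet^2 + (1 - p_i)^2 sigma_DIC^2)` with
#' `logit(p_i) = alpha_stock + u_fish(i) + w_year(i)`.  Source uncertainty
#' enters the likelihood variance analytically.  Priors: Normal(0, 10^2)
#' on the logit intercept, half-normal(1) on all SDs.  Sampling is
#' Metropolis-within-Gibbs with vectorized element-wise random-effect
#' updates, step-size adaptation during burn-in only, and `chains`
#' independent chains with overdispersed starts.  Split-chain Gelman-Rubin
#' and Geweke diagnostics are reported.
#'
#' @param panel an `otolith_panel` carrying Suess-corrected values in
#'   `d13c_col`, or a data frame with `fish_id`, `year`, `stock` and that
#'   column.
#' @param sources a [source_config()].
#' @param mcmc a [mixing_mcmc()] configuration.
#' @param seed integer seed (chain c of stock s uses a deterministic
#'   offset).
#' @param d13c_col column holding the corrected delta-13-C.
#' @param strict error (instead of flag) when R-hat exceeds 1.1.
#' @return named list (one `mixing_posterior` per stock); each has
#'   `draws` (data frame `cresp, alpha, sd_fish, sd_year, sd_resid`,
#'   chains stacked), `annual` (per-year posterior mean and SD of
#'   `plogis(alpha + w_year)`), `diagnostics` and `converged`.
#' @export
fit_mixing <- function(panel, sources, mcmc = mixing_mcmc(), seed = 1L,
                       d13c_col = "d13c_suess", strict = FALSE) {
  stopifnot(inherits(sources, "source_config"))
  df <- as.data.frame(panel)
  if (!d13c_col %in% names(df))
    stop("column ", d13c_col, " not found; run suess_correct() first")
  df <- df[!is.na(df[[d13c_col]]), c("fish_id", "year", "stock", d13c_col)]
  if (anyNA(df)) stop("records with missing stock, fish_id or year")
  out <- list()
  for (s in unique(as.character(df$stock))) {
    ds <- df[df$stock == s, ]
    fi <- as.integer(factor(ds$fish_id))
    yi <- as.integer(factor(ds$year))
    years <- sort(unique(ds$year))
    src <- list(diet = sources$diet_mean[[s]], diet_sd = sources$diet_sd[[s]],
                dic = sources$dic_mean[[s]], dic_sd = sources$dic_sd[[s]],
                epsilon = sources$epsilon)
    chains <- lapply(seq_len(mcmc$chains), function(cc)
      mixing_chain(ds[[d13c_col]], fi, yi, max(fi), max(yi), src, mcmc,
                   seed = seed + 1000L * match(s, c("ICE", "NEA"),
                                               nomatch = 3L) + cc,
                   init_spread = (cc - 1.5) * 1.0))
    alpha_all <- unlist(lapply(chains, `[[`, "alpha"))
    draws <- data.frame(
      cresp = stats::plogis(alpha_all), alpha = alpha_all,
      sd_fish = unlist(lapply(chains, `[[`, "su")),
      sd_year = unlist(lapply(chains, `[[`, "sw")),
      sd_resid = unlist(lapply(chains, `[[`, "sr")))
    w_all <- do.call(rbind, lapply(chains, `[[`, "w"))
    p_year <- stats::plogis(alpha_all + w_all)
    annual <- data.frame(stock = s, year = years,
                         mean = colMeans(p_year),
                         sd = apply(p_year, 2, stats::sd))
    diag_tab <- data.frame(
      parameter = c("alpha", "sd_fish", "sd_year", "sd_resid"),
      rhat = vapply(c("alpha", "su", "sw", "sr"), function(p)
        rhat(lapply(chains, `[[`, p)), 0),
      ess = vapply(c("alpha", "su", "sw", "sr"), function(p)
        sum(vapply(chains, function(ch) ess(ch[[p]]), 0)), 0),
      geweke_z = vapply(c("alpha", "su", "sw", "sr"), function(p)
        geweke_z(chains[[1]][[p]]), 0),
      row.names = NULL)
    converged <- all(diag_tab$rhat < 1.1)
    if (strict && !converged)
      stop("mixing model failed convergence for stock ", s,
           " (max R-hat ", round(max(diag_tab$rhat), 3), ")")
    out[[s]] <- structure(list(stock = s, draws = draws, annual = annual,
                               diagnostics = diag_tab, converged = converged,
                               n_fish = max(fi), n_years = max(yi),
                               mcmc = mcmc),
                          class = "mixing_posterior")
  }
  out
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("C_resp mixing posterior, stock ", x$stock, ": ",
      nrow(x$draws), " draws (", x$mcmc$chains, " chains)\n", sep = "")
  cat(sprintf("  global C_resp: %.3f (posterior SD %.3f)\n",
              mean(x$draws$cresp), stats::sd(x$draws$cresp)))
  cat("  converged:", x$converged,
      "| max R-hat:", round(max(x$diagnostics$rhat), 3), "\n")
  invisible(x)
}

#' Posterior stock difference in C_resp
#'
#' Draw-wise difference `C_resp(NEA) - C_resp(ICE)` on the proportion
#' scale; significant when the central 95% credible interval excludes 0.
#'
#' @param post_ice,post_nea `mixing_posterior` objects for the two stocks.
#' @return list `mean, lo, hi, significant, draws`.
#' @export
stock_difference <- function(post_ice, post_nea) {
  n <- min(nrow(post_ice$draws), nrow(post_nea$draws))
  dd <- post_nea$draws$cresp[seq_len(n)] - post_ice$draws$cresp[seq_len(n)]
  q <- stats::quantile(dd, c(0.025, 0.975), names = FALSE)
  list(mean = mean(dd), lo = q[1], hi = q[2],
       significant = q[1] > 0 | q[2] < 0, draws = dd)
}

#' Synchrony of annual C_resp series between stocks
#'
#' Pearson correlation of the posterior-mean annual C_resp across the
#' years common to both stocks, with the usual t-based two-sided p-value.
#'
#' @param series_ice,series_nea `annual` tables from [fit_mixing()] (or any
#'   data frames with `year` and `mean`).
#' @return list `r, p, n_years`.
#' @export
annual_synchrony <- function(series_ice, series_nea) {
  common <- intersect(series_ice$year, series_nea$year)
  if (length(common) < 3) stop("need at least 3 common years")
  x <- series_ice$mean[match(common, series_ice$year)]
  y <- series_nea$mean[match(common, series_nea$year)]
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_years = length(common))
}
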