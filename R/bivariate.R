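#' Standardize the bivariate otolith trait table
#'
#' Builds the two-response table used by the bivariate model from a panel:
#' trait 1 is delta-13-C (NA outside milled increments), trait 2 is the
#' natural log of increment width; both are z-scored over their non-missing
#' values with the sample SD (n-1 denominator).  Scaling constants are kept
#' as an attribute so values can be mapped back.
#'
#' @param panel an `otolith_panel`.
#' @return data frame `fish_id, stock, year, year_group, y1, y2` with
#'   attribute `scaling`; rows are the non-excluded increments.
#' @export
standardize_traits <- function(panel) {
  stopifnot(inherits(panel, "otolith_panel"))
  d <- panel[!panel$excluded, , drop = FALSE]
  if (all(is.na(d$d13c_permil))) stop("all delta-13-C values missing")
  if (all(is.na(d$width_um))) stop("all width values missing")
  lw <- log(d$width_um)
  sc <- list(m1 = mean(d$d13c_permil, na.rm = TRUE),
             s1 = stats::sd(d$d13c_permil, na.rm = TRUE),
             m2 = mean(lw, na.rm = TRUE),
             s2 = stats::sd(lw, na.rm = TRUE))
  out <- data.frame(fish_id = d$fish_id, stock = d$stock, year = d$year,
                    year_group = paste(d$stock, d$year),
                    y1 = (d$d13c_permil - sc$m1) / sc$s1,
                    y2 = (lw - sc$m2) / sc$s2,
                    tl_c = (d$tl_cm - attr(panel, "centers")$tl_cm) / 100,
                    log_age_c = log(d$age) - attr(panel, "centers")$log_age,
                    year_c = d$year - attr(panel, "centers")$year,
                    stringsAsFactors = FALSE)
  attr(out, "scaling") <- sc
  out
}

#' Destandardize trait values
#' @param z data frame or matrix with columns y1, y2 on the standardized
#'   scale.
#' @param scaling the `scaling` attribute from [standardize_traits()].
#' @return two-column matrix on the original (permil, log-um) scales.
#' @export
destandardize_traits <- function(z, scaling) {
  cbind(y1 = z[, "y1"] * scaling$s1 + scaling$m1,
        y2 = z[, "y2"] * scaling$s2 + scaling$m2)
}

#' Specify the bivariate Bayesian trait model
#'
#' @param fixed one of `"random_only"`, `"intrinsic"`,
#'   `"intrinsic_extrinsic"`: the fixed-effect set (intercept only;
#'   + stock, centered TL, centered log age; + centered year and
#'   temperature anomaly when available).
#' @param iterations,burn_in,thinning MCMC run length (defaults are the
#'   test-scale 12,000 / 2,000 / 10; the full-scale analysis setting is
#'   120,000 / 20,000 / 10).
#' @param prior_scale scale of the parameter-expansion working prior on
#'   standardized responses.
#' @param seed integer seed.
#' @return list of class `bivariate_spec`.
#' @export
bivariate_spec <- function(fixed = c("random_only", "intrinsic",
                                     "intrinsic_extrinsic"),
                           iterations = 12000L, burn_in = 2000L,
                           thinning = 10L, prior_scale = 1, seed = 1L) {
  fixed <- match.arg(fixed)
  stopifnot(iterations > burn_in, thinning >= 1)
  structure(list(fixed = fixed, iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 prior_scale = prior_scale, seed = as.integer(seed)),
            class = "bivariate_spec")
}

bivariate_design <- function(spec, data) {
  base <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (spec$fixed == "random_only") return(base)
  intr <- cbind(base,
                stockNEA = as.numeric(data$stock == "NEA"),
                tl_c = data$tl_c,
                log_age_c = data$log_age_c)
  if (spec$fixed == "intrinsic") return(intr)
  ext <- intr
  if (!is.null(data$year_c)) ext <- cbind(ext, year_c = data$year_c)
  if (!is.null(data$anom_t)) ext <- cbind(ext, anom_t = data$anom_t)
  ext
}

# closed-form 2x2 helpers: the sampler spends its time in tiny matrices,
# generic solve()/chol() dispatch dominates otherwise
inv2 <- function(M) {
  d <- M[1] * M[4] - M[2] * M[3]
  matrix(c(M[4], -M[2], -M[3], M[1]), 2, 2) / d
}
chol2u <- function(M) {
  l11 <- sqrt(M[1]); l12 <- M[3] / l11
  matrix(c(l11, 0, l12, sqrt(M[4] - l12^2)), 2, 2)
}
scale_cols2 <- function(M, a) cbind(M[, 1] * a[1], M[, 2] * a[2])

riwish2 <- function(nu, S) {
  # inverse-Wishart draw via rWishart on the inverse scale
  inv2(stats::rWishart(1, nu, inv2(S))[, , 1])
}

#' Fit the bivariate crossed random-intercept model by Gibbs sampling
#'
#' Native Gibbs sampler for
#' `y_i = X_i B + u_fish(i) + w_year(i) + e_i` with bivariate normal
#' components at the fish, year-group and residual levels.  The sweep
#' alternates (a) a matrix-normal draw of the fixed effects, (b) batched
#' conjugate draws of the fish and year random-effect vectors, (c)
#' inverse-Wishart updates of all three covariance matrices, with the fish
#' and year levels parameter-expanded through redundant per-trait scale
#' parameters (half-t style working prior, scale `prior_scale`), and (d)
#' conditional-normal data augmentation of missing trait-1 responses.
#' Every stored covariance draw is symmetric positive definite by
#' construction.
#'
#' @param spec a [bivariate_spec()].
#' @param data output of [standardize_traits()] or a data frame with
#'   `fish_id`, `year_group` (or `year`), `y1` (may contain NA), `y2`.
#' @return object of class `bivariate_posterior`: list with `Sigma`
#'   (draws x 3 x 3 array of v11, v22, c12 for levels resid/fish/year),
#'   `B` (draws x p x 2), `n_draws`, `spec`, `levels`.
#' @export
fit_bivariate <- function(spec, data) {
  stopifnot(inherits(spec, "bivariate_spec"))
  if (is.null(data$year_group)) data$year_group <- as.character(data$year)
  fid <- factor(data$fish_id)
  yid <- factor(data$year_group)
  if (nlevels(fid) < 2 || nlevels(yid) < 2)
    stop("need at least 2 levels per random factor")
  X <- bivariate_design(spec, data)
  # drop constant non-intercept columns (single-stock panels etc.)
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                            function(v) stats::var(v) > 0))
  X <- X[, keep_col, drop = FALSE]
  n <- nrow(data); p <- ncol(X)
  Y <- cbind(data$y1, data$y2)
  miss <- is.na(Y[, 1])
  if (any(is.na(Y[, 2]))) stop("trait 2 (log width) must be complete")
  Y[miss, 1] <- 0

  set.seed(spec$seed)
  XtX <- crossprod(X)
  Lx <- t(chol(solve(XtX)))
  fi <- as.integer(fid); yi <- as.integer(yid)
  FN <- nlevels(fid); YN <- nlevels(yid)
  nf <- tabulate(fi, FN); ny <- tabulate(yi, YN)
  # group row indices by replicate count so effect draws share one Cholesky
  fish_by_n <- split(seq_len(FN), nf)
  year_by_n <- split(seq_len(YN), ny)

  # state
  B <- matrix(0, p, 2)
  Xi_u <- matrix(0, FN, 2); a_u <- c(1, 1); Psi_u <- diag(2) * 0.5
  Xi_w <- matrix(0, YN, 2); a_w <- c(1, 1); Psi_w <- diag(2) * 0.5
  Sig_e <- diag(2)
  nu0 <- 3; S0 <- diag(2); A0 <- spec$prior_scale

  n_keep <- (spec$iterations - spec$burn_in) %/% spec$thinning
  Sig_draws <- array(NA_real_, c(n_keep, 3, 3),
                     dimnames = list(NULL, c("resid", "fish", "year"),
                                     c("v11", "v22", "c12")))
  B_draws <- array(NA_real_, c(n_keep, p, 2),
                   dimnames = list(NULL, colnames(X), c("y1", "y2")))
  kept <- 0L
  rejected <- 0L

  draw_level <- function(R, gi, G, by_n, alpha, Psi, Sig_e_inv) {
    # conjugate draw of expanded effects Xi given scale alpha
    D <- diag(alpha, 2)
    # rows of S are (Sig_e^-1 s_g)' with s_g the within-group residual sum
    S <- rowsum(R %*% Sig_e_inv, gi, reorder = TRUE)
    Xi <- matrix(0, G, 2)
    Pinv <- inv2(Psi)
    M <- D %*% Sig_e_inv %*% D
    for (cnt_chr in names(by_n)) {
      idx <- by_n[[cnt_chr]]
      cnt <- as.numeric(cnt_chr)
      Vp <- inv2(Pinv + cnt * M)
      mu <- S[idx, , drop = FALSE] %*% (D %*% Vp)
      Xi[idx, ] <- mu + matrix(stats::rnorm(2 * length(idx)),
                               length(idx), 2) %*% chol2u(Vp)
    }
    Xi
  }

  for (it in seq_len(spec$iterations)) {
    U <- scale_cols2(Xi_u, a_u)
    W <- scale_cols2(Xi_w, a_w)
    Uf <- U[fi, , drop = FALSE]; Wy <- W[yi, , drop = FALSE]
    mu_all <- X %*% B + Uf + Wy
    # (d) augment missing trait 1 from its conditional normal
    if (any(miss)) {
      s11 <- Sig_e[1, 1]; s12 <- Sig_e[1, 2]; s22 <- Sig_e[2, 2]
      cm <- mu_all[miss, 1] + (s12 / s22) * (Y[miss, 2] - mu_all[miss, 2])
      cv <- s11 - s12^2 / s22
      Y[miss, 1] <- cm + stats::rnorm(sum(miss), 0, sqrt(cv))
    }
    # (a) fixed effects, matrix-normal full conditional (flat prior)
    R <- Y - Uf - Wy
    Bhat <- solve(XtX, crossprod(X, R))
    B <- Bhat + Lx %*% matrix(stats::rnorm(2 * p), p, 2) %*% chol2u(Sig_e)
    XB <- X %*% B
    Ymb <- Y - XB
    Sig_e_inv <- inv2(Sig_e)
    # (b) fish effects (parameter-expanded)
    R_u <- Ymb - Wy
    Xi_u <- draw_level(R_u, fi, FN, fish_by_n, a_u, Psi_u, Sig_e_inv)
    # working scale alpha_u | Xi_u
    Zu <- Xi_u[fi, , drop = FALSE]
    Au <- diag(2) / A0^2 + Sig_e_inv * crossprod(Zu)
    bu <- colSums(Zu * (R_u %*% Sig_e_inv))
    Va <- inv2(Au)
    a_u <- as.numeric(Va %*% bu + t(chol2u(Va)) %*% stats::rnorm(2))
    Psi_u <- riwish2(nu0 + FN, S0 + crossprod(Xi_u))
    U <- scale_cols2(Xi_u, a_u)
    Uf <- U[fi, , drop = FALSE]
    # (b') year effects
    R_w <- Ymb - Uf
    Xi_w <- draw_level(R_w, yi, YN, year_by_n, a_w, Psi_w, Sig_e_inv)
    Zw <- Xi_w[yi, , drop = FALSE]
    Aw <- diag(2) / A0^2 + Sig_e_inv * crossprod(Zw)
    bw <- colSums(Zw * (R_w %*% Sig_e_inv))
    Vw <- inv2(Aw)
    a_w <- as.numeric(Vw %*% bw + t(chol2u(Vw)) %*% stats::rnorm(2))
    Psi_w <- riwish2(nu0 + YN, S0 + crossprod(Xi_w))
    W <- scale_cols2(Xi_w, a_w)
    Wy <- W[yi, , drop = FALSE]
    # (c) residual covariance
    E <- Ymb - Uf - Wy
    Se <- riwish2(nu0 + n, S0 * 0.1 + crossprod(E))
    if (!is.finite(Se[1]) || Se[1] <= 0 || Se[4] <= 0 ||
        Se[1] * Se[4] - Se[2]^2 <= 0) {
      rejected <- rejected + 1L
      if (rejected > 100) stop("excessive non-PD covariance updates (",
                               rejected, "); aborting")
    } else Sig_e <- Se

    if (it > spec$burn_in && (it - spec$burn_in) %% spec$thinning == 0) {
      kept <- kept + 1L
      Sig_u <- diag(a_u, 2) %*% Psi_u %*% diag(a_u, 2)
      Sig_w <- diag(a_w, 2) %*% Psi_w %*% diag(a_w, 2)
      Sig_draws[kept, "resid", ] <- c(Sig_e[1, 1], Sig_e[2, 2], Sig_e[1, 2])
      Sig_draws[kept, "fish", ]  <- c(Sig_u[1, 1], Sig_u[2, 2], Sig_u[1, 2])
      Sig_draws[kept, "year", ]  <- c(Sig_w[1, 1], Sig_w[2, 2], Sig_w[1, 2])
      B_draws[kept, , ] <- B
    }
  }
  structure(list(Sigma = Sig_draws, B = B_draws, n_draws = kept,
                 rejected = rejected, spec = spec,
                 levels = c("resid", "fish", "year")),
            class = "bivariate_posterior")
}

level_r_draws <- function(post, level) {
  S <- post$Sigma[, level, , drop = FALSE]
  S[, 1, "c12"] / sqrt(S[, 1, "v11"] * S[, 1, "v22"])
}

#' Level-wise correlation summaries
#'
#' Per posterior draw, `r = c12 / sqrt(v11 v22)` at each level; summarized
#' by the posterior mean and central 95% credible interval.  A correlation
#' is flagged significant when its credible interval excludes zero.
#'
#' @param post a `bivariate_posterior`.
#' @return data frame `level, mean, lo, hi, significant` with levels
#'   `within_individual` (residual), `between_individual` (fish),
#'   `between_year` (year-group).
#' @export
level_correlations <- function(post) {
  stopifnot(inherits(post, "bivariate_posterior"))
  lv <- c(within_individual = "resid", between_individual = "fish",
          between_year = "year")
  out <- lapply(names(lv), function(nm) {
    r <- level_r_draws(post, lv[[nm]])
    q <- stats::quantile(r, c(0.025, 0.975), names = FALSE)
    data.frame(level = nm, mean = mean(r), lo = q[1], hi = q[2],
               significant = q[1] > 0 | q[2] < 0)
  })
  do.call(rbind, out)
}

#' Correlation attribution across nested fixed-effect sets
#'
#' Fits the bivariate model under the three fixed-effect sets (random
#' effects only; + intrinsic; + intrinsic and extrinsic) and tabulates the
#' level-wise correlations.  A correlation is attributed to a factor set
#' when it is significant under the random-effects-only model but loses
#' significance once that set is included.
#'
#' @param data output of [standardize_traits()].
#' @param specs named list of three [bivariate_spec()] objects
#'   (`random_only`, `intrinsic`, `intrinsic_extrinsic`); defaults are
#'   test-scale specs sharing `seed`.
#' @param seed seed used when `specs` is NULL.
#' @return long data frame `model, level, mean, lo, hi, significant,
#'   attributed_to`.
#' @export
attribution_table <- function(data, specs = NULL, seed = 1L) {
  if (is.null(specs))
    specs <- list(
      random_only = bivariate_spec("random_only", seed = seed),
      intrinsic = bivariate_spec("intrinsic", seed = seed),
      intrinsic_extrinsic = bivariate_spec("intrinsic_extrinsic", seed = seed))
  rows <- lapply(names(specs), function(nm) {
    cs <- level_correlations(fit_bivariate(specs[[nm]], data))
    cs$model <- nm
    cs
  })
  tab <- do.call(rbind, rows)
  base <- tab[tab$model == "random_only", ]
  tab$attributed_to <- NA_character_
  for (lv in unique(tab$level)) {
    if (!base$significant[base$level == lv]) next
    for (nm in c("intrinsic", "intrinsic_extrinsic")) {
      row <- tab$level == lv & tab$model == nm
      if (any(row) && !tab$significant[row]) {
        tab$attributed_to[tab$level == lv & tab$model == "random_only"] <-
          if (nm == "intrinsic") "intrinsic" else "intrinsic+extrinsic"
        break
      }
    }
  }
  tab[, c("model", "level", "mean", "lo", "hi", "significant",
          "attributed_to")]
}

#' MCMC chain diagnostics for a bivariate posterior
#'
#' Lag autocorrelations, integrated autocorrelation time and effective
#' sample size (Geyer initial positive-sequence estimator) for the three
#' level correlations.
#'
#' @param post a `bivariate_posterior`.
#' @param ess_floor warn when any ESS falls below this value.
#' @return data frame `parameter, n_draws, ess, act, lag1`.
#' @export
mcmc_diagnostics <- function(post, ess_floor = 200) {
  stopifnot(inherits(post, "bivariate_posterior"))
  lv <- c(r_within = "resid", r_between_individual = "fish",
          r_between_year = "year")
  out <- lapply(names(lv), function(nm) {
    x <- level_r_draws(post, lv[[nm]])
    e <- ess(x)
    data.frame(parameter = nm, n_draws = length(x), ess = e,
               act = length(x) / e, lag1 = autocorr(x, 1))
  })
  tab <- do.call(rbind, out)
  if (any(tab$ess < ess_floor))
    warning("effective sample size below ", ess_floor, " for: ",
            paste(tab$parameter[tab$ess < ess_floor], collapse = ", "))
  tab
}
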