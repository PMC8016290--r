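#' Specify a univariate otolith trait model
#'
#' A model specification names the response (`"d13c"` or `"log_width"`),
#' an ordered set of fixed terms drawn from the workflow vocabulary
#' (`Stock`, `Sex`, `TL`, `Age`, `Age:Stock`, `TL:Stock`, `Age:Sex:Stock`,
#' `SZ`, `AnomT`, `AnomT:Stock`, `Year`, `Year:Stock`), a random structure
#' (subset of `fish`, `stock_year`) and the estimation criterion.
#' `Age` enters the delta-13-C model as a two-level milled-age-class factor
#' (reference age 3) and the width model as centered log age; covariates are
#' mean-centered with the constants stored on the panel (TL in metres).
#' Treatment coding uses Icelandic stock, age-class 3 and female as
#' reference levels.
#'
#' @param response `"d13c"` or `"log_width"`.
#' @param fixed character vector of fixed terms (may be empty: intercept
#'   only).  Interactions require their main effects.
#' @param random character subset of `c("fish", "stock_year")`.
#' @param method `"REML"` or `"ML"`.
#' @return list of class `lmm_spec`.
#' @export
lmm_spec <- function(response = c("d13c", "log_width"),
                     fixed = character(),
                     random = c("fish", "stock_year"),
                     method = c("REML", "ML")) {
  response <- match.arg(response)
  method <- match.arg(method)
  allowed <- c("Stock", "Sex", "TL", "Age", "Age:Stock", "TL:Stock",
               "Age:Sex:Stock", "SZ", "AnomT", "AnomT:Stock",
               "Year", "Year:Stock")
  if (length(fixed) && !all(fixed %in% allowed))
    stop("unknown fixed term(s): ",
         paste(setdiff(fixed, allowed), collapse = ", "))
  for (tm in fixed) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1 && !all(parts %in% fixed))
      stop("interaction ", tm, " requires main effects ",
           paste(setdiff(parts, fixed), collapse = ", "))
  }
  if (!all(random %in% c("fish", "stock_year")))
    stop("random terms must be a subset of fish, stock_year")
  structure(list(response = response, fixed = fixed, random = random,
                 method = method), class = "lmm_spec")
}

term_to_var <- function(term, response) {
  age_var <- if (response == "d13c") "age8" else "log_age_c"
  map <- c(Stock = "stock", Sex = "sex", TL = "tl_c", Age = age_var,
           SZ = "spawning_zone", AnomT = "anom_t", Year = "year_c")
  vapply(strsplit(term, ":", fixed = TRUE)[[1]],
         function(p) map[[p]], "", USE.NAMES = FALSE) |>
    paste(collapse = ":")
}

#' Build the model frame for a univariate trait model
#'
#' Subsets the panel to the rows carrying the response (milled increments
#' with delta-13-C, or non-excluded increments with widths), attaches
#' centered covariates using the panel's stored centering constants, and
#' joins stock-year temperature anomalies.  Rows with missing covariates
#' are dropped with a message.
#'
#' @param panel an `otolith_panel`.
#' @param env temperature series (only required when AnomT terms are used).
#' @param response `"d13c"` or `"log_width"`.
#' @return data frame ready for fitting.
#' @export
lmm_model_frame <- function(panel, env = NULL, response = "d13c") {
  ctr <- attr(panel, "centers")
  if (response == "d13c") {
    d <- panel[panel$milled & !is.na(panel$d13c_permil), , drop = FALSE]
    d$resp <- d$d13c_permil
    d$age8 <- factor(milled_age_class(d$age), levels = c("3", "8"))
  } else {
    d <- panel[!panel$excluded & !is.na(panel$width_um), , drop = FALSE]
    d$resp <- log(d$width_um)
    d$log_age_c <- log(d$age) - ctr$log_age
  }
  d$tl_c <- (d$tl_cm - ctr$tl_cm) / 100
  d$year_c <- d$year - ctr$year
  d$stock_year <- paste(d$stock, d$year)
  if (!is.null(env)) d$anom_t <- lookup_anomt(d, env)
  keep <- stats::complete.cases(d[, intersect(c("resp", "tl_c", "sex", "stock"),
                                              names(d))])
  if (any(!keep))
    message(sum(!keep), " rows with missing covariates dropped")
  droplevels(d[keep, , drop = FALSE])
}

#' Fit a crossed random-intercept mixed model for an otolith trait
#'
#' REML or ML estimation of the specified trait model with random
#' intercepts for fish and/or stock-year (profiled-deviance optimization
#' over the variance ratios with the fixed effects solved by generalized
#' least squares, as implemented in lme4).  Boundary variance estimates
#' are reported as 0 with a `boundary` flag; non-convergence is flagged,
#' not raised.
#'
#' @param spec an [lmm_spec()].
#' @param panel an `otolith_panel`.
#' @param env temperature series, if AnomT terms are used.
#' @return object of class `otolith_lmm` with elements `coefficients`
#'   (named vector), `varcomp` (`sigma2` plus `tau_*`), `logLik`, `n_obs`,
#'   `n_groups`, `converged`, `boundary`, `spec` and the underlying lme4
#'   `model`.
#' @export
fit_lmm <- function(spec, panel, env = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  d <- lmm_model_frame(panel, env, spec$response)
  for (tm in spec$random) {
    g <- if (tm == "fish") d$fish_id else d$stock_year
    if (length(unique(g)) < 2)
      stop("random term ", tm, " has fewer than 2 groups")
  }
  fixed_vars <- vapply(spec$fixed, term_to_var, "", response = spec$response)
  rhs <- if (length(fixed_vars)) paste(fixed_vars, collapse = " + ") else "1"
  # reject rank-deficient fixed designs up front, naming the aliased columns
  Xf <- tryCatch(
    stats::model.matrix(stats::as.formula(paste("~", rhs)), d),
    error = function(e) {
      const <- names(which(vapply(d[intersect(fixed_vars, names(d))],
                                  function(v) length(unique(v)) < 2, TRUE)))
      stop("singular fixed-effect design; collinear terms: ",
           if (length(const)) paste(const, collapse = ", ")
           else conditionMessage(e), call. = FALSE)
    })
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("singular fixed-effect design; collinear terms: ",
         paste(aliased, collapse = ", "))
  }
  ran <- c(fish = "(1 | fish_id)", stock_year = "(1 | stock_year)")[spec$random]
  form <- stats::as.formula(paste("resp ~", rhs, "+", paste(ran, collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = spec$method == "REML",
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- lme4::VarCorr(fit)
  tau <- c(fish = if ("fish_id" %in% names(vc)) as.numeric(vc$fish_id) else NULL,
           stock_year = if ("stock_year" %in% names(vc))
             as.numeric(vc$stock_year) else NULL)
  sigma2 <- stats::sigma(fit)^2
  boundary <- any(tau < 1e-8 * sigma2)
  conv <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  ng <- vapply(lme4::getME(fit, "flist"), nlevels, 0L)
  names(ng) <- c(fish_id = "fish", stock_year = "stock_year")[names(ng)]
  structure(list(
    coefficients = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    varcomp = c(sigma2 = sigma2, tau),
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d), n_groups = ng,
    converged = conv, boundary = boundary,
    spec = spec, formula = form, data = d, model = fit
  ), class = "otolith_lmm")
}

#' @export
print.otolith_lmm <- function(x, ...) {
  cat("Otolith trait mixed model (", x$spec$response, ", ", x$spec$method,
      ")\n", sep = "")
  cat("  n =", x$n_obs, "; groups:",
      paste(names(x$n_groups), x$n_groups, collapse = ", "), "\n")
  cat("  variance components:\n")
  print(round(x$varcomp, 4))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Assemble a fit object from published variance components
#'
#' Convenience constructor for arithmetic operations ([icc()],
#' [year_trend()]) on printed estimates when no data are at hand.
#'
#' @param sigma2 residual variance.
#' @param tau named vector of random-intercept variances
#'   (`fish`, `stock_year`).
#' @param coefficients optional named fixed-effect vector.
#' @export
lmm_components <- function(sigma2, tau, coefficients = NULL) {
  stopifnot(sigma2 >= 0, all(tau >= 0))
  structure(list(coefficients = coefficients,
                 varcomp = c(sigma2 = sigma2, tau)),
            class = "otolith_lmm_components")
}

varcomp_of <- function(fit) {
  if (inherits(fit, c("otolith_lmm", "otolith_lmm_components"))) return(fit$varcomp)
  stop("expected an otolith_lmm or lmm_components object")
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with `k` counting fixed
#' coefficients plus variance components (including the residual).
#'
#' @param fit an `otolith_lmm`, or a list with `logLik`, `k`, `n`.
#' @export
aicc <- function(fit) {
  if (inherits(fit, "otolith_lmm")) {
    if (!fit$converged) warning("AICc computed on a non-converged fit")
    ll <- fit$logLik
    k <- length(fit$coefficients) + length(fit$varcomp)
    n <- fit$n_obs
  } else {
    ll <- fit$logLik; k <- fit$k; n <- fit$n
  }
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Intraclass correlation coefficient of a random term
#'
#' `ICC(term) = tau_term / (sigma2 + sum of all tau)`.
#'
#' @param fit an `otolith_lmm` or [lmm_components()] object.
#' @param term `"fish"` or `"stock_year"`.
#' @export
icc <- function(fit, term) {
  v <- varcomp_of(fit)
  taus <- v[setdiff(names(v), "sigma2")]
  if (!term %in% names(taus)) stop("unknown random term: ", term)
  as.numeric(taus[[term]] / (v[["sigma2"]] + sum(taus)))
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-partition R2: marginal = var(X beta-hat) over the total
#' (fixed + random + residual) variance; conditional adds the random
#' intercept variances to the numerator.  `var(X beta-hat)` is the sample
#' variance of the fixed-effect linear predictor over the fitted data.
#'
#' @param fit an `otolith_lmm`.
#' @return named vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "otolith_lmm"))
  eta <- as.numeric(stats::model.matrix(fit$model) %*% fit$coefficients)
  vf <- stats::var(eta)
  v <- fit$varcomp
  tt <- sum(v[setdiff(names(v), "sigma2")])
  tot <- vf + tt + v[["sigma2"]]
  c(marginal = vf / tot, conditional = (vf + tt) / tot)
}

# Independent sparse REML log-likelihood used for Satterthwaite machinery.
# phi = log(c(sigma2, tau_1, ...)); V = sigma2 I + sum tau_k Z_k Z_k'.
reml_loglik_factory <- function(fit) {
  y <- fit$data$resp
  X <- stats::model.matrix(fit$model)
  Zt <- lme4::getME(fit$model, "Ztlist")
  n <- length(y); p <- ncol(X)
  ZZt <- lapply(Zt, function(z) Matrix::crossprod(z))
  function(phi, what = "loglik") {
    v <- exp(phi)
    V <- v[1] * Matrix::Diagonal(n)
    for (k in seq_along(ZZt)) V <- V + v[k + 1] * ZZt[[k]]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(V), LDL = FALSE)
    ldV <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    ViX <- as.matrix(Matrix::solve(V, X))
    XtViX <- crossprod(as.matrix(X), ViX)
    C <- solve(XtViX)
    if (what == "cbeta") return(C)
    beta <- C %*% crossprod(ViX, y)
    r <- y - X %*% beta
    quad <- sum(r * as.numeric(Matrix::solve(V, r)))
    ld2 <- determinant(XtViX)$modulus
    as.numeric(-0.5 * (ldV + ld2 + quad + (n - p) * log(2 * pi)))
  }
}

#' Per-coefficient tests with Satterthwaite degrees of freedom
#'
#' t statistics for each fixed-effect coefficient with denominator degrees
#' of freedom from the Satterthwaite approximation: the gradient of the
#' coefficient's sampling variance with respect to the log variance
#' components is combined with the observed-information covariance of
#' those components, both computed from an independently implemented
#' sparse REML log-likelihood (numerical derivatives).  95% confidence
#' intervals use the same df.  The intercept is omitted.
#'
#' @param fit a converged `otolith_lmm` (REML recommended).
#' @return data frame `term, estimate, se, df, t, p, ci_lo, ci_hi`.
#' @export
fixed_effect_tests <- function(fit) {
  stopifnot(inherits(fit, "otolith_lmm"))
  if (!fit$converged) stop("refusing to test a non-converged fit")
  beta <- fit$coefficients
  keep <- setdiff(names(beta), "(Intercept)")
  if (!length(keep))
    return(data.frame(term = character(), estimate = numeric(),
                      se = numeric(), df = numeric(), t = numeric(),
                      p = numeric(), ci_lo = numeric(), ci_hi = numeric()))
  ll <- reml_loglik_factory(fit)
  phi_hat <- log(pmax(fit$varcomp, 1e-8))
  # names(varcomp) order: sigma2, then taus in Ztlist order (fish_id, stock_year
  # as returned by lme4); align explicitly
  zt_names <- names(lme4::getME(fit$model, "Ztlist"))
  grp <- sub("\\.\\(Intercept\\)$", "", zt_names)
  tau_keys <- unname(c(fish_id = "fish", stock_year = "stock_year")[grp])
  if (anyNA(tau_keys)) stop("unrecognized random-effect factor(s): ",
                            paste(grp, collapse = ", "))
  phi_hat <- phi_hat[c("sigma2", tau_keys)]
  A <- tryCatch(solve(-numDeriv::hessian(function(ph) ll(ph), phi_hat)),
                error = function(e) NULL)
  C0 <- ll(phi_hat, what = "cbeta")
  # central-difference gradient of each diag(C) element w.r.t. phi
  h <- 1e-4
  G <- matrix(0, length(beta), length(phi_hat))
  for (j in seq_along(phi_hat)) {
    up <- phi_hat; up[j] <- up[j] + h
    dn <- phi_hat; dn[j] <- dn[j] - h
    G[, j] <- (diag(ll(up, what = "cbeta")) - diag(ll(dn, what = "cbeta"))) / (2 * h)
  }
  se <- sqrt(diag(C0))
  df <- vapply(seq_along(beta), function(i) {
    if (is.null(A)) return(fit$n_obs - length(beta))
    denom <- drop(t(G[i, ]) %*% A %*% G[i, ])
    if (denom <= 0) return(fit$n_obs - length(beta))
    max(1, 2 * diag(C0)[i]^2 / denom)
  }, 0)
  idx <- match(keep, names(beta))
  tval <- beta[idx] / se[idx]
  data.frame(term = keep, estimate = unname(beta[idx]), se = se[idx],
             df = df[idx], t = unname(tval),
             p = 2 * stats::pt(-abs(tval), df[idx]),
             ci_lo = unname(beta[idx] - stats::qt(0.975, df[idx]) * se[idx]),
             ci_hi = unname(beta[idx] + stats::qt(0.975, df[idx]) * se[idx]),
             row.names = NULL)
}

#' Stock-specific year trend of delta-13-C
#'
#' Slope for the requested stock (`beta_year` plus, for NEA, the
#' year-by-stock interaction) and the implied change per century.
#'
#' @param fit an `otolith_lmm` fitted with Year terms, or a named numeric
#'   vector with elements `year` and optionally `year_nea`.
#' @param stock `"ICE"` or `"NEA"`.
#' @return named vector `c(slope, per_century)`.
#' @export
year_trend <- function(fit, stock = c("ICE", "NEA")) {
  stock <- match.arg(stock)
  if (is.numeric(fit)) {
    slope <- fit[["year"]]
    if (stock == "NEA" && "year_nea" %in% names(fit))
      slope <- slope + fit[["year_nea"]]
  } else {
    beta <- fit$coefficients
    if (!"year_c" %in% names(beta)) stop("fit has no Year term")
    slope <- beta[["year_c"]]
    inter <- intersect(c("year_c:stockNEA", "stockNEA:year_c"), names(beta))
    if (stock == "NEA" && length(inter))
      slope <- slope + beta[[inter[1]]]
  }
  c(slope = slope, per_century = 100 * slope)
}

#' Two-phase AICc structure selection
#'
#' Phase 1 compares REML fits with the most complex candidate fixed
#' structure across the candidate random structures; phase 2 compares ML
#' fits of the candidate fixed structures under the selected random
#' structure; the winner is refitted with REML.  AICc ties closer than
#' 0.01 resolve to the model with fewer parameters.
#'
#' @param panel an `otolith_panel`.
#' @param env temperature series (if AnomT candidates appear).
#' @param response `"d13c"` or `"log_width"`.
#' @param random_candidates list of random-structure character vectors.
#' @param fixed_candidates list of fixed-term character vectors; the
#'   longest is used as the maximal structure in phase 1.
#' @return list with `spec` (selected, REML-refitted `otolith_lmm` in
#'   `fit`), and `table` (AICc ledger for every candidate).
#' @export
select_structure <- function(panel, env = NULL, response = "d13c",
                             random_candidates = list(c("fish", "stock_year"),
                                                      "fish", "stock_year"),
                             fixed_candidates) {
  if (!length(random_candidates) || !length(fixed_candidates))
    stop("empty candidate set")
  nterms <- vapply(fixed_candidates, length, 0L)
  maximal <- fixed_candidates[[which.max(nterms)]]
  ledger <- list()
  pick <- function(tab) {
    best <- min(tab$aicc)
    cand <- which(tab$aicc <= best + 0.01)
    cand[which.min(tab$k[cand])]
  }
  # phase 1: random structure under REML + maximal fixed structure
  p1 <- lapply(random_candidates, function(rn) {
    f <- fit_lmm(lmm_spec(response, maximal, rn, "REML"), panel, env)
    data.frame(phase = 1, random = paste(rn, collapse = "+"),
               fixed = paste(maximal, collapse = "+"),
               k = length(f$coefficients) + length(f$varcomp),
               aicc = aicc(f))
  })
  t1 <- do.call(rbind, p1)
  best_random <- random_candidates[[pick(t1)]]
  # phase 2: fixed structure under ML + selected random structure
  p2 <- lapply(fixed_candidates, function(fx) {
    f <- fit_lmm(lmm_spec(response, fx, best_random, "ML"), panel, env)
    data.frame(phase = 2, random = paste(best_random, collapse = "+"),
               fixed = paste(fx, collapse = "+"),
               k = length(f$coefficients) + length(f$varcomp),
               aicc = aicc(f))
  })
  t2 <- do.call(rbind, p2)
  best_fixed <- fixed_candidates[[pick(t2)]]
  final_spec <- lmm_spec(response, best_fixed, best_random, "REML")
  list(spec = final_spec, fit = fit_lmm(final_spec, panel, env),
       table = rbind(t1, t2))
}
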