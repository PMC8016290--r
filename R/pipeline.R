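#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are deterministic offsets.
#' @param scale `"demo"` (20-fish seeded fixture, short chains),
#'   `"study"` (study-design cohort, test-scale chains) or `"full"`
#'   (study cohort, publication-scale chains).
#' @param panel_csv,env_csv optional existing inputs; when NULL the
#'   synthesis stage generates them.
#' @param sources a [source_config()].
#' @param stages character subset of
#'   `c("synth", "fit", "covar", "cresp")`.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scale = c("demo", "study", "full"),
                            panel_csv = NULL, env_csv = NULL,
                            sources = source_config(),
                            stages = c("synth", "fit", "covar", "cresp")) {
  scale <- match.arg(scale)
  structure(list(out_dir = out_dir, seed = as.integer(seed), scale = scale,
                 panel_csv = panel_csv, env_csv = env_csv, sources = sources,
                 stages = stages), class = "run_config")
}

demo_params <- function(seed) {
  cohort_params(n_fish = c(ICE = 10L, NEA = 10L),
                span = list(ICE = c(2000L, 2009L), NEA = c(2000L, 2009L)),
                n_single_meas = 2L, seed = seed)
}

scale_mcmc <- function(scale) {
  switch(scale,
         demo = list(biv = bivariate_spec(iterations = 3000, burn_in = 1000,
                                          thinning = 5),
                     mix = mixing_mcmc(4000, 2000, 5, 2)),
         study = list(biv = bivariate_spec(), mix = mixing_mcmc()),
         full = list(biv = bivariate_spec(iterations = 120000,
                                          burn_in = 20000, thinning = 10),
                     mix = mixing_mcmc(100000, 50000, 50, 2)))
}

#' Run the full inference pipeline
#'
#' Executes synthesize -> univariate fits -> bivariate correlation
#' decomposition -> Suess correction (slopes taken from the delta-13-C
#' univariate fit) -> C_resp mixing model -> summary, writing every stage
#' output under `config$out_dir` and a manifest JSON with input/output
#' hashes, seeds and stage timings.  Outputs of each stage are readable by
#' the next with no manual step; a stage failure aborts with the stage
#' name while retaining earlier outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[otocarb] ", ...)
  manifest <- list(seed = config$seed, scale = config$scale,
                   stages = list(), files = list())
  t_all <- proc.time()[3]
  path <- function(f) file.path(config$out_dir, f)
  add_file <- function(f) {
    manifest$files[[basename(f)]] <<-
      list(path = f, md5 = unname(tools::md5sum(f)))
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    say("stage ", name, " ...")
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }
  mc <- scale_mcmc(config$scale)

  # --- synth ----------------------------------------------------------------
  if ("synth" %in% config$stages && is.null(config$panel_csv)) {
    run_stage("synth", function() {
      params <- if (config$scale == "demo") demo_params(config$seed)
                else cohort_params(seed = config$seed)
      panel <- generate_cohort(params)
      years <- seq(min(panel$year) - 1L, max(panel$year))
      env <- simulate_temperature(years, seed = config$seed + 10L)
      panel <- simulate_widths(panel, params, env)
      panel <- simulate_d13c_lmm(panel, params)
      write_panel(panel, path("panel.csv"))
      write_environment(env, path("environment.csv"))
      yaml::write_yaml(list(seed = params$seed,
                            n_fish = as.list(params$n_fish),
                            milled_ages = params$milled_ages,
                            d13c_var = as.list(params$d13c_var),
                            width_var = as.list(params$width_var)),
                       path("params.yaml"))
      invisible(NULL)
    })
    config$panel_csv <- path("panel.csv")
    config$env_csv <- path("environment.csv")
  }
  panel <- read_panel(config$panel_csv)
  env <- read_environment(config$env_csv)

  # --- univariate fits -------------------------------------------------------
  fits <- NULL
  if ("fit" %in% config$stages) {
    fits <- run_stage("fit", function() {
      d13c_spec <- lmm_spec("d13c",
                            c("Stock", "Age", "Age:Stock", "TL",
                              "Year", "Year:Stock"),
                            c("fish", "stock_year"), "REML")
      width_spec <- lmm_spec("log_width",
                             c("Stock", "Age", "Age:Stock", "TL", "AnomT"),
                             c("fish", "stock_year"), "REML")
      f1 <- fit_lmm(d13c_spec, panel, env)
      f2 <- fit_lmm(width_spec, panel, env)
      tab <- rbind(
        data.frame(response = "d13c", term = names(f1$coefficients),
                   estimate = unname(f1$coefficients)),
        data.frame(response = "log_width", term = names(f2$coefficients),
                   estimate = unname(f2$coefficients)))
      utils::write.csv(tab, path("univariate_estimates.csv"),
                       row.names = FALSE)
      bundle <- list(
        d13c = list(coefficients = as.list(f1$coefficients),
                    varcomp = as.list(f1$varcomp), aicc = aicc(f1),
                    icc = list(fish = icc(f1, "fish"),
                               stock_year = icc(f1, "stock_year")),
                    r2 = as.list(r2_nakagawa(f1)), n_obs = f1$n_obs),
        log_width = list(coefficients = as.list(f2$coefficients),
                         varcomp = as.list(f2$varcomp), aicc = aicc(f2),
                         icc = list(fish = icc(f2, "fish"),
                                    stock_year = icc(f2, "stock_year")),
                         r2 = as.list(r2_nakagawa(f2)), n_obs = f2$n_obs))
      jsonlite::write_json(bundle, path("univariate_fits.json"),
                           auto_unbox = TRUE, digits = NA)
      list(d13c = f1, width = f2)
    })
    add_file(path("univariate_estimates.csv"))
    add_file(path("univariate_fits.json"))
  }

  # --- bivariate decomposition ----------------------------------------------
  if ("covar" %in% config$stages) {
    run_stage("covar", function() {
      std <- standardize_traits(panel)
      specs <- list(
        random_only = bivariate_spec("random_only",
                                     iterations = mc$biv$iterations,
                                     burn_in = mc$biv$burn_in,
                                     thinning = mc$biv$thinning,
                                     seed = config$seed + 20L),
        intrinsic = bivariate_spec("intrinsic",
                                   iterations = mc$biv$iterations,
                                   burn_in = mc$biv$burn_in,
                                   thinning = mc$biv$thinning,
                                   seed = config$seed + 20L),
        intrinsic_extrinsic = bivariate_spec("intrinsic_extrinsic",
                                             iterations = mc$biv$iterations,
                                             burn_in = mc$biv$burn_in,
                                             thinning = mc$biv$thinning,
                                             seed = config$seed + 20L))
      tab <- attribution_table(std, specs)
      utils::write.csv(tab, path("correlation_decomposition.csv"),
                       row.names = FALSE)
      invisible(NULL)
    })
    add_file(path("correlation_decomposition.csv"))
  }

  # --- Suess correction + mixing --------------------------------------------
  if ("cresp" %in% config$stages) {
    summary_out <- run_stage("cresp", function() {
      if (is.null(fits))
        stop("cresp stage needs the univariate delta-13-C fit (enable 'fit')")
      slopes <- c(ICE = unname(year_trend(fits$d13c, "ICE")["slope"]),
                  NEA = unname(year_trend(fits$d13c, "NEA")["slope"]))
      panel2 <- suess_correct(panel, slopes)
      posts <- fit_mixing(panel2, config$sources, mcmc = mc$mix,
                          seed = config$seed + 30L)
      annual <- do.call(rbind, lapply(posts, `[[`, "annual"))
      utils::write.csv(annual, path("cresp_annual.csv"), row.names = FALSE)
      con <- gzfile(path("cresp_draws.csv.gz"), "w")
      utils::write.csv(do.call(rbind, lapply(posts, function(p)
        cbind(stock = p$stock, p$draws))), con, row.names = FALSE)
      close(con)
      summ <- list(suess = list(slopes = as.list(slopes),
                                reference_year =
                                  attr(panel2, "suess")$reference_year))
      for (s in names(posts))
        summ[[s]] <- list(cresp_mean = mean(posts[[s]]$draws$cresp),
                          cresp_sd = stats::sd(posts[[s]]$draws$cresp),
                          rhat_max = max(posts[[s]]$diagnostics$rhat),
                          geweke_max_abs =
                            max(abs(posts[[s]]$diagnostics$geweke_z)),
                          converged = posts[[s]]$converged)
      if (all(c("ICE", "NEA") %in% names(posts))) {
        sd_ <- stock_difference(posts$ICE, posts$NEA)
        summ$stock_difference <- sd_[c("mean", "lo", "hi", "significant")]
        sync <- tryCatch(annual_synchrony(posts$ICE$annual, posts$NEA$annual),
                         error = function(e) NULL)
        if (!is.null(sync)) summ$annual_synchrony <- sync
      }
      jsonlite::write_json(summ, path("cresp_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      summ
    })
    add_file(path("cresp_annual.csv"))
    add_file(path("cresp_summary.json"))
  }

  for (f in c("panel.csv", "environment.csv", "params.yaml"))
    if (file.exists(path(f))) add_file(path(f))
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in ", manifest$total_seconds, " s")
  invisible(manifest)
}
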