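#' Otolith increment panels
#'
#' An `otolith_panel` is a long-format data frame with one row per annual
#' otolith increment per fish, the canonical container moved between all
#' stages of the pipeline.  Columns:
#'
#' \describe{
#'   \item{fish_id}{character, unique fish identifier}
#'   \item{stock}{factor, `"ICE"` (Icelandic, reference level) or `"NEA"`
#'     (Northeast Arctic)}
#'   \item{sex}{factor `"F"`, `"M"`, `"UNKNOWN"`}
#'   \item{tl_cm}{total length at capture, cm}
#'   \item{age_at_capture}{integer, otolith age at capture (years)}
#'   \item{capture_year}{integer calendar year of capture}
#'   \item{age}{integer increment age, starting at 1}
#'   \item{year}{integer calendar year of increment formation;
#'     always `capture_year - (age_at_capture - age)`}
#'   \item{width_um}{increment width, micrometres (NA until simulated or
#'     measured)}
#'   \item{spawning_zone}{logical, increment visually classed as a spawning
#'     zone}
#'   \item{milled}{logical, increment milled for isotope analysis}
#'   \item{excluded}{logical, first/last increment excluded from width
#'     analysis (partial growth years)}
#'   \item{d13c_permil}{delta-13-C of the increment carbonate, permil VPDB;
#'     NA for unmilled increments}
#' }
#'
#' Centering constants shared between simulation and fitting are stored in
#' `attr(panel, "centers")`: `log_age` (mean of log increment age over
#' width-analysis rows), `tl_cm` (mean total length over fish) and `year`
#' (mean formation year over milled rows).  Storing them with the panel
#' guarantees that a model fitted to a simulated panel centers covariates
#' exactly as the generator did.
#'
#' @param df data frame with the columns above.
#' @param recompute_centers recompute centering constants from `df` (default
#'   TRUE when none are attached).
#' @return `as_otolith_panel()` returns a validated `otolith_panel`.
#' @export
as_otolith_panel <- function(df, recompute_centers = is.null(attr(df, "centers"))) {
  req <- c("fish_id", "stock", "sex", "tl_cm", "age_at_capture",
           "capture_year", "age", "year", "width_um", "spawning_zone",
           "milled", "excluded", "d13c_permil")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  df$fish_id <- as.character(df$fish_id)
  df$stock <- factor(as.character(df$stock), levels = c("ICE", "NEA"))
  df$sex <- factor(as.character(df$sex), levels = c("F", "M", "UNKNOWN"))
  centers <- attr(df, "centers")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_panel(df)
  if (recompute_centers) centers <- panel_centers(df)
  attr(df, "centers") <- centers
  class(df) <- c("otolith_panel", "data.frame")
  df
}

panel_centers <- function(df) {
  wrows <- !df$excluded
  fish <- !duplicated(df$fish_id)
  list(
    log_age = mean(log(df$age[wrows])),
    tl_cm   = mean(df$tl_cm[fish]),
    year    = mean(df$year[df$milled])
  )
}

validate_panel <- function(df) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("invalid panel: %s (first offending row %d of %d)",
                   what, idx[1], length(idx)), call. = FALSE)
  }
  bad(is.na(df$fish_id) | df$fish_id == "", "missing fish_id")
  bad(is.na(df$stock), "stock not one of ICE/NEA")
  bad(!is.na(df$tl_cm) & df$tl_cm <= 0, "non-positive total length")
  bad(df$age < 1 | df$age != round(df$age), "increment ages must be integers >= 1")
  bad(df$age > df$age_at_capture, "increment age exceeds age at capture")
  bad(df$year != df$capture_year - (df$age_at_capture - df$age),
      "formation year inconsistent with capture year and ages")
  bad(!is.na(df$width_um) & df$width_um <= 0, "non-positive increment width")
  bad(!df$milled & !is.na(df$d13c_permil), "d13c present on unmilled increment")
  key <- paste(df$fish_id, df$age)
  bad(duplicated(key), "duplicate (fish_id, age)")
  invisible(df)
}

#' Read / write otolith panels as CSV
#'
#' Fixed CSV dialect: UTF-8, header row, `.` decimal separator, empty string
#' for missing values.  Centering constants are carried in a sidecar JSON
#' file (`<path>.centers.json`) so a written panel round-trips exactly.
#'
#' @param path file path of the panel CSV.
#' @param panel an `otolith_panel`.
#' @return `read_panel()` returns an `otolith_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("spawning_zone", "milled", "excluded"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  centers_path <- paste0(path, ".centers.json")
  if (file.exists(centers_path))
    attr(df, "centers") <- jsonlite::read_json(centers_path, simplifyVector = TRUE)
  as_otolith_panel(df)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "otolith_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  centers <- attr(panel, "centers")
  if (!is.null(centers))
    jsonlite::write_json(centers, paste0(path, ".centers.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write per-stock annual temperature series
#'
#' Columns `stock`, `year`, `temp_c`, `anom_t`; one row per stock-year,
#' anomalies relative to the mean of that stock's series.
#'
#' @param env data frame with the columns above.
#' @param path CSV file path.
#' @export
write_environment <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_environment(env)
  env
}

validate_environment <- function(env) {
  req <- c("stock", "year", "temp_c", "anom_t")
  missing_cols <- setdiff(req, names(env))
  if (length(missing_cols))
    stop("environment series missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(paste(env$stock, env$year)))
    stop("environment series has duplicate stock-year rows")
  invisible(env)
}
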