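#' Read assessment data from CSV files
#'
#' `catch_file` must have columns `year,catch_t`; `indices_file` columns
#' `fleet,year,index`.
#'
#' @param catch_file,indices_file Paths to headered CSV files.
#' @return An [assessment_data()] object.
#' @export
read_assessment_data <- function(catch_file, indices_file) {
  for (f in c(catch_file, indices_file))
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
  ca <- read.csv(catch_file)
  if (!all(c("year", "catch_t") %in% names(ca)))
    stop(sprintf("%s: expected columns year,catch_t", catch_file))
  idx <- read.csv(indices_file)
  if (!all(c("fleet", "year", "index") %in% names(idx)))
    stop(sprintf("%s: expected columns fleet,year,index", indices_file))
  assessment_data(data.frame(year = ca$year, catch = ca$catch_t), idx)
}

#' Write assessment data as CSV files
#'
#' @param data An [assessment_data()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`catch.csv`, `indices.csv`).
#' @export
write_assessment_data <- function(data, dir) {
  if (!inherits(data, "assessment_data")) stop("'data' must be assessment_data")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- file.path(dir, "catch.csv")
  pi <- file.path(dir, "indices.csv")
  write.csv(data.frame(year = data$catch$year, catch_t = data$catch$catch),
            pc, row.names = FALSE)
  write.csv(data$indices, pi, row.names = FALSE)
  invisible(c(catch = pc, indices = pi))
}

#' Read an environmental covariate table
#'
#' @param file CSV with a `year` column and one column per covariate; one
#'   row per year, no missing years.
#' @return Data frame.
#' @export
read_env_table <- function(file) {
  if (!file.exists(file)) stop(sprintf("input file not found: %s", file))
  env <- read.csv(file, check.names = FALSE)
  if (!"year" %in% names(env)) stop(sprintf("%s: missing 'year' column", file))
  if (any(diff(env$year) != 1)) stop("environmental table has missing years")
  if (any(!vapply(env, function(x) all(is.finite(x)), logical(1))))
    stop("environmental table contains non-finite values")
  env
}

#' Serialize a fit as JSON
#'
#' Writes the fixed-effect estimates with intervals, the marginal
#' log-likelihood, parameter and observation counts, AICc and convergence
#' diagnostics.
#'
#' @param fit An [fit_spm()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "spm_fit")) stop("'fit' must be an spm_fit")
  x <- list(
    scenario = fit$scenario$name,
    shape = fit$shape$mode,
    loglik = fit$loglik,
    n_par = fit$n_par,
    n_obs = fit$n_obs,
    aicc = fit$aicc,
    converged = fit$converged,
    max_gradient = fit$max_gradient,
    estimates = fit$estimates
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
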