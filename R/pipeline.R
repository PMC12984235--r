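#' Simulate a synthetic study and write it to disk
#'
#' Runs the full generative process (population trajectory, fishery
#' observations, environmental table) and writes `catch.csv`,
#' `indices.csv`, `env.csv` and a `truth.json` sidecar with the generating
#' parameters and true annual reference points.
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @return Invisibly, a list with the trajectory, data and file paths.
#' @export
run_simulate <- function(out_dir, cfg = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_population(cfg)
  data <- observe(traj, cfg)
  paths <- write_assessment_data(data, out_dir)
  envt <- simulate_env_table(data$catch$year, seed = cfg$seed + 900007L)
  pe <- file.path(out_dir, "env.csv")
  write.csv(envt$env, pe, row.names = FALSE)
  truth <- list(
    config = list(years = cfg$years, dt = cfg$dt, shape = cfg$shape$mode,
                  scenario = cfg$scenario$name, m_bar = cfg$m_bar,
                  K_bar = cfg$K_bar, d0 = cfg$d0, sigma_B = cfg$sigma_B,
                  sigma_F = cfg$sigma_F, sigma_C = cfg$sigma_C,
                  sigma_I = cfg$sigma_I, q = cfg$q, seed = cfg$seed),
    true_refpoints = traj$true_refpoints
  )
  pt <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("simulated %d catch years, %d index series -> %s",
                  nrow(data$catch), length(unique(data$indices$fleet)), out_dir))
  invisible(list(trajectory = traj, data = data,
                 paths = c(paths, env = pe, truth = pt)))
}

#' Run the assessment over a set of scenarios and write results
#'
#' Fits every requested scenario, writes a per-scenario fit JSON, the
#' scenario comparison table (`comparison.csv`), per-year reference points
#' (`refpoints_<scenario>.csv`), stock status (`status_<scenario>.csv`)
#' and one-step-ahead residuals (`residuals_<scenario>.csv`).
#'
#' @param catch_file,indices_file Input CSVs (see
#'   [read_assessment_data()]).
#' @param out_dir Output directory.
#' @param scenarios Scenario names to fit.
#' @param shape A [production_shape()].
#' @param priors A [prior_spec()].
#' @param dt Euler step.
#' @param control An [spm_control()].
#' @param osa Also compute one-step-ahead residuals (default TRUE).
#' @return Invisibly, the [compare_scenarios()] result.
#' @export
run_assess <- function(catch_file, indices_file, out_dir,
                       scenarios = c("CM", "RM", "KM"),
                       shape = production_shape("schaefer"),
                       priors = prior_spec(), dt = 1 / 8,
                       control = spm_control(), osa = TRUE) {
  data <- read_assessment_data(catch_file, indices_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compare_scenarios(data, scenarios, shape, priors, dt, control)
  write.csv(cmp$table, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  any_ok <- FALSE
  for (s in scenarios) {
    f <- cmp$fits[[s]]
    if (inherits(f, "try-error")) next
    any_ok <- any_ok || f$converged
    write_fit_json(f, file.path(out_dir, sprintf("fit_%s.json", s)))
    if (!is.null(f$refpoints))
      write.csv(f$refpoints, file.path(out_dir, sprintf("refpoints_%s.csv", s)),
                row.names = FALSE)
    st <- try(stock_status(f), silent = TRUE)
    if (!inherits(st, "try-error"))
      write.csv(st, file.path(out_dir, sprintf("status_%s.csv", s)),
                row.names = FALSE)
    if (osa && f$converged) {
      res <- try(osa_residuals(f), silent = TRUE)
      if (!inherits(res, "try-error"))
        write.csv(res, file.path(out_dir, sprintf("residuals_%s.csv", s)),
                  row.names = FALSE)
    }
  }
  if (!any_ok) stop("no requested scenario converged")
  invisible(cmp)
}

#' Run the environmental-linkage analysis and write results
#'
#' VIF-screens the covariate table, then AIC-selects an additive model of
#' the annual productivity response on the retained covariates (year smooth
#' always included). Writes `vif_report.csv`, `model_ranking.csv` and
#' `effects.csv`.
#'
#' @param env_file Environmental table CSV.
#' @param response_file CSV with columns `year,m` (annual maximum net
#'   productivity, e.g. the `m` column written by [run_assess()]'s
#'   reference-point table for a time-varying scenario).
#' @param out_dir Output directory.
#' @param threshold VIF threshold (default 10).
#' @param k_default,k_year Basis dimensions for [select_model()].
#' @return Invisibly, a list with the `vif_report` and the selection
#'   result.
#' @export
run_envlink <- function(env_file, response_file, out_dir,
                        threshold = 10, k_default = 5, k_year = 3) {
  env <- read_env_table(env_file)
  resp <- read.csv(response_file)
  if (!all(c("year", "m") %in% names(resp)))
    stop(sprintf("%s: expected columns year,m", response_file))
  common <- intersect(resp$year, env$year)
  if (length(common) < 10) stop("insufficient annual observations (need >= 10)")
  env <- env[env$year %in% common, ]
  resp <- resp[resp$year %in% common, ]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  vr <- vif_screen(env, threshold = threshold)
  audit <- do.call(rbind, lapply(seq_along(vr$steps), function(i) {
    s <- vr$steps[[i]]
    data.frame(step = i, variable = names(s$vif), vif = unname(s$vif),
               removed = names(s$vif) %in% s$removed)
  }))
  write.csv(audit, file.path(out_dir, "vif_report.csv"), row.names = FALSE)

  sel <- select_model(resp, env, vr$retained,
                      k_default = k_default, k_year = k_year)
  write.csv(sel$ranking, file.path(out_dir, "model_ranking.csv"),
            row.names = FALSE)
  eff <- do.call(rbind, lapply(names(sel$best$curves), function(v)
    cbind(term = v, sel$best$curves[[v]])))
  write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)
  invisible(list(vif = vr, selection = sel))
}

#' Run a retrospective analysis and write the peel table
#'
#' @inheritParams run_assess
#' @param scenario Scenario to peel.
#' @param n_peels Number of terminal-year peels.
#' @return Invisibly, the [retrospective()] result.
#' @export
run_retro <- function(catch_file, indices_file, out_dir, scenario = "CM",
                      shape = production_shape("schaefer"),
                      priors = prior_spec(), dt = 1 / 8,
                      control = spm_control(), n_peels = 5) {
  data <- read_assessment_data(catch_file, indices_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rr <- retrospective(data, scenario, shape, priors, dt, control, n_peels)
  tab <- do.call(rbind, lapply(rr$peels, function(p)
    data.frame(peel = p$peel, converged = p$converged,
               B_terminal = p$B, F_terminal = p$F)))
  tab <- rbind(tab, data.frame(peel = NA, converged = NA,
                               B_terminal = rr$rho["B"],
                               F_terminal = rr$rho["F"]))
  write.csv(tab, file.path(out_dir, sprintf("retro_%s.csv", scenario)),
            row.names = FALSE)
  invisible(rr)
}
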