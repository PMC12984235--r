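#' Fitting options
#'
#' @param catch_error Model the catch with lognormal observation error and
#'   estimate its SD (default `TRUE`); if `FALSE` the catch SD is fixed at
#'   0.001 (catch treated as essentially exact).
#' @param f_dynamics Treat annual log fishing mortality as a latent random
#'   walk (default `TRUE`); if `FALSE`, `F_values` (per year, natural
#'   scale) must be supplied and F is held fixed.
#' @param F_values Known annual fishing mortalities when
#'   `f_dynamics = FALSE`.
#' @param est_psi_m,est_sigma_m,est_psi_K,est_sigma_K Estimate the OU
#'   hyper-parameters instead of fixing them at the values in
#'   [prior_spec()] (defaults `FALSE`, the fixed-at-0.2 convention).
#' @param fix Named list of parameters to fix at given values (full-length
#'   vectors for vector parameters), e.g.
#'   `list(logsdb = log(0.001), lambda = 1)`.
#' @param mean_correct Apply the lognormal mean correction `-sd^2/2` to
#'   observation means (default `TRUE`, matching the simulator).
#' @param report_refpoints Compute delta-method uncertainty for the annual
#'   reference-point series (default `TRUE`; turn off for speed in
#'   simulation studies).
#' @param se Run [TMB::sdreport()] after optimization (default `TRUE`).
#' @param grad_tol Gradient infinity-norm below which the outer optimum is
#'   declared converged (default 1e-3).
#' @param maxit Maximum outer iterations (default 500).
#' @return A list of class `spm_control`.
#' @export
spm_control <- function(catch_error = TRUE, f_dynamics = TRUE, F_values = NULL,
                        est_psi_m = FALSE, est_sigma_m = FALSE,
                        est_psi_K = FALSE, est_sigma_K = FALSE,
                        fix = list(), mean_correct = TRUE,
                        report_refpoints = TRUE, se = TRUE,
                        grad_tol = 1e-3, maxit = 500) {
  structure(list(catch_error = catch_error, f_dynamics = f_dynamics,
                 F_values = F_values,
                 est_psi_m = est_psi_m, est_sigma_m = est_sigma_m,
                 est_psi_K = est_psi_K, est_sigma_K = est_sigma_K,
                 fix = fix, mean_correct = mean_correct,
                 report_refpoints = report_refpoints, se = se,
                 grad_tol = grad_tol, maxit = maxit),
            class = "spm_control")
}

map_off <- function(len) factor(rep(NA, len))

tmb_inputs <- function(data, scenario, shape, priors, dt, control) {
  if (!inherits(data, "assessment_data"))
    data <- assessment_data(data$catch, data$indices)
  scenario <- check_scenario(scenario)
  check_shape(shape)
  nsub <- 1 / dt
  if (abs(nsub - round(nsub)) > 1e-8 || nsub < 1)
    stop("1/dt must be a positive integer")
  nsub <- as.integer(round(nsub))
  catch <- data$catch
  idx <- data$indices
  nyears <- nrow(catch)
  year0 <- catch$year[1]
  fleets <- sort(unique(idx$fleet))
  nq <- length(fleets)
  ns <- nyears * nsub

  # observation vector in time order: within a year, catch then indices
  ob <- rbind(
    data.frame(year = catch$year, type = 0L, fleet = -1L,
               value = catch$catch),
    data.frame(year = idx$year, type = 1L,
               fleet = match(idx$fleet, fleets) - 1L, value = idx$index)
  )
  ob <- ob[order(ob$year, ob$type, ob$fleet), ]

  tmbdat <- list(
    nyears = nyears, nsub = nsub,
    fox = as.integer(is_fox(shape)),
    scenario = scenario$code,
    d0 = priors$d0,
    f_dynamics = as.integer(control$f_dynamics),
    mean_correct = as.integer(control$mean_correct),
    report_ref = as.integer(control$report_refpoints),
    obsvec = log(ob$value),
    obstype = ob$type,
    obsyear = as.integer(ob$year - year0),
    obsfleet = as.integer(ob$fleet),
    prior_logr = c(priors$log_r_mean, priors$log_r_sd, as.numeric(priors$use_r)),
    prior_logK = c(priors$log_K_mean, priors$log_K_sd, as.numeric(priors$use_K)),
    prior_logalpha = c(0, priors$alpha_sd, as.numeric(priors$use_alpha)),
    prior_logbeta = c(0, priors$beta_sd,
                      as.numeric(priors$use_beta && control$catch_error &&
                                 control$f_dynamics))
  )

  # scale-aware starting values
  K0 <- max(catch$catch) * 10
  logq0 <- vapply(fleets, function(f)
    mean(log(idx$index[idx$fleet == f])) - log(priors$d0 * K0), numeric(1))
  logF0 <- log(pmin(pmax(catch$catch / (priors$d0 * K0), 1e-4), 2))
  if (!control$f_dynamics) {
    if (is.null(control$F_values) || length(control$F_values) != nyears)
      stop("f_dynamics = FALSE requires 'F_values', one per year")
    logF0 <- log(control$F_values)
  }
  pars <- list(
    logr = priors$log_r_mean, logK = log(K0), logn = log(2),
    logq = unname(logq0),
    logsdb = log(0.1), logsdf = log(0.1), logsdc = log(0.1),
    logsdi = rep(log(0.1), nq),
    logpsim = log(priors$psi_m), logsigm = log(max(priors$sigma_m, 1e-8)),
    logpsik = log(priors$psi_K), logsigk = log(max(priors$sigma_K, 1e-8)),
    lambda = scenario$lambda,
    logF = logF0,
    logB = rep(log(priors$d0 * K0), ns),
    Um = numeric(ns + 1), Uk = numeric(ns + 1)
  )

  um_active <- scenario$ou_m_active
  uk_active <- scenario$ou_K_active
  map <- list()
  if (shape$mode != "pella_tomlinson") map$logn <- map_off(1)
  if (!(um_active && control$est_psi_m)) map$logpsim <- map_off(1)
  if (!(um_active && control$est_sigma_m)) map$logsigm <- map_off(1)
  if (!(uk_active && control$est_psi_K)) map$logpsik <- map_off(1)
  if (!(uk_active && control$est_sigma_K)) map$logsigk <- map_off(1)
  if (scenario$name != "LKRM") map$lambda <- map_off(1)
  if (!control$catch_error) {
    pars$logsdc <- log(0.001)
    map$logsdc <- map_off(1)
  }
  if (!um_active) map$Um <- map_off(ns + 1)
  if (!uk_active) map$Uk <- map_off(ns + 1)
  if (!control$f_dynamics) {
    map$logF <- map_off(nyears)
    map$logsdf <- map_off(1)
  }
  for (nm in names(control$fix)) {
    if (!nm %in% names(pars)) stop(sprintf("unknown parameter '%s' in fix", nm))
    v <- control$fix[[nm]]
    if (length(v) != length(pars[[nm]]))
      stop(sprintf("fix$%s must have length %d", nm, length(pars[[nm]])))
    pars[[nm]] <- v
    map[[nm]] <- map_off(length(v))
  }

  random <- "logB"
  if (control$f_dynamics && is.null(control$fix$logF)) random <- c(random, "logF")
  if (um_active && is.null(control$fix$Um)) random <- c(random, "Um")
  if (uk_active && is.null(control$fix$Uk)) random <- c(random, "Uk")

  list(data = tmbdat, parameters = pars, map = map, random = random,
       fleets = fleets, year0 = year0, obs = ob, nyears = nyears,
       nsub = nsub, scenario = scenario, shape = shape, priors = priors)
}

#' Build the model objective
#'
#' Constructs the TMB objective of the state-space surplus production model:
#' by default the Laplace-marginalized negative log-likelihood over the
#' latent states (log-biomass on the Euler grid, annual log fishing
#' mortality, active OU deviation paths); with `joint = TRUE`, the joint
#' negative log-likelihood with the latents treated as free arguments.
#'
#' @param data An [assessment_data()] object.
#' @param scenario A [scenario_spec()] or scenario name.
#' @param shape A [production_shape()].
#' @param priors A [prior_spec()].
#' @param dt Euler step (default 1/8 yr).
#' @param control An [spm_control()].
#' @param joint If `TRUE`, return the joint (unmarginalized) objective.
#' @return A `TMB::MakeADFun` object (`fn`, `gr`, `par`, ...).
#' @export
spm_objective <- function(data, scenario = "CM",
                          shape = production_shape("schaefer"),
                          priors = prior_spec(), dt = 1 / 8,
                          control = spm_control(), joint = FALSE) {
  inp <- tmb_inputs(data, scenario, shape, priors, dt, control)
  obj <- TMB::MakeADFun(
    data = inp$data, parameters = inp$parameters, map = inp$map,
    random = if (joint) NULL else inp$random,
    DLL = "tvspm", silent = TRUE
  )
  attr(obj, "inputs") <- inp
  obj
}

#' Fit the state-space surplus production model
#'
#' Maximizes the Laplace-approximated marginal likelihood (latent states
#' integrated out) with [stats::nlminb()], then computes standard errors by
#' the delta method on the log scale via [TMB::sdreport()].
#'
#' @inheritParams spm_objective
#' @return An object of class `spm_fit` with elements `estimates` (data
#'   frame of fixed effects with 95% intervals), `loglik`, `n_par`,
#'   `n_obs`, `aicc`, `converged`, `max_gradient`, `latents` (smoothed
#'   paths with SDs), `refpoints` (annual reference-point series when
#'   `report_refpoints`), and the underlying `obj`, `opt`, `sdr`.
#' @examples
#' \donttest{
#' d <- observe(simulate_population(sim_config(seed = 1)))
#' fit <- fit_spm(d, scenario = "CM")
#' fit$estimates
#' }
#' @export
fit_spm <- function(data, scenario = "CM",
                    shape = production_shape("schaefer"),
                    priors = prior_spec(), dt = 1 / 8,
                    control = spm_control()) {
  obj <- spm_objective(data, scenario, shape, priors, dt, control)
  inp <- attr(obj, "inputs")
  # box constraints keeping weakly identified parameters in a numerically
  # safe region: coupling exponent lambda in [-1, 4] (below -1 productivity
  # would fall as carrying capacity rises — implausible and unstable under
  # the fixed OU volatility), shape n in [1.01, 14]
  lower <- rep(-Inf, length(obj$par))
  upper <- rep(Inf, length(obj$par))
  names(lower) <- names(upper) <- names(obj$par)
  lower[names(lower) == "lambda"] <- -1
  upper[names(upper) == "lambda"] <- 4
  lower[names(lower) == "logn"] <- log(1.01)
  upper[names(upper) == "logn"] <- log(14)
  if (length(obj$par) == 0) {
    # every fixed effect is fixed: pure state smoothing, nothing to optimize
    opt <- list(par = obj$par, objective = as.numeric(obj$fn(obj$par)),
                convergence = 0L)
  } else {
    opt <- nlminb(obj$par, obj$fn, obj$gr, lower = lower, upper = upper,
                  control = list(iter.max = control$maxit,
                                 eval.max = 2L * control$maxit))
  }
  # one polishing restart if the first pass stalled
  if (opt$convergence != 0) {
    opt2 <- try(nlminb(opt$par, obj$fn, obj$gr,
                       control = list(iter.max = control$maxit,
                                      eval.max = 2L * control$maxit)),
                silent = TRUE)
    if (!inherits(opt2, "try-error")) opt <- opt2
  }
  gr <- try(obj$gr(opt$par), silent = TRUE)
  max_grad <- if (inherits(gr, "try-error")) NA_real_ else {
    # projected gradient: directions blocked by an active box bound
    # cannot be improved and do not count against convergence
    g <- as.numeric(gr)
    g[opt$par <= lower + 1e-8 & g > 0] <- 0
    g[opt$par >= upper - 1e-8 & g < 0] <- 0
    if (length(g) == 0) 0 else max(abs(g))
  }

  sdr <- NULL
  pdhess <- NA
  estimates <- NULL
  if (control$se) {
    # near-boundary variance parameters yield benign NaN standard errors
    sdr <- try(suppressWarnings(TMB::sdreport(obj, getReportCovariance = FALSE)),
               silent = TRUE)
    if (inherits(sdr, "try-error")) {
      sdr <- NULL
    } else {
      pdhess <- isTRUE(sdr$pdHess)
      est <- sdr$par.fixed
      se <- suppressWarnings(sqrt(diag(sdr$cov.fixed)))
      nm <- names(est)
      natural <- ifelse(startsWith(nm, "log"), "exp", "id")
      point <- ifelse(natural == "exp", exp(est), est)
      lo <- ifelse(natural == "exp", exp(est - 1.96 * se), est - 1.96 * se)
      hi <- ifelse(natural == "exp", exp(est + 1.96 * se), est + 1.96 * se)
      pname <- sub("^log", "", nm)
      idx <- stats::ave(seq_along(nm), nm, FUN = seq_along)
      multi <- nm %in% nm[duplicated(nm)]
      pname[multi] <- paste0(pname[multi], idx[multi])
      estimates <- data.frame(parameter = pname, estimate = point,
                              se_log = se, lower = lo, upper = hi,
                              row.names = NULL)
    }
  }

  converged <- (opt$convergence == 0) &&
    (is.na(max_grad) || max_grad < control$grad_tol) &&
    (!control$se || isTRUE(pdhess))

  latents <- NULL
  if (!is.null(sdr)) {
    rs <- suppressWarnings(summary(sdr, "random"))
    latents <- lapply(unique(rownames(rs)), function(nm) {
      m <- rs[rownames(rs) == nm, , drop = FALSE]
      data.frame(estimate = m[, 1], sd = m[, 2], row.names = NULL)
    })
    names(latents) <- unique(rownames(rs))
  }

  n_obs <- nrow(inp$obs)
  n_par <- length(opt$par)
  loglik <- -opt$objective

  fit <- structure(list(
    obj = obj, opt = opt, sdr = sdr, inputs = inp,
    data = data, scenario = inp$scenario, shape = inp$shape,
    priors = inp$priors, dt = 1 / inp$nsub, control = control,
    estimates = estimates, latents = latents,
    loglik = loglik, n_par = n_par, n_obs = n_obs,
    aicc = if (n_obs > n_par + 1) aicc(loglik, n_par, n_obs) else NA_real_,
    converged = converged, max_gradient = max_grad,
    pd_hessian = pdhess
  ), class = "spm_fit")
  fit$refpoints <- if (control$report_refpoints && !is.null(sdr))
    reference_point_series(fit) else NULL
  fit
}

#' @export
print.spm_fit <- function(x, ...) {
  cat(sprintf("state-space surplus production fit: scenario %s, %s shape\n",
              x$scenario$name, x$shape$mode))
  cat(sprintf("  log-likelihood %.3f, %d fixed effects, %d observations, AICc %.2f\n",
              x$loglik, x$n_par, x$n_obs, x$aicc))
  cat(sprintf("  converged: %s (max |gradient| %.2e)\n",
              x$converged, x$max_gradient))
  if (!is.null(x$estimates)) {
    cat("\n")
    print(x$estimates, digits = 4)
  }
  invisible(x)
}

report_series <- function(fit, name) {
  sm <- summary(fit$sdr, "report")
  m <- sm[rownames(sm) == name, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  list(est = m[, 1], se = m[, 2])
}

#' Annual time-varying reference-point series
#'
#' Per-year maximum sustainable yield, F_MSY and B_MSY (with 95% intervals
#' by the delta method on the log scale) implied by the fitted annualized
#' productivity paths: MSY_t = m_t, B_MSY_t from K_t and the curve shape,
#' F_MSY_t = MSY_t / B_MSY_t.
#'
#' @param fit A converged [fit_spm()] result with `report_refpoints` on.
#' @return Data frame with columns `year`, `m`, `K`, `r`, `MSY`, `FMSY`,
#'   `BMSY` and `.lo` / `.hi` interval columns for the three reference
#'   points.
#' @export
reference_point_series <- function(fit) {
  if (!inherits(fit, "spm_fit")) stop("'fit' must be an spm_fit")
  if (is.null(fit$sdr)) stop("fit has no sdreport; refit with se = TRUE")
  years <- fit$data$catch$year
  get <- function(nm) report_series(fit, nm)
  msy_s <- get("logMSY_y"); fmsy_s <- get("logFmsy_y"); bmsy_s <- get("logBmsy_y")
  if (is.null(msy_s))
    stop("reference-point series not reported; refit with report_refpoints = TRUE")
  m_s <- get("logm_y"); K_s <- get("logK_y"); r_s <- get("logr_y")
  data.frame(
    year = years,
    m = exp(m_s$est), K = exp(K_s$est), r = exp(r_s$est),
    MSY = exp(msy_s$est),
    MSY.lo = exp(msy_s$est - 1.96 * msy_s$se),
    MSY.hi = exp(msy_s$est + 1.96 * msy_s$se),
    FMSY = exp(fmsy_s$est),
    FMSY.lo = exp(fmsy_s$est - 1.96 * fmsy_s$se),
    FMSY.hi = exp(fmsy_s$est + 1.96 * fmsy_s$se),
    BMSY = exp(bmsy_s$est),
    BMSY.lo = exp(bmsy_s$est - 1.96 * bmsy_s$se),
    BMSY.hi = exp(bmsy_s$est + 1.96 * bmsy_s$se),
    row.names = NULL
  )
}

#' Stock status relative to MSY reference points
#'
#' Annual ratios of biomass to B_MSY and fishing mortality to F_MSY
#' (smoothed latent paths over the year's reference points), with a Kobe
#' quadrant classification and a terminal-year summary.
#'
#' @param fit A converged [fit_spm()] result.
#' @return Data frame `year`, `BBmsy` (+ interval), `FFmsy` (+ interval),
#'   `status` in `{"sustainable", "overfished", "overfishing", "both"}`;
#'   the terminal-year row is attached as attribute `"terminal"`.
#' @export
stock_status <- function(fit) {
  if (!inherits(fit, "spm_fit")) stop("'fit' must be an spm_fit")
  if (!fit$converged) warning("stock status from a non-converged fit")
  bb <- report_series(fit, "logBBmsy")
  ff <- report_series(fit, "logFFmsy")
  if (is.null(bb))
    stop("status series not reported; refit with report_refpoints = TRUE")
  out <- data.frame(
    year = fit$data$catch$year,
    BBmsy = exp(bb$est),
    BBmsy.lo = exp(bb$est - 1.96 * bb$se),
    BBmsy.hi = exp(bb$est + 1.96 * bb$se),
    FFmsy = exp(ff$est),
    FFmsy.lo = exp(ff$est - 1.96 * ff$se),
    FFmsy.hi = exp(ff$est + 1.96 * ff$se)
  )
  out$status <- ifelse(out$BBmsy > 1 & out$FFmsy < 1, "sustainable",
                ifelse(out$BBmsy <= 1 & out$FFmsy >= 1, "both",
                ifelse(out$BBmsy <= 1, "overfished", "overfishing")))
  attr(out, "terminal") <- out[nrow(out), ]
  out
}
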