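#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2 p + 2 p (p + 1) / (n - p - 1)` with `p` the number
#' of free fixed effects (latent states are marginalized) and `n` the total
#' number of observations.
#'
#' @param loglik Marginal log-likelihood.
#' @param n_par Free fixed-effect count.
#' @param n_obs Observation count; must exceed `n_par + 1`.
#' @return The AICc value.
#' @examples
#' aicc(0, 2, 30) # 4 + 12/27
#' @export
aicc <- function(loglik, n_par, n_obs) {
  if (n_obs <= n_par + 1)
    stop("AICc undefined: n_obs must exceed n_par + 1")
  -2 * loglik + 2 * n_par + 2 * n_par * (n_par + 1) / (n_obs - n_par - 1)
}

#' Ljung-Box test of serial independence
#'
#' Portmanteau statistic
#' `Q = n (n + 2) sum_{k=1..L} rho_k^2 / (n - k)` referred to a chi-square
#' law with `L` degrees of freedom (computed via [stats::Box.test()]).
#' The default lag is `min(10, floor(n / 7))` (4 for a 30-point annual
#' series).
#'
#' @param x Ordered residual series.
#' @param n_lags Number of lags `L`; must be less than `length(x)`.
#' @return List with `statistic`, `p_value`, `n_lags`.
#' @export
ljung_box <- function(x, n_lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(n_lags)) n_lags <- min(10L, max(1L, n %/% 7L))
  if (n <= n_lags) stop("series length must exceed the number of lags")
  if (var(x) == 0) stop("zero-variance residuals")
  bt <- Box.test(x, lag = n_lags, type = "Ljung-Box")
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       n_lags = n_lags)
}

#' One-step-ahead residuals
#'
#' Standardized prediction residuals of each observation given all earlier
#' observations, computed by sequentially conditioning the fitted
#' state-space model with fixed effects frozen at their estimates
#' (via [TMB::oneStepPredict()]). Under a correctly specified model they
#' are approximately iid standard normal.
#'
#' The very first catch observation is conditioned on rather than
#' predicted: the initial fishing mortality is diffuse, so that
#' observation has no proper one-step predictive law.
#'
#' @param fit A converged [fit_spm()] result.
#' @param method Conditioning method passed to [TMB::oneStepPredict()]
#'   (default `"oneStepGaussianOffMode"`; `"oneStepGaussian"` is the
#'   slower reference implementation).
#' @return Data frame with columns `stream` (`"catch"` or the fleet id),
#'   `year`, `residual`, ordered in time within each stream.
#' @export
osa_residuals <- function(fit, method = "oneStepGaussianOffMode") {
  if (!inherits(fit, "spm_fit")) stop("'fit' must be an spm_fit")
  if (!fit$converged) stop("refusing to compute OSA residuals from a non-converged fit")
  cond <- which(fit$inputs$obs$type == 0L)[1]
  osa <- TMB::oneStepPredict(fit$obj, observation.name = "obsvec",
                             data.term.indicator = "keep",
                             method = method, conditional = cond,
                             trace = FALSE)
  ob <- fit$inputs$obs[-cond, , drop = FALSE]
  stream <- ifelse(ob$type == 0L, "catch", fit$inputs$fleets[ob$fleet + 1L])
  out <- data.frame(stream = stream, year = ob$year, residual = osa$residual)
  out[order(out$stream, out$year), , drop = FALSE]
}

#' Fit and compare several time-varying scenarios
#'
#' Fits each requested scenario to the same data and tabulates marginal
#' log-likelihood, parameter count and AICc.
#'
#' @param data An [assessment_data()] object.
#' @param scenarios Character vector of scenario names (default all six).
#' @param shape A [production_shape()].
#' @param priors A [prior_spec()].
#' @param dt Euler step.
#' @param control An [spm_control()].
#' @return List with `table` (data frame: scenario, loglik, n_par, AICc,
#'   dAICc, converged) and `fits` (named list of `spm_fit` objects).
#' @export
compare_scenarios <- function(data, scenarios = SCENARIOS,
                              shape = production_shape("schaefer"),
                              priors = prior_spec(), dt = 1 / 8,
                              control = spm_control()) {
  fits <- lapply(scenarios, function(s)
    try(fit_spm(data, scenario = s, shape = shape, priors = priors,
                dt = dt, control = control), silent = TRUE))
  names(fits) <- scenarios
  tab <- do.call(rbind, lapply(scenarios, function(s) {
    f <- fits[[s]]
    if (inherits(f, "try-error"))
      return(data.frame(scenario = s, loglik = NA, n_par = NA,
                        AICc = NA, converged = FALSE))
    data.frame(scenario = s, loglik = f$loglik, n_par = f$n_par,
               AICc = f$aicc, converged = f$converged)
  }))
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  list(table = tab, fits = fits)
}

#' Retrospective analysis
#'
#' Refits the model dropping 1..`n_peels` terminal years and computes
#' Mohn's rho for terminal biomass and fishing mortality: the mean over
#' peels of (peeled terminal estimate - full-fit estimate at that year) /
#' full-fit estimate.
#'
#' @inheritParams compare_scenarios
#' @param scenario Scenario to refit (single name or [scenario_spec()]).
#' @param n_peels Number of terminal years to drop (must leave at least
#'   6 years).
#' @return List with `rho` (named vector, `B` and `F`), `peels` (per-peel
#'   terminal-year estimates and convergence flags) and `full` (the
#'   full-data fit).
#' @export
retrospective <- function(data, scenario = "CM",
                          shape = production_shape("schaefer"),
                          priors = prior_spec(), dt = 1 / 8,
                          control = spm_control(), n_peels = 5) {
  if (!inherits(data, "assessment_data")) stop("'data' must be assessment_data")
  nyears <- nrow(data$catch)
  if (n_peels >= nyears - 5) stop("n_peels must be less than years - 5")
  annual_BF <- function(fit) {
    rep_ <- fit$obj$report(fit$obj$env$last.par.best)
    pl <- fit$obj$env$parList(par = fit$obj$env$last.par.best)
    list(B = rep_$Bbar, F = exp(pl$logF))
  }
  full <- fit_spm(data, scenario, shape, priors, dt, control)
  fb <- annual_BF(full)
  peels <- lapply(seq_len(n_peels), function(p) {
    keep_years <- data$catch$year[seq_len(nyears - p)]
    d <- assessment_data(data$catch[seq_len(nyears - p), ],
                         data$indices[data$indices$year %in% keep_years, ])
    f <- try(fit_spm(d, scenario, shape, priors, dt, control), silent = TRUE)
    if (inherits(f, "try-error"))
      return(list(peel = p, converged = FALSE, B = NA, F = NA))
    bf <- annual_BF(f)
    ny <- nyears - p
    list(peel = p, converged = f$converged,
         B = bf$B[ny], F = bf$F[ny],
         B_full = fb$B[ny], F_full = fb$F[ny])
  })
  ok <- vapply(peels, function(p) isTRUE(p$converged), logical(1))
  if (!all(ok))
    warning(sprintf("%d of %d peels failed to converge; rho uses the rest",
                    sum(!ok), n_peels))
  rel <- function(q)
    vapply(peels[ok], function(p) (p[[q]] - p[[paste0(q, "_full")]]) /
             p[[paste0(q, "_full")]], numeric(1))
  rho <- c(B = mean(rel("B")), F = mean(rel("F")))
  list(rho = rho, peels = peels, full = full)
}
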