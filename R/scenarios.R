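SCENARIOS <- c("CM", "RM", "KM", "PKRM", "LKRM", "IKRM")

#' Time-varying productivity scenario
#'
#' Defines which Ornstein-Uhlenbeck deviation processes are active and how
#' the deviations of maximum net productivity `G_t(m)` and carrying capacity
#' `G_t(K)` are coupled. The implied deviation of the intrinsic growth rate
#' is always `G_t(r) = G_t(m) / G_t(K)`.
#'
#' \describe{
#'   \item{CM}{Constant parameters: `G_t(r) = G_t(K) = 1`.}
#'   \item{RM}{`r` (through `m`) varies, `K` constant: OU on `log G_t(m)`.}
#'   \item{KM}{`K` varies, `r` constant: a single OU driver shared by
#'     `log G_t(m)` and `log G_t(K)`, so `G_t(r) = 1`.}
#'   \item{PKRM}{`r` and `K` vary proportionally: `G_t(r) = G_t(K)`, i.e.
#'     `log G_t(m) = 2 log G_t(K)` with one OU driver.}
#'   \item{LKRM}{Power-law coupling `G_t(r) = G_t(K)^lambda`, i.e.
#'     `log G_t(m) = (1 + lambda) log G_t(K)`; `lambda` is estimated
#'     (initial value 1) unless fixed. `lambda = 1` reproduces PKRM.}
#'   \item{IKRM}{Independent OU processes on `log G_t(m)` and `log G_t(K)`.}
#' }
#'
#' @param name Scenario name: CM, RM, KM, PKRM, LKRM or IKRM.
#' @param lambda Power-law exponent; only used by LKRM (default 1, the
#'   initial value for estimation and the value used in simulation).
#' @return An object of class `scenario_spec` with fields `name`,
#'   `ou_m_active`, `ou_K_active`, `coupling`, `lambda`, `code`.
#' @examples
#' scenario_spec("RM")
#' scenario_spec("LKRM", lambda = 1.5)
#' @export
scenario_spec <- function(name = SCENARIOS, lambda = 1) {
  name <- match.arg(name)
  code <- match(name, SCENARIOS) - 1L
  structure(list(
    name = name,
    ou_m_active = name %in% c("RM", "IKRM"),
    ou_K_active = name %in% c("KM", "PKRM", "LKRM", "IKRM"),
    coupling = switch(name,
      CM = "none", RM = "none", KM = "shared",
      PKRM = "proportional", LKRM = "power_law", IKRM = "independent"),
    lambda = lambda,
    code = code
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario %s (coupling: %s%s)\n", x$name, x$coupling,
              if (x$name == "LKRM") sprintf(", lambda = %g", x$lambda) else ""))
  invisible(x)
}

check_scenario <- function(x) {
  if (is.character(x)) x <- scenario_spec(x)
  if (!inherits(x, "scenario_spec")) stop("'scenario' must be a scenario_spec")
  x
}

#' Deviation coupling of a scenario
#'
#' Maps the active OU driver paths to the multiplicative deviations of
#' maximum net productivity and carrying capacity (log scale), mirroring the
#' coupling used inside the estimation engine.
#'
#' @param scenario A [scenario_spec()] or scenario name.
#' @param Um OU path for the m side (numeric vector; ignored if inactive).
#' @param Uk OU path for the K side (numeric vector; ignored if inactive).
#' @return List with `logGm` and `logGk` vectors.
#' @export
couple_deviations <- function(scenario, Um = NULL, Uk = NULL) {
  scenario <- check_scenario(scenario)
  nlen <- max(length(Um), length(Uk), 1L)
  z <- numeric(nlen)
  switch(scenario$name,
    CM   = list(logGm = z, logGk = z),
    RM   = list(logGm = Um, logGk = numeric(length(Um))),
    KM   = list(logGm = Uk, logGk = Uk),
    PKRM = list(logGm = 2 * Uk, logGk = Uk),
    LKRM = list(logGm = (1 + scenario$lambda) * Uk, logGk = Uk),
    IKRM = list(logGm = Um, logGk = Uk)
  )
}

#' Prior specification for the fixed effects
#'
#' Log-normal priors on the intrinsic growth rate and carrying capacity,
#' plus the fixed initial depletion and the OU hyper-parameters (held at
#' 0.2 by default).
#'
#' @param log_r_mean,log_r_sd Normal prior on `log r` (default
#'   `log(0.49)`, sd 0.2).
#' @param log_K_mean,log_K_sd Normal prior on `log K` in tonnes (default
#'   `log(11230000)`, sd 0.5).
#' @param use_r,use_K Logical; include the respective prior in the
#'   objective.
#' @param d0 Initial depletion `B0 / K`, fixed (default 0.46).
#' @param psi_m,sigma_m,psi_K,sigma_K OU mean-reversion rates and diffusion
#'   SDs, fixed at 0.2 unless estimation is requested via [spm_control()].
#' @param alpha_sd,use_alpha Weakly informative normal prior, SD
#'   `alpha_sd` around 0, on each `log(sdi_f / sdb)` — the standard
#'   stabilizer of the observation/process noise decomposition (default
#'   on, SD 2).
#' @param beta_sd,use_beta The analogous weak prior on
#'   `log(sdc / sdf)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(log_r_mean = log(0.49), log_r_sd = 0.2,
                       log_K_mean = log(11230000), log_K_sd = 0.5,
                       use_r = TRUE, use_K = TRUE, d0 = 0.46,
                       psi_m = 0.2, sigma_m = 0.2,
                       psi_K = 0.2, sigma_K = 0.2,
                       alpha_sd = 2, use_alpha = TRUE,
                       beta_sd = 2, use_beta = TRUE) {
  stopifnot(log_r_sd > 0, log_K_sd > 0, d0 > 0, d0 <= 1,
            psi_m > 0, sigma_m >= 0, psi_K > 0, sigma_K >= 0,
            alpha_sd > 0, beta_sd > 0)
  structure(list(log_r_mean = log_r_mean, log_r_sd = log_r_sd,
                 log_K_mean = log_K_mean, log_K_sd = log_K_sd,
                 use_r = use_r, use_K = use_K, d0 = d0,
                 psi_m = psi_m, sigma_m = sigma_m,
                 psi_K = psi_K, sigma_K = sigma_K,
                 alpha_sd = alpha_sd, use_alpha = use_alpha,
                 beta_sd = beta_sd, use_beta = use_beta),
            class = "prior_spec")
}
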