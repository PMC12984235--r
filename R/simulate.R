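#' Simulation configuration
#'
#' Defines the generative process emulated by the synthetic-data module: a
#' 30-year annual fishery (catch plus four fleet-specific CPUE indices) on a
#' stock whose biomass follows the stochastic surplus production equation,
#' with optional OU variation in maximum net productivity and carrying
#' capacity. Defaults emulate the western and central Pacific yellowfin
#' tuna setting: mean carrying capacity 11.23 million t, intrinsic growth
#' rate 0.49 / yr, initial depletion 0.46, Euler step 1/8 yr, and a one-way
#' trip in fishing mortality over 1992-2021.
#'
#' @param years Number of assessment years (default 30).
#' @param year0 First calendar year (default 1992).
#' @param dt Euler step in years; `1/dt` must be a positive integer
#'   (default 1/8).
#' @param shape A [production_shape()] (default Schaefer).
#' @param K_bar Mean carrying capacity, tonnes (default 11.23e6).
#' @param m_bar Mean maximum net productivity, tonnes/yr; default derived
#'   from `r_bar` and `K_bar` under `shape`.
#' @param r_bar Convenience: mean intrinsic growth rate used to derive the
#'   default `m_bar` (default 0.49).
#' @param scenario A [scenario_spec()] controlling time variation
#'   (default CM, no variation).
#' @param psi_m,sigma_m,psi_K,sigma_K OU parameters of the active deviation
#'   processes (defaults 0.2, the moderately persistent setting).
#' @param lambda Power-law coupling exponent for LKRM simulation (default 1).
#' @param sigma_B Biomass process SD (default 0.05).
#' @param sigma_F Annual log-F random-walk SD (default 0.1).
#' @param F_init Initial fishing mortality, 1/yr (default 0.05).
#' @param F_drift Deterministic annual drift of log F (default 0.05,
#'   producing a one-way trip from 0.05 to roughly 0.21 over 30 years —
#'   ending just below F_MSY, so the emulated stock finishes in the
#'   sustainable Kobe quadrant like the assessed population).
#' @param n_fleets Number of CPUE fleets (default 4).
#' @param q Catchability per fleet (index units per tonne); length
#'   `n_fleets`.
#' @param sigma_I Index observation SD per fleet (default 0.2 each).
#' @param sigma_C Catch observation SD (default 0.05).
#' @param d0 Initial depletion B0/K (default 0.46).
#' @param index_timing `"mean"` (indices observe the annual mean of biomass
#'   on the grid; default) or `"start"` (start-of-year snapshot).
#' @param index_gaps Optional list of per-fleet year vectors to drop from
#'   the index series (gaps).
#' @param logGm_custom Optional vector of annual log-deviations of m
#'   (length `years + 1`, linearly interpolated onto the grid) overriding
#'   the OU draw on the m side; used to plant a known environmental signal.
#' @param seed Integer seed; the full simulation is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(years = 30, year0 = 1992, dt = 1 / 8,
                       shape = production_shape("schaefer"),
                       K_bar = 11.23e6, m_bar = NULL, r_bar = 0.49,
                       scenario = scenario_spec("CM"),
                       psi_m = 0.2, sigma_m = 0.2,
                       psi_K = 0.2, sigma_K = 0.2, lambda = 1,
                       sigma_B = 0.05, sigma_F = 0.1,
                       F_init = 0.05, F_drift = 0.05,
                       n_fleets = 4, q = c(0.5, 1, 2, 4)[seq_len(n_fleets)] * 1e-6,
                       sigma_I = rep(0.2, n_fleets), sigma_C = 0.05,
                       d0 = 0.46,
                       index_timing = c("mean", "start"),
                       index_gaps = NULL,
                       logGm_custom = NULL,
                       seed = 1L) {
  check_shape(shape)
  scenario <- check_scenario(scenario)
  index_timing <- match.arg(index_timing)
  nsub <- 1 / dt
  if (abs(nsub - round(nsub)) > 1e-8 || nsub < 1)
    stop("1/dt must be a positive integer")
  if (years < 2) stop("'years' must be at least 2")
  if (length(q) != n_fleets || any(q <= 0))
    stop("'q' must be positive, one value per fleet")
  if (length(sigma_I) == 1) sigma_I <- rep(sigma_I, n_fleets)
  if (length(sigma_I) != n_fleets) stop("'sigma_I' must have one value per fleet")
  stopifnot(sigma_B >= 0, sigma_F >= 0, sigma_C >= 0, all(sigma_I >= 0),
            d0 > 0, d0 <= 1, F_init > 0, K_bar > 0)
  if (is.null(m_bar)) m_bar <- m_from_r(r_bar, K_bar, shape)
  if (!is.null(logGm_custom) && length(logGm_custom) != years + 1)
    stop("'logGm_custom' must have length years + 1 (annual knots)")
  structure(list(
    years = years, year0 = year0, dt = dt, nsub = as.integer(round(nsub)),
    shape = shape, K_bar = K_bar, m_bar = m_bar,
    scenario = scenario,
    psi_m = psi_m, sigma_m = sigma_m, psi_K = psi_K, sigma_K = sigma_K,
    lambda = lambda,
    sigma_B = sigma_B, sigma_F = sigma_F,
    F_init = F_init, F_drift = F_drift,
    n_fleets = n_fleets, q = q, sigma_I = sigma_I, sigma_C = sigma_C,
    d0 = d0, index_timing = index_timing, index_gaps = index_gaps,
    logGm_custom = logGm_custom, seed = as.integer(seed)
  ), class = "sim_config")
}

trapz_year <- function(x, nsub, years) {
  # per-year trapezoid mean of a grid series of length years*nsub + 1
  vapply(seq_len(years), function(y) {
    i <- ((y - 1) * nsub + 1):(y * nsub + 1)
    v <- x[i]
    (sum(v) - (v[1] + v[length(v)]) / 2) / nsub
  }, numeric(1))
}

#' Simulate the latent population trajectory
#'
#' Euler-Maruyama integration of log-biomass under the stochastic surplus
#' production equation (Ito-corrected drift, guaranteeing positivity), with
#' OU deviation paths drawn by the exact transition and an annual log-scale
#' random walk (with drift) for fishing mortality, constant within each
#' year.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `spm_trajectory`: the time grid, biomass `B`,
#'   per-step fishing mortality `F` and annual `F_year`, the deviation
#'   paths `logGm` / `logGk`, the derived `m_t`, `K_t`, `r_t` paths, and
#'   `true_refpoints`, a per-year data frame of MSY, F_MSY, B_MSY and the
#'   status ratios implied by the simulated truth.
#' @examples
#' traj <- simulate_population(sim_config(seed = 7))
#' @export
simulate_population <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("'cfg' must be a sim_config")
  set.seed(cfg$seed)
  years <- cfg$years; nsub <- cfg$nsub; dt <- cfg$dt
  ns <- years * nsub
  grid <- seq(0, years, by = dt)
  scen <- cfg$scenario

  Um <- Uk <- numeric(ns + 1)
  if (scen$ou_m_active)
    Um <- simulate_ou(ou_spec(cfg$psi_m, cfg$sigma_m), grid)$values
  if (scen$ou_K_active)
    Uk <- simulate_ou(ou_spec(cfg$psi_K, cfg$sigma_K), grid)$values
  scen$lambda <- cfg$lambda
  dev <- couple_deviations(scen, Um = Um, Uk = Uk)
  logGm <- dev$logGm; logGk <- dev$logGk
  if (length(logGm) != ns + 1) logGm <- numeric(ns + 1)
  if (length(logGk) != ns + 1) logGk <- numeric(ns + 1)
  if (!is.null(cfg$logGm_custom))
    logGm <- approx(0:years, cfg$logGm_custom, xout = grid)$y

  m_t <- cfg$m_bar * exp(logGm)
  K_t <- cfg$K_bar * exp(logGk)
  r_t <- r_from_m(m_t, K_t, cfg$shape)

  logF_year <- log(cfg$F_init) +
    cumsum(c(0, cfg$F_drift + cfg$sigma_F * rnorm(years - 1)))
  F_step <- exp(logF_year)[rep(seq_len(years), each = nsub)]

  B <- numeric(ns + 1)
  B[1] <- cfg$d0 * K_t[1]
  z <- rnorm(ns)
  floor_B <- 1e-6 * cfg$K_bar
  for (i in seq_len(ns)) {
    prodrate <- surplus_production(B[i], m_t[i], K_t[i], cfg$shape) / B[i]
    logB_next <- log(B[i]) +
      (prodrate - F_step[i] - cfg$sigma_B^2 / 2) * dt +
      cfg$sigma_B * sqrt(dt) * z[i]
    B[i + 1] <- exp(logB_next)
    if (B[i + 1] < floor_B)
      stop(sprintf(paste0("simulated collapse: biomass fell below %g t at ",
                          "t = %.3f (year %d); check F and productivity settings"),
                   floor_B, grid[i + 1], cfg$year0 + floor(grid[i + 1])))
  }

  m_y <- cfg$m_bar * exp(trapz_year(logGm, nsub, years))
  K_y <- cfg$K_bar * exp(trapz_year(logGk, nsub, years))
  B_y <- trapz_year(B, nsub, years)
  Bmsy_y <- bmsy(K_y, cfg$shape)
  true_refpoints <- data.frame(
    year = cfg$year0 + seq_len(years) - 1,
    m = m_y, K = K_y, r = r_from_m(m_y, K_y, cfg$shape),
    MSY = msy(m_y), FMSY = fmsy(m_y, K_y, cfg$shape), BMSY = Bmsy_y,
    BBmsy = B_y / Bmsy_y, FFmsy = exp(logF_year) / fmsy(m_y, K_y, cfg$shape)
  )

  structure(list(
    cfg = cfg, grid = grid, B = B, F = F_step, F_year = exp(logF_year),
    logGm = logGm, logGk = logGk, m_t = m_t, K_t = K_t, r_t = r_t,
    B_year = B_y, true_refpoints = true_refpoints
  ), class = "spm_trajectory")
}

#' Generate fishery observations from a trajectory
#'
#' Annual catch is the trapezoid integral of `F * B` over each year times a
#' mean-corrected lognormal error; each fleet's index observes catchability
#' times the annual biomass summary (mean on the grid, or start-of-year
#' snapshot) times a mean-corrected lognormal error. Optional per-fleet
#' year masks create gaps.
#'
#' @param traj An `spm_trajectory` from [simulate_population()].
#' @param cfg The [sim_config()] used to generate it (defaults to the one
#'   stored in the trajectory).
#' @return An [assessment_data()] object.
#' @export
observe <- function(traj, cfg = traj$cfg) {
  if (!inherits(traj, "spm_trajectory")) stop("'traj' must be an spm_trajectory")
  set.seed(cfg$seed + 500009L)
  years <- cfg$years; nsub <- cfg$nsub
  yrs <- cfg$year0 + seq_len(years) - 1

  FB <- traj$F * (traj$B[-length(traj$B)] + traj$B[-1]) / 2
  catch_true <- vapply(seq_len(years), function(y)
    sum(FB[((y - 1) * nsub + 1):(y * nsub)]) * cfg$dt, numeric(1))
  catch_obs <- catch_true *
    exp(cfg$sigma_C * rnorm(years) - cfg$sigma_C^2 / 2)

  B_summary <- if (cfg$index_timing == "mean") traj$B_year
               else traj$B[seq(1, years * nsub, by = nsub)]
  idx <- do.call(rbind, lapply(seq_len(cfg$n_fleets), function(f) {
    val <- cfg$q[f] * B_summary *
      exp(cfg$sigma_I[f] * rnorm(years) - cfg$sigma_I[f]^2 / 2)
    data.frame(fleet = paste0("fleet", f), year = yrs, index = val)
  }))
  if (!is.null(cfg$index_gaps)) {
    for (f in seq_along(cfg$index_gaps)) {
      drop <- idx$fleet == paste0("fleet", f) & idx$year %in% cfg$index_gaps[[f]]
      idx <- idx[!drop, ]
    }
  }
  assessment_data(data.frame(year = yrs, catch = catch_obs), idx)
}

#' Assessment data container
#'
#' Annual catch plus one or more relative-abundance index series.
#'
#' @param catch Data frame with columns `year`, `catch` (tonnes); years
#'   must be contiguous.
#' @param indices Data frame with columns `fleet`, `year`, `index`; gaps
#'   allowed, all index years must lie within the catch span.
#' @return An object of class `assessment_data`.
#' @export
assessment_data <- function(catch, indices) {
  stopifnot(all(c("year", "catch") %in% names(catch)),
            all(c("fleet", "year", "index") %in% names(indices)))
  catch <- catch[order(catch$year), c("year", "catch")]
  if (!all(diff(catch$year) == 1)) stop("catch years must be contiguous")
  if (any(catch$catch <= 0)) stop("catch values must be positive")
  if (any(indices$index <= 0)) stop("index values must be positive")
  if (any(!indices$year %in% catch$year))
    stop("every index year must lie within the catch span")
  indices <- indices[order(indices$fleet, indices$year),
                     c("fleet", "year", "index")]
  rownames(catch) <- rownames(indices) <- NULL
  structure(list(catch = catch, indices = indices), class = "assessment_data")
}

#' @export
print.assessment_data <- function(x, ...) {
  cat(sprintf("assessment data: %d catch years (%d-%d), %d index series, %d index observations\n",
              nrow(x$catch), min(x$catch$year), max(x$catch$year),
              length(unique(x$indices$fleet)), nrow(x$indices)))
  invisible(x)
}

ar1_series <- function(n, phi) {
  # unit-marginal-variance AR(1) draw
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in seq_len(n - 1))
    x[i + 1] <- phi * x[i] + sqrt(1 - phi^2) * rnorm(1)
  x
}

default_env_loadings <- function() {
  # three latent ocean-climate factors; loadings chosen so that an
  # ENSO-like block (SST, SSH, ENSO, WPSTA) is nearly collinear and the
  # decadal pair (PDO, IPO) is strongly but not problematically correlated
  L <- rbind(
    SST   = c(0.97, 0.10, 0.10),
    SSS   = c(0.30, 0.05, 0.40),
    SSO   = c(-0.35, 0.10, 0.45),
    SSCA  = c(0.10, 0.15, 0.60),
    MLT   = c(0.15, 0.25, 0.70),
    SSH   = c(0.96, 0.12, 0.08),
    ENSO  = c(0.98, 0.05, 0.05),
    PDO   = c(0.25, 0.90, 0.10),
    IPO   = c(0.25, 0.62, 0.05),
    WPSTA = c(0.80, 0.20, 0.10)
  )
  L
}

#' Simulate an annual environmental covariate table
#'
#' Draws a correlated (Gaussian-copula style) table of ten standardized
#' ocean-climate covariates (SST, SSS, SSO, SSCA, MLT, SSH, ENSO, PDO, IPO,
#' WPSTA) with a built-in near-collinear block so that iterative VIF
#' screening has variables to remove, plus an optional response series
#' built from known smooth effects for recovery tests.
#'
#' @param years Vector of calendar years (one row each).
#' @param correlation Either `NULL` (default factor-structured correlation),
#'   a correlation matrix (10 x 10, or `length(vars)^2` when `vars` given),
#'   or `"identity"` for independent covariates.
#' @param vars Covariate names (default the ten standard ones).
#' @param response_link Optional named list of effect functions of single
#'   covariates, e.g. `list(PDO = function(x) 2 * x)`; their sum (plus
#'   `trend` and noise) forms the response.
#' @param trend Optional function of standardized year added to the
#'   response.
#' @param noise_sd Response noise SD (default 0).
#' @param seed Integer seed.
#' @return List with `env` (data frame: `year` + covariates), `response`
#'   (numeric or NULL) and `truth` (the generating spec).
#' @export
simulate_env_table <- function(years, correlation = NULL,
                               vars = rownames(default_env_loadings()),
                               response_link = NULL, trend = NULL,
                               noise_sd = 0, seed = 1L) {
  set.seed(seed)
  n <- length(years)
  p <- length(vars)
  if (is.null(correlation)) {
    L <- default_env_loadings()
    if (!all(vars %in% rownames(L)))
      stop("custom 'vars' require an explicit 'correlation'")
    L <- L[vars, , drop = FALSE]
    # latent climate factors are temporally persistent: interannual
    # (ENSO-like), decadal (PDO-like) and upper-ocean factors as AR(1)
    phi_f <- c(0.5, 0.85, 0.6)
    f <- vapply(phi_f, function(ph) ar1_series(n, ph), numeric(n))
    uniq <- pmax(1 - rowSums(L^2), 0.02)
    e <- vapply(seq_len(p), function(j) ar1_series(n, 0.3), numeric(n))
    X <- f %*% t(L) + e %*% diag(sqrt(uniq))
  } else if (identical(correlation, "identity")) {
    X <- matrix(rnorm(n * p), n)
  } else {
    if (!is.matrix(correlation) || nrow(correlation) != p)
      stop("'correlation' must be a correlation matrix matching 'vars'")
    ch <- tryCatch(chol(correlation),
                   error = function(e) stop("correlation matrix is not positive definite"))
    X <- matrix(rnorm(n * p), n) %*% ch
  }
  colnames(X) <- vars
  env <- data.frame(year = years, X, check.names = FALSE)

  response <- NULL
  if (!is.null(response_link) || !is.null(trend)) {
    response <- numeric(n)
    for (v in names(response_link)) {
      if (!v %in% vars) stop(sprintf("unknown covariate '%s' in response_link", v))
      response <- response + response_link[[v]](env[[v]])
    }
    if (!is.null(trend)) {
      ys <- (years - mean(years)) / sd(years)
      response <- response + trend(ys)
    }
    if (noise_sd > 0) response <- response + rnorm(n, 0, noise_sd)
  }
  list(env = env, response = response,
       truth = list(response_link = response_link, trend = trend,
                    noise_sd = noise_sd, seed = seed))
}
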