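# independent hand-coded joint negative log-likelihood for the 3-year toy:
# Euler log-biomass transitions, annual log-F random walk, lognormal
# observations (mean-corrected), and the prior terms
toy_joint_nll <- function(p, d, d0 = 0.46, nsub = 2) {
  dt <- 1 / nsub
  r <- exp(p$logr); K <- exp(p$logK)
  sdb <- exp(p$logsdb); sdf <- exp(p$logsdf)
  sdc <- exp(p$logsdc); sdi <- exp(p$logsdi)
  B <- c(d0 * K, exp(p$logB))
  ll <- 0
  for (i in seq_len(length(B) - 1)) {
    y <- (i - 1) %/% nsub + 1
    mu <- log(B[i]) + (r * (1 - B[i] / K) - exp(p$logF[y]) - sdb^2 / 2) * dt
    ll <- ll + dnorm(log(B[i + 1]), mu, sdb * sqrt(dt), log = TRUE)
  }
  for (y in 2:3) ll <- ll + dnorm(p$logF[y], p$logF[y - 1], sdf, log = TRUE)
  Bbar <- sapply(1:3, function(y) {
    i <- ((y - 1) * nsub + 1):(y * nsub + 1)
    (sum(B[i]) - (B[i[1]] + B[i[nsub + 1]]) / 2) / nsub
  })
  Chat <- exp(p$logF) * Bbar
  ll <- ll + sum(dnorm(log(d$catch$catch), log(Chat) - sdc^2 / 2, sdc, log = TRUE))
  ll <- ll + sum(dnorm(log(d$indices$index),
                       p$logq + log(Bbar) - sdi^2 / 2, sdi, log = TRUE))
  ll <- ll + dnorm(p$logr, log(0.49), 0.2, log = TRUE) +
    dnorm(p$logK, log(11230000), 0.5, log = TRUE) +
    dnorm(p$logsdi - p$logsdb, 0, 2, log = TRUE) +
    dnorm(p$logsdc - p$logsdf, 0, 2, log = TRUE)
  -ll
}

test_that("the joint objective equals an independently coded density sum on a toy", {
  d <- toy_data()
  obj <- spm_objective(d, "CM", dt = 1 / 2, joint = TRUE)
  p <- list(logr = log(0.6), logK = log(25000), logq = log(8e-6),
            logsdb = log(0.12), logsdf = log(0.25), logsdc = log(0.07),
            logsdi = log(0.3),
            logF = log(c(0.08, 0.1, 0.12)),
            logB = log(c(11000, 11500, 11800, 12000, 12100, 11900)))
  par <- obj$par
  for (nm in c("logr", "logK", "logq", "logsdb", "logsdf", "logsdc", "logsdi"))
    par[names(par) == nm] <- p[[nm]]
  par[names(par) == "logF"] <- p$logF
  par[names(par) == "logB"] <- p$logB
  expect_equal(obj$fn(par), toy_joint_nll(p, d), tolerance = 1e-10)
})

test_that("the CM objective carries no deviation states; active scenarios do", {
  d <- toy_data()
  o_cm <- spm_objective(d, "CM", dt = 1 / 2, joint = TRUE)
  expect_false(any(grepl("^U", names(o_cm$par))))
  o_rm <- spm_objective(d, "RM", dt = 1 / 2, joint = TRUE)
  expect_equal(sum(names(o_rm$par) == "Um"), 7) # grid points 0..6
  expect_false(any(names(o_rm$par) == "Uk"))
})

test_that("Laplace marginal likelihood matches dense latent integration on a 5-year toy", {
  r <- 0.5; K <- 1e6; q <- 1e-5; sdb <- 0.3; sdc <- 0.1; sdi <- 0.2
  d0 <- 0.46; Fv <- rep(0.1, 5)
  set.seed(99)
  B <- numeric(6); B[1] <- d0 * K
  for (i in 1:5)
    B[i + 1] <- exp(log(B[i]) + (r * (1 - B[i] / K) - Fv[i] - sdb^2 / 2) +
                      sdb * rnorm(1))
  Bbar <- (B[-6] + B[-1]) / 2
  catch <- Fv * Bbar * exp(sdc * rnorm(5) - sdc^2 / 2)
  index <- q * Bbar * exp(sdi * rnorm(5) - sdi^2 / 2)
  d <- assessment_data(data.frame(year = 2001:2005, catch = catch),
                       data.frame(fleet = "f1", year = 2001:2005, index = index))
  pri <- prior_spec(use_r = FALSE, use_K = FALSE,
                    use_alpha = FALSE, use_beta = FALSE)
  ctl <- spm_control(f_dynamics = FALSE, F_values = Fv, se = FALSE,
                     report_refpoints = FALSE,
                     fix = list(logr = log(r), logK = log(K), logq = log(q),
                                logsdb = log(sdb), logsdc = log(sdc),
                                logsdi = log(sdi)))
  f <- fit_spm(d, "CM", priors = pri, dt = 1, control = ctl)

  # dense grid-based forward filter over the latent log-biomass chain
  m <- r * K / 4
  mu_fun <- function(x) x + 4 * m / K * (1 - exp(x) / K) - 0.1 - sdb^2 / 2
  obsfac <- function(y, xa, xb) {
    Bb <- (exp(xa) + exp(xb)) / 2
    dnorm(log(catch[y]), log(0.1 * Bb) - sdc^2 / 2, sdc, log = TRUE) +
      dnorm(log(index[y]), log(q * Bb) - sdi^2 / 2, sdi, log = TRUE)
  }
  ng <- 1201
  gridx <- seq(log(0.05 * K), log(3 * K), length.out = ng)
  dx <- diff(gridx)[1]
  x0 <- log(d0 * K)
  la <- dnorm(gridx, mu_fun(x0), sdb, log = TRUE) + obsfac(1, x0, gridx)
  for (y in 2:5) {
    M <- outer(gridx, gridx, function(xnew, xold)
      dnorm(xnew, mu_fun(xold), sdb, log = TRUE) + obsfac(y, xold, xnew))
    mx <- max(la)
    la <- mx + log((exp(M) %*% exp(la - mx)) * dx)[, 1]
  }
  mx <- max(la)
  ll_exact <- mx + log(sum(exp(la - mx)) * dx)
  # agreement within 1% on the likelihood scale
  expect_lt(abs(f$loglik - ll_exact), log(1.01))
})

test_that("noise-free synthetic data are recovered within 1%", {
  cfg <- sim_config(sigma_B = 0, sigma_F = 0, sigma_C = 0,
                    sigma_I = rep(0, 4), seed = 1)
  d <- observe(simulate_population(cfg), cfg)
  f <- fit_spm(d, "CM", control = spm_control(report_refpoints = FALSE,
    fix = list(logsdb = log(1e-3), logsdc = log(1e-3),
               logsdi = rep(log(1e-3), 4))))
  expect_lt(abs(est_of(f, "r") / 0.49 - 1), 0.01)
  expect_lt(abs(est_of(f, "K") / 11.23e6 - 1), 0.01)
  qhat <- vapply(paste0("q", 1:4), function(p) est_of(f, p), numeric(1))
  expect_lt(max(abs(qhat / (c(0.5, 1, 2, 4) * 1e-6) - 1)), 0.01)
})

test_that("with uninformative observations the estimates collapse to the priors", {
  d <- cm_data(3)
  f <- fit_spm(d, "CM", control = spm_control(
    report_refpoints = FALSE, mean_correct = FALSE,
    f_dynamics = FALSE, F_values = rep(0.1, 30),
    fix = list(logsdb = log(1e-3), logsdc = log(5), logsdi = rep(log(5), 4))))
  expect_lt(abs(est_of(f, "r") / 0.49 - 1), 0.1)
  expect_lt(abs(est_of(f, "K") / 11.23e6 - 1), 0.1)
})

test_that("a standard fit converges with plausible estimates and honest intervals", {
  f <- cm_fit()
  expect_true(f$converged)
  expect_true(f$pd_hessian)
  expect_lt(f$max_gradient, 1e-3)
  e <- f$estimates
  expect_true(all(e$lower < e$estimate & e$estimate < e$upper))
  # interval endpoints follow the lognormal construction
  rl <- e[e$parameter == "r", ]
  expect_equal(rl$upper / rl$estimate, exp(1.96 * rl$se_log), tolerance = 1e-10)
  expect_equal(f$n_obs, 150)
  expect_equal(f$aicc, aicc(f$loglik, f$n_par, f$n_obs))
})

test_that("refitting with everything fixed at the optimum reproduces the likelihood", {
  f <- cm_fit()
  pl <- f$obj$env$parList(f$opt$par)
  f2 <- fit_spm(cm_data(), "CM", control = spm_control(
    report_refpoints = FALSE, se = FALSE,
    fix = list(logr = pl$logr, logK = pl$logK, logq = pl$logq,
               logsdb = pl$logsdb, logsdf = pl$logsdf, logsdc = pl$logsdc,
               logsdi = pl$logsdi)))
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-6)
})

test_that("rescaling one index series rescales its catchability and nothing else", {
  d <- cm_data(3)
  d2 <- d
  sel <- d2$indices$fleet == "fleet2"
  d2$indices$index[sel] <- d2$indices$index[sel] * 10
  ctl <- spm_control(report_refpoints = FALSE)
  f1 <- fit_spm(d, "CM", control = ctl)
  f2 <- fit_spm(d2, "CM", control = ctl)
  expect_equal(est_of(f2, "q2") / est_of(f1, "q2"), 10, tolerance = 1e-4)
  expect_equal(est_of(f2, "r"), est_of(f1, "r"), tolerance = 1e-5)
  expect_equal(est_of(f2, "K"), est_of(f1, "K"), tolerance = 1e-5)
})

test_that("changing biomass units rescales K and leaves r and F_MSY alone", {
  d <- cm_data(3)
  dk <- d; dk$catch$catch <- dk$catch$catch / 1000
  prk <- prior_spec(log_K_mean = log(11230000 / 1000))
  f1 <- fit_spm(d, "CM", control = spm_control(report_refpoints = TRUE))
  f2 <- fit_spm(dk, "CM", priors = prk,
                control = spm_control(report_refpoints = TRUE))
  expect_equal(est_of(f2, "K") * 1000, est_of(f1, "K"), tolerance = 1e-5)
  expect_equal(est_of(f2, "r"), est_of(f1, "r"), tolerance = 1e-5)
  expect_equal(f2$refpoints$FMSY, f1$refpoints$FMSY, tolerance = 1e-5)
  expect_equal(f2$refpoints$BMSY * 1000, f1$refpoints$BMSY, tolerance = 1e-5)
})

test_that("a flexible productivity model fits no worse than the constant one", {
  d <- cm_data(3)
  fCM <- fit_spm(d, "CM", control = spm_control(report_refpoints = FALSE,
                                                se = FALSE))
  fRM <- fit_spm(d, "RM", control = spm_control(report_refpoints = FALSE,
                                                se = FALSE, est_sigma_m = TRUE))
  expect_gte(fRM$loglik, fCM$loglik - 1e-5)
})

test_that("LKRM with the exponent fixed at 1 reproduces the proportional model", {
  d <- cm_data(3)
  ctl <- spm_control(report_refpoints = FALSE, se = FALSE)
  fPK <- fit_spm(d, "PKRM", control = ctl)
  fLK <- fit_spm(d, scenario_spec("LKRM", lambda = 1),
                 control = spm_control(report_refpoints = FALSE, se = FALSE,
                                       fix = list(lambda = 1)))
  expect_equal(fLK$loglik, fPK$loglik, tolerance = 1e-6)
})

test_that("reference-point series obey the defining identities", {
  f <- cm_fit()
  rp <- f$refpoints
  expect_equal(rp$MSY, rp$FMSY * rp$BMSY, tolerance = 1e-9)
  expect_equal(rp$MSY, rp$m)
  # constant-parameter fit: flat series
  expect_equal(diff(range(rp$MSY)), 0)
  expect_equal(diff(range(rp$BMSY)), 0)
  expect_equal(rp$BMSY[1], est_of(f, "K") / 2, tolerance = 1e-6)
  expect_equal(rp$FMSY[1], est_of(f, "r") / 2, tolerance = 1e-6)
  # a time-varying fit reports a genuinely varying series
  drm <- observe(simulate_population(
    sim_config(scenario = scenario_spec("RM"), seed = 11)))
  frm <- fit_spm(drm, "RM")
  expect_gt(diff(range(frm$refpoints$MSY)) / frm$refpoints$MSY[1], 0.01)
  expect_equal(frm$refpoints$MSY, frm$refpoints$m)
})

test_that("a stock fished at half F_MSY settles in the sustainable quadrant", {
  cfg <- sim_config(years = 30, sigma_B = 0, sigma_F = 0, sigma_C = 0,
                    sigma_I = rep(0, 4), F_init = 0.1225, F_drift = 0, seed = 1)
  d <- observe(simulate_population(cfg), cfg)
  f <- fit_spm(d, "CM", control = spm_control(
    fix = list(logsdb = log(1e-2), logsdc = log(1e-2),
               logsdi = rep(log(1e-2), 4))))
  st <- stock_status(f)
  term <- attr(st, "terminal")
  expect_gt(term$BBmsy, 1)
  expect_lt(term$FFmsy, 1)
  expect_equal(term$status, "sustainable")
})

test_that("input contract violations are rejected", {
  d <- cm_data()
  expect_error(fit_spm(d, "CM", dt = 0.3), "1/dt")
  expect_error(spm_control_bad <- fit_spm(d, "CM",
    control = spm_control(fix = list(nonsense = 1))), "unknown parameter")
  expect_error(fit_spm(d, "CM",
    control = spm_control(f_dynamics = FALSE)), "F_values")
})
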