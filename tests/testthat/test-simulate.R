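test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(dt = 0.3), "1/dt")
  expect_error(sim_config(years = 1), "at least 2")
  expect_error(sim_config(q = c(1, 2)), "per fleet")
  expect_error(sim_config(logGm_custom = 1:5), "years \\+ 1")
})

test_that("with no noise and no fishing the population sits at carrying capacity", {
  for (mode in c("schaefer", "fox")) {
    cfg <- sim_config(shape = production_shape(mode), sigma_B = 0, sigma_F = 0,
                      F_init = 1e-9, F_drift = 0, d0 = 1, seed = 1)
    traj <- simulate_population(cfg)
    expect_equal(traj$B, rep(cfg$K_bar, length(traj$B)), tolerance = 1e-6)
  }
})

test_that("constant F below F_MSY drives the stock to the Schaefer equilibrium K(1 - F/r)", {
  cfg <- sim_config(years = 200, sigma_B = 0, sigma_F = 0, sigma_C = 0,
                    sigma_I = rep(0, 4), F_init = 0.1, F_drift = 0, seed = 1)
  traj <- simulate_population(cfg)
  r <- r_from_m(cfg$m_bar, cfg$K_bar, cfg$shape)
  Bstar <- cfg$K_bar * (1 - 0.1 / r)
  expect_equal(traj$B[length(traj$B)], Bstar, tolerance = 1e-3)
  # at equilibrium the noise-free annual catch equals F B*
  d <- observe(traj, cfg)
  expect_equal(d$catch$catch[200], 0.1 * Bstar, tolerance = 1e-3)
})

test_that("the CM scenario has identically zero deviations", {
  traj <- simulate_population(sim_config(seed = 3))
  expect_identical(traj$logGm, numeric(length(traj$grid)))
  expect_identical(traj$logGk, numeric(length(traj$grid)))
  expect_equal(traj$m_t, rep(traj$cfg$m_bar, length(traj$grid)))
})

test_that("scenario couplings satisfy the deviation algebra", {
  U <- c(-0.2, 0.1, 0.3)
  pk <- couple_deviations("PKRM", Uk = U)
  expect_equal(pk$logGm - pk$logGk, pk$logGk) # G(r) = G(K)
  lk <- couple_deviations(scenario_spec("LKRM", lambda = 1), Uk = U)
  expect_equal(lk, pk)
  lk2 <- couple_deviations(scenario_spec("LKRM", lambda = 2.5), Uk = U)
  expect_equal(lk2$logGm - lk2$logGk, 2.5 * lk2$logGk) # G(r) = G(K)^lambda
  km <- couple_deviations("KM", Uk = U)
  expect_equal(km$logGm - km$logGk, rep(0, 3)) # G(r) = 1
  ik <- couple_deviations("IKRM", Um = U, Uk = 2 * U)
  expect_equal(ik$logGm, U); expect_equal(ik$logGk, 2 * U)
})

test_that("halving the Euler step barely moves the deterministic solution", {
  term <- function(dt, drift) {
    cfg <- sim_config(sigma_B = 0, sigma_F = 0, F_drift = drift, dt = dt,
                      seed = 1)
    B <- simulate_population(cfg)$B
    B[length(B)]
  }
  # constant fishing mortality: terminal biomass is essentially converged
  expect_lt(abs(term(1 / 16, 0) / term(1 / 8, 0) - 1), 5e-4)
  # transient (one-way trip) trajectory: refinement shrinks the difference,
  # first-order in dt
  d1 <- abs(term(1 / 16, 0.05) / term(1 / 8, 0.05) - 1)
  d2 <- abs(term(1 / 64, 0.05) / term(1 / 16, 0.05) - 1)
  expect_lt(d1, 2e-3)
  expect_lt(d2, d1)
})

test_that("simulation is deterministic given the seed and collapses are reported", {
  cfg <- sim_config(seed = 42)
  t1 <- simulate_population(cfg); t2 <- simulate_population(cfg)
  expect_identical(t1$B, t2$B)
  d1 <- observe(t1, cfg); d2 <- observe(t2, cfg)
  expect_identical(d1$catch, d2$catch)
  expect_identical(d1$indices, d2$indices)
  expect_error(simulate_population(sim_config(F_init = 5, seed = 1)),
               "simulated collapse")
})

test_that("observations have the study's shape and exact proportionality when noise-free", {
  d <- cm_data()
  expect_equal(nrow(d$catch), 30)
  expect_equal(length(unique(d$indices$fleet)), 4)
  expect_equal(nrow(d$indices), 120)
  cfg <- sim_config(sigma_I = rep(0, 4), seed = 5)
  d0 <- observe(simulate_population(cfg), cfg)
  w <- reshape(d0$indices, idvar = "year", timevar = "fleet", direction = "wide")
  expect_equal(w$index.fleet2 / w$index.fleet1, rep(2, 30), tolerance = 1e-12)
  expect_equal(w$index.fleet4 / w$index.fleet3, rep(2, 30), tolerance = 1e-12)
})

test_that("index gaps and timing options are honored", {
  cfg <- sim_config(index_gaps = list(fleet1 = 1995:1999), seed = 6)
  d <- observe(simulate_population(cfg), cfg)
  f1 <- d$indices[d$indices$fleet == "fleet1", ]
  expect_equal(nrow(f1), 25)
  expect_false(any(f1$year %in% 1995:1999))
  cfg2 <- sim_config(index_timing = "start", sigma_I = rep(0, 4), seed = 6)
  traj <- simulate_population(cfg2)
  d2 <- observe(traj, cfg2)
  snap <- traj$B[seq(1, 30 * 8, by = 8)]
  f1 <- d2$indices[d2$indices$fleet == "fleet1", ]
  expect_equal(f1$index, cfg2$q[1] * snap, tolerance = 1e-12)
})

test_that("assessment data validation rejects malformed inputs", {
  good <- cm_data()
  expect_error(assessment_data(good$catch[-3, ], good$indices), "contiguous")
  bad <- good$indices; bad$year[1] <- 1950
  expect_error(assessment_data(good$catch, bad), "within the catch span")
  bad2 <- good$indices; bad2$index[1] <- -1
  expect_error(assessment_data(good$catch, bad2), "positive")
})

test_that("true reference points satisfy the productivity identities", {
  cfg <- sim_config(scenario = scenario_spec("IKRM"), seed = 8)
  traj <- simulate_population(cfg)
  rp <- traj$true_refpoints
  expect_equal(rp$MSY, rp$FMSY * rp$BMSY, tolerance = 1e-12)
  expect_equal(rp$MSY, rp$m)
  expect_equal(rp$r, r_from_m(rp$m, rp$K, cfg$shape), tolerance = 1e-12)
  # r_t satisfies the m-r map at every grid point
  expect_equal(traj$r_t, r_from_m(traj$m_t, traj$K_t, cfg$shape),
               tolerance = 1e-12)
})

test_that("environmental tables: identity draws are near-orthogonal, duplicates explode VIF", {
  et <- simulate_env_table(1981:2020, correlation = "identity", seed = 2)
  cc <- cor(et$env[, -1])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.45)
  expect_true(all(tvspm:::vif_table(et$env, setdiff(names(et$env), "year")) < 10))
  # near-duplicate pair
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.999
  et2 <- simulate_env_table(1991:2020, correlation = R,
                            vars = c("a", "b", "c"), seed = 3)
  v <- tvspm:::vif_table(et2$env, c("a", "b", "c"))
  expect_gt(v[["a"]], 100)
  expect_gt(v[["b"]], 100)
})

test_that("planted responses are recorded and exactly recoverable without noise", {
  et <- simulate_env_table(1992:2021,
                           response_link = list(PDO = function(x) 2 * x),
                           seed = 4)
  expect_equal(et$response, 2 * et$env$PDO)
  co <- coef(lm(et$response ~ et$env$PDO))
  expect_equal(unname(co[2]), 2, tolerance = 1e-12)
  expect_error(simulate_env_table(1992:2021,
                                  response_link = list(nope = identity)),
               "unknown covariate")
})
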