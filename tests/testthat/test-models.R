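test_that("build_group_data restricts to the observed part and validates", {
  pop <- simulate_population(8, 6, seed = 21)
  perfect <- simulate_capture_histories(pop, 1, 1, seed = 22)
  d <- build_group_data(perfect)
  expect_true(all(d$W == 1))
  expect_identical(d$n_counts, pop$group_sizes)
  expect_identical(unname(vapply(d$counts, function(m) all(m == 3), logical(1))),
                   rep(TRUE, 8))
  ## undetected groups are absent
  cap <- fixture_captures(seed = 50, p_g = 0.4)
  d2 <- build_group_data(cap)
  expect_identical(nrow(d2$W), sum(rowSums(cap$group_detections) > 0))
  expect_true(all(rowSums(d2$W) > 0))
})

test_that("build_group_data matches a hand-built two-group example", {
  ## group 1 (2 members) detected both sweeps, group 2 (3 members) sweep 2 only
  gdet <- rbind(c(1L, 1L), c(0L, 1L))
  idet <- rbind(
    c(1, 0, 0, 0, 1, 0),   # member of g1: 1 hit sweep1, 1 hit sweep2
    c(0, 0, 0, 0, 0, 0),   # member of g1: never detected
    c(0, 0, 0, 1, 1, 0),   # member of g2: 2 hits sweep2
    c(0, 0, 0, 0, 0, 1),   # member of g2: 1 hit sweep2
    c(0, 0, 0, 0, 0, 0))   # member of g2: never detected
  cap <- structure(list(group_detections = gdet,
                        individual_detections = idet,
                        membership = c(1L, 1L, 2L, 2L, 2L),
                        solitary_detections = matrix(0L, 0, 2),
                        K = 2L, T_occ = 3L),
                   class = "cmr_captures")
  d <- build_group_data(cap)
  expect_identical(d$W, gdet)
  expect_identical(d$n_counts, c(1L, 2L))
  expect_identical(d$counts[[1]], matrix(c(1L, 1L), 1, 2))
  expect_identical(d$counts[[2]], rbind(c(0L, 2L), c(0L, 1L)))
  ## integrity violation: detection inside an undetected sweep
  bad <- cap
  bad$individual_detections[3, 1] <- 1
  expect_error(build_group_data(bad), "group was not detected")
})

test_that("Two-Step log-likelihood equals the hand-derived toy value", {
  d <- toy_twostep_data()
  for (pars in list(c(0.7, 0.6, 10), c(0.3, 0.9, 4), c(0.55, 0.25, 17))) {
    for (m in list(c(3L, 2L), c(5L, 6L), c(11L, 3L))) {
      expect_equal(twostep_loglik(d, pars[1], pars[2], pars[3], m),
                   toy_loglik(pars[1], pars[2], pars[3], m[1], m[2]),
                   tolerance = 1e-10)
    }
  }
  ## truncation bound propagates
  expect_equal(twostep_loglik(d, 0.7, 0.6, 10, c(4L, 2L), group_size_min = 2),
               toy_loglik(0.7, 0.6, 10, 4, 2, min_size = 2),
               tolerance = 1e-10)
  expect_error(twostep_loglik(d, 0.7, 0.6, 10, c(2L, 2L)), "m")
})

test_that("One-Step fit: perfect detection pins p and N", {
  y <- matrix(1L, 20, 2)
  fit <- fit_onestep(y, mcmc = mcmc_config(n_chains = 2, n_iter = 4000,
                                           burn_in = 500, seed = 13))
  expect_gt(fit["p", "mean"], 0.9)
  expect_lt(abs(fit["N", "mean"] - 20), 0.5)
  expect_error(fit_onestep(rbind(y, 0L)), "nonzero")
  expect_error(fit_onestep(y, M = 20), "exceed")
})

test_that("Two-Step fit recovers simulated parameters and bounds N below by the observed count", {
  cap <- fixture_captures(seed = 61, n_groups = 30, lambda = 13)
  d <- build_group_data(cap)
  fit <- fit_twostep(d, mcmc = mcmc_config(n_chains = 3, n_iter = 4000,
                                           burn_in = 1000, seed = 62))
  for (par in c("p_g", "p_i", "lambda")) {
    truth <- c(p_g = 0.7, p_i = 0.7, lambda = 13)[par]
    expect_lt(abs(fit[par, "mean"] - truth), 3 * fit[par, "sd"])
  }
  expect_gte(fit["N", "q2.5"], sum(d$n_counts))
  expect_gte(fit["G", "q2.5"], nrow(d$W))
  expect_lt(max_rhat(fit), 1.1)
})

test_that("saturated group detection concentrates G at the observed count", {
  pop <- simulate_population(12, 9, seed = 71)
  cap <- simulate_capture_histories(pop, 1, 0.8, seed = 72)
  d <- build_group_data(cap)
  fit <- fit_twostep(d, mcmc = mcmc_config(n_chains = 2, n_iter = 3000,
                                           burn_in = 500, seed = 73))
  expect_lt(fit["G", "mean"], 12.2)
  expect_gt(mean(posterior_draws(fit, "G") == 12), 0.95)
})

test_that("Two-Step posterior mean of N matches the importance-sampling oracle on 3 tiny groups", {
  ## every group detected in both sweeps, K = 2, T = 1
  d <- structure(list(
    W = matrix(1L, 3, 2),
    counts = list(rbind(c(1L, 1L), c(1L, 0L)),
                  rbind(c(0L, 1L), c(1L, 1L), c(1L, 1L)),
                  rbind(c(1L, 1L))),
    n_counts = c(2L, 3L, 1L),
    solitary_W = matrix(0L, 0, 2),
    K = 2L, T_occ = 1L), class = "cmr_twostep_data")
  oracle <- oracle_twostep_EN(d, M_groups = 9, n_draws = 2e5, seed = 99)
  expect_gt(oracle$ess, 1000)  # importance sample is usable
  fit <- fit_twostep(d, M_groups = 9,
                     mcmc = mcmc_config(n_chains = 3, n_iter = 20000,
                                        burn_in = 2000, seed = 101))
  expect_equal(fit["N", "mean"], oracle$EN, tolerance = 0.03)
})

test_that("solitaries variant: degenerate reduction and recovery of S", {
  cap <- fixture_captures(seed = 81, n_groups = 20, lambda = 8)
  d <- build_group_data(cap)
  cfg <- mcmc_config(n_chains = 2, n_iter = 3000, burn_in = 500, seed = 82)
  plain <- fit_twostep(d, mcmc = cfg, group_size_min = 2)
  reduced <- fit_twostep_solitaries(d, M_solitaries = 0, mcmc = cfg,
                                    group_size_min = 2)
  expect_identical(posterior_draws(plain)[[1]][, c("p_g", "p_i", "lambda", "G", "N")],
                   posterior_draws(reduced)[[1]][, c("p_g", "p_i", "lambda", "G", "N")])

  pop <- simulate_population(25, 10, min_size = 2, n_solitaries = 50, seed = 83)
  caps <- simulate_capture_histories(pop, 0.7, 0.7, p_s = 0.2, seed = 84)
  ds <- build_group_data(caps)
  expect_gt(nrow(ds$solitary_W), 0)
  fit <- fit_twostep_solitaries(ds, M_solitaries = 300,
                                mcmc = mcmc_config(n_chains = 3,
                                                   n_iter = 6000,
                                                   burn_in = 1000,
                                                   seed = 85))
  expect_lt(abs(fit["S", "mean"] - 50), 3 * fit["S", "sd"])
  expect_lt(abs(fit["p_s", "mean"] - 0.2), 3 * fit["p_s", "sd"])
  ## N = grouped abundance + S, and grouped abundance >= observed individuals
  Nd <- posterior_draws(fit, "N"); Sd <- posterior_draws(fit, "S")
  expect_true(all(Nd - Sd >= sum(ds$n_counts)))
})

test_that("augmentation ceiling triggers a warning", {
  cap <- fixture_captures(seed = 91, p_g = 0.3, n_groups = 10)
  d <- build_group_data(cap)
  expect_warning(
    fit_twostep(d, M_groups = nrow(d$W) + 1L,
                mcmc = mcmc_config(n_chains = 2, n_iter = 2000,
                                   burn_in = 500, seed = 92)),
    "ceiling")
})
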