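test_that("zero-truncated Poisson pmf matches closed forms and normalizes", {
  ## support below the truncation bound is excluded, not an error
  expect_identical(dztpois(0, 13), 0)
  expect_identical(dztpois(0, 13, log = TRUE), -Inf)
  expect_identical(dztpois(1, 13, min_value = 2, log = TRUE), -Inf)
  ## closed form at the bound
  expect_equal(dztpois(1, 1, log = TRUE), log(exp(-1) / (1 - exp(-1))),
               tolerance = 1e-12)
  ## normalization over a bounded support
  for (lam in c(0.5, 1, 13, 25)) {
    expect_equal(sum(dztpois(1:200, lam)), 1, tolerance = 1e-10)
    expect_equal(sum(dztpois(2:200, lam, min_value = 2)), 1, tolerance = 1e-10)
  }
  expect_error(dztpois(1, -2), "positive")
  expect_error(dztpois(1, 13, min_value = 0), "integer")
})

test_that("ztpois_mean equals the truncated-mean identity and a direct sum", {
  expect_equal(ztpois_mean(13), 13 / (1 - exp(-13)), tolerance = 1e-12)
  expect_equal(ztpois_mean(1), 1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(ztpois_mean(700), 700, tolerance = 1e-12)
  ## independent check: direct expectation over the pmf, including min_value 2
  for (lam in c(0.7, 3, 13)) {
    for (mv in 1:2) {
      expect_equal(ztpois_mean(lam, mv), sum((mv:300) * dztpois(mv:300, lam, mv)),
                   tolerance = 1e-10)
    }
  }
})

test_that("rztpois respects support, seed and mean", {
  set.seed(1)
  x <- rztpois(5000, 1, min_value = 1)
  expect_true(min(x) >= 1)
  expect_equal(mean(x), ztpois_mean(1), tolerance = 4 * sd(x) / sqrt(5000))
  y <- rztpois(2000, 6, min_value = 2)
  expect_true(min(y) >= 2)
  set.seed(7); a <- rztpois(50, 13)
  set.seed(7); b <- rztpois(50, 13)
  expect_identical(a, b)
})

test_that("zero-truncated Binomial pmf: edge cases, enumeration, normalization", {
  expect_identical(dztbinom(5, 5, 1, log = TRUE), 0)
  expect_identical(dztbinom(0, 5, 0.4), 0)
  expect_identical(dztbinom(6, 5, 0.4), 0)
  expect_equal(dztbinom(1, 2, 0.5, log = TRUE), log(2 / 3), tolerance = 1e-12)
  ## p = 0 with positive count is log-zero, not an exception
  expect_identical(dztbinom(1, 3, 0, log = TRUE), -Inf)
  for (size in c(1, 2, 7, 40)) {
    for (p in c(0.05, 0.3, 0.9)) {
      expect_equal(sum(dztbinom(1:size, size, p)), 1, tolerance = 1e-10)
    }
  }
})

test_that("p_star evaluates the at-least-once probability", {
  expect_equal(p_star(0.7, c(1, 1), 1), 0.91, tolerance = 1e-15)
  expect_identical(p_star(0.9, c(0, 0), 3), 0)
  expect_equal(p_star(0.5, c(1, 0), 3), 1 - 0.5^3, tolerance = 1e-12)
})

test_that("p_star is monotone in p_i, T and detected sweeps", {
  for (i in 1:20) {
    set.seed(i)
    p <- runif(1, 0.05, 0.95)
    w <- c(1, rbinom(2, 1, 0.5))
    expect_true(p_star(p + 0.04, w, 2) >= p_star(p, w, 2))
    expect_true(p_star(p, w, 3) >= p_star(p, w, 2))
    if (any(w == 0)) {                   # add a detected sweep when possible
      w2 <- w; w2[which(w == 0)[1]] <- 1
      expect_true(p_star(p, w2, 2) >= p_star(p, w, 2))
    }
  }
})

test_that("history cell probabilities match the brute-force enumeration oracle", {
  set.seed(42)
  for (K in 1:2) {
    for (T_occ in 1:3) {
      for (rep in 1:20) {
        p <- runif(1, 0.02, 0.98)
        w <- rbinom(K, 1, 0.6)
        if (!any(w == 1)) w[sample(K, 1)] <- 1
        got <- history_cell_probs(p, w, T_occ)
        want <- oracle_cell_probs(p, w, T_occ)
        expect_identical(names(got), names(want))
        expect_equal(got, want, tolerance = 1e-12)
        expect_equal(sum(got), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("cell probabilities and p_star are mutually consistent", {
  ## total unconditional mass of observable histories equals p_star
  set.seed(11)
  for (rep in 1:10) {
    p <- runif(1, 0.05, 0.95)
    w <- c(1, rbinom(1, 1, 0.5))
    T_occ <- sample(1:3, 1)
    cells <- history_cell_probs(p, w, T_occ)
    ps <- p_star(p, w, T_occ)
    expect_equal(sum(cells * ps), ps, tolerance = 1e-12)
  }
  ## forced conditioning: one detected sweep, T = 1, single observable history
  cells <- history_cell_probs(0.3, c(1, 0), 1)
  expect_identical(names(cells), "10")
  expect_equal(unname(cells), 1, tolerance = 1e-12)
  expect_error(history_cell_probs(0.5, c(0, 0), 2), "undetected")
})
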