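# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (full enumeration, prior-space
# importance sampling) and never call the code paths they check.

# Enumerate all 2^(K*T) occasion histories, weight each by its unconditional
# Bernoulli product with per-occasion probability p_i * w, drop the all-zero
# history and renormalize. Zero-probability histories (a 1 inside an
# undetected sweep) are dropped too.
oracle_cell_probs <- function(p_i, w, T_occ) {
  K <- length(w)
  occ_p <- rep(p_i * w, each = T_occ)
  hist <- as.matrix(expand.grid(rep(list(0:1), K * T_occ)))
  ## expand.grid varies the first factor fastest; occasion 1 must be the
  ## leftmost digit of the label
  pr <- apply(hist, 1, function(h) prod(occ_p^h * (1 - occ_p)^(1 - h)))
  keep <- rowSums(hist) > 0 & pr > 0
  labs <- apply(hist[keep, , drop = FALSE], 1, paste0, collapse = "")
  out <- stats::setNames(pr[keep] / sum(pr[keep]), labs)
  out[order(names(out))]
}

# Hand-built two-group toy: K = 2 sweeps, T = 1 nest site.
# Group 1 detected in both sweeps, 3 observed members with histories
# "10", "01", "11"; group 2 detected in sweep 1 only, 2 observed members
# both "10" (the only observable history).
toy_twostep_data <- function() {
  structure(list(
    W = rbind(c(1L, 1L), c(1L, 0L)),
    counts = list(rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                  rbind(c(1L, 0L), c(1L, 0L))),
    n_counts = c(3L, 2L),
    solitary_W = matrix(0L, 0, 2),
    K = 2L, T_occ = 1L), class = "cmr_twostep_data")
}

# Independent log-likelihood for the toy above at fixed parameters,
# written out term by term from the model definition.
toy_loglik <- function(p_g, p_i, lambda, m1, m2, min_size = 1) {
  ztp <- function(m) dpois(m, lambda) / ppois(min_size - 1, lambda, lower.tail = FALSE)
  ## group 1: W = (1,1); cells 10, 01, 11 with probs p(1-p), (1-p)p, pp over
  ## pstar = 1 - (1-p)^2; members 10, 01, 11; n = 3 ~ ZTBinom(m1, pstar)
  ps1 <- 1 - (1 - p_i)^2
  cells1 <- log(p_i * (1 - p_i) / ps1) + log((1 - p_i) * p_i / ps1) +
    log(p_i * p_i / ps1)
  ztb1 <- choose(m1, 3) * ps1^3 * (1 - ps1)^(m1 - 3) / (1 - (1 - ps1)^m1)
  g1 <- log(p_g) + log(p_g) + cells1 + log(ztb1) + log(ztp(m1))
  ## group 2: W = (1,0); single observable history "10" with probability 1;
  ## pstar = p_i; n = 2 ~ ZTBinom(m2, p_i)
  ztb2 <- choose(m2, 2) * p_i^2 * (1 - p_i)^(m2 - 2) / (1 - (1 - p_i)^m2)
  g2 <- log(p_g) + log(1 - p_g) + 2 * log(p_i / p_i) + log(ztb2) + log(ztp(m2))
  g1 + g2
}

# Prior-space importance-sampling oracle for E[N | data] under the Two-Step
# model: draws (p_g, psi_g, p_i, lambda) from their uniform priors, weights
# by the marginal likelihood with the group sizes and augmented inclusion
# indicators summed out analytically, and accumulates the posterior mean of
# N by Rao-Blackwellization. Only feasible for tiny datasets.
oracle_twostep_EN <- function(data, M_groups, n_draws = 2e5, lambda_upper = 30,
                              min_size = 1, m_cap = 60, seed = 99,
                              chunk = 2e4) {
  set.seed(seed)
  nG <- nrow(data$W); K <- data$K; T_occ <- data$T_occ
  M_extra <- M_groups - nG
  Sw <- sum(data$W)
  mgrid <- 0:m_cap
  logw_all <- EN_all <- numeric(0)
  done <- 0
  while (done < n_draws) {
    B <- min(chunk, n_draws - done); done <- done + B
    p_g <- runif(B); psi <- runif(B)
    p_i <- runif(B); lam <- runif(B, 0, lambda_upper)
    ## group-detection part for observed groups (z = 1), augmented rows with
    ## z summed out
    logw <- Sw * log(p_g) + (K * nG - Sw) * log(1 - p_g) + nG * log(psi)
    qz <- psi * (1 - p_g)^K + (1 - psi)
    logw <- logw + M_extra * log(qz)
    ## expected included augmented groups, times expected ZT-Poisson size
    pinc <- psi * (1 - p_g)^K / qz
    ztp_mean <- lam * ppois(min_size - 2, lam, lower.tail = FALSE) /
      ppois(min_size - 1, lam, lower.tail = FALSE)
    EN <- M_extra * pinc * ztp_mean
    for (g in seq_len(nG)) {
      w <- data$W[g, ]; n_g <- data$n_counts[g]; cnt <- data$counts[[g]]
      d_g <- sum(w)
      li <- 0
      for (k in which(w == 1))
        li <- li + colSums(matrix(
          dbinom(rep(cnt[, k], times = B), T_occ,
                 rep(p_i, each = nrow(cnt)), log = TRUE), nrow = nrow(cnt)))
      ps <- 1 - (1 - p_i)^(T_occ * d_g)
      li <- li - n_g * log(ps)
      ## sum over m_g: ZT-Poisson prior times ZT-Binomial for n_g
      lz <- outer(mgrid, lam, function(m, l) dpois(m, l, log = TRUE))
      lz <- sweep(lz, 2, ppois(min_size - 1, lam, lower.tail = FALSE,
                               log.p = TRUE))
      lt <- lz + lchoose(mgrid, n_g) +
        outer(mgrid - n_g, log1p(-ps)) -
        outer(mgrid, ps, function(m, p) log1p(-(1 - p)^m)) +
        rep(n_g * log(ps), each = length(mgrid))
      lt[mgrid < max(n_g, min_size), ] <- -Inf
      mx <- apply(lt, 2, max)
      ew <- exp(sweep(lt, 2, mx))
      wsum <- colSums(ew)
      Em <- colSums(mgrid * ew) / wsum
      logw <- logw + li + mx + log(wsum)
      EN <- EN + Em
    }
    logw_all <- c(logw_all, logw)
    EN_all <- c(EN_all, EN)
  }
  W_is <- exp(logw_all - max(logw_all))
  list(EN = sum(W_is * EN_all) / sum(W_is),
       ess = sum(W_is)^2 / sum(W_is^2))
}

# deterministic small capture dataset used by several files
fixture_captures <- function(seed = 301, p_g = 0.7, p_i = 0.7,
                             n_groups = 15, lambda = 8, n_solitaries = 0,
                             p_s = 0.3) {
  pop <- simulate_population(n_groups, lambda, n_solitaries = n_solitaries,
                             seed = seed)
  simulate_capture_histories(pop, p_g, p_i, K = 2, T_occ = 3, p_s = p_s,
                             seed = seed + 1)
}
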