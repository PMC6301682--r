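#' Assemble Two-Step model data from capture histories
#'
#' Restricts a capture dataset to its observed part: groups detected in at
#' least one sweep, and—within those—individuals detected at least once.
#' Individual nest-site detections are reduced to per-sweep counts in
#' `0..T_occ`, the sufficient statistic under a constant per-occasion
#' detection probability. Validates the conditional-detection invariant (no
#' individual detection inside a sweep in which the group was not detected).
#'
#' @param x A `cmr_captures` object from [simulate_capture_histories()], or a
#'   list of parsed capture records from [read_capture_csv()] (elements
#'   `grouped` and optionally `solitary`). For parsed records, a group's
#'   sweep-level detection is inferred as "any member sampled in that sweep".
#' @param K,T_occ Sweeps and nest sites per sweep (taken from `x` when it is a
#'   `cmr_captures`).
#' @return Object of class `cmr_twostep_data`: list with `W` (observed groups
#'   x K binary), `counts` (list of per-group matrices, observed individuals x
#'   K sweep counts), `n_counts` (observed individuals per group),
#'   `solitary_W` (observed solitaries x K binary), `K`, `T_occ`.
#' @export
build_group_data <- function(x, K = NULL, T_occ = NULL) {
  if (inherits(x, "cmr_captures")) {
    K <- x$K; T_occ <- x$T_occ
    sweep_of <- rep(seq_len(K), each = T_occ)
    cnt <- vapply(seq_len(K), function(k)
      rowSums(x$individual_detections[, sweep_of == k, drop = FALSE]),
      numeric(nrow(x$individual_detections)))
    cnt <- matrix(as.integer(cnt), ncol = K)
    ## invariant: no individual detections in an undetected sweep
    bad <- which(cnt > 0 & x$group_detections[x$membership, , drop = FALSE] == 0,
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("individual ", bad[1, 1], " detected in sweep ", bad[1, 2],
           " but its group was not detected in that sweep", call. = FALSE)
    obs_groups <- which(rowSums(x$group_detections) > 0)
    W <- x$group_detections[obs_groups, , drop = FALSE]
    counts <- lapply(obs_groups, function(g) {
      rows <- cnt[x$membership == g, , drop = FALSE]
      rows[rowSums(rows) > 0, , drop = FALSE]
    })
    sol_W <- x$solitary_detections
    sol_W <- sol_W[rowSums(sol_W) > 0, , drop = FALSE]
  } else if (is.list(x) && !is.null(x$grouped)) {
    rec <- x$grouped
    if (is.null(K)) K <- ncol(rec$counts)
    if (is.null(T_occ)) T_occ <- max(1L, max(rec$counts))
    gid <- factor(rec$group_id)
    counts <- lapply(levels(gid), function(g)
      rec$counts[gid == g, , drop = FALSE])
    if (!is.null(x$groups)) {
      ## sweep-level group records supplied: restrict to groups with members
      idx <- match(levels(gid), x$groups$group_id)
      if (anyNA(idx))
        stop("group(s) missing from the group-detection records: ",
             paste(levels(gid)[is.na(idx)], collapse = ", "), call. = FALSE)
      W <- x$groups$W[idx, , drop = FALSE]
    } else {
      ## infer group detection: a sweep counts as detected if any member was
      ## sampled in it (adequate unless whole detected nest sites yield no
      ## samples)
      W <- t(vapply(counts, function(m) as.integer(colSums(m) > 0), integer(K)))
    }
    sol_W <- if (!is.null(x$solitary))
      as.matrix(x$solitary$counts > 0) * 1L else matrix(0L, 0, K)
  } else stop("`x` must be a cmr_captures object or parsed capture records",
              call. = FALSE)

  if (any(rowSums(W) == 0))
    stop("internal error: all-zero group detection row", call. = FALSE)
  if (any(unlist(lapply(counts, rowSums)) == 0))
    stop("all-zero individual history in observed data", call. = FALSE)
  for (g in seq_along(counts)) {
    viol <- counts[[g]][, W[g, ] == 0, drop = FALSE]
    if (length(viol) && any(viol > 0))
      stop("group ", g, ": individual counts in an undetected sweep",
           call. = FALSE)
    if (any(counts[[g]] > T_occ))
      stop("group ", g, ": sweep count exceeds T = ", T_occ, call. = FALSE)
  }
  structure(list(W = W, counts = counts,
                 n_counts = vapply(counts, nrow, integer(1)),
                 solitary_W = sol_W,
                 K = as.integer(K), T_occ = as.integer(T_occ)),
            class = "cmr_twostep_data")
}

#' @export
print.cmr_twostep_data <- function(x, ...) {
  cat("Two-Step CMR data:", nrow(x$W), "observed groups (",
      sum(x$n_counts), "individuals ),", nrow(x$solitary_W),
      "observed solitaries;", x$K, "sweeps x", x$T_occ, "nest sites\n")
  invisible(x)
}

## default augmentation sizes; generous enough that the ceiling warning
## rarely fires at the detection levels of interest
default_M_groups <- function(n_obs) max(3L * n_obs, n_obs + 20L)
default_M_individuals <- function(n_obs) 3L * n_obs
default_M_solitaries <- function(n_obs) max(8L * n_obs, n_obs + 20L)

ceiling_warning <- function(draws, M, what) {
  if (mean(draws > 0.95 * M) > 0.01)
    warning("posterior of ", what, " has mass near the augmentation ceiling (M = ",
            M, "); increase M", call. = FALSE)
}

## dispersed initial value for a detection probability
init_prob <- function(est) min(0.95, max(0.05, est + stats::runif(1, -0.15, 0.15)))

run_chains <- function(cfg, one_chain) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lapply(seq_len(cfg$n_chains), function(ch) {
    draws <- one_chain(cfg$n_iter, cfg$burn_in)
    if (cfg$thin > 1L)
      draws <- draws[seq(1L, nrow(draws), by = cfg$thin), , drop = FALSE]
    draws
  })
}

## refit once with doubled iterations if any r-hat >= 1.1
rhat_gate <- function(summary, cfg, refit) {
  r <- max_rhat(summary)
  if (!is.na(r) && r >= 1.1) {
    cfg$n_iter <- 2L * cfg$n_iter
    summary2 <- refit(cfg)
    r2 <- max_rhat(summary2)
    if (!is.na(r2) && r2 >= 1.1)
      warning("chains not converged after extension (max r-hat = ",
              round(r2, 3), ")", call. = FALSE)
    return(summary2)
  }
  summary
}

#' Fit the conventional One-Step closed CMR model
#'
#' Individual sweep-level detection histories `y_ik ~ Bernoulli(z_i p)` with
#' data augmentation: the observed histories are augmented with `M -
#' n_observed` all-zero rows and inclusion indicators `z_i ~
#' Bernoulli(psi)`; abundance is `N = sum(z_i)`. Priors are uniform(0,1) on
#' `p` and `psi`. All updates are conjugate Gibbs steps.
#'
#' @param y Binary matrix of observed individuals x sweeps (every row
#'   nonzero), e.g. from [condense_sweep_histories()].
#' @param M Total number of individual rows after augmentation; default
#'   `3 * nrow(y)`.
#' @param mcmc An [mcmc_config()].
#' @return A [summarize_draws()] `posterior_summary` for `p`, `psi`, `N`.
#' @export
fit_onestep <- function(y, M = NULL, mcmc = mcmc_config()) {
  y <- as.matrix(y)
  if (any(rowSums(y) == 0))
    stop("`y` must contain observed (nonzero) histories only", call. = FALSE)
  n_obs <- nrow(y); K <- ncol(y); S_det <- sum(y)
  if (is.null(M)) M <- default_M_individuals(n_obs)
  if (M <= n_obs) stop("augmented size M must exceed observed rows", call. = FALSE)

  fit_once <- function(cfg) {
    chains <- run_chains(cfg, function(n_iter, burn_in) {
      p0 <- init_prob(S_det / (n_obs * K))
      onestep_mcmc_chain(n_obs, S_det, K, M, n_iter, burn_in, p0)
    })
    s <- summarize_draws(chains, integer_params = "N")
    ceiling_warning(do.call(rbind, chains)[, "N"], M, "N")
    s
  }
  s <- fit_once(mcmc)
  rhat_gate(s, mcmc, fit_once)
}

#' Fit the Two-Step closed CMR model
#'
#' Step one estimates the number of groups `G` from sweep-level group
#' detection histories with data augmentation (`W_gk ~ Bernoulli(z_g p_g)`,
#' `z_g ~ Bernoulli(psi_g)`). Step two estimates each observed group's size
#' `m_g`: the collection of individual histories in a detected group is
#' conditional-multinomial with per-occasion detection probability `p_i`
#' zeroed in undetected sweeps, and the number of observed members `n_g` is
#' zero-truncated Binomial(`m_g`, `p*`). Group sizes follow a zero-truncated
#' Poisson with mean parameter `lambda ~ uniform(0, lambda_upper)`; sizes of
#' included never-detected groups are fresh draws from that distribution.
#' Total abundance is the sum of `m_g` over included groups.
#'
#' @param data A `cmr_twostep_data` from [build_group_data()].
#' @param M_groups Total group rows after augmentation; default
#'   `max(3 * observed, observed + 20)`.
#' @param mcmc An [mcmc_config()].
#' @param group_size_min Lower truncation bound for group size (1 for general
#'   use; 2 when singletons are modelled as solitaries).
#' @param lambda_upper Upper bound of the uniform prior on mean group size.
#' @return A `posterior_summary` for `p_g`, `p_i`, `psi_g`, `lambda`, `G`, `N`.
#' @export
fit_twostep <- function(data, M_groups = NULL, mcmc = mcmc_config(),
                        group_size_min = 1L, lambda_upper = 30) {
  stopifnot(inherits(data, "cmr_twostep_data"))
  fit_twostep_impl(data, M_groups, M_solitaries = 0L, mcmc,
                   group_size_min, lambda_upper)
}

#' Fit the Two-Step model with a solitary-individual component
#'
#' Extension for populations containing lone animals: solitaries have their
#' own per-sweep detection probability `p_s` and their number `S` is
#' estimated with a separate data-augmentation step; group sizes are
#' truncated at `group_size_min = 2` by default (a "group" of one is a
#' solitary). Total abundance is `N = sum(m_g) + S`.
#'
#' @inheritParams fit_twostep
#' @param M_solitaries Total solitary rows after augmentation; default
#'   `max(8 * observed, observed + 20)` (solitary detection tends to be low,
#'   so the posterior of `S` is wide). With no observed solitaries and
#'   `M_solitaries = 0` the fit reduces exactly to [fit_twostep()].
#' @return A `posterior_summary` adding `p_s`, `psi_s`, `S`.
#' @export
fit_twostep_solitaries <- function(data, M_groups = NULL, M_solitaries = NULL,
                                   mcmc = mcmc_config(), group_size_min = 2L,
                                   lambda_upper = 30) {
  stopifnot(inherits(data, "cmr_twostep_data"))
  n_sol <- nrow(data$solitary_W)
  if (is.null(M_solitaries)) M_solitaries <- default_M_solitaries(n_sol)
  if (M_solitaries > 0 && M_solitaries <= n_sol)
    stop("M_solitaries must exceed the number of observed solitaries",
         call. = FALSE)
  fit_twostep_impl(data, M_groups, M_solitaries, mcmc,
                   group_size_min, lambda_upper)
}

fit_twostep_impl <- function(data, M_groups, M_solitaries, mcmc,
                             group_size_min, lambda_upper) {
  W <- data$W
  nG <- nrow(W); K <- data$K; T_occ <- data$T_occ
  if (nG < 1) stop("no observed groups", call. = FALSE)
  if (is.null(M_groups)) M_groups <- default_M_groups(nG)
  if (M_groups <= nG) stop("M_groups must exceed observed groups", call. = FALSE)
  n_g <- data$n_counts
  d_g <- as.integer(rowSums(W))
  S_ind <- sum(vapply(data$counts, sum, numeric(1)))
  Tr_ind <- sum(n_g * T_occ * d_g)
  n_sol <- nrow(data$solitary_W)
  S_sol <- sum(data$solitary_W)
  m_cap <- max(80L, max(n_g) + 20L)
  if (lambda_upper <= max(n_g))
    warning("uniform prior upper bound for lambda is below the largest ",
            "observed group; estimates will be constrained", call. = FALSE)

  fit_once <- function(cfg) {
    chains <- run_chains(cfg, function(n_iter, burn_in) {
      pg0 <- init_prob(mean(W))
      pi0 <- init_prob(S_ind / max(1, Tr_ind))
      lam0 <- min(lambda_upper - 0.5,
                  max(group_size_min + 0.5,
                      mean(pmax(n_g, group_size_min)) * stats::runif(1, 0.8, 1.3)))
      twostep_mcmc_chain(n_g, d_g, sum(W), S_ind, Tr_ind, K, T_occ,
                         M_groups, group_size_min, lambda_upper,
                         n_sol, S_sol, M_solitaries,
                         n_iter, burn_in, m_cap, pg0, pi0, lam0)
    })
    s <- summarize_draws(chains, integer_params = c("G", "N", "S"))
    all_d <- do.call(rbind, chains)
    ceiling_warning(all_d[, "G"], M_groups, "G")
    if (M_solitaries > 0) ceiling_warning(all_d[, "S"], M_solitaries, "S")
    s
  }
  s <- fit_once(mcmc)
  rhat_gate(s, mcmc, fit_once)
}

#' Two-Step observed-data log-likelihood at fixed parameter values
#'
#' Joint log-density of the observed group detection histories, the observed
#' individual sweep counts (conditional multinomial), the observed member
#' counts (zero-truncated Binomial) and the group sizes (zero-truncated
#' Poisson), for the observed groups only, at fixed `p_g`, `p_i`, `lambda`
#' and group sizes `m`. Exists chiefly so the sampler can be checked against
#' brute-force enumeration on small datasets.
#'
#' @param data A `cmr_twostep_data`.
#' @param p_g,p_i,lambda Parameter values.
#' @param m Integer vector of group sizes, one per observed group, each at
#'   least the group's observed count.
#' @param group_size_min Truncation bound of the group-size distribution.
#' @return The log-likelihood (a scalar).
#' @export
twostep_loglik <- function(data, p_g, p_i, lambda, m, group_size_min = 1L) {
  stopifnot(inherits(data, "cmr_twostep_data"),
            length(m) == nrow(data$W), all(m >= data$n_counts))
  ll <- 0
  for (g in seq_len(nrow(data$W))) {
    w <- data$W[g, ]
    ll <- ll + sum(stats::dbinom(w, 1, p_g, log = TRUE))
    ps <- p_star(p_i, w, data$T_occ)
    cnt <- data$counts[[g]]
    for (k in which(w == 1))
      ll <- ll + sum(stats::dbinom(cnt[, k], data$T_occ, p_i, log = TRUE))
    ll <- ll - nrow(cnt) * log(ps)
    ll <- ll + dztbinom(nrow(cnt), m[g], ps, log = TRUE)
    ll <- ll + dztpois(m[g], lambda, group_size_min, log = TRUE)
  }
  ll
}
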