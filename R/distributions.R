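#' Zero-truncated Poisson density
#'
#' Probability mass function of a Poisson random variable conditioned on being
#' at least `min_value`. Used for group sizes: a group must contain at least one
#' member (`min_value = 1`), or at least two when lone animals are modelled
#' separately from groups (`min_value = 2`).
#'
#' @param x Integer vector of quantiles.
#' @param lambda Positive Poisson rate before truncation.
#' @param min_value Integer lower truncation bound, at least 1.
#' @param log Logical; return log-probabilities?
#' @return Numeric vector of (log-)probabilities. Values of `x` below
#'   `min_value` (or non-integer) have probability 0 (`-Inf` on the log scale),
#'   never an error, so samplers can reject naturally.
#' @examples
#' dztpois(1, lambda = 1)                  # e^-1 / (1 - e^-1)
#' sum(dztpois(1:60, lambda = 13))         # ~1
#' @export
dztpois <- function(x, lambda, min_value = 1L, log = FALSE) {
  check_ztpois_params(lambda, min_value)
  lp <- stats::dpois(x, lambda, log = TRUE) - ztpois_lognorm(lambda, min_value)
  bad <- x < min_value | x != floor(x)
  lp[bad] <- -Inf
  if (log) lp else exp(lp)
}

## log P(Poisson(lambda) >= min_value), the truncation normalizer
ztpois_lognorm <- function(lambda, min_value) {
  stats::ppois(min_value - 1, lambda, lower.tail = FALSE, log.p = TRUE)
}

check_ztpois_params <- function(lambda, min_value) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("`lambda` must be a single positive finite number", call. = FALSE)
  if (length(min_value) != 1L || min_value < 1 || min_value != floor(min_value))
    stop("`min_value` must be a single integer >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Mean of the zero-truncated Poisson distribution
#'
#' Equals `lambda / (1 - exp(-lambda))` when `min_value = 1`; computed from the
#' truncated-mean identity for general bounds.
#'
#' @inheritParams dztpois
#' @return The expectation of the truncated variable.
#' @export
ztpois_mean <- function(lambda, min_value = 1L) {
  check_ztpois_params(lambda, min_value)
  ## E[X | X >= a] = lambda * P(X >= a - 1) / P(X >= a)
  exp(log(lambda) +
        stats::ppois(min_value - 2, lambda, lower.tail = FALSE, log.p = TRUE) -
        ztpois_lognorm(lambda, min_value))
}

#' Sample from the zero-truncated Poisson distribution
#'
#' Exact inverse-CDF sampling on the truncated support (no rejection, so small
#' rates behave well).
#'
#' @param n Number of draws.
#' @inheritParams dztpois
#' @return Integer vector of length `n`, all values `>= min_value`.
#' @export
rztpois <- function(n, lambda, min_value = 1L) {
  check_ztpois_params(lambda, min_value)
  ## U on (P(X < min_value), 1), then invert the untruncated CDF
  p0 <- stats::ppois(min_value - 1, lambda)
  u <- p0 + stats::runif(n) * (1 - p0)
  as.integer(stats::qpois(pmin(u, 1 - 1e-16), lambda))
}

#' Zero-truncated Binomial density
#'
#' Probability mass of a Binomial(`size`, `prob`) variable conditioned on being
#' nonzero. Models the number of group members observed at least once, given
#' that the group itself was detected.
#'
#' @param x Integer vector of quantiles.
#' @param size Integer number of trials (group size), at least 1.
#' @param prob Per-trial success probability in \[0, 1\].
#' @param log Logical; return log-probabilities?
#' @return Numeric vector; `x = 0` or `x > size` yields 0 (`-Inf` on the log
#'   scale). `prob = 0` gives log-zero for any positive `x`, not an error.
#' @export
dztbinom <- function(x, size, prob, log = FALSE) {
  if (any(size < 1) || any(prob < 0) || any(prob > 1))
    stop("`size` must be >= 1 and `prob` in [0,1]", call. = FALSE)
  if (prob == 0) return(if (log) rep(-Inf, length(x)) else numeric(length(x)))
  lp <- stats::dbinom(x, size, prob, log = TRUE) -
    log1p(-stats::dbinom(0, size, prob))
  lp[x < 1 | x > size | x != floor(x)] <- -Inf
  if (log) lp else exp(lp)
}

#' Probability of detecting a group member at least once
#'
#' Given the group's per-sweep detection pattern `w` over `K` sweeps and `T`
#' nest-site sub-occasions per sweep, an individual with per-occasion detection
#' probability `p_i` is missed entirely with probability
#' `prod((1 - p_i * w_k)^T)`. `p_star()` is the complement: the conditioning
#' denominator for observed detection histories. It is 0 when the group was
#' never detected.
#'
#' @param p_i Individual per-occasion detection probability.
#' @param w Binary vector of the group's sweep-level detections.
#' @param T_occ Integer number of nest sites (sub-occasions) per sweep.
#' @return Probability of at least one detection.
#' @examples
#' p_star(0.7, c(1, 1), 1)  # 1 - 0.3^2 = 0.91
#' @export
p_star <- function(p_i, w, T_occ) {
  stopifnot(p_i >= 0, p_i <= 1, all(w %in% c(0, 1)), T_occ >= 1)
  1 - prod((1 - p_i * w)^T_occ)
}

#' Conditional multinomial cell probabilities for individual histories
#'
#' Enumerates every binary detection history over the `K * T_occ` occasions that
#' is observable: nonzero overall, and zero at every occasion of a sweep in
#' which the group was not detected. Each history's unconditional Bernoulli
#' probability is divided by [p_star()] so the cells sum to 1 — the multinomial
#' distribution of the collection of observed individual histories in a
#' detected group.
#'
#' Histories are labelled by their occasion string (sweep-major: occasions
#' `1..T_occ` of sweep 1, then sweep 2, ...) and returned in plain binary
#' lexicographic ascending order of that string (e.g. `"01" < "10" < "11"`).
#'
#' @inheritParams p_star
#' @return Named numeric vector of cell probabilities summing to 1; names are
#'   the occasion strings.
#' @examples
#' history_cell_probs(0.7, c(1, 1), 1)  # cells 01, 10, 11
#' @export
history_cell_probs <- function(p_i, w, T_occ) {
  stopifnot(p_i >= 0, p_i <= 1, all(w %in% c(0, 1)), T_occ >= 1)
  if (!any(w == 1))
    stop("no observable histories: group undetected in every sweep", call. = FALSE)
  K <- length(w)
  occ_open <- rep(w == 1, each = T_occ)          # occasions where detection is possible
  n_open <- sum(occ_open)
  ps <- p_star(p_i, w, T_occ)
  ## enumerate histories over open occasions only; closed occasions are 0
  combos <- as.matrix(expand.grid(rep(list(0:1), n_open)))[-1, , drop = FALSE]
  full <- matrix(0L, nrow(combos), K * T_occ)
  full[, occ_open] <- combos
  pr <- apply(combos, 1L, function(h) prod(p_i^h * (1 - p_i)^(1 - h))) / ps
  labs <- apply(full, 1L, paste0, collapse = "")
  ord <- order(labs)
  stats::setNames(pr[ord], labs[ord])
}
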