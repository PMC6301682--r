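#' MCMC settings
#'
#' Defaults follow common practice for these models: 3 parallel chains of
#' 50,000 iterations with the first 1,000 discarded as burn-in. `preset =
#' "fast"` is the documented reduced setting used by the simulation-study
#' harness (3 chains x 6,000 iterations, 1,000 burn-in) so that a
#' hundred-replicate scenario finishes in minutes on one core; an automatic
#' one-shot 2x extension is applied by the fitters when any monitored
#' parameter has r-hat >= 1.1.
#'
#' @param n_chains Number of chains (>= 1; >= 2 needed for r-hat).
#' @param n_iter Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded from the front of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed for the whole run.
#' @param preset `"paper"` (full-length) or `"fast"` (study mode); explicit
#'   `n_iter`/`burn_in` arguments override the preset.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = NULL, burn_in = NULL,
                        thin = 1L, seed = NULL, preset = c("paper", "fast")) {
  preset <- match.arg(preset)
  if (is.null(n_iter)) n_iter <- if (preset == "fast") 6000L else 50000L
  if (is.null(burn_in)) burn_in <- 1000L
  stopifnot(n_chains >= 1, thin >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, preset = preset),
            class = "mcmc_config")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split, non-rank-normalized) form, matching its long-standing
#' use with general-purpose Gibbs samplers: with `m` chains of length `n`,
#' within-chain variance `W` and between-chain variance `B`,
#' `rhat = sqrt(((n-1)/n * W + B/n) / W)`.
#'
#' @param draws Matrix with one column per chain (or a list of equal-length
#'   numeric vectors, one per chain).
#' @return The r-hat estimate. Chains that are all constant and identical
#'   return 1 by convention.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L)
    stop("r-hat needs at least 2 chains", call. = FALSE)
  if (nrow(draws) < 2L)
    stop("r-hat needs at least 2 draws per chain", call. = FALSE)
  n <- nrow(draws)
  W <- mean(apply(draws, 2L, stats::var))
  B <- n * stats::var(colMeans(draws))
  if (W == 0) return(1)   # degenerate: zero within-chain variance
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior draws
#'
#' Equal-tailed credible intervals at the 2.5 and 97.5 percentiles. For
#' real-valued parameters quantiles use linear interpolation between order
#' statistics (R type 7); for integer-valued parameters (abundances, counts)
#' the nearest-rank convention (type 1) is used so interval endpoints are
#' achieved draw values — posterior means are never rounded.
#'
#' @param chains List of per-chain draw matrices (post-burn-in iterations x
#'   parameters, identical column names).
#' @param integer_params Character vector of parameter names summarized on the
#'   integer scale.
#' @param level Credible level (default 0.95).
#' @return Object of class `posterior_summary`: a data.frame with columns
#'   `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, and the draws kept in
#'   attribute `"chains"`.
#' @export
summarize_draws <- function(chains, integer_params = character(), level = 0.95) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  chains <- lapply(chains, as.matrix)
  if (nrow(chains[[1L]]) == 0L) stop("no post-burn-in draws", call. = FALSE)
  pars <- colnames(chains[[1L]])
  all_draws <- do.call(rbind, chains)
  alpha <- (1 - level) / 2
  rows <- lapply(pars, function(p) {
    x <- all_draws[, p]
    qt <- if (p %in% integer_params) 1L else 7L
    q <- stats::quantile(x, c(alpha, 1 - alpha), type = qt, names = FALSE)
    rhat <- if (length(chains) >= 2L)
      gelman_rubin(lapply(chains, function(ch) ch[, p])) else NA_real_
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1L], q97.5 = q[2L], rhat = rhat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$parameter
  attr(out, "chains") <- chains
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  attr(df, "chains") <- NULL
  print.data.frame(df, digits = digits, row.names = FALSE, ...)
  bad <- df$parameter[!is.na(df$rhat) & df$rhat >= 1.1]
  if (length(bad))
    cat("Warning: r-hat >= 1.1 for:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Extract posterior draws from a summary
#'
#' @param x A `posterior_summary`.
#' @param parameter Optional parameter name; if given, returns a matrix of
#'   that parameter's draws (iterations x chains), else the list of per-chain
#'   draw matrices.
#' @return See above.
#' @export
posterior_draws <- function(x, parameter = NULL) {
  chains <- attr(x, "chains")
  if (is.null(parameter)) return(chains)
  sapply(chains, function(ch) ch[, parameter])
}

#' Export draws as a long rectangular table
#'
#' @param x A `posterior_summary`.
#' @return data.frame with columns `chain`, `iteration`, then one column per
#'   parameter; suitable for writing to CSV for cross-tool comparison.
#' @export
draws_table <- function(x) {
  chains <- attr(x, "chains")
  do.call(rbind, lapply(seq_along(chains), function(i) {
    data.frame(chain = i, iteration = seq_len(nrow(chains[[i]])),
               chains[[i]], check.names = FALSE)
  }))
}

## max r-hat over monitored parameters; NA-safe (single chain)
max_rhat <- function(summary) {
  r <- summary$rhat
  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
}
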