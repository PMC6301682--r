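#' Simulate a group-structured population
#'
#' Group sizes are independent zero-truncated Poisson draws; solitary
#' individuals (animals never associated with a group) are counted separately.
#' Total abundance is `sum(group_sizes) + n_solitaries`.
#'
#' @param n_groups Number of groups (>= 1).
#' @param lambda Poisson rate of the group-size distribution before truncation.
#' @param min_size Lower truncation bound on group size.
#' @param n_solitaries Number of solitary individuals (>= 0).
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return An object of class `cmr_population`: list with `group_sizes`,
#'   `n_solitaries`, `N` (total abundance).
#' @export
simulate_population <- function(n_groups, lambda = 13, min_size = 1L,
                                n_solitaries = 0L, seed = NULL) {
  stopifnot(n_groups >= 1, n_solitaries >= 0)
  if (!is.null(seed)) set.seed(seed)
  sizes <- rztpois(n_groups, lambda, min_size)
  structure(list(group_sizes = sizes,
                 n_solitaries = as.integer(n_solitaries),
                 N = sum(sizes) + as.integer(n_solitaries)),
            class = "cmr_population")
}

#' @export
print.cmr_population <- function(x, ...) {
  cat("Group-structured population:", length(x$group_sizes), "groups,",
      x$n_solitaries, "solitaries, N =", x$N, "\n")
  invisible(x)
}

#' Simulate sweep-by-nest-site capture histories
#'
#' Mirrors a nest-survey design: each of `K` sweeps is a full search of the
#' study area during which each group is detected with probability `p_g`.
#' Within a detected sweep, each group member is detected at each of `T_occ`
#' nest sites with probability `p_i`; members of a group not detected in a
#' sweep have all-zero histories for that sweep, by construction. Solitaries
#' get a single Bernoulli(`p_s`) trial per sweep (a lone animal builds one
#' nest per night, so there is no nest-site sub-occasion).
#'
#' @param pop A `cmr_population`.
#' @param p_g Per-sweep group detection probability.
#' @param p_i Per-nest-site individual detection probability, conditional on
#'   group detection.
#' @param K Number of sweeps.
#' @param T_occ Nest sites per sweep.
#' @param p_s Per-sweep solitary detection probability.
#' @param seed Optional integer seed.
#' @return An object of class `cmr_captures`: list with
#'   `group_detections` (G x K binary), `individual_detections`
#'   (N_grouped x (K*T_occ) binary, occasions sweep-major), `membership`
#'   (group index per grouped individual), `solitary_detections`
#'   (n_solitaries x K binary), and the detection parameters.
#' @export
simulate_capture_histories <- function(pop, p_g, p_i, K = 2L, T_occ = 3L,
                                       p_s = p_g, seed = NULL) {
  stopifnot(inherits(pop, "cmr_population"),
            p_g >= 0, p_g <= 1, p_i >= 0, p_i <= 1, p_s >= 0, p_s <= 1,
            K >= 1, T_occ >= 1)
  if (!is.null(seed)) set.seed(seed)
  G <- length(pop$group_sizes)
  n_ind <- sum(pop$group_sizes)
  membership <- rep(seq_len(G), pop$group_sizes)

  gdet <- matrix(stats::rbinom(G * K, 1L, p_g), G, K)
  ## occasion-level individual detections, masked by the group's sweep detection
  occ_mask <- gdet[membership, rep(seq_len(K), each = T_occ), drop = FALSE]
  idet <- matrix(stats::rbinom(n_ind * K * T_occ, 1L, p_i), n_ind, K * T_occ) * occ_mask

  sdet <- matrix(stats::rbinom(pop$n_solitaries * K, 1L, p_s),
                 pop$n_solitaries, K)

  structure(list(group_detections = gdet,
                 individual_detections = idet,
                 membership = membership,
                 solitary_detections = sdet,
                 p_g = p_g, p_i = p_i, p_s = p_s,
                 K = as.integer(K), T_occ = as.integer(T_occ),
                 population = pop),
            class = "cmr_captures")
}

#' @export
print.cmr_captures <- function(x, ...) {
  cat("Capture histories:", nrow(x$group_detections), "groups x", x$K,
      "sweeps,", x$T_occ, "nest sites/sweep;",
      sum(rowSums(x$individual_detections) > 0), "of",
      nrow(x$individual_detections), "grouped individuals detected\n")
  invisible(x)
}

#' Condense nest-site detections to one binary record per sweep
#'
#' The conventional (One-Step) model treats sweeps as the only occasions: an
#' individual's record for sweep `k` is 1 if it was detected at any nest site
#' during that sweep. Never-detected individuals are dropped (observed-only
#' data); detected solitaries are appended, their per-sweep records already
#' being binary.
#'
#' @param cap A `cmr_captures` object.
#' @return Binary matrix, rows = observed individuals, columns = sweeps; every
#'   row contains at least one 1.
#' @export
condense_sweep_histories <- function(cap) {
  stopifnot(inherits(cap, "cmr_captures"))
  K <- cap$K; T_occ <- cap$T_occ
  sweep_of <- rep(seq_len(K), each = T_occ)
  y <- vapply(seq_len(K), function(k)
    as.integer(rowSums(cap$individual_detections[, sweep_of == k, drop = FALSE]) > 0),
    integer(nrow(cap$individual_detections)))
  y <- matrix(y, ncol = K)
  y <- rbind(y, cap$solitary_detections)
  y[rowSums(y) > 0, , drop = FALSE]
}

#' Summaries of an observed capture dataset
#'
#' @param cap A `cmr_captures` object.
#' @return List with `prop_groups_detected` (fraction of groups seen at least
#'   once), `prop_members_detected` (fraction of members of detected groups
#'   seen at least once), `observed_group_sizes` (number observed per detected
#'   group) and `sweep_counts` (individuals detected per sweep).
#' @export
observed_summaries <- function(cap) {
  stopifnot(inherits(cap, "cmr_captures"))
  gdet_any <- rowSums(cap$group_detections) > 0
  ind_det <- rowSums(cap$individual_detections) > 0
  in_det_group <- gdet_any[cap$membership]
  K <- cap$K; T_occ <- cap$T_occ
  sweep_of <- rep(seq_len(K), each = T_occ)
  sweep_counts <- vapply(seq_len(K), function(k)
    sum(rowSums(cap$individual_detections[, sweep_of == k, drop = FALSE]) > 0),
    integer(1))
  list(prop_groups_detected = mean(gdet_any),
       prop_members_detected = if (any(in_det_group))
         mean(ind_det[in_det_group]) else 0,
       observed_group_sizes = as.integer(
         table(factor(cap$membership[ind_det], levels = which(gdet_any)))),
       sweep_counts = sweep_counts)
}

#' Derive reproducible per-replicate seeds from one base seed
#'
#' A single base seed deterministically spawns one sub-seed per replicate by
#' seeding R's generator with the base and drawing `n` integers; replicate `r`
#' then seeds its own simulation and fit with `seeds[r]`. The scheme gives
#' exactly reproducible studies from one integer while keeping replicate
#' streams distinct.
#'
#' @param base_seed Single integer.
#' @param n Number of replicates.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
replicate_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
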