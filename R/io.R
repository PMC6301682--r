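#' Describe a capture-history CSV dialect
#'
#' Capture-history files carry one row per observed individual: an identifier
#' column, optionally a group column (absent for a solitaries file), and one
#' column per sweep holding either a binary indicator or a count of nest
#' sites in `0..T_occ` at which the individual was sampled ("summed by
#' sweep").
#'
#' @param id_column Name of the individual identifier column.
#' @param group_column Name of the group column, or `NULL` for solitaries.
#' @param sweep_columns Ordered character vector of sweep column names.
#' @param value_semantics `"binary"` or `"count"`.
#' @param T_occ Maximum count per sweep under count semantics.
#' @return Object of class `capture_dialect`.
#' @export
capture_dialect <- function(id_column = "individual_id",
                            group_column = "group_id",
                            sweep_columns = c("sweep1", "sweep2"),
                            value_semantics = c("count", "binary"),
                            T_occ = 3L) {
  value_semantics <- match.arg(value_semantics)
  if (!length(sweep_columns)) stop("need at least one sweep column", call. = FALSE)
  structure(list(id_column = id_column, group_column = group_column,
                 sweep_columns = sweep_columns,
                 value_semantics = value_semantics, T_occ = as.integer(T_occ)),
            class = "capture_dialect")
}

#' Read a capture-history CSV
#'
#' Validates against the dialect and fails loudly: missing columns,
#' non-integer or negative values, counts above `T_occ`, duplicate individual
#' identifiers and all-zero rows (the files contain observed individuals
#' only) are each a distinct error naming the offender.
#'
#' @param path CSV file path.
#' @param dialect A [capture_dialect()]; its `group_column` decides whether
#'   the file is read as grouped individuals or solitaries.
#' @return List with `id`, `group_id` (absent for solitaries), and `counts`
#'   (matrix individuals x sweeps, integer).
#' @export
read_capture_csv <- function(path, dialect = capture_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("no records in ", path, call. = FALSE)
  need <- c(dialect$id_column, dialect$group_column, dialect$sweep_columns)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- as.character(df[[dialect$id_column]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate individual id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  cnt <- as.matrix(df[dialect$sweep_columns])
  if (!is.numeric(cnt) || any(is.na(cnt)) || any(cnt != floor(cnt)) || any(cnt < 0))
    stop("sweep columns must hold non-negative integers (", path, ")",
         call. = FALSE)
  cap <- if (dialect$value_semantics == "binary") 1L else dialect$T_occ
  over <- which(cnt > cap, arr.ind = TRUE)
  if (nrow(over))
    stop("individual ", ids[over[1, 1]], ": sweep count ",
         cnt[over[1, 1], over[1, 2]], " exceeds maximum ", cap, call. = FALSE)
  zero <- which(rowSums(cnt) == 0)
  if (length(zero))
    stop("all-zero capture history for individual ", ids[zero[1]],
         " (files contain observed individuals only)", call. = FALSE)
  storage.mode(cnt) <- "integer"
  out <- list(id = ids, counts = cnt)
  if (!is.null(dialect$group_column))
    out$group_id <- as.character(df[[dialect$group_column]])
  out
}

#' Read sweep-level group detection records
#'
#' Companion to [read_capture_csv()]: one row per group, binary detection per
#' sweep. Supplying these to [build_group_data()] avoids inferring group
#' detections from member samples.
#'
#' @param path CSV file path.
#' @param sweep_columns Ordered sweep column names.
#' @param group_column Name of the group identifier column.
#' @return List with `group_id` and `W` (binary matrix groups x sweeps).
#' @export
read_group_csv <- function(path, sweep_columns = c("sweep1", "sweep2"),
                           group_column = "group_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c(group_column, sweep_columns), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  W <- as.matrix(df[sweep_columns])
  if (any(!W %in% c(0, 1)))
    stop("group sweep records must be binary (", path, ")", call. = FALSE)
  storage.mode(W) <- "integer"
  list(group_id = as.character(df[[group_column]]), W = W)
}

#' Write simulated capture histories to CSV
#'
#' Two files: individual histories (one column per sweep x nest-site
#' occasion, plus per-sweep summed counts) and group sweep-level detections.
#' The summed-by-sweep columns round-trip through [read_capture_csv()] with
#' the default count dialect.
#'
#' @param cap A `cmr_captures` object.
#' @param individuals_path,groups_path Output CSV paths.
#' @param solitaries_path Optional CSV of solitary per-sweep histories
#'   (written only when the population has observed solitaries).
#' @return Invisibly, the paths written.
#' @export
write_capture_csv <- function(cap, individuals_path, groups_path,
                              solitaries_path = NULL) {
  stopifnot(inherits(cap, "cmr_captures"))
  K <- cap$K; T_occ <- cap$T_occ
  occ_names <- paste0("sweep", rep(seq_len(K), each = T_occ),
                      "_site", rep(seq_len(T_occ), K))
  det <- rowSums(cap$individual_detections) > 0
  sweep_of <- rep(seq_len(K), each = T_occ)
  sums <- vapply(seq_len(K), function(k)
    rowSums(cap$individual_detections[, sweep_of == k, drop = FALSE]),
    numeric(nrow(cap$individual_detections)))
  ind <- data.frame(individual_id = sprintf("ind%05d", which(det)),
                    group_id = sprintf("grp%04d", cap$membership[det]))
  ind[occ_names] <- cap$individual_detections[det, , drop = FALSE]
  ind[paste0("sweep", seq_len(K))] <- matrix(sums, ncol = K)[det, , drop = FALSE]
  utils::write.csv(ind, individuals_path, row.names = FALSE)

  grp <- data.frame(group_id = sprintf("grp%04d", seq_len(nrow(cap$group_detections))))
  grp[paste0("sweep", seq_len(K))] <- cap$group_detections
  utils::write.csv(grp, groups_path, row.names = FALSE)

  paths <- c(individuals_path, groups_path)
  if (!is.null(solitaries_path)) {
    sdet <- rowSums(cap$solitary_detections) > 0
    sol <- data.frame(individual_id = sprintf("sol%04d", which(sdet)))
    sol[paste0("sweep", seq_len(K))] <-
      cap$solitary_detections[sdet, , drop = FALSE]
    utils::write.csv(sol, solitaries_path, row.names = FALSE)
    paths <- c(paths, solitaries_path)
  }
  invisible(paths)
}

#' Write a posterior summary or metrics table to CSV
#'
#' Stable column order (`parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`
#' for posterior summaries); round-trips through [read_summary_csv()].
#'
#' @param x A `posterior_summary` or a metrics data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(x, path) {
  df <- as.data.frame(x)
  attr(df, "chains") <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}
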