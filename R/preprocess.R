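#' Aggregate probe replicates into per-miRNA signals
#'
#' Sums all replicate probe signals of a miRNA within each sample, yielding
#' the total expression value per miRNA per array. A (miRNA, sample) pair
#' with no probe rows gets signal 0 and is marked undetected.
#'
#' @param pt A validated probe table (see [read_probe_table()]).
#' @return A list with `matrix` (linear-scale [mir_matrix()]) and
#'   `detection`: a logical miRNA-by-sample matrix if the table carried a
#'   vendor `detected` flag (OR over a miRNA's probes), otherwise `NULL`
#'   and detection is deferred to [call_detection()].
#' @export
#' @examples
#' pt <- tibble::tibble(
#'   probe_id = paste0("p", 1:4), mirna_id = "miR-1",
#'   sample_id = rep(c("s1", "s2"), each = 2), signal = c(1, 2, 3, 4)
#' )
#' aggregate_probes(pt)$matrix
aggregate_probes <- function(pt) {
  pt <- validate_probe_table(pt)
  mirnas <- unique(pt$mirna_id)
  samples <- unique(pt$sample_id)
  mi <- match(pt$mirna_id, mirnas)
  si <- match(pt$sample_id, samples)
  vals <- matrix(0, length(mirnas), length(samples),
    dimnames = list(mirnas, samples)
  )
  agg <- tapply(pt$signal, list(mi, si), sum)
  vals[!is.na(agg)] <- agg[!is.na(agg)]
  m <- mir_matrix(vals, scale = "linear")
  det <- NULL
  if ("detected" %in% names(pt)) {
    det <- matrix(FALSE, length(mirnas), length(samples),
      dimnames = list(mirnas, samples)
    )
    dagg <- tapply(pt$detected, list(mi, si), any)
    det[!is.na(dagg)] <- dagg[!is.na(dagg)]
  }
  list(matrix = m, detection = det)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common distribution: the across-sample
#' mean of order statistics. Within a column, a group of tied values receives
#' the mean of the target order statistics over the ranks the group occupies,
#' so ties stay tied and per-column rankings are preserved.
#'
#' @param m A [mir_matrix()] with at least two samples.
#' @return A [mir_matrix()] on the same scale with identical row/column ids.
#' @export
#' @examples
#' m <- mir_matrix(matrix(c(1, 3, 2, 4), 2, 2,
#'   dimnames = list(c("a", "b"), c("s1", "s2"))), "linear")
#' quantile_normalize(m)
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "mir_matrix"))
  if (ncol(m) < 2) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  v <- mir_values(m)
  ref <- rowMeans(apply(v, 2, sort, method = "radix"))
  cs <- c(0, cumsum(ref))
  out <- apply(v, 2, function(col) {
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    res <- ref[rmin]
    tied <- rmax > rmin
    res[tied] <- (cs[rmax[tied] + 1] - cs[rmin[tied]]) /
      (rmax[tied] - rmin[tied] + 1)
    res
  })
  # guard against cancellation dust on the linear scale
  if (mir_scale(m) == "linear") out <- pmax(out, 0)
  dimnames(out) <- dimnames(v)
  mir_matrix(out, scale = mir_scale(m))
}

#' Log2-transform a linear-scale matrix
#'
#' Applies `log2(max(value, floor))` entrywise. With the default floor of 1,
#' undetected signals (0) map to 0 on the log2 scale.
#'
#' @param m A linear-scale [mir_matrix()].
#' @param floor Positive value below which signals are clamped before the
#'   logarithm. Default 1.
#' @return A log2-scale [mir_matrix()].
#' @export
log2_transform <- function(m, floor = 1) {
  stopifnot(inherits(m, "mir_matrix"))
  if (mir_scale(m) != "linear") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    stop("`floor` must be a positive number", call. = FALSE)
  }
  v <- mir_values(m)
  out <- log2(pmax(v, floor))
  dimnames(out) <- dimnames(v)
  mir_matrix(out, scale = "log2")
}

#' Call detection from linear signals
#'
#' A miRNA is called detected in a sample when its aggregated linear signal
#' strictly exceeds the threshold. Default threshold 0: any nonzero signal
#' counts as detected.
#'
#' @param m A linear-scale [mir_matrix()].
#' @param threshold Nonnegative signal cutoff (strict inequality).
#' @return Logical matrix with the same dimnames as `m`.
#' @export
call_detection <- function(m, threshold = 0) {
  stopifnot(inherits(m, "mir_matrix"))
  if (mir_scale(m) != "linear") {
    stop("detection is called on the linear scale", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a nonnegative number", call. = FALSE)
  }
  v <- mir_values(m)
  out <- v > threshold
  dimnames(out) <- dimnames(v)
  out
}

#' Count detected miRNAs within a sample group
#'
#' For a group of samples, counts miRNAs detected in at least one sample
#' (`n_any`) and in every sample (`n_all`), with the corresponding id lists.
#'
#' @param d Logical detection matrix (miRNAs x samples).
#' @param samples Character vector of sample ids (columns of `d`) forming the
#'   group; must be non-empty.
#' @return A list with `n_any`, `n_all`, `ids_any`, `ids_all`.
#' @export
detection_summary <- function(d, samples) {
  stopifnot(is.matrix(d), is.logical(d))
  if (length(samples) == 0) stop("empty sample group", call. = FALSE)
  missing <- setdiff(samples, colnames(d))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- d[, samples, drop = FALSE]
  any_hit <- rowSums(sub) > 0
  all_hit <- rowSums(sub) == ncol(sub)
  list(
    n_any = sum(any_hit),
    n_all = sum(all_hit),
    ids_any = rownames(d)[any_hit],
    ids_all = rownames(d)[all_hit]
  )
}

#' Detection counts per cell type and condition
#'
#' Tidy wrapper around [detection_summary()] over every (cell type,
#' condition) group in the sheet.
#'
#' @param d Logical detection matrix.
#' @param sheet A [sample_sheet()].
#' @return A tibble with one row per group: `cell_type`, `condition`,
#'   `n_samples`, `n_any`, `n_all`.
#' @export
detection_by_group <- function(d, sheet) {
  groups <- dplyr::distinct(sheet, .data$cell_type, .data$condition)
  purrr::pmap_dfr(groups, function(cell_type, condition) {
    ids <- sheet_samples(sheet, cell_type = cell_type, condition = condition)
    s <- detection_summary(d, ids)
    tibble::tibble(
      cell_type = cell_type, condition = condition,
      n_samples = length(ids), n_any = s$n_any, n_all = s$n_all
    )
  })
}

#' Run the standard preprocessing chain
#'
#' Quantile normalization of the linear-scale aggregated matrix across all
#' arrays, detection calling on the raw (pre-normalization) signals, then
#' log2 transformation.
#'
#' @param m Linear-scale aggregated [mir_matrix()].
#' @param detection Optional vendor detection matrix from
#'   [aggregate_probes()]; when `NULL`, detection is called from `m` at
#'   `threshold`.
#' @param threshold Detection cutoff for [call_detection()].
#' @param floor Log2 floor for [log2_transform()].
#' @param sheet Optional [sample_sheet()]; when given together with
#'   `scope = "per_cell_type"`, samples are normalized within each cell type
#'   instead of across the whole run.
#' @param scope `"all"` (default, one normalization across every array) or
#'   `"per_cell_type"`.
#' @return A list with `log2` (normalized log2 [mir_matrix()]), `linear`
#'   (normalized linear matrix) and `detection` (logical matrix).
#' @export
preprocess_cohort <- function(m, detection = NULL, threshold = 0, floor = 1,
                              sheet = NULL, scope = c("all", "per_cell_type")) {
  scope <- match.arg(scope)
  stopifnot(inherits(m, "mir_matrix"), mir_scale(m) == "linear")
  if (is.null(detection)) detection <- call_detection(m, threshold)
  if (scope == "per_cell_type") {
    if (is.null(sheet)) {
      stop("per-cell-type normalization needs a sample sheet", call. = FALSE)
    }
    check_sheet_matrix(m, sheet)
    norm <- m
    for (ct in unique(sheet$cell_type)) {
      ids <- sheet_samples(sheet, cell_type = ct)
      norm[, ids] <- mir_values(quantile_normalize(m[, ids]))
    }
  } else {
    norm <- quantile_normalize(m)
  }
  list(
    log2 = log2_transform(norm, floor = floor),
    linear = norm,
    detection = detection
  )
}
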