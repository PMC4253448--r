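#' Row-wise two-sample t statistics
#'
#' Vectorized two-tailed independent t test applied to every miRNA of a
#' log2-scale matrix, comparing two disjoint sample groups. Welch's unequal
#' variance form is the default; the pooled-variance Student form is
#' available with `var_equal = TRUE`.
#'
#' The statistic is `(mean_a - mean_b) / se`. Rows where both groups are
#' constant with equal means get `t = 0, p = 1`; rows where both groups are
#' constant with different means have a degenerate zero standard error and
#' are reported with `p` equal to the smallest positive double and flagged
#' in `degenerate`.
#'
#' @param m Log2-scale [mir_matrix()].
#' @param samples_a,samples_b Disjoint character vectors of sample ids with
#'   at least two samples each.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A tibble with one row per miRNA: `mirna_id`, `mean_a`, `mean_b`,
#'   `t_stat`, `df`, `raw_p`, `direction` (`up_in_b`, `down_in_b`, `none`)
#'   and `degenerate`.
#' @export
#' @examples
#' m <- mir_matrix(
#'   matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
#'     dimnames = list("miR-1", paste0("s", 1:6))
#'   ),
#'   scale = "log2"
#' )
#' row_t_test(m, paste0("s", 1:3), paste0("s", 4:6))
row_t_test <- function(m, samples_a, samples_b, var_equal = FALSE) {
  stopifnot(inherits(m, "mir_matrix"))
  if (mir_scale(m) != "log2") {
    stop("differential testing expects log2-scale values", call. = FALSE)
  }
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (length(intersect(samples_a, samples_b)) > 0) {
    stop("sample groups overlap", call. = FALSE)
  }
  missing <- setdiff(c(samples_a, samples_b), colnames(m))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- mir_values(m)[, samples_a, drop = FALSE]
  b <- mir_values(m)[, samples_b, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- (ma - mb) / se
  raw_p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  equal_const <- degenerate & ma == mb
  diff_const <- degenerate & ma != mb
  t_stat[equal_const] <- 0
  raw_p[equal_const] <- 1
  df[equal_const] <- na + nb - 2
  t_stat[diff_const] <- sign(ma - mb)[diff_const] * Inf
  raw_p[diff_const] <- .Machine$double.xmin
  df[diff_const] <- na + nb - 2
  tibble::tibble(
    mirna_id = rownames(m),
    mean_a = unname(ma), mean_b = unname(mb),
    t_stat = unname(t_stat), df = unname(df), raw_p = unname(raw_p),
    direction = dplyr::case_when(
      mb > ma ~ "up_in_b",
      mb < ma ~ "down_in_b",
      TRUE ~ "none"
    ),
    degenerate = diff_const
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, order-preserving and elementwise `>= p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression for one contrast
#'
#' Runs the row-wise t test over a tested universe, adjusts with
#' Benjamini-Hochberg within the contrast, and annotates each miRNA with the
#' detected-in-all-samples flags of both groups used by the candidate
#' filter.
#'
#' @inheritParams row_t_test
#' @param detection Optional logical detection matrix aligned to `m`. When
#'   given, the tested universe is restricted per `tested`, and the
#'   `detected_all_a` / `detected_all_b` flags are filled; otherwise every
#'   miRNA is tested and both flags are `TRUE`.
#' @param tested `"detected"` (default): test only miRNAs detected in at
#'   least one sample of either group; `"all"`: test every miRNA.
#' @param contrast Length-2 character vector naming groups a and b (e.g.
#'   `c("control", "cancer")`); group b is the second-named group, so
#'   `direction = "up_in_b"` reads "up-regulated in b".
#' @return A `de_result` tibble: the [row_t_test()] columns plus `adj_p`,
#'   `detected_all_a`, `detected_all_b`; the contrast labels are attached as
#'   the `contrast` attribute.
#' @export
two_group_de <- function(m, samples_a, samples_b, detection = NULL,
                         var_equal = FALSE, tested = c("detected", "all"),
                         contrast = c("a", "b")) {
  tested <- match.arg(tested)
  if (!is.null(detection)) {
    stopifnot(identical(dim(detection), dim(unclass(m))))
    if (tested == "detected") {
      da <- detection[, samples_a, drop = FALSE]
      db <- detection[, samples_b, drop = FALSE]
      keep <- rowSums(da) + rowSums(db) > 0
      m <- m[keep, , drop = FALSE]
      detection <- detection[keep, , drop = FALSE]
    }
  }
  de <- row_t_test(m, samples_a, samples_b, var_equal = var_equal)
  de$adj_p <- bh_adjust(de$raw_p)
  if (!is.null(detection)) {
    de$detected_all_a <-
      rowSums(detection[, samples_a, drop = FALSE]) == length(samples_a)
    de$detected_all_b <-
      rowSums(detection[, samples_b, drop = FALSE]) == length(samples_b)
  } else {
    de$detected_all_a <- TRUE
    de$detected_all_b <- TRUE
  }
  attr(de, "contrast") <- contrast
  class(de) <- c("de_result", class(de))
  de
}

#' Condition contrast within one cell type
#'
#' Convenience wrapper comparing control versus cancer samples of a single
#' cell type (including whole blood).
#'
#' @param m Log2-scale [mir_matrix()].
#' @param sheet A [sample_sheet()].
#' @param cell_type One of [all_cell_types()].
#' @inheritParams two_group_de
#' @return A `de_result` tibble with contrast `c("control", "cancer")`.
#' @export
condition_contrast <- function(m, sheet, cell_type, detection = NULL,
                               var_equal = FALSE,
                               tested = c("detected", "all")) {
  check_sheet_matrix(m, sheet)
  sa <- sheet_samples(sheet, cell_type = cell_type, condition = "control")
  sb <- sheet_samples(sheet, cell_type = cell_type, condition = "cancer")
  if (length(sa) < 2 || length(sb) < 2) {
    stop("cell type ", cell_type, " needs >= 2 samples per condition",
      call. = FALSE
    )
  }
  two_group_de(m, sa, sb,
    detection = detection, var_equal = var_equal,
    tested = tested, contrast = c("control", "cancer")
  )
}

#' Select deregulation candidates
#'
#' The reporting filter applied to each contrast: keep miRNAs with raw
#' p below `raw_alpha` that are detected in every sample of at least one of
#' the two groups.
#'
#' @param de A `de_result` from [two_group_de()].
#' @param raw_alpha Raw p-value cutoff (strict `<`), default 0.05.
#' @return The selected rows of `de` (a tibble), directions carried through.
#' @export
select_candidates <- function(de, raw_alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  if (!is.numeric(raw_alpha) || raw_alpha < 0 || raw_alpha > 1) {
    stop("`raw_alpha` must be in [0, 1]", call. = FALSE)
  }
  dplyr::filter(
    tibble::as_tibble(de),
    .data$raw_p < raw_alpha,
    .data$detected_all_a | .data$detected_all_b
  )
}

#' Union report over several contrasts
#'
#' Combines the selected miRNAs of two or more contrasts into one table:
#' one row per miRNA in the union, one raw-p column per contrast (`NA` where
#' the miRNA was not selected), and an `n_contrasts` overlap count. Rows are
#' ordered by overlap count (descending) then miRNA id; per-contrast
#' selection totals are attached as the `totals` attribute.
#'
#' @param selected Named list of tibbles with columns `mirna_id` and `raw_p`
#'   (e.g. outputs of [select_candidates()]), one per contrast.
#' @return A `union_report` tibble.
#' @export
build_union_report <- function(selected) {
  stopifnot(is.list(selected), length(selected) >= 1, !is.null(names(selected)))
  cols <- purrr::imap(selected, function(df, nm) {
    tibble::tibble(
      mirna_id = df$mirna_id,
      contrast = nm,
      raw_p = df$raw_p
    )
  })
  long <- dplyr::bind_rows(cols)
  if (nrow(long) == 0) {
    wide <- tibble::tibble(mirna_id = character())
    for (nm in names(selected)) wide[[nm]] <- numeric()
    wide$n_contrasts <- numeric()
    return(structure(wide,
      totals = vapply(selected, nrow, integer(1)),
      class = c("union_report", class(wide))
    ))
  }
  wide <- tidyr::pivot_wider(long,
    names_from = "contrast", values_from = "raw_p",
    names_sort = FALSE
  )
  pcols <- names(selected)
  for (nm in setdiff(pcols, names(wide))) wide[[nm]] <- NA_real_
  wide <- wide[, c("mirna_id", pcols)]
  wide$n_contrasts <- rowSums(!is.na(wide[, pcols, drop = FALSE]))
  wide <- dplyr::arrange(wide, dplyr::desc(.data$n_contrasts), .data$mirna_id)
  totals <- vapply(selected, nrow, integer(1))
  structure(wide,
    totals = totals,
    class = c("union_report", class(wide))
  )
}

#' Write a union report as TSV
#'
#' Mirrors the published layout: one raw-p column per contrast, an overlap
#' column, and a final totals row giving the number of selected miRNAs per
#' contrast.
#'
#' @param report A `union_report` from [build_union_report()].
#' @param path Output file path.
#' @export
write_union_report <- function(report, path) {
  stopifnot(inherits(report, "union_report"))
  totals <- attr(report, "totals")
  out <- dplyr::mutate(
    tibble::as_tibble(report),
    dplyr::across(dplyr::where(is.numeric), as.character)
  )
  out[is.na(out)] <- "-"
  total_row <- c("total", as.character(totals), "")
  names(total_row) <- names(out)
  out <- dplyr::bind_rows(out, tibble::as_tibble_row(total_row))
  readr::write_tsv(out, path)
  invisible(path)
}
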