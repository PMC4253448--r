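#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [two_group_de()].
#' @param raw_alpha Highlight cutoff on the raw p value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, raw_alpha = 0.05, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    log2_fc = .data$mean_b - .data$mean_a,
    selected = .data$raw_p < raw_alpha &
      (.data$detected_all_a | .data$detected_all_b)
  )
  ct <- attr(object, "contrast")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$raw_p),
    colour = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s vs %s)", ct[2], ct[1]),
      y = "-log10 raw p"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of specific-set sizes
#'
#' @param object A `marker_sets` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_sets <- function(object, ...) {
  df <- tibble::tibble(
    cell_type = names(object$specific_sets),
    candidates = lengths(object$candidate_sets),
    specific = lengths(object$specific_sets)
  )
  long <- tidyr::pivot_longer(df, -"cell_type",
    names_to = "stage", values_to = "n"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cell_type, y = .data$n, fill = .data$stage
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "miRNAs") +
    ggplot2::theme_minimal()
}

#' Observed versus fitted whole-blood expression
#'
#' @param object A `wb_fit` from [fit_wholeblood_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wb_fit <- function(object, ...) {
  df <- tibble::tibble(
    fitted = object$fitted,
    observed = object$fitted + object$residuals
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::labs(
      x = "fitted whole blood", y = "observed whole blood",
      title = sprintf(
        "donor %s, R² = %.3f", object$donor, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of an over-representation result
#'
#' @param object An `ora_result` from [ora_hypergeometric()].
#' @param max_pathways Show at most this many pathways (by raw p).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ora_result <- function(object, max_pathways = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), max_pathways)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$raw_p), y = .data$pathway,
    size = .data$overlap_count, colour = .data$coverage_fraction
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 raw p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the top-variance panel
#'
#' Draws the classic panel heatmap (rows row-scaled for display only) with
#' complete-linkage Euclidean clustering on both axes. Needs the
#' `pheatmap` package.
#'
#' @param m Log2-scale [mir_matrix()].
#' @param sheet Optional [sample_sheet()] for column annotation.
#' @param k Panel size (top-variance miRNAs).
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(m, sheet = NULL, k = 50, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_expression_heatmap needs the pheatmap package", call. = FALSE)
  }
  panel <- top_variance_features(m, k = min(k, nrow(m)))
  v <- mir_values(m)[panel, , drop = FALSE]
  ann <- NULL
  if (!is.null(sheet)) {
    ann <- data.frame(
      cell_type = sheet$cell_type, condition = sheet$condition,
      row.names = sheet$sample_id
    )[colnames(v), , drop = FALSE]
  }
  p <- pheatmap::pheatmap(v,
    scale = "row",
    clustering_method = "complete",
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    annotation_col = ann, silent = TRUE, ...
  )
  invisible(p)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
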