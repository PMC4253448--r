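#' Collect validated targets of a miRNA set
#'
#' Union of the target-gene sets of the queried miRNAs. miRNAs without an
#' entry in the map are counted, not an error — target databases never
#' cover every probe.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param tm Target map: named list miRNA id -> character vector of gene
#'   symbols (see [read_target_map()]).
#' @return List with `genes` (sorted union) and `n_unmapped`.
#' @export
#' @examples
#' collect_targets(c("miR-1", "miR-2"),
#'   list(`miR-1` = c("TP53", "KRAS"), `miR-2` = c("KRAS", "EGFR"))
#' )
collect_targets <- function(mirnas, tm) {
  hit <- mirnas %in% names(tm)
  genes <- sort(unique(toupper(unlist(tm[mirnas[hit]], use.names = FALSE))))
  list(genes = genes, n_unmapped = sum(!hit))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of the overlap between a target
#' gene set and each pathway, conditioned on a reference universe (for
#' miRNA targets: the validated targets of every miRNA on the array).
#' P values are Benjamini-Hochberg adjusted across pathways.
#'
#' @param targets Character vector of gene symbols (the query). Genes
#'   outside the universe are dropped; their count is attached as the
#'   `n_dropped` attribute with a warning.
#' @param universe Character vector of gene symbols, non-empty.
#' @param pathways Named list of gene-symbol vectors (see [read_gmt()]).
#'   Pathway members outside the universe are ignored.
#' @return An `ora_result` tibble, one row per pathway: `pathway`,
#'   `overlap_count`, `pathway_size` (within the universe),
#'   `target_set_size`, `universe_size`, `coverage_fraction`
#'   (= overlap / target set size), `raw_p`, `adj_p`, `overlap_genes`
#'   (list-column), ordered by `raw_p`.
#' @export
ora_hypergeometric <- function(targets, universe, pathways) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty reference universe", call. = FALSE)
  targets <- unique(toupper(targets))
  outside <- setdiff(targets, universe)
  if (length(outside) > 0) {
    warning(length(outside), " target gene(s) outside the universe dropped",
      call. = FALSE
    )
  }
  targets <- intersect(targets, universe)
  n_univ <- length(universe)
  n_targ <- length(targets)
  res <- purrr::imap_dfr(pathways, function(genes, name) {
    pw <- intersect(unique(toupper(genes)), universe)
    hits <- intersect(pw, targets)
    k <- length(hits)
    raw_p <- stats::phyper(k - 1, length(pw), n_univ - length(pw), n_targ,
      lower.tail = FALSE
    )
    tibble::tibble(
      pathway = name,
      overlap_count = k,
      pathway_size = length(pw),
      target_set_size = n_targ,
      universe_size = n_univ,
      coverage_fraction = if (n_targ > 0) k / n_targ else NA_real_,
      raw_p = raw_p,
      overlap_genes = list(sort(hits))
    )
  })
  res$adj_p <- bh_adjust(res$raw_p)
  res <- dplyr::arrange(res, .data$raw_p, .data$pathway)
  res <- res[, c(
    "pathway", "overlap_count", "pathway_size", "target_set_size",
    "universe_size", "coverage_fraction", "raw_p", "adj_p", "overlap_genes"
  )]
  attr(res, "n_dropped") <- length(outside)
  class(res) <- c("ora_result", class(res))
  res
}

#' Filter pathways by target coverage
#'
#' Reporting filter keeping only pathways that contain at least the given
#' fraction of the query's target genes (default: at least 10%).
#'
#' @param res An `ora_result` from [ora_hypergeometric()].
#' @param fraction Minimum coverage fraction (`>=`, not strict), in (0, 1].
#' @return The filtered `ora_result`.
#' @export
filter_by_coverage <- function(res, fraction = 0.10) {
  stopifnot(inherits(res, "ora_result"))
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  out <- dplyr::filter(tibble::as_tibble(res), .data$coverage_fraction >= fraction)
  class(out) <- c("ora_result", class(out))
  out
}

#' Over-representation of a marker set's targets
#'
#' Convenience wrapper: collect the validated targets of one cell type's
#' specific miRNAs, test them against the pathways using the array-wide
#' target universe, and apply the coverage filter.
#'
#' @param mirnas miRNA id vector (e.g. one specific set).
#' @param tm Target map.
#' @param pathways Pathway collection.
#' @param universe Reference gene universe; defaults to the union of all
#'   targets in `tm` (the validated targets of the whole array).
#' @param coverage Coverage filter fraction; `NULL` disables it.
#' @return An `ora_result`.
#' @export
ora_marker_set <- function(mirnas, tm, pathways, universe = NULL,
                           coverage = 0.10) {
  if (is.null(universe)) {
    universe <- sort(unique(toupper(unlist(tm, use.names = FALSE))))
  }
  targets <- collect_targets(mirnas, tm)$genes
  res <- ora_hypergeometric(targets, universe, pathways)
  if (!is.null(coverage)) res <- filter_by_coverage(res, coverage)
  res
}
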