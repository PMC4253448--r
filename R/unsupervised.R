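#' Highest-variance miRNAs
#'
#' Ranks miRNAs by unbiased sample variance across the selected samples and
#' returns the top `k` ids. Ties are broken by lexicographic miRNA id so
#' the selection is deterministic.
#'
#' @param m A [mir_matrix()].
#' @param k Number of miRNAs to keep (default 50, the usual heatmap panel
#'   size); must not exceed the number of miRNAs.
#' @param samples Optional sample ids to compute the variance over;
#'   defaults to all samples.
#' @return Character vector of `k` miRNA ids, highest variance first.
#' @export
top_variance_features <- function(m, k = 50, samples = NULL) {
  stopifnot(inherits(m, "mir_matrix"))
  v <- mir_values(m)
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (k > nrow(v)) {
    stop("k (", k, ") exceeds the number of miRNAs (", nrow(v), ")",
      call. = FALSE
    )
  }
  vars <- apply(v, 1, stats::var)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord[seq_len(k)]]
}

#' Hierarchical clustering of samples or miRNAs
#'
#' Agglomerative clustering on Euclidean distances, complete linkage by
#' default, over either axis of the matrix independently.
#'
#' @param m A [mir_matrix()].
#' @param axis `"samples"` (cluster columns) or `"mirnas"` (cluster rows).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An [stats::hclust] tree whose leaves are the sample or miRNA
#'   ids.
#' @export
hierarchical_cluster <- function(m, axis = c("samples", "mirnas"),
                                 linkage = c("complete", "average", "single")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  stopifnot(inherits(m, "mir_matrix"))
  v <- mir_values(m)
  items <- if (axis == "samples") t(v) else v
  if (nrow(items) < 2) {
    stop("clustering needs >= 2 items on axis ", axis, call. = FALSE)
  }
  stats::hclust(stats::dist(items, method = "euclidean"), method = linkage)
}

#' Purity of a dendrogram cut
#'
#' Cuts the tree into `n_clusters` groups and scores how homogeneous the
#' groups are with respect to known labels: the summed majority-class count
#' over clusters divided by the number of leaves. Purity 1 means every
#' cluster is single-class.
#'
#' @param hc An [stats::hclust] tree.
#' @param labels Named vector mapping every leaf id to a class.
#' @param n_clusters Number of clusters to cut into.
#' @return Purity in \[0, 1\].
#' @export
cluster_purity <- function(hc, labels, n_clusters) {
  stopifnot(inherits(hc, "hclust"))
  if (n_clusters < 1 || n_clusters > length(hc$labels)) {
    stop("`n_clusters` must be between 1 and the number of leaves", call. = FALSE)
  }
  unlabeled <- setdiff(hc$labels, names(labels))
  if (length(unlabeled) > 0) {
    stop("unlabeled leaf/leaves: ", paste(utils::head(unlabeled, 5), collapse = ", "),
      call. = FALSE
    )
  }
  cl <- stats::cutree(hc, k = n_clusters)
  lab <- labels[names(cl)]
  sum(tapply(lab, cl, function(x) max(table(x)))) / length(cl)
}

#' Do samples of one group form their own branch?
#'
#' Checks whether some cut of the tree isolates exactly the given leaf set
#' as one cluster — e.g. whether all whole-blood samples split off from the
#' sorted subsets before any mixed grouping.
#'
#' @param hc An [stats::hclust] tree.
#' @param leaves Character vector of leaf ids.
#' @return `TRUE` if, at some `k`, one cluster equals `leaves` exactly.
#' @export
is_monophyletic_cluster <- function(hc, leaves) {
  stopifnot(inherits(hc, "hclust"))
  for (k in seq.int(2L, length(hc$labels))) {
    cl <- stats::cutree(hc, k = k)
    for (g in unique(cl)) {
      mem <- names(cl)[cl == g]
      if (setequal(mem, leaves)) return(TRUE)
    }
  }
  FALSE
}

#' Export a sample tree as newick text
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
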