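# Independent brute-force oracles and small fixtures shared across tests.

# plain numeric values of a mir_matrix (drops class and scale tag)
mvals <- function(m) {
  v <- unclass(m)
  attr(v, "scale") <- NULL
  v
}

# compact cohort for fast module tests
small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_mirna = 300, n_markers_per_celltype = 5, n_disease_per_celltype = 2,
    n_hidden = 5, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# naive quantile normalization: sort each column, average order statistics,
# reassign by order (valid for tie-free input only)
oracle_qn <- function(v) {
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(v)
  out
}

# literal step-up definition of the Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(p >= p[i])
    adj[i] <- min(1, min(p[js] * n / rank(p, ties.method = "max")[js]))
  }
  adj
}

# upper-tail hypergeometric by explicit pmf summation
oracle_hyper_upper <- function(k, pathway, universe, draws) {
  js <- k:min(pathway, draws)
  sum(choose(pathway, js) * choose(universe - pathway, draws - js)) /
    choose(universe, draws)
}

# O(n^3) complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# build a toy log2 matrix with named rows/columns
toy_log2 <- function(v, mirnas = NULL, samples = NULL) {
  if (is.null(mirnas)) mirnas <- paste0("miR-", seq_len(nrow(v)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(v)))
  dimnames(v) <- list(mirnas, samples)
  mir_matrix(v, scale = "log2")
}
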