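#' miRNA expression matrix
#'
#' A light container around a numeric miRNA-by-sample matrix carrying a scale
#' tag. All downstream analyses take a `mir_matrix` plus a sample sheet.
#'
#' @param values Numeric matrix, miRNAs in rows, samples in columns. Row and
#'   column names are the miRNA and sample identifiers and must be unique.
#' @param scale Either `"linear"` (summed probe signals) or `"log2"`.
#'
#' @details Linear-scale values must be finite and nonnegative; log2-scale
#'   values must be finite. Identifiers are kept verbatim and case-sensitive:
#'   `"hsa-miR-21"` and `"hsa-miR-21*"` are distinct miRNAs.
#'
#' @return An object of class `mir_matrix`.
#' @export
#' @examples
#' m <- mir_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("miR-1", "miR-2"), c("s1", "s2"))), scale = "linear")
#' mir_scale(m)
mir_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have miRNA rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate miRNA ids in matrix rows", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in matrix columns", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  }
  structure(values, scale = scale, class = c("mir_matrix", "matrix", "array"))
}

#' @rdname mir_matrix
#' @param x A `mir_matrix`.
#' @export
mir_scale <- function(x) {
  stopifnot(inherits(x, "mir_matrix"))
  attr(x, "scale")
}

#' @export
print.mir_matrix <- function(x, ...) {
  cat(sprintf(
    "<mir_matrix> %d miRNAs x %d samples [%s scale]\n",
    nrow(x), ncol(x), mir_scale(x)
  ))
  n <- min(5L, nrow(x))
  k <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(k), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > k) cat("...\n")
  invisible(x)
}

#' @export
`[.mir_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out,
      scale = attr(x, "scale"),
      class = c("mir_matrix", "matrix", "array")
    )
  } else {
    out
  }
}

# internal: plain numeric matrix view
mir_values <- function(x) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

#' The five sorted leukocyte subsets and the whole-blood label
#'
#' @return `leukocyte_subsets()` returns the five CD labels of the sorted
#'   populations; `wb_label()` returns the whole-blood label `"WB"`;
#'   `all_cell_types()` returns both.
#' @export
#' @examples
#' leukocyte_subsets()
leukocyte_subsets <- function() c("CD3", "CD14", "CD15", "CD19", "CD56")

#' @rdname leukocyte_subsets
#' @export
wb_label <- function() "WB"

#' @rdname leukocyte_subsets
#' @export
all_cell_types <- function() c(wb_label(), leukocyte_subsets())

#' @rdname leukocyte_subsets
#' @export
conditions <- function() c("control", "cancer")

#' Immunological groupings of the five leukocyte subsets
#'
#' Three fixed two-sided partitions of the sorted subsets used for grouped
#' contrasts: developmental lineage (myeloid vs lymphoid progenitor), line of
#' defense (innate vs adaptive immune system) and effector function (antigen
#' presenting vs cytotoxic cells). Whole blood belongs to none of them.
#'
#' @return Named list of three axes; each axis is a named list of two
#'   character vectors of cell types.
#' @export
#' @examples
#' cell_type_ontology()$lineage
cell_type_ontology <- function() {
  list(
    lineage = list(
      myeloid = c("CD15", "CD14"),
      lymphoid = c("CD3", "CD19", "CD56")
    ),
    defense = list(
      innate = c("CD15", "CD14", "CD56"),
      adaptive = c("CD3", "CD19")
    ),
    `function` = list(
      APC = c("CD19", "CD14"),
      cytotoxic = c("CD3", "CD56")
    )
  )
}
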