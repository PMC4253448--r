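#' Column-name mapping for probe-level exports
#'
#' Feature-extraction exports name their columns differently between vendors
#' and software versions (the total-probe-signal column in particular). A
#' dialect maps the canonical field names onto the column headers of the file
#' at hand.
#'
#' @param probe_id,mirna_id,sample_id,signal Column names in the file.
#' @param detected Optional column name holding a 0/1 or TRUE/FALSE detection
#'   flag; `NULL` (default) if the export carries none, in which case
#'   detection is called downstream from the aggregated signal.
#' @return A named list of class `probe_dialect`.
#' @export
probe_dialect <- function(probe_id = "probe_id", mirna_id = "mirna_id",
                          sample_id = "sample_id", signal = "signal",
                          detected = NULL) {
  structure(
    list(
      probe_id = probe_id, mirna_id = mirna_id,
      sample_id = sample_id, signal = signal, detected = detected
    ),
    class = "probe_dialect"
  )
}

#' Read a probe-level signal table
#'
#' Reads a tab-separated probe-level table (one row per probe replicate per
#' sample) as exported by feature-extraction software, e.g. 40 replicate
#' probes per miRNA per array.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect A [probe_dialect()] mapping canonical fields to the file's
#'   column names.
#' @return A tibble with columns `probe_id`, `mirna_id`, `sample_id`,
#'   `signal` and, when the dialect maps it, `detected`.
#' @export
read_probe_table <- function(path, dialect = probe_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(dialect$probe_id, dialect$mirna_id, dialect$sample_id, dialect$signal)
  missing <- setdiff(c(needed, dialect$detected), names(raw))
  if (length(missing) > 0) {
    stop(
      "probe table is missing mapped column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  pt <- tibble::tibble(
    probe_id = as.character(raw[[dialect$probe_id]]),
    mirna_id = as.character(raw[[dialect$mirna_id]]),
    sample_id = as.character(raw[[dialect$sample_id]]),
    signal = suppressWarnings(as.numeric(raw[[dialect$signal]]))
  )
  if (!is.null(dialect$detected)) {
    pt$detected <- as.logical(raw[[dialect$detected]])
  }
  bad <- which(is.na(pt$signal))
  if (length(bad) > 0) {
    stop(
      length(bad), " probe row(s) with unparseable signal, first at data row ",
      bad[1],
      call. = FALSE
    )
  }
  validate_probe_table(pt)
}

#' Validate a probe table
#'
#' Checks the probe-table invariants: unique (probe, sample) pairs and
#' finite nonnegative signals.
#'
#' @param pt A data frame with columns `probe_id`, `mirna_id`, `sample_id`,
#'   `signal` and optionally `detected`.
#' @return The validated table as a tibble (invisibly unchanged).
#' @export
validate_probe_table <- function(pt) {
  pt <- tibble::as_tibble(pt)
  req <- c("probe_id", "mirna_id", "sample_id", "signal")
  missing <- setdiff(req, names(pt))
  if (length(missing) > 0) {
    stop("probe table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(pt) == 0) stop("probe table is empty", call. = FALSE)
  if (any(!is.finite(pt$signal)) || any(pt$signal < 0)) {
    stop("probe signals must be finite and >= 0", call. = FALSE)
  }
  dup <- duplicated(pt[c("probe_id", "sample_id")])
  if (any(dup)) {
    d <- pt[dup, ][1, ]
    stop(
      "duplicated (probe_id, sample_id) pair: (",
      d$probe_id, ", ", d$sample_id, ")",
      call. = FALSE
    )
  }
  pt
}

#' Read and write an expression matrix
#'
#' The canonical on-disk form is a rectangular TSV: first column `mirna_id`,
#' remaining columns one per sample. Writing then reading reproduces the
#' matrix exactly (ids verbatim, values to full printed precision).
#'
#' @param path File path.
#' @param scale Scale tag to attach on read (`"linear"` or `"log2"`).
#' @return `read_expression_matrix()` returns a [mir_matrix()];
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(file.exists(path))
  # base strtod parsing is correctly rounded, making write/read bit-exact
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  df[-1] <- lapply(df[-1], as.numeric)
  if (anyNA(df[-1])) stop("non-numeric expression values in matrix file", call. = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs >= 1 sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate miRNA ids in matrix file", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in matrix file", call. = FALSE)
  rownames(vals) <- ids
  mir_matrix(vals, scale = scale)
}

#' @rdname read_expression_matrix
#' @param m A [mir_matrix()].
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "mir_matrix"))
  v <- mir_values(m)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  df <- tibble::as_tibble(
    matrix(sprintf("%.17g", v), nrow(v), ncol(v), dimnames = dimnames(v)),
    rownames = "mirna_id"
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' One row per array: which donor it came from, which sorted population (or
#' whole blood) it profiles, and the donor's condition. Every grouping used
#' downstream is defined here.
#'
#' @param df Data frame with columns `sample_id`, `donor_id`, `cell_type`
#'   (one of `WB`, `CD3`, `CD14`, `CD15`, `CD19`, `CD56`) and `condition`
#'   (`control` or `cancer`).
#' @return A validated tibble.
#' @export
sample_sheet <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("sample_id", "donor_id", "cell_type", "condition")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(req), as.character))
  bad_ct <- setdiff(unique(df$cell_type), all_cell_types())
  if (length(bad_ct) > 0) {
    stop(
      "unknown cell_type token(s): ", paste(bad_ct, collapse = ", "),
      "; allowed: ", paste(all_cell_types(), collapse = ", "),
      call. = FALSE
    )
  }
  bad_cond <- setdiff(unique(df$condition), conditions())
  if (length(bad_cond) > 0) {
    stop(
      "unknown condition token(s): ", paste(bad_cond, collapse = ", "),
      "; allowed: ", paste(conditions(), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (anyDuplicated(df[c("donor_id", "cell_type")])) {
    stop("a (donor_id, cell_type) pair appears more than once", call. = FALSE)
  }
  df
}

#' @rdname sample_sheet
#' @param path Path to a TSV sample sheet.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  sample_sheet(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then tab-separated member gene
#' symbols. Symbols are upper-cased on read.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (pathway name -> gene symbols).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names)) stop("duplicate pathway names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) {
    genes <- unique(toupper(p[-(1:2)]))
    genes[nzchar(genes)]
  })
  names(sets) <- names
  empty <- names[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop("pathway with no member genes: ", paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  sets
}

#' Read a miRNA-to-target-gene mapping
#'
#' Two tab-separated columns: miRNA id and a `;`-separated list of validated
#' target gene symbols. miRNA ids are kept verbatim (case-sensitive, the
#' star form is a distinct miRNA); gene symbols are upper-cased.
#'
#' @param path Path to the TSV mapping (no header required; a header line
#'   whose first field is `mirna_id` is skipped).
#' @return Named list of character vectors (miRNA id -> gene symbols).
#' @export
read_target_map <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && startsWith(lines[1], "mirna_id")) lines <- lines[-1]
  if (length(lines) == 0) stop("empty target map", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) >= 2
  if (!all(ok)) {
    stop("target map line without a target field, first at line ", which(!ok)[1],
      call. = FALSE
    )
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate miRNA id in target map", call. = FALSE)
  tm <- lapply(parts, function(p) {
    genes <- unique(toupper(trimws(strsplit(p[[2]], ";", fixed = TRUE)[[1]])))
    genes[nzchar(genes)]
  })
  names(tm) <- ids
  empty <- ids[lengths(tm) == 0]
  if (length(empty) > 0) {
    stop("mapped miRNA with empty target set: ", paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  tm
}

#' @rdname read_target_map
#' @param tm Named list of character vectors.
#' @export
write_target_map <- function(tm, path) {
  lines <- c(
    "mirna_id\ttargets",
    vapply(
      names(tm),
      function(id) paste0(id, "\t", paste(tm[[id]], collapse = ";")),
      character(1)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @param pathways Named list of character vectors.
#' @param descriptions Optional character vector of per-pathway descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# internal: sample ids for a cell type / condition slice of the sheet
sheet_samples <- function(sheet, cell_type = NULL, condition = NULL,
                          donor = NULL) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(cell_type)) keep <- keep & sheet$cell_type %in% cell_type
  if (!is.null(condition)) keep <- keep & sheet$condition %in% condition
  if (!is.null(donor)) keep <- keep & sheet$donor_id %in% donor
  sheet$sample_id[keep]
}

# internal: check that every sheet sample is a matrix column
check_sheet_matrix <- function(m, sheet) {
  missing <- setdiff(sheet$sample_id, colnames(m))
  if (length(missing) > 0) {
    stop(
      "sample sheet lists sample(s) absent from matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
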