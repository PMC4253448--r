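#' All pairwise subset contrasts within one condition
#'
#' Runs a differential test for every unordered pair of sorted leukocyte
#' subsets among samples of one condition. Whole blood never takes part.
#' Each pair is Benjamini-Hochberg adjusted within its own contrast.
#'
#' @param m Log2-scale [mir_matrix()].
#' @param sheet A [sample_sheet()].
#' @param condition `"control"` or `"cancer"`.
#' @param cell_types Cell-type universe; defaults to the five sorted
#'   subsets. Every listed type must have at least two samples in the
#'   condition.
#' @param detection Optional detection matrix passed through to
#'   [two_group_de()].
#' @param var_equal Pooled-variance Student t instead of Welch.
#' @return Named list of `de_result` tibbles; names are `"A.vs.B"` with A, B
#'   in the order of `cell_types`. For five subsets: `choose(5, 2) = 10`
#'   entries.
#' @export
pairwise_cell_tests <- function(m, sheet, condition,
                                cell_types = leukocyte_subsets(),
                                detection = NULL, var_equal = FALSE) {
  check_sheet_matrix(m, sheet)
  cell_types <- setdiff(cell_types, wb_label())
  present <- vapply(cell_types, function(ct) {
    length(sheet_samples(sheet, cell_type = ct, condition = condition)) >= 2
  }, logical(1))
  if (!all(present)) {
    stop(
      "cell type(s) with < 2 samples in condition ", condition, ": ",
      paste(cell_types[!present], collapse = ", "),
      call. = FALSE
    )
  }
  pairs <- utils::combn(cell_types, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    sa <- sheet_samples(sheet, cell_type = p[1], condition = condition)
    sb <- sheet_samples(sheet, cell_type = p[2], condition = condition)
    two_group_de(m, sa, sb,
      detection = detection, var_equal = var_equal,
      contrast = p
    )
  })
  names(out) <- vapply(pairs, function(p) paste(p, collapse = ".vs."), character(1))
  out
}

#' Derive disjoint cell-type-specific miRNA sets
#'
#' For each cell type, the candidate set contains the miRNAs with adjusted
#' p below `adj_alpha` in every pairwise contrast involving that cell type.
#' Candidates appearing in more than one cell type's set are then removed
#' from all of them, leaving mutually disjoint specific sets.
#'
#' @param pairwise Named list of `de_result` tibbles from
#'   [pairwise_cell_tests()]; must cover every pair of the cell-type
#'   universe.
#' @param adj_alpha Adjusted p-value cutoff (strict `<`), default 0.05.
#' @param strict_direction When `TRUE`, a candidate must additionally be
#'   deregulated in a consistent direction relative to the considered cell
#'   type (always higher, or always lower, than every other subset).
#' @param condition Optional condition label stored on the result.
#' @return A `marker_sets` object: list with `candidate_sets` and
#'   `specific_sets` (named lists of miRNA id vectors), `adj_alpha`,
#'   `strict_direction` and `condition`.
#' @export
derive_specific_sets <- function(pairwise, adj_alpha = 0.05,
                                 strict_direction = FALSE, condition = NA) {
  stopifnot(is.list(pairwise), length(pairwise) >= 1)
  pairs <- lapply(pairwise, attr, "contrast")
  cts <- sort(unique(unlist(pairs)))
  expected <- utils::combn(cts, 2, simplify = FALSE)
  have <- vapply(pairs, function(p) paste(sort(p), collapse = "|"), character(1))
  want <- vapply(expected, paste, character(1), collapse = "|")
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stop("pairwise map misses contrast(s): ",
      paste(gsub("\\|", " vs ", missing), collapse = ", "),
      call. = FALSE
    )
  }
  candidate_sets <- lapply(cts, function(ct) {
    involving <- pairwise[vapply(pairs, function(p) ct %in% p, logical(1))]
    sets <- lapply(involving, function(de) {
      sig <- de$adj_p < adj_alpha
      if (strict_direction) {
        # direction relative to the considered cell type: TRUE = higher in ct
        a_is_ct <- attr(de, "contrast")[1] == ct
        higher <- if (a_is_ct) de$mean_a > de$mean_b else de$mean_b > de$mean_a
        list(
          up = de$mirna_id[sig & higher],
          down = de$mirna_id[sig & !higher]
        )
      } else {
        list(any = de$mirna_id[sig])
      }
    })
    if (strict_direction) {
      up <- Reduce(intersect, lapply(sets, `[[`, "up"))
      down <- Reduce(intersect, lapply(sets, `[[`, "down"))
      sort(union(up, down))
    } else {
      sort(Reduce(intersect, lapply(sets, `[[`, "any")))
    }
  })
  names(candidate_sets) <- cts
  all_ids <- unlist(candidate_sets, use.names = FALSE)
  shared <- unique(all_ids[duplicated(all_ids)])
  specific_sets <- lapply(candidate_sets, setdiff, y = shared)
  structure(
    list(
      candidate_sets = candidate_sets,
      specific_sets = specific_sets,
      adj_alpha = adj_alpha,
      strict_direction = strict_direction,
      condition = condition
    ),
    class = "marker_sets"
  )
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("<marker_sets>",
    if (!is.na(x$condition)) paste0("condition: ", x$condition), "\n"
  )
  for (ct in names(x$specific_sets)) {
    cat(sprintf(
      "  %-5s candidates: %3d  specific: %3d\n",
      ct, length(x$candidate_sets[[ct]]), length(x$specific_sets[[ct]])
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a marker-set collection
#'
#' @param x A `marker_sets` object.
#' @param ... Unused.
#' @return A tibble with one row per (cell type, miRNA): `cell_type`,
#'   `mirna_id`, `candidate` (always `TRUE`), `specific`, `condition`.
#' @export
tidy.marker_sets <- function(x, ...) {
  purrr::imap_dfr(x$candidate_sets, function(ids, ct) {
    if (length(ids) == 0) {
      return(tibble::tibble(
        cell_type = character(), mirna_id = character(),
        candidate = logical(), specific = logical(), condition = character()
      ))
    }
    tibble::tibble(
      cell_type = ct,
      mirna_id = ids,
      candidate = TRUE,
      specific = ids %in% x$specific_sets[[ct]],
      condition = as.character(x$condition)
    )
  })
}

#' Grouped immune-axis contrast
#'
#' Compares the two sides of an immunological grouping (lineage, line of
#' defense, or function) within one condition. The tested universe is
#' restricted to miRNAs detected in every sample of at least one side, and
#' significance is Benjamini-Hochberg adjusted p below `adj_alpha`.
#'
#' @param m Log2-scale [mir_matrix()].
#' @param sheet A [sample_sheet()].
#' @param axis One of `"lineage"`, `"defense"`, `"function"`.
#' @param condition `"control"` or `"cancer"`.
#' @param detection Logical detection matrix aligned to `m` (required: the
#'   detection filter defines the tested universe).
#' @param adj_alpha Adjusted p cutoff, default 0.05.
#' @param ontology Grouping definitions, defaults to [cell_type_ontology()].
#' @return A tibble of the significant miRNAs (columns as in
#'   [two_group_de()]); the full tested universe size is attached as the
#'   `n_tested` attribute and the side labels as `contrast`.
#' @export
group_contrast <- function(m, sheet, axis, condition, detection,
                           adj_alpha = 0.05, ontology = cell_type_ontology()) {
  if (!axis %in% names(ontology)) {
    stop(
      "unknown axis '", axis, "'; expected one of: ",
      paste(names(ontology), collapse = ", "),
      call. = FALSE
    )
  }
  sides <- ontology[[axis]]
  sa <- sheet_samples(sheet, cell_type = sides[[1]], condition = condition)
  sb <- sheet_samples(sheet, cell_type = sides[[2]], condition = condition)
  if (length(sa) == 0 || length(sb) == 0) {
    stop("axis side with no samples in condition ", condition, call. = FALSE)
  }
  # universe: detected in all samples of at least one side
  all_a <- rowSums(detection[, sa, drop = FALSE]) == length(sa)
  all_b <- rowSums(detection[, sb, drop = FALSE]) == length(sb)
  keep <- all_a | all_b
  de <- two_group_de(m[keep, , drop = FALSE], sa, sb,
    detection = detection[keep, , drop = FALSE], tested = "all",
    contrast = names(sides)
  )
  sig <- dplyr::filter(tibble::as_tibble(de), .data$adj_p < adj_alpha)
  attr(sig, "n_tested") <- sum(keep)
  attr(sig, "contrast") <- names(sides)
  sig
}

#' Overlap of two significant sets with direction agreement
#'
#' Partitions the union of two deregulated-miRNA sets into: exclusive to
#' the first set, exclusive to the second, shared with the same direction,
#' and shared with opposite directions.
#'
#' @param sig_a,sig_b Tibbles with columns `mirna_id` and `direction` (no
#'   missing directions), e.g. significant rows of [group_contrast()] for
#'   two conditions.
#' @param labels Length-2 character vector naming the two sets.
#' @return A `contrast_overlap` object: list of the four id vectors plus
#'   the labels.
#' @export
condition_overlap <- function(sig_a, sig_b, labels = c("a", "b")) {
  for (s in list(sig_a, sig_b)) {
    stopifnot(all(c("mirna_id", "direction") %in% names(s)))
    if (anyNA(s$direction)) stop("member without direction", call. = FALSE)
    if (anyDuplicated(s$mirna_id)) stop("duplicate miRNA in set", call. = FALSE)
  }
  shared <- intersect(sig_a$mirna_id, sig_b$mirna_id)
  dir_a <- sig_a$direction[match(shared, sig_a$mirna_id)]
  dir_b <- sig_b$direction[match(shared, sig_b$mirna_id)]
  structure(
    list(
      exclusive_a = sort(setdiff(sig_a$mirna_id, shared)),
      exclusive_b = sort(setdiff(sig_b$mirna_id, shared)),
      shared_same_direction = sort(shared[dir_a == dir_b]),
      shared_opposite_direction = sort(shared[dir_a != dir_b]),
      labels = labels
    ),
    class = "contrast_overlap"
  )
}

#' @export
print.contrast_overlap <- function(x, ...) {
  cat(sprintf(
    "<contrast_overlap> %s vs %s\n  only %s: %d  only %s: %d  shared same: %d  shared opposite: %d\n",
    x$labels[1], x$labels[2],
    x$labels[1], length(x$exclusive_a),
    x$labels[2], length(x$exclusive_b),
    length(x$shared_same_direction), length(x$shared_opposite_direction)
  ))
  invisible(x)
}

#' @rdname condition_overlap
#' @param x A `contrast_overlap`.
#' @param ... Unused.
#' @export
tidy.contrast_overlap <- function(x, ...) {
  part <- c(
    "exclusive_a", "exclusive_b",
    "shared_same_direction", "shared_opposite_direction"
  )
  purrr::map_dfr(part, function(p) {
    ids <- x[[p]]
    tibble::tibble(
      mirna_id = as.character(ids),
      partition = rep(p, length(ids))
    )
  })
}

#' Score recovery of planted cell-type markers
#'
#' Compares derived specific sets against the generator's ground truth. The
#' expected set is condition-aware: under the control condition it is the
#' planted marker map; under cancer it additionally contains disease-effect
#' miRNAs planted in exactly one sorted subset, which are genuinely
#' cell-type specific in patients.
#'
#' @param markers A `marker_sets` object.
#' @param truth A `synthetic_truth` from [generate_cohort()].
#' @param condition Condition the marker sets were derived in.
#' @return A tibble per cell type: `cell_type`, `n_expected`, `n_found`,
#'   `precision`, `recall`.
#' @export
score_marker_recovery <- function(markers, truth,
                                  condition = c("control", "cancer")) {
  condition <- match.arg(condition)
  expected <- truth$marker_map
  if (condition == "cancer") {
    extra <- dplyr::filter(
      truth$disease_effects,
      lengths(.data$cell_types) == 1,
      !vapply(.data$cell_types, function(x) wb_label() %in% x, logical(1))
    )
    for (i in seq_len(nrow(extra))) {
      ct <- extra$cell_types[[i]]
      expected[[ct]] <- union(expected[[ct]], extra$mirna_id[i])
    }
  }
  purrr::map_dfr(names(markers$specific_sets), function(ct) {
    found <- markers$specific_sets[[ct]]
    exp <- expected[[ct]] %||% character()
    tp <- length(intersect(found, exp))
    tibble::tibble(
      cell_type = ct,
      n_expected = length(exp),
      n_found = length(found),
      precision = if (length(found) > 0) tp / length(found) else NA_real_,
      recall = if (length(exp) > 0) tp / length(exp) else NA_real_
    )
  })
}
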