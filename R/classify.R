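#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall on the positive class) and specificity
#' (recall on the negative class). Ratios with an empty denominator are
#' returned as `NA`.
#'
#' @param truth,predicted Equal-length label vectors over exactly two
#'   classes.
#' @param positive The positive-class label (the disease condition in
#'   condition contrasts).
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(rep(c("cancer", "control"), each = 7),
#'   rep("cancer", 14),
#'   positive = "cancer"
#' )
confusion_metrics <- function(truth, predicted, positive) {
  stopifnot(length(truth) == length(predicted))
  labs <- unique(truth)
  unknown <- setdiff(unique(predicted), labs)
  if (length(unknown) > 0) {
    stop("predicted label(s) not among truth labels: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!positive %in% labs) stop("unknown positive label", call. = FALSE)
  pos <- truth == positive
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    accuracy = ratio(tp + tn, length(truth)),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  )
}

# internal: one LOOCV pass with a linear SVM; returns predicted labels
loocv_pass <- function(x, y, cost, negative) {
  n <- length(y)
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    # drop features constant in the training fold (not scalable)
    keep <- apply(xtr, 2, function(col) stats::sd(col) > 0)
    if (!any(keep) || length(unique(ytr)) < 2) {
      pred[i] <- majority_label(ytr, negative)
      next
    }
    fit <- e1071::svm(xtr[, keep, drop = FALSE], factor(ytr),
      kernel = "linear", cost = cost, scale = TRUE
    )
    pred[i] <- as.character(stats::predict(fit, x[i, keep, drop = FALSE]))
  }
  pred
}

# internal: majority vote, ties broken toward the negative (control) class
majority_label <- function(y, negative) {
  tab <- table(y)
  top <- names(tab)[tab == max(tab)]
  if (negative %in% top) negative else top[1]
}

# internal: fold-level candidate selection used by nested mode
fold_select_features <- function(m, detection, sa, sb, raw_alpha) {
  de <- two_group_de(m, sa, sb,
    detection = detection, tested = "detected",
    contrast = c("control", "cancer")
  )
  select_candidates(de, raw_alpha = raw_alpha)$mirna_id
}

#' Leave-one-out SVM classification of condition
#'
#' Linear-kernel support-vector classification (via the `e1071` package,
#' cost 1, features standardized on the training fold) of control versus
#' cancer samples of one cell type under leave-one-out cross-validation.
#'
#' Two feature regimes are available. `"as_published"` uses a feature list
#' fixed before cross-validation — either `features` as given, or the
#' candidate filter (raw p < `raw_alpha` plus the detected-in-all-of-one-
#' group rule) computed once on *all* samples of the contrast. Selecting on
#' all samples lets information about the left-out sample leak into
#' training, so this regime is optimistically biased; it is provided,
#' labelled, for comparability with the published protocol. `"nested"`
#' re-runs the same candidate filter inside every training fold and is
#' leakage-free.
#'
#' @param m Log2-scale [mir_matrix()].
#' @param sheet A [sample_sheet()].
#' @param cell_type Cell type whose samples are classified.
#' @param mode `"as_published"` or `"nested"`.
#' @param features Optional fixed miRNA id list for `"as_published"`.
#' @param detection Detection matrix (needed whenever the candidate filter
#'   runs, i.e. `features = NULL` or nested mode).
#' @param raw_alpha Raw-p cutoff of the candidate filter.
#' @param n_repeats Number of repetitions, default 20. Deterministic LOOCV
#'   makes every repetition identical; the knob exists for protocol parity
#'   and matters only with a stochastic solver or selection.
#' @param cost SVM cost parameter.
#' @return A `loocv_report`: per-repetition accuracy/sensitivity/
#'   specificity, their means, the feature list (for `as_published`), mode
#'   and cell type. Sensitivity is recall on cancer, specificity recall on
#'   control; prediction ties and empty feature sets fall back to the
#'   majority class, broken toward control.
#' @export
loocv_svm <- function(m, sheet, cell_type, mode = c("as_published", "nested"),
                      features = NULL, detection = NULL, raw_alpha = 0.05,
                      n_repeats = 20, cost = 1) {
  mode <- match.arg(mode)
  check_sheet_matrix(m, sheet)
  sa <- sheet_samples(sheet, cell_type = cell_type, condition = "control")
  sb <- sheet_samples(sheet, cell_type = cell_type, condition = "cancer")
  if (length(sa) < 2 || length(sb) < 2) {
    stop("each condition needs >= 2 samples for cell type ", cell_type,
      call. = FALSE
    )
  }
  samples <- c(sa, sb)
  y <- c(rep("control", length(sa)), rep("cancer", length(sb)))
  v <- mir_values(m)
  if (mode == "as_published") {
    if (is.null(features)) {
      if (is.null(detection)) {
        stop("as_published mode without `features` needs a detection matrix",
          call. = FALSE
        )
      }
      features <- fold_select_features(m, detection, sa, sb, raw_alpha)
    } else {
      missing <- setdiff(features, rownames(m))
      if (length(missing) > 0) {
        stop("feature(s) absent from matrix: ",
          paste(utils::head(missing, 5), collapse = ", "),
          call. = FALSE
        )
      }
    }
  } else if (is.null(detection)) {
    stop("nested mode needs a detection matrix", call. = FALSE)
  }

  run_once <- function() {
    if (mode == "as_published") {
      if (length(features) == 0) {
        pred <- vapply(seq_along(y), function(i) {
          majority_label(y[-i], "control")
        }, character(1))
      } else {
        x <- t(v[features, samples, drop = FALSE])
        pred <- loocv_pass(x, y, cost, "control")
      }
    } else {
      pred <- character(length(y))
      for (i in seq_along(y)) {
        tr <- samples[-i]
        tr_a <- intersect(tr, sa)
        tr_b <- intersect(tr, sb)
        feats <- fold_select_features(m, detection, tr_a, tr_b, raw_alpha)
        if (length(feats) == 0) {
          pred[i] <- majority_label(y[-i], "control")
          next
        }
        xtr <- t(v[feats, tr, drop = FALSE])
        keep <- apply(xtr, 2, function(col) stats::sd(col) > 0)
        if (!any(keep)) {
          pred[i] <- majority_label(y[-i], "control")
          next
        }
        fit <- e1071::svm(xtr[, keep, drop = FALSE], factor(y[-i]),
          kernel = "linear", cost = cost, scale = TRUE
        )
        pred[i] <- as.character(
          stats::predict(fit, t(v[feats, samples[i], drop = FALSE])[, keep, drop = FALSE])
        )
      }
    }
    confusion_metrics(y, pred, positive = "cancer")
  }

  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    met <- run_once()
    tibble::tibble(
      repetition = r,
      accuracy = met$accuracy,
      sensitivity = met$sensitivity,
      specificity = met$specificity
    )
  })
  structure(
    list(
      cell_type = cell_type,
      mode = mode,
      features = if (mode == "as_published") features else NULL,
      repetitions = reps,
      accuracy_mean = mean(reps$accuracy),
      sensitivity_mean = mean(reps$sensitivity),
      specificity_mean = mean(reps$specificity)
    ),
    class = "loocv_report"
  )
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf(
    "<loocv_report> %s (%s): accuracy %.4f  sensitivity %.4f  specificity %.4f (%d repetitions)\n",
    x$cell_type, x$mode, x$accuracy_mean, x$sensitivity_mean,
    x$specificity_mean, nrow(x$repetitions)
  ))
  invisible(x)
}

#' @rdname loocv_svm
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @export
tidy.loocv_report <- function(x, ...) {
  x$repetitions
}

#' @rdname loocv_svm
#' @export
glance.loocv_report <- function(x, ...) {
  tibble::tibble(
    cell_type = x$cell_type,
    mode = x$mode,
    n_features = if (is.null(x$features)) NA_integer_ else length(x$features),
    accuracy_mean = x$accuracy_mean,
    sensitivity_mean = x$sensitivity_mean,
    specificity_mean = x$specificity_mean
  )
}

#' Classification report across cell types
#'
#' Runs [loocv_svm()] for each cell type and collects the mean metrics into
#' one table shaped like a published classification summary (one row per
#' contrast, columns accuracy/specificity/sensitivity means).
#'
#' @inheritParams loocv_svm
#' @param cell_types Cell types to classify; defaults to the five subsets
#'   plus whole blood.
#' @return A tibble with one row per cell type.
#' @export
classification_report <- function(m, sheet, detection,
                                  cell_types = all_cell_types(),
                                  mode = "as_published", raw_alpha = 0.05,
                                  n_repeats = 20, cost = 1) {
  purrr::map_dfr(cell_types, function(ct) {
    rep <- loocv_svm(m, sheet, ct,
      mode = mode, detection = detection,
      raw_alpha = raw_alpha, n_repeats = n_repeats, cost = cost
    )
    tibble::tibble(
      cell_type = ct,
      n_features = length(rep$features %||% integer()),
      accuracy_mean = rep$accuracy_mean,
      specificity_mean = rep$specificity_mean,
      sensitivity_mean = rep$sensitivity_mean
    )
  })
}
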