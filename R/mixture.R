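#' @importFrom rlang .data %||%
NULL

#' Model a donor's whole blood as a combination of subset profiles
#'
#' Regresses the donor's whole-blood expression vector on the expression
#' vectors of the donor's sorted subsets, across miRNAs. `mode = "ols"` is
#' ordinary least squares; `mode = "nnls"` constrains the subset
#' coefficients to be nonnegative (the intercept, when included, stays
#' free). The regression runs on whichever scale `m` carries; the log2
#' normalized scale mirrors the published analysis, while the linear scale
#' matches the physics of mixing.
#'
#' @param m A [mir_matrix()].
#' @param sheet A [sample_sheet()].
#' @param donor Donor id with a whole-blood sample and at least two subset
#'   samples.
#' @param mode `"ols"` or `"nnls"`.
#' @param intercept Include an intercept (default `TRUE`).
#' @param detection Optional detection matrix; when given, only miRNAs
#'   detected in at least one of the donor's samples enter the fit
#'   (all-undetected rows are degenerate).
#' @return A `wb_fit` object: coefficients (named by cell type), intercept,
#'   `r_squared`, per-miRNA `residuals` and `fitted`, `rank_deficient`
#'   flag, donor id and mode.
#' @export
fit_wholeblood_model <- function(m, sheet, donor, mode = c("ols", "nnls"),
                                 intercept = TRUE, detection = NULL) {
  mode <- match.arg(mode)
  check_sheet_matrix(m, sheet)
  wb <- sheet_samples(sheet, cell_type = wb_label(), donor = donor)
  sub_sheet <- sheet[sheet$donor_id == donor & sheet$cell_type != wb_label(), ]
  if (length(wb) != 1) {
    stop("donor ", donor, " has no whole-blood sample", call. = FALSE)
  }
  if (nrow(sub_sheet) < 2) {
    stop("donor ", donor, " needs >= 2 subset samples", call. = FALSE)
  }
  y <- mir_values(m)[, wb]
  X <- mir_values(m)[, sub_sheet$sample_id, drop = FALSE]
  colnames(X) <- sub_sheet$cell_type
  if (!is.null(detection)) {
    seen <- rowSums(detection[, c(wb, sub_sheet$sample_id), drop = FALSE]) > 0
    y <- y[seen]
    X <- X[seen, , drop = FALSE]
  }
  mirnas <- rownames(X)
  D <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  rk <- qr(D)$rank
  rank_deficient <- rk < ncol(D)
  if (mode == "ols") {
    if (rank_deficient) {
      warning("rank-deficient design for donor ", donor,
        "; returning minimum-norm solution",
        call. = FALSE
      )
      sv <- svd(D)
      pos <- sv$d > max(dim(D)) * .Machine$double.eps * sv$d[1]
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      beta <- drop(beta)
    } else {
      beta <- drop(solve(crossprod(D), crossprod(D, y)))
    }
    names(beta) <- colnames(D)
  } else {
    # nonnegative subset coefficients; free intercept via split columns
    Dn <- if (intercept) cbind(ip = 1, im = -1, X) else X
    fit <- pracma::lsqnonneg(Dn, y)
    b <- fit$x
    if (intercept) {
      beta <- c(`(Intercept)` = b[1] - b[2], b[-(1:2)])
    } else {
      beta <- b
    }
    names(beta) <- colnames(D)
  }
  fitted <- drop(D %*% beta)
  resid <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  coefs <- beta[colnames(X)]
  structure(
    list(
      donor = donor,
      mode = mode,
      coefficients = coefs,
      intercept = if (intercept) unname(beta["(Intercept)"]) else 0,
      r_squared = r2,
      residuals = stats::setNames(resid, mirnas),
      fitted = stats::setNames(fitted, mirnas),
      rank_deficient = rank_deficient,
      n_mirna = length(y)
    ),
    class = "wb_fit"
  )
}

#' @export
print.wb_fit <- function(x, ...) {
  cat(sprintf(
    "<wb_fit> donor %s (%s, %d miRNAs)  R^2 = %.3f\n",
    x$donor, x$mode, x$n_mirna, x$r_squared
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_wholeblood_model
#' @param x A `wb_fit`.
#' @param ... Unused.
#' @export
tidy.wb_fit <- function(x, ...) {
  tibble::tibble(
    donor = x$donor,
    cell_type = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname fit_wholeblood_model
#' @export
glance.wb_fit <- function(x, ...) {
  tibble::tibble(
    donor = x$donor,
    mode = x$mode,
    r_squared = x$r_squared,
    intercept = x$intercept,
    n_mirna = x$n_mirna,
    rank_deficient = x$rank_deficient
  )
}

#' Fit the whole-blood model for every donor
#'
#' @inheritParams fit_wholeblood_model
#' @param donors Donor ids; defaults to every donor with a whole-blood
#'   sample.
#' @return Named list of `wb_fit` objects.
#' @export
fit_wholeblood_models <- function(m, sheet, donors = NULL,
                                  mode = c("ols", "nnls"), intercept = TRUE,
                                  detection = NULL) {
  mode <- match.arg(mode)
  if (is.null(donors)) {
    donors <- unique(sheet$donor_id[sheet$cell_type == wb_label()])
  }
  fits <- lapply(donors, function(d) {
    fit_wholeblood_model(m, sheet, d,
      mode = mode, intercept = intercept,
      detection = detection
    )
  })
  stats::setNames(fits, donors)
}

#' Correlation of each subset with whole blood, per donor
#'
#' Pearson correlation across all miRNAs between a donor's subset profile
#' and the same donor's whole-blood profile. A zero-variance vector leaves
#' the correlation undefined (`NA`).
#'
#' @param m A [mir_matrix()] (log2 scale mirrors the published analysis).
#' @param sheet A [sample_sheet()].
#' @return A tibble `donor_id`, `cell_type`, `rho`, with the min-max band
#'   across all (donor, subset) pairs attached as the `rho_range`
#'   attribute.
#' @export
subset_wb_correlation <- function(m, sheet) {
  check_sheet_matrix(m, sheet)
  donors <- unique(sheet$donor_id[sheet$cell_type == wb_label()])
  v <- mir_values(m)
  out <- purrr::map_dfr(donors, function(d) {
    wb <- sheet_samples(sheet, cell_type = wb_label(), donor = d)
    subs <- sheet[sheet$donor_id == d & sheet$cell_type != wb_label(), ]
    purrr::map_dfr(seq_len(nrow(subs)), function(i) {
      x <- v[, subs$sample_id[i]]
      y <- v[, wb]
      rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        NA_real_
      } else {
        stats::cor(x, y, method = "pearson")
      }
      tibble::tibble(donor_id = d, cell_type = subs$cell_type[i], rho = rho)
    })
  })
  attr(out, "rho_range") <- if (all(is.na(out$rho))) {
    c(NA_real_, NA_real_)
  } else {
    range(out$rho, na.rm = TRUE)
  }
  out
}

#' Presence discordance between whole blood and the sorted subsets
#'
#' Within one condition, finds miRNAs detected in every whole-blood sample
#' but in no subset sample (`wb_only` — the signature of blood compartments
#' outside the sorted populations, e.g. erythrocytes, platelets, exosomes)
#' and miRNAs detected in more than `subset_fraction` of all subset samples
#' but in no whole-blood sample (`subset_only`).
#'
#' @param d Logical detection matrix.
#' @param sheet A [sample_sheet()].
#' @param condition `"control"` or `"cancer"`.
#' @param subset_fraction Fraction of subset samples (strict `>`) required
#'   for `subset_only`; default 0.90.
#' @return A `presence_discordance` object: `wb_only`, `subset_only`
#'   (sorted id vectors) and the parameters.
#' @export
presence_discordance <- function(d, sheet, condition, subset_fraction = 0.9) {
  stopifnot(is.matrix(d), is.logical(d))
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop("`subset_fraction` must be in (0, 1]", call. = FALSE)
  }
  wb <- sheet_samples(sheet, cell_type = wb_label(), condition = condition)
  subs <- sheet_samples(sheet,
    cell_type = leukocyte_subsets(),
    condition = condition
  )
  if (length(wb) == 0) {
    stop("no whole-blood samples in condition ", condition, call. = FALSE)
  }
  if (length(subs) == 0) {
    stop("no subset samples in condition ", condition, call. = FALSE)
  }
  wb_all <- rowSums(d[, wb, drop = FALSE]) == length(wb)
  wb_none <- rowSums(d[, wb, drop = FALSE]) == 0
  sub_frac <- rowSums(d[, subs, drop = FALSE]) / length(subs)
  structure(
    list(
      wb_only = sort(rownames(d)[wb_all & sub_frac == 0]),
      subset_only = sort(rownames(d)[wb_none & sub_frac > subset_fraction]),
      condition = condition,
      subset_fraction = subset_fraction
    ),
    class = "presence_discordance"
  )
}

#' @export
print.presence_discordance <- function(x, ...) {
  cat(sprintf(
    "<presence_discordance> condition %s: %d whole-blood-only, %d subset-only (> %.0f%% of subsets)\n",
    x$condition, length(x$wb_only), length(x$subset_only),
    100 * x$subset_fraction
  ))
  invisible(x)
}

#' @rdname presence_discordance
#' @param x A `presence_discordance`.
#' @param ... Unused.
#' @export
tidy.presence_discordance <- function(x, ...) {
  tibble::tibble(
    mirna_id = c(x$wb_only, x$subset_only),
    side = c(
      rep("wb_only", length(x$wb_only)),
      rep("subset_only", length(x$subset_only))
    ),
    condition = x$condition
  )
}
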