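# run code under a fixed seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a 7-versus-7 donor
#' cohort, five sorted leukocyte subsets plus whole blood per donor, 1,205
#' miRNAs measured by 40 replicate probes, cell-type marker miRNAs, disease
#' effects (including one miRNA deregulated in every subset and in whole
#' blood), whole blood as a convex mixture of the subsets plus a hidden
#' non-leukocyte component, and detection censoring.
#'
#' @param n_donors_per_condition Donors per condition (default 7).
#' @param n_mirna Number of miRNAs on the array (default 1205).
#' @param n_markers_per_celltype Planted markers per sorted subset
#'   (default 20).
#' @param marker_effect Log2 elevation of a marker in its own cell type
#'   (default 4).
#' @param universal_effect Log2 disease effect of the one miRNA deregulated
#'   in all subsets and whole blood (default +1.5).
#' @param n_disease_per_celltype Disease-effect miRNAs planted in exactly
#'   one subset (default 10 per subset, alternating sign).
#' @param disease_effect Magnitude (log2) of the per-subset disease effects
#'   (default 1.5).
#' @param frac_silent Fraction of miRNAs with baseline below the detection
#'   range, emulating the large never-detected part of the array
#'   (default 0.45).
#' @param baseline_meanlog2,baseline_sdlog2 Log2-normal baseline of
#'   expressed miRNAs (defaults 7 and 2, i.e. linear signals are
#'   log-normal).
#' @param silent_meanlog2,silent_sdlog2 Baseline of silent miRNAs
#'   (defaults -2 and 1 — essentially background).
#' @param noise_sd Measurement noise on the log2 scale (default 0.5).
#' @param mixture_weights Named nonnegative weights of the five subsets in
#'   whole blood, summing to at most 1 (defaults follow textbook leukocyte
#'   proportions: CD15 0.55, CD3 0.20, CD14 0.08, CD19 0.07, CD56 0.05).
#'   The remainder to 1 is the hidden-component weight.
#' @param n_hidden Number of hidden-component miRNAs — expressed in no
#'   sorted subset but contributed to whole blood by other blood
#'   compartments (default 15).
#' @param hidden_meanlog2,hidden_sdlog2 Log2-normal profile of the hidden
#'   component (defaults 13 and 1: erythrocyte/platelet-borne miRNAs are
#'   among the most abundant species in whole blood, so their weighted
#'   contribution clears detection there).
#' @param detection_threshold Linear signal below which values are censored
#'   to 0 (default 50).
#' @param n_probe_replicates Replicate probes per miRNA per array
#'   (default 40).
#' @param probe_noise_cv Coefficient of variation of the replicate probe
#'   split (default 0.1).
#' @param seed Integer seed; the generator uses R's default Mersenne
#'   Twister stream and is fully reproducible from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_donors_per_condition = 7,
                             n_mirna = 1205,
                             n_markers_per_celltype = 20,
                             marker_effect = 4,
                             universal_effect = 1.5,
                             n_disease_per_celltype = 10,
                             disease_effect = 1.5,
                             frac_silent = 0.45,
                             baseline_meanlog2 = 7, baseline_sdlog2 = 2,
                             silent_meanlog2 = -2, silent_sdlog2 = 1,
                             noise_sd = 0.5,
                             mixture_weights = c(
                               CD15 = 0.55, CD3 = 0.20, CD14 = 0.08,
                               CD19 = 0.07, CD56 = 0.05
                             ),
                             n_hidden = 15,
                             hidden_meanlog2 = 13, hidden_sdlog2 = 1,
                             detection_threshold = 50,
                             n_probe_replicates = 40,
                             probe_noise_cv = 0.1,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (any(mixture_weights < 0)) {
    stop("mixture weights must be nonnegative", call. = FALSE)
  }
  if (!setequal(names(mixture_weights), leukocyte_subsets())) {
    stop("mixture weights must name exactly the five sorted subsets",
      call. = FALSE
    )
  }
  if (sum(mixture_weights) > 1 + 1e-12) {
    stop("mixture weights must sum to at most 1", call. = FALSE)
  }
  cfg$hidden_weight <- max(0, 1 - sum(mixture_weights))
  n_planted <- 5 * n_markers_per_celltype + 5 * n_disease_per_celltype + 1
  if (n_planted > n_mirna * (1 - frac_silent) * 0.9) {
    stop("too many planted effects for the number of expressed miRNAs",
      call. = FALSE
    )
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic immune-cell miRNome cohort
#'
#' Draws a full cohort under the configured study conditions. A sorted
#' subset sample of miRNA `m` for donor `d` of cell type `c` has linear
#' signal `2^(baseline(m) + marker_effect*[m marker of c] +
#' disease(m, c)*[d diseased] + N(0, noise_sd))`. The donor's whole blood
#' mixes the realized linear subset signals with the planted weights, adds
#' the hidden-component profile at its weight, and applies mean-one
#' multiplicative measurement noise of the same log2 spread (mean-one so
#' mixing noise does not inflate totals). Values below the detection
#' threshold are censored to 0.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A list of class `synthetic_cohort`: `matrix` (linear-scale
#'   [mir_matrix()], censored), `sheet` (a [sample_sheet()]) and `truth`
#'   (class `synthetic_truth`: `marker_map`, `disease_effects` tibble
#'   (`mirna_id`, `cell_types` list-column including `"WB"` for the
#'   universal effect, `effect`, `universal`), per-donor `mixture_weights`,
#'   `hidden_weight`, `hidden_ids`, `hidden_profile`, `detection_mask`,
#'   `seed`, `config`).
#' @export
generate_cohort <- function(cfg = synthetic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seed <- seed %||% cfg$seed
  with_seed_local(seed, {
    n <- cfg$n_mirna
    mirnas <- sprintf("syn-miR-%04d", seq_len(n))
    silent <- stats::runif(n) < cfg$frac_silent
    baseline <- ifelse(
      silent,
      stats::rnorm(n, cfg$silent_meanlog2, cfg$silent_sdlog2),
      stats::rnorm(n, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
    )
    expressed_idx <- which(!silent)

    # planted markers: disjoint blocks of well-expressed miRNAs
    subs <- leukocyte_subsets()
    pool <- sample(expressed_idx)
    need <- 5 * cfg$n_markers_per_celltype
    marker_idx <- pool[seq_len(need)]
    pool <- pool[-seq_len(need)]
    marker_map <- split(
      mirnas[marker_idx],
      rep(subs, each = cfg$n_markers_per_celltype)
    )[subs]
    is_marker <- matrix(FALSE, n, 5, dimnames = list(mirnas, subs))
    for (ct in subs) is_marker[marker_map[[ct]], ct] <- TRUE

    # disease effects: one universal miRNA + per-subset blocks, planted on
    # reliably detectable baselines (the deregulation filter requires
    # detection in all samples of one group; the universal effect emulates
    # an abundant oncomiR)
    plant_floor <- log2(max(cfg$detection_threshold, 1)) + 1.5
    pool <- setdiff(
      intersect(pool, which(baseline >= plant_floor)),
      marker_idx
    )
    n_disease <- 1 + 5 * cfg$n_disease_per_celltype
    if (length(pool) < n_disease) {
      stop("not enough well-expressed miRNAs to plant disease effects",
        call. = FALSE
      )
    }
    universal_idx <- pool[1]
    pool <- pool[-1]
    eff_rows <- list(tibble::tibble(
      mirna_id = mirnas[universal_idx],
      cell_types = list(c(subs, wb_label())),
      effect = cfg$universal_effect,
      universal = TRUE
    ))
    disease_mat <- matrix(0, n, 5, dimnames = list(mirnas, subs))
    disease_mat[universal_idx, ] <- cfg$universal_effect
    if (cfg$n_disease_per_celltype > 0) {
      for (ct in subs) {
        idx <- pool[seq_len(cfg$n_disease_per_celltype)]
        pool <- pool[-seq_len(cfg$n_disease_per_celltype)]
        sgn <- rep_len(c(1, -1), length(idx))
        disease_mat[idx, ct] <- sgn * cfg$disease_effect
        eff_rows[[length(eff_rows) + 1]] <- tibble::tibble(
          mirna_id = mirnas[idx],
          cell_types = rep(list(ct), length(idx)),
          effect = sgn * cfg$disease_effect,
          universal = FALSE
        )
      }
    }
    disease_effects <- dplyr::bind_rows(eff_rows)

    # hidden non-leukocyte component, drawn from the silent pool
    silent_idx <- which(silent)
    hidden_idx <- if (cfg$n_hidden > 0 && cfg$hidden_weight > 0) {
      sample(silent_idx, min(cfg$n_hidden, length(silent_idx)))
    } else {
      integer(0)
    }
    hidden_profile <- stats::setNames(numeric(n), mirnas)
    if (length(hidden_idx) > 0) {
      hidden_profile[hidden_idx] <-
        2^stats::rnorm(length(hidden_idx), cfg$hidden_meanlog2, cfg$hidden_sdlog2)
    }

    donors <- c(
      sprintf("ctrl%02d", seq_len(cfg$n_donors_per_condition)),
      sprintf("case%02d", seq_len(cfg$n_donors_per_condition))
    )
    cond_of <- stats::setNames(
      rep(conditions(), each = cfg$n_donors_per_condition), donors
    )
    sheet <- tidyr::expand_grid(donor_id = donors, cell_type = all_cell_types())
    sheet <- dplyr::mutate(sheet,
      sample_id = paste(.data$donor_id, .data$cell_type, sep = "_"),
      condition = cond_of[.data$donor_id]
    )
    sheet <- sample_sheet(sheet[, c("sample_id", "donor_id", "cell_type", "condition")])

    sdln <- cfg$noise_sd * log(2)
    vals <- matrix(0, n, nrow(sheet), dimnames = list(mirnas, sheet$sample_id))
    w <- cfg$mixture_weights[subs]
    for (d in donors) {
      diseased <- cond_of[d] == "cancer"
      sub_lin <- matrix(0, n, 5, dimnames = list(mirnas, subs))
      for (ct in subs) {
        mu <- baseline + cfg$marker_effect * is_marker[, ct] +
          if (diseased) disease_mat[, ct] else 0
        sub_lin[, ct] <- 2^(mu + stats::rnorm(n, 0, cfg$noise_sd))
        vals[, paste(d, ct, sep = "_")] <- sub_lin[, ct]
      }
      hidden_contrib <- cfg$hidden_weight * hidden_profile
      if (diseased) {
        # the universal miRNA's effect also reaches the non-leukocyte part
        hidden_contrib[universal_idx] <-
          hidden_contrib[universal_idx] * 2^cfg$universal_effect
      }
      wb_true <- drop(sub_lin %*% w) + hidden_contrib
      eta <- if (cfg$noise_sd > 0) {
        exp(sdln * stats::rnorm(n) - sdln^2 / 2)
      } else {
        rep(1, n)
      }
      vals[, paste(d, wb_label(), sep = "_")] <- wb_true * eta
    }

    detection_mask <- vals >= cfg$detection_threshold
    vals[!detection_mask] <- 0
    m <- mir_matrix(vals, scale = "linear")

    truth <- structure(
      list(
        marker_map = marker_map,
        disease_effects = disease_effects,
        mixture_weights = t(replicate(length(donors), w)) |>
          `rownames<-`(donors),
        hidden_weight = cfg$hidden_weight,
        hidden_ids = sort(mirnas[hidden_idx]),
        hidden_profile = hidden_profile,
        detection_mask = detection_mask,
        baseline_log2 = stats::setNames(baseline, mirnas),
        seed = seed,
        config = cfg
      ),
      class = "synthetic_truth"
    )
    structure(
      list(matrix = m, sheet = sheet, truth = truth),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d miRNAs x %d samples (%d donors, seed %d)\n",
    nrow(x$matrix), ncol(x$matrix),
    length(unique(x$sheet$donor_id)), x$truth$seed
  ))
  invisible(x)
}

#' Null cohort with all planted effects removed
#'
#' Same generative model with the marker effect and every disease effect
#' set to zero — the global-null reference for false-discovery-rate and
#' permutation checks.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort` whose truth has empty marker and disease
#'   tables.
#' @export
null_cohort <- function(cfg = synthetic_config(), seed = NULL) {
  cfg$marker_effect <- 0
  cfg$universal_effect <- 0
  cfg$n_disease_per_celltype <- 0
  out <- generate_cohort(cfg, seed = seed)
  out$truth$marker_map <- lapply(out$truth$marker_map, function(x) character(0))
  out$truth$disease_effects <-
    out$truth$disease_effects[0, ]
  out
}

#' Expand an expression matrix into replicate probe rows
#'
#' Splits each (miRNA, sample) linear value into `n_probe_replicates` probe
#' signals with multiplicative noise, renormalized so the probe signals of
#' a miRNA sum exactly to the original value — the adjoint of
#' [aggregate_probes()].
#'
#' @param m Linear-scale [mir_matrix()].
#' @param n_replicates Probe replicates per miRNA (default from `cfg`).
#' @param probe_noise_cv Coefficient of variation of the split; 0 gives an
#'   exact equal split.
#' @param seed Seed for the split noise.
#' @return A probe-table tibble (`probe_id`, `mirna_id`, `sample_id`,
#'   `signal`).
#' @export
expand_to_probes <- function(m, n_replicates = 40, probe_noise_cv = 0.1,
                             seed = 1L) {
  stopifnot(inherits(m, "mir_matrix"), mir_scale(m) == "linear")
  with_seed_local(seed, {
    v <- mir_values(m)
    n <- nrow(v)
    k <- ncol(v)
    r <- n_replicates
    if (probe_noise_cv > 0) {
      shape <- 1 / probe_noise_cv^2
      raw <- matrix(stats::rgamma(n * k * r, shape = shape, rate = shape), nrow = r)
    } else {
      raw <- matrix(1, nrow = r, ncol = n * k)
    }
    frac <- sweep(raw, 2, colSums(raw), "/")
    signal <- as.vector(frac) * rep(as.vector(v), each = r)
    tibble::tibble(
      probe_id = paste0(
        rep(rownames(v), each = r, times = k), "_p",
        rep(seq_len(r), times = n * k)
      ),
      mirna_id = rep(rownames(v), each = r, times = k),
      sample_id = rep(colnames(v), each = n * r),
      signal = signal
    )
  })
}

#' Random miRNA-target and pathway annotation for a synthetic cohort
#'
#' Draws a synthetic validated-target map over a synthetic gene universe
#' and random pathway gene sets, so the enrichment stage can run end to end
#' on generated data. Purely synthetic: no real miRNA-target or pathway
#' identities are implied.
#'
#' @param mirna_ids miRNA ids to annotate.
#' @param n_genes Size of the synthetic gene universe.
#' @param n_pathways Number of pathways.
#' @param targets_range,pathway_size_range Ranges the per-miRNA target
#'   counts and pathway sizes are drawn from.
#' @param seed Seed.
#' @return List with `target_map` and `pathways`.
#' @export
simulate_annotation <- function(mirna_ids, n_genes = 400, n_pathways = 25,
                                targets_range = c(5, 30),
                                pathway_size_range = c(10, 60), seed = 1L) {
  with_seed_local(seed, {
    genes <- sprintf("SYNGENE%04d", seq_len(n_genes))
    tm <- lapply(mirna_ids, function(id) {
      sample(genes, sample(targets_range[1]:targets_range[2], 1))
    })
    names(tm) <- mirna_ids
    pw <- lapply(seq_len(n_pathways), function(i) {
      sample(genes, sample(pathway_size_range[1]:pathway_size_range[2], 1))
    })
    names(pw) <- sprintf("syn_pathway_%02d", seq_len(n_pathways))
    list(target_map = tm, pathways = pw)
  })
}
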