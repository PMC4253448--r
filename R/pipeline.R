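#' Analysis parameters for a full pipeline run
#'
#' Collects every stage's tunables with defaults matching the standard
#' protocol: raw and adjusted alpha 0.05, top-50 variance panel, 20
#' classification repetitions, 10% pathway coverage filter.
#'
#' @param detection_threshold Linear detection cutoff (used when no vendor
#'   flag is available).
#' @param log2_floor Floor of the log2 transform.
#' @param normalize_scope `"all"` or `"per_cell_type"`.
#' @param raw_alpha Raw-p cutoff of the candidate filter.
#' @param adj_alpha Adjusted-p cutoff for specific sets and group
#'   contrasts.
#' @param var_equal Pooled-variance t instead of Welch.
#' @param top_k Variance panel size for clustering.
#' @param n_repeats LOOCV repetitions.
#' @param classify_mode `"as_published"` or `"nested"`.
#' @param mixture_mode `"ols"` or `"nnls"`.
#' @param mixture_scale `"log2"` (published protocol) or `"linear"`
#'   (physical mixing).
#' @param subset_fraction Presence-discordance subset fraction.
#' @param coverage Pathway coverage filter fraction.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_threshold = 0, log2_floor = 1,
                            normalize_scope = "all",
                            raw_alpha = 0.05, adj_alpha = 0.05,
                            var_equal = FALSE, top_k = 50, n_repeats = 20,
                            classify_mode = "as_published",
                            mixture_mode = "ols", mixture_scale = "log2",
                            subset_fraction = 0.9, coverage = 0.10) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing, detection summaries, per-cell-type condition
#' contrasts with the union report, disjoint cell-type-specific sets per
#' condition, grouped immune-axis overlaps, whole-blood mixture fits and
#' presence discordance, classification, clustering with purity, and —
#' when annotation is supplied — pathway over-representation of each
#' specific set. All tables are written as TSV under `out_dir` together
#' with a JSON manifest (parameters and summary counts); the run is
#' deterministic given its inputs.
#'
#' @param m Linear-scale aggregated [mir_matrix()] (or a
#'   `synthetic_cohort`, in which case `sheet` is taken from it).
#' @param sheet A [sample_sheet()]; ignored when `m` is a cohort.
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output.
#' @param config A [pipeline_config()].
#' @param target_map,pathways Optional annotation for the enrichment
#'   stage.
#' @param detection Optional vendor detection matrix.
#' @return Invisibly, a list with elements `preprocessed`,
#'   `detection_summary`, `condition_de`, `union_report`, `markers`
#'   (per condition), `group_overlaps`, `mixture_fits`, `correlations`,
#'   `discordance`, `classification`, `clustering`, `ora` and `manifest`.
#' @export
run_pipeline <- function(m, sheet = NULL, out_dir = NULL,
                         config = pipeline_config(),
                         target_map = NULL, pathways = NULL,
                         detection = NULL) {
  if (inherits(m, "synthetic_cohort")) {
    sheet <- m$sheet
    m <- m$matrix
  }
  stopifnot(inherits(m, "mir_matrix"), !is.null(sheet))
  check_sheet_matrix(m, sheet)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      readr::write_tsv(tibble::as_tibble(df), file.path(out_dir, name))
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  pp <- preprocess_cohort(m,
    detection = detection,
    threshold = config$detection_threshold,
    floor = config$log2_floor, sheet = sheet,
    scope = config$normalize_scope
  )
  det <- pp$detection
  lg <- pp$log2

  det_sum <- detection_by_group(det, sheet)
  emit(det_sum, "detection_summary.tsv")

  # condition contrasts per cell type + union report
  cts <- intersect(all_cell_types(), unique(sheet$cell_type))
  cond_de <- lapply(cts, function(ct) {
    condition_contrast(lg, sheet, ct,
      detection = det,
      var_equal = config$var_equal
    )
  })
  names(cond_de) <- cts
  selected <- lapply(cond_de, select_candidates, raw_alpha = config$raw_alpha)
  union_rep <- build_union_report(selected)
  for (ct in cts) emit(cond_de[[ct]], paste0("de_condition_", ct, ".tsv"))
  if (!is.null(out_dir)) {
    write_union_report(union_rep, file.path(out_dir, "union_report.tsv"))
  }

  # disjoint specific sets per condition
  markers <- lapply(conditions(), function(cond) {
    pw <- pairwise_cell_tests(lg, sheet, cond,
      detection = det,
      var_equal = config$var_equal
    )
    derive_specific_sets(pw, adj_alpha = config$adj_alpha, condition = cond)
  })
  names(markers) <- conditions()
  emit(
    dplyr::bind_rows(lapply(markers, tidy)),
    "marker_sets.tsv"
  )

  # grouped immune-axis contrasts, overlap between conditions
  axes <- names(cell_type_ontology())
  group_overlaps <- lapply(axes, function(ax) {
    sig <- lapply(conditions(), function(cond) {
      group_contrast(lg, sheet, ax, cond, det, adj_alpha = config$adj_alpha)
    })
    condition_overlap(sig[[2]], sig[[1]], labels = c("cancer", "control"))
  })
  names(group_overlaps) <- axes
  emit(
    dplyr::bind_rows(
      lapply(axes, function(ax) {
        dplyr::mutate(tidy(group_overlaps[[ax]]), axis = ax)
      })
    ),
    "group_overlaps.tsv"
  )

  # whole-blood mixture modelling
  mix_m <- if (config$mixture_scale == "log2") lg else pp$linear
  fits <- fit_wholeblood_models(mix_m, sheet,
    mode = config$mixture_mode,
    detection = det
  )
  emit(dplyr::bind_rows(lapply(fits, glance)), "mixture_fits.tsv")
  correlations <- subset_wb_correlation(lg, sheet)
  emit(correlations, "subset_wb_correlation.tsv")
  discord <- lapply(conditions(), function(cond) {
    presence_discordance(det, sheet, cond,
      subset_fraction = config$subset_fraction
    )
  })
  names(discord) <- conditions()
  emit(dplyr::bind_rows(lapply(discord, tidy)), "presence_discordance.tsv")

  # classification per cell type
  classification <- classification_report(lg, sheet, det,
    cell_types = cts,
    mode = config$classify_mode,
    raw_alpha = config$raw_alpha,
    n_repeats = config$n_repeats
  )
  emit(classification, "classification.tsv")

  # clustering on the top-variance panel
  panel <- top_variance_features(lg, k = min(config$top_k, nrow(lg)))
  hc <- hierarchical_cluster(lg[panel, , drop = FALSE], axis = "samples")
  ct_labels <- stats::setNames(sheet$cell_type, sheet$sample_id)
  purity <- cluster_purity(hc, ct_labels, n_clusters = length(cts))
  if (!is.null(out_dir)) {
    write_newick(hc, file.path(out_dir, "sample_tree.nwk"))
  }

  # enrichment of each condition's specific sets
  ora <- NULL
  if (!is.null(target_map) && !is.null(pathways)) {
    universe <- sort(unique(toupper(unlist(target_map, use.names = FALSE))))
    ora <- purrr::map_dfr(conditions(), function(cond) {
      purrr::map_dfr(
        names(markers[[cond]]$specific_sets),
        function(ct) {
          ids <- markers[[cond]]$specific_sets[[ct]]
          if (length(ids) == 0) return(NULL)
          res <- ora_marker_set(ids, target_map, pathways,
            universe = universe, coverage = config$coverage
          )
          if (nrow(res) == 0) return(NULL)
          dplyr::mutate(
            dplyr::select(tibble::as_tibble(res), -"overlap_genes"),
            cell_type = ct, condition = cond
          )
        }
      )
    })
    emit(ora, "ora.tsv")
  }

  manifest <- list(
    n_mirna = nrow(m),
    n_samples = ncol(m),
    parameters = unclass(config),
    selected_per_contrast = as.list(attr(union_rep, "totals")),
    specific_set_sizes = lapply(
      markers,
      function(ms) lapply(ms$specific_sets, length)
    ),
    rho_range = attr(correlations, "rho_range"),
    cluster_purity = purity
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  invisible(list(
    preprocessed = pp,
    detection_summary = det_sum,
    condition_de = cond_de,
    union_report = union_rep,
    markers = markers,
    group_overlaps = group_overlaps,
    mixture_fits = fits,
    correlations = correlations,
    discordance = discord,
    classification = classification,
    clustering = list(tree = hc, panel = panel, purity = purity),
    ora = ora,
    manifest = manifest
  ))
}
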