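# hand-built pairwise results over a 3-cell-type universe
fake_de <- function(pair, sig_ids, all_ids, up_in_first = sig_ids) {
  de <- tibble::tibble(
    mirna_id = all_ids,
    mean_a = ifelse(all_ids %in% up_in_first, 5, 1),
    mean_b = 1,
    t_stat = 0, df = 4, raw_p = ifelse(all_ids %in% sig_ids, 1e-4, 0.5),
    direction = ifelse(all_ids %in% up_in_first, "down_in_b", "up_in_b"),
    degenerate = FALSE,
    adj_p = ifelse(all_ids %in% sig_ids, 1e-3, 0.8),
    detected_all_a = TRUE, detected_all_b = TRUE
  )
  attr(de, "contrast") <- pair
  class(de) <- c("de_result", class(de))
  de
}

test_that("pairwise tests cover each unordered cell-type pair once", {
  co <- generate_cohort(small_cfg(seed = 31))
  pp <- preprocess_cohort(co$matrix)
  pw <- pairwise_cell_tests(pp$log2, co$sheet, "control", detection = pp$detection)
  expect_length(pw, choose(5, 2))
  pairs <- lapply(pw, attr, "contrast")
  expect_false(any(vapply(pairs, function(p) "WB" %in% p, logical(1))))
  expect_equal(anyDuplicated(vapply(
    pairs, function(p) paste(sort(p), collapse = "|"), character(1)
  )), 0)
  sub <- pairwise_cell_tests(pp$log2, co$sheet, "control",
    cell_types = c("CD3", "CD14", "CD19"), detection = pp$detection
  )
  expect_length(sub, 3)
})

test_that("specific sets follow the intersect-then-disjointify definition", {
  ids <- paste0("m", 1:6)
  # m1 high only in X: significant exactly in the two X pairs
  # m2 graded across all three: significant everywhere
  pw <- list(
    fake_de(c("X", "Y"), sig_ids = c("m1", "m2"), all_ids = ids),
    fake_de(c("X", "Z"), sig_ids = c("m1", "m2"), all_ids = ids),
    fake_de(c("Y", "Z"), sig_ids = c("m2"), all_ids = ids)
  )
  ms <- derive_specific_sets(pw)
  expect_equal(ms$candidate_sets$X, c("m1", "m2"))
  expect_equal(ms$candidate_sets$Y, "m2")
  expect_equal(ms$candidate_sets$Z, "m2")
  # m2 sits in every candidate set, so disjointification removes it everywhere
  expect_equal(ms$specific_sets$X, "m1")
  expect_equal(ms$specific_sets$Y, character(0))
  expect_equal(ms$specific_sets$Z, character(0))

  # no significance anywhere: all sets empty
  none <- lapply(pw, function(de) {
    de$adj_p <- 0.9
    de
  })
  ms0 <- derive_specific_sets(none)
  expect_true(all(lengths(ms0$candidate_sets) == 0))

  # incomplete pair map is rejected
  expect_error(derive_specific_sets(pw[1:2]), "misses contrast")
})

test_that("specific sets are always pairwise disjoint and shrink with alpha", {
  set.seed(32)
  ids <- paste0("m", 1:40)
  cts <- c("P", "Q", "R", "S")
  for (rep in 1:30) {
    pw <- lapply(utils::combn(cts, 2, simplify = FALSE), function(pair) {
      de <- fake_de(pair, sig_ids = character(0), all_ids = ids)
      de$adj_p <- stats::runif(length(ids))
      de
    })
    ms <- derive_specific_sets(pw, adj_alpha = 0.3)
    all_ids <- unlist(ms$specific_sets)
    expect_equal(anyDuplicated(all_ids), 0)
    for (ct in cts) {
      expect_true(all(ms$specific_sets[[ct]] %in% ms$candidate_sets[[ct]]))
    }
    # every removed candidate appears in >= 2 candidate sets
    removed <- setdiff(unlist(ms$candidate_sets), all_ids)
    for (id in removed) {
      hits <- sum(vapply(ms$candidate_sets, function(s) id %in% s, logical(1)))
      expect_gte(hits, 2)
    }
    # monotonicity: a stricter alpha never grows a candidate set
    stricter <- derive_specific_sets(pw, adj_alpha = 0.1)
    for (ct in cts) {
      expect_true(all(stricter$candidate_sets[[ct]] %in% ms$candidate_sets[[ct]]))
    }
  }
})

test_that("candidate sets match the brute-force definition on a real cohort", {
  co <- generate_cohort(small_cfg(seed = 33))
  pp <- preprocess_cohort(co$matrix)
  pw <- pairwise_cell_tests(pp$log2, co$sheet, "cancer", detection = pp$detection)
  ms <- derive_specific_sets(pw, condition = "cancer")
  for (ct in leukocyte_subsets()) {
    involving <- pw[vapply(pw, function(de) ct %in% attr(de, "contrast"), logical(1))]
    expect_length(involving, 4)
    ref <- Reduce(intersect, lapply(involving, function(de) {
      de$mirna_id[de$adj_p < 0.05]
    }))
    expect_setequal(ms$candidate_sets[[ct]], ref)
  }
})

test_that("planted markers are recovered as specific sets", {
  co <- generate_cohort(small_cfg(seed = 34))
  pp <- preprocess_cohort(co$matrix)
  pw <- pairwise_cell_tests(pp$log2, co$sheet, "control", detection = pp$detection)
  ms <- derive_specific_sets(pw, condition = "control")
  sc <- score_marker_recovery(ms, co$truth, "control")
  expect_true(all(sc$precision >= 0.8))
  expect_true(all(sc$recall >= 0.8))
})

test_that("group contrasts use the correct sides and detection universe", {
  co <- generate_cohort(small_cfg(seed = 35))
  pp <- preprocess_cohort(co$matrix)
  sig <- group_contrast(pp$log2, co$sheet, "lineage", "control", pp$detection)
  expect_equal(attr(sig, "contrast"), c("myeloid", "lymphoid"))
  expect_true(all(sig$adj_p < 0.05))
  # tested universe: detected in all samples of at least one side
  myel <- co$sheet$sample_id[
    co$sheet$cell_type %in% c("CD15", "CD14") & co$sheet$condition == "control"
  ]
  lymph <- co$sheet$sample_id[
    co$sheet$cell_type %in% c("CD3", "CD19", "CD56") & co$sheet$condition == "control"
  ]
  expect_length(myel, 14)
  expect_length(lymph, 21)
  n_ref <- sum(
    rowSums(pp$detection[, myel]) == length(myel) |
      rowSums(pp$detection[, lymph]) == length(lymph)
  )
  expect_equal(attr(sig, "n_tested"), n_ref)
  expect_error(
    group_contrast(pp$log2, co$sheet, "size", "control", pp$detection),
    "unknown axis"
  )
})

test_that("a planted lineage-axis effect is recovered at q = 0.05", {
  # markers of myeloid cell types separate the axis sides by construction
  co <- generate_cohort(small_cfg(seed = 36, n_markers_per_celltype = 10))
  pp <- preprocess_cohort(co$matrix)
  sig <- group_contrast(pp$log2, co$sheet, "lineage", "control", pp$detection)
  planted <- unlist(co$truth$marker_map[c("CD15", "CD14")])
  # the tested universe requires detection in every sample of one side
  myel <- co$sheet$sample_id[
    co$sheet$cell_type %in% c("CD15", "CD14") & co$sheet$condition == "control"
  ]
  lymph <- co$sheet$sample_id[
    co$sheet$cell_type %in% c("CD3", "CD19", "CD56") &
      co$sheet$condition == "control"
  ]
  universe <- rownames(pp$detection)[
    rowSums(pp$detection[, myel]) == length(myel) |
      rowSums(pp$detection[, lymph]) == length(lymph)
  ]
  qualified <- intersect(planted, universe)
  recovered <- intersect(sig$mirna_id, qualified)
  expect_gte(length(recovered) / max(1, length(qualified)), 0.8)
})

test_that("condition overlap partitions by membership and direction", {
  a <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"),
    direction = c("up_in_b", "up_in_b", "down_in_b")
  )
  b <- tibble::tibble(
    mirna_id = c("m2", "m3", "m4"),
    direction = c("up_in_b", "up_in_b", "down_in_b")
  )
  ov <- condition_overlap(a, b, labels = c("cancer", "control"))
  expect_equal(ov$exclusive_a, "m1")
  expect_equal(ov$exclusive_b, "m4")
  expect_equal(ov$shared_same_direction, "m2")
  expect_equal(ov$shared_opposite_direction, "m3")

  # identical sets: everything shared in the same direction
  ov2 <- condition_overlap(a, a)
  expect_length(ov2$exclusive_a, 0)
  expect_setequal(ov2$shared_same_direction, a$mirna_id)

  expect_error(
    condition_overlap(a, dplyr::mutate(b, direction = NA_character_)),
    "without direction"
  )
})

test_that("overlap partition equals brute-force set algebra on random inputs", {
  set.seed(37)
  ids <- paste0("m", 1:25)
  for (i in 1:200) {
    a_ids <- sample(ids, sample(0:15, 1))
    b_ids <- sample(ids, sample(0:15, 1))
    a <- tibble::tibble(
      mirna_id = a_ids,
      direction = sample(c("up_in_b", "down_in_b"), length(a_ids), TRUE)
    )
    b <- tibble::tibble(
      mirna_id = b_ids,
      direction = sample(c("up_in_b", "down_in_b"), length(b_ids), TRUE)
    )
    ov <- condition_overlap(a, b)
    parts <- list(
      ov$exclusive_a, ov$exclusive_b,
      ov$shared_same_direction, ov$shared_opposite_direction
    )
    expect_equal(anyDuplicated(unlist(parts)), 0)
    expect_setequal(unlist(parts), union(a_ids, b_ids))
    expect_setequal(ov$exclusive_a, setdiff(a_ids, b_ids))
    shared <- intersect(a_ids, b_ids)
    same <- shared[a$direction[match(shared, a$mirna_id)] ==
      b$direction[match(shared, b$mirna_id)]]
    expect_setequal(ov$shared_same_direction, same)
  }
})

test_that("exclusive counts are consistent with published-style overlap arithmetic", {
  # |A| = 75, |B| = 64, shared same-direction 60 -> exclusives 15 and 4
  a <- tibble::tibble(
    mirna_id = paste0("m", 1:75),
    direction = "up_in_b"
  )
  b <- tibble::tibble(
    mirna_id = paste0("m", c(1:60, 76:79)),
    direction = "up_in_b"
  )
  ov <- condition_overlap(a, b, labels = c("cancer", "control"))
  expect_length(ov$shared_same_direction, 60)
  expect_length(ov$exclusive_a, 15)
  expect_length(ov$exclusive_b, 4)
  expect_length(ov$shared_opposite_direction, 0)
})
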