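test_that("Welch t matches the textbook worked example", {
  m <- toy_log2(matrix(c(1, 2, 3, 4, 5, 6), 1, 6))
  de <- row_t_test(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$t_stat, -3.674235, tolerance = 1e-6)
  expect_equal(de$df, 4, tolerance = 1e-9)
  expect_equal(de$raw_p, 0.02131164, tolerance = 1e-6)
  expect_equal(de$direction, "up_in_b")
})

test_that("identical constant groups give t = 0, p = 1, direction none", {
  m <- toy_log2(matrix(c(5, 6, 7, 5, 6, 7), 1, 6))
  de <- row_t_test(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$t_stat, 0)
  expect_equal(de$raw_p, 1)
  # constant but different groups: flagged degenerate, p at machine minimum
  m2 <- toy_log2(matrix(c(2, 2, 2, 3, 3, 3), 1, 6))
  de2 <- row_t_test(m2, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(de2$degenerate)
  expect_equal(de2$raw_p, .Machine$double.xmin)
  expect_equal(de2$direction, "up_in_b")
})

test_that("row t statistics agree with stats::t.test on random instances", {
  set.seed(21)
  for (var_equal in c(FALSE, TRUE)) {
    v <- matrix(stats::rnorm(500 * 9), 500, 9,
      dimnames = list(paste0("m", 1:500), paste0("s", 1:9))
    )
    m <- mir_matrix(v, "log2")
    de <- row_t_test(m, paste0("s", 1:4), paste0("s", 5:9), var_equal = var_equal)
    idx <- sample(500, 120)
    for (i in idx) {
      ref <- stats::t.test(v[i, 1:4], v[i, 5:9], var.equal = var_equal)
      expect_equal(de$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(de$df[i], unname(ref$parameter), tolerance = 1e-10)
      expect_equal(de$raw_p[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("swapping groups negates t, preserves p and flips direction", {
  set.seed(22)
  v <- matrix(stats::rnorm(50 * 8), 50, 8,
    dimnames = list(paste0("m", 1:50), paste0("s", 1:8))
  )
  m <- mir_matrix(v, "log2")
  ab <- row_t_test(m, paste0("s", 1:4), paste0("s", 5:8))
  ba <- row_t_test(m, paste0("s", 5:8), paste0("s", 1:4))
  expect_equal(ab$t_stat, -ba$t_stat)
  expect_equal(ab$raw_p, ba$raw_p)
  flips <- ab$direction == "up_in_b" & ba$direction == "down_in_b" |
    ab$direction == "down_in_b" & ba$direction == "up_in_b"
  expect_true(all(flips | ab$direction == "none"))
})

test_that("null data give uniform raw p values", {
  set.seed(23)
  v <- matrix(stats::rnorm(200 * 14), 200, 14,
    dimnames = list(paste0("m", 1:200), paste0("s", 1:14))
  )
  de <- row_t_test(mir_matrix(v, "log2"), paste0("s", 1:7), paste0("s", 8:14))
  frac <- mean(de$raw_p < 0.05)
  ci <- stats::binom.test(round(frac * 200), 200, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_gt(stats::ks.test(de$raw_p, "punif")$p.value, 0.01)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("BH agrees with the brute-force step-up definition on random vectors", {
  set.seed(24)
  for (i in 1:250) {
    p <- stats::runif(40)
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(diff(got[order(p)]) >= 0)) # order-preserving
  }
})

test_that("candidate selection applies the raw-p and detection filter", {
  de <- tibble::tibble(
    mirna_id = paste0("m", 1:4),
    mean_a = 0, mean_b = 1, t_stat = -2, df = 10,
    raw_p = c(0.01, 0.06, 0.01, 0.04),
    direction = "up_in_b", degenerate = FALSE,
    adj_p = c(0.04, 0.2, 0.04, 0.1),
    detected_all_a = c(FALSE, TRUE, FALSE, TRUE),
    detected_all_b = c(FALSE, TRUE, TRUE, FALSE)
  )
  attr(de, "contrast") <- c("control", "cancer")
  class(de) <- c("de_result", class(de))
  sel <- select_candidates(de)
  # m1: p ok but undetected in both groups; m2: detected but p too high
  expect_setequal(sel$mirna_id, c("m3", "m4"))
})

test_that("candidate selection equals a brute-force row scan on random inputs", {
  set.seed(25)
  co <- generate_cohort(small_cfg(seed = 25))
  pp <- preprocess_cohort(co$matrix)
  de <- condition_contrast(pp$log2, co$sheet, "CD3", detection = pp$detection)
  sel <- select_candidates(de, raw_alpha = 0.05)
  manual <- character(0)
  for (i in seq_len(nrow(de))) {
    if (de$raw_p[i] < 0.05 && (de$detected_all_a[i] || de$detected_all_b[i])) {
      manual <- c(manual, de$mirna_id[i])
    }
  }
  expect_setequal(sel$mirna_id, manual)
})

test_that("union reports count overlaps and per-contrast totals", {
  sel <- list(
    c1 = tibble::tibble(mirna_id = c("miR-a", "miR-b"), raw_p = c(0.01, 0.02)),
    c2 = tibble::tibble(mirna_id = "miR-a", raw_p = 0.03),
    c3 = tibble::tibble(mirna_id = "miR-c", raw_p = 0.04)
  )
  rep <- build_union_report(sel)
  expect_equal(rep$mirna_id[1], "miR-a") # highest overlap first
  expect_equal(rep$n_contrasts[rep$mirna_id == "miR-a"], 2)
  expect_equal(unname(attr(rep, "totals")), c(2L, 1L, 1L))
  # row overlap equals the number of non-absent cells
  for (i in seq_len(nrow(rep))) {
    expect_equal(
      rep$n_contrasts[i],
      sum(!is.na(rep[i, c("c1", "c2", "c3")]))
    )
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_union_report(rep, f)
  lines <- readLines(f)
  expect_match(lines[length(lines)], "^total\t2\t1\t1")
})

test_that("union overlap counts equal brute-force set algebra on random selections", {
  set.seed(26)
  ids <- paste0("m", 1:30)
  sel <- lapply(1:4, function(i) {
    pick <- sample(ids, sample(0:12, 1))
    tibble::tibble(mirna_id = pick, raw_p = stats::runif(length(pick), 0, 0.05))
  })
  names(sel) <- paste0("k", 1:4)
  rep <- build_union_report(sel)
  for (id in rep$mirna_id) {
    n_ref <- sum(vapply(sel, function(df) id %in% df$mirna_id, logical(1)))
    expect_equal(rep$n_contrasts[rep$mirna_id == id], n_ref)
  }
  expect_setequal(rep$mirna_id, unique(unlist(lapply(sel, `[[`, "mirna_id"))))
})
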