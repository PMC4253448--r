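test_that("an exact mixture is recovered to numerical precision", {
  set.seed(41)
  n <- 200
  mirnas <- paste0("m", 1:n)
  profiles <- matrix(2^stats::rnorm(n * 3, 7, 2), n, 3,
    dimnames = list(mirnas, c("d1_CD15", "d1_CD3", "d1_CD14"))
  )
  wb <- 0.6 * profiles[, 1] + 0.3 * profiles[, 2] + 0.1 * profiles[, 3]
  m <- mir_matrix(cbind(profiles, d1_WB = wb), scale = "linear")
  sheet <- sample_sheet(tibble::tibble(
    sample_id = colnames(m),
    donor_id = "d1",
    cell_type = c("CD15", "CD3", "CD14", "WB"),
    condition = "control"
  ))
  fit <- fit_wholeblood_model(m, sheet, "d1")
  expect_equal(unname(fit$coefficients[c("CD15", "CD3", "CD14")]),
    c(0.6, 0.3, 0.1),
    tolerance = 1e-8
  )
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # OLS residuals are orthogonal to every regressor
  for (ct in c("CD15", "CD3", "CD14")) {
    expect_lt(abs(sum(fit$residuals * profiles[, paste0("d1_", ct)])) /
      sqrt(sum(profiles[, paste0("d1_", ct)]^2)), 1e-6)
  }
})

test_that("noisy planted weights are recovered within tolerance", {
  set.seed(42)
  n <- 800
  w <- c(CD15 = 0.55, CD3 = 0.25, CD14 = 0.10, CD19 = 0.07, CD56 = 0.03)
  errs <- replicate(20, {
    profiles <- matrix(2^stats::rnorm(n * 5, 7, 1), n, 5)
    colnames(profiles) <- paste0("d1_", names(w))
    rownames(profiles) <- paste0("m", 1:n)
    wb <- drop(profiles %*% w) * 2^stats::rnorm(n, 0, 0.2)
    m <- mir_matrix(cbind(profiles, d1_WB = wb), scale = "linear")
    sheet <- sample_sheet(tibble::tibble(
      sample_id = colnames(m), donor_id = "d1",
      cell_type = c(names(w), "WB"), condition = "control"
    ))
    fit <- fit_wholeblood_model(m, sheet, "d1")
    max(abs(fit$coefficients[names(w)] - w))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("nnls coefficients are nonnegative and match OLS when OLS is feasible", {
  co <- generate_cohort(small_cfg(seed = 43, n_hidden = 0))
  det <- call_detection(co$matrix)
  ols <- fit_wholeblood_model(co$matrix, co$sheet, "ctrl01",
    mode = "ols", detection = det
  )
  nn <- fit_wholeblood_model(co$matrix, co$sheet, "ctrl01",
    mode = "nnls", detection = det
  )
  expect_true(all(nn$coefficients >= 0))
  if (all(ols$coefficients >= 0)) {
    expect_equal(nn$coefficients, ols$coefficients, tolerance = 1e-6)
    expect_equal(nn$intercept, ols$intercept, tolerance = 1e-4)
  }
})

test_that("rank-deficient designs are flagged and still solved", {
  set.seed(44)
  n <- 50
  a <- 2^stats::rnorm(n, 6, 1)
  m <- mir_matrix(
    cbind(d1_CD3 = a, d1_CD14 = a, d1_WB = 2 * a) |>
      `rownames<-`(paste0("m", 1:n)),
    scale = "linear"
  )
  sheet <- sample_sheet(tibble::tibble(
    sample_id = colnames(m), donor_id = "d1",
    cell_type = c("CD3", "CD14", "WB"), condition = "control"
  ))
  expect_warning(
    fit <- fit_wholeblood_model(m, sheet, "d1"),
    "rank-deficient"
  )
  expect_true(fit$rank_deficient)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("hidden whole-blood components surface in the largest residuals", {
  cfg <- small_cfg(seed = 45, noise_sd = 0.1)
  co <- generate_cohort(cfg)
  det <- call_detection(co$matrix)
  fit <- fit_wholeblood_model(co$matrix, co$sheet, "ctrl02",
    mode = "ols", detection = det
  )
  hidden_present <- intersect(co$truth$hidden_ids, names(fit$residuals))
  top <- names(sort(fit$residuals, decreasing = TRUE))[seq_along(hidden_present)]
  expect_gte(length(intersect(top, hidden_present)) / length(hidden_present), 0.8)
})

test_that("subset-whole-blood correlations behave at the trivial extremes", {
  set.seed(46)
  x <- 2^stats::rnorm(100, 6, 1)
  m <- mir_matrix(
    cbind(d1_CD3 = x, d1_WB = x) |> `rownames<-`(paste0("m", 1:100)),
    scale = "linear"
  )
  sheet <- sample_sheet(tibble::tibble(
    sample_id = colnames(m), donor_id = "d1",
    cell_type = c("CD3", "WB"), condition = "control"
  ))
  corr <- subset_wb_correlation(m, sheet)
  expect_equal(corr$rho, 1)

  # anti-correlated vector
  m2 <- mir_matrix(
    cbind(d1_CD3 = max(x) - x, d1_WB = x) |> `rownames<-`(paste0("m", 1:100)),
    scale = "linear"
  )
  corr2 <- subset_wb_correlation(m2, sheet)
  expect_equal(corr2$rho, -1)

  # zero-variance subset: undefined correlation recorded as missing
  m3 <- mir_matrix(
    cbind(d1_CD3 = rep(5, 100), d1_WB = x) |> `rownames<-`(paste0("m", 1:100)),
    scale = "linear"
  )
  expect_true(is.na(subset_wb_correlation(m3, sheet)$rho))
})

test_that("default cohorts show a tight high correlation band", {
  co <- generate_cohort(synthetic_config(seed = 47))
  pp <- preprocess_cohort(co$matrix)
  corr <- subset_wb_correlation(pp$log2, co$sheet)
  expect_equal(nrow(corr), 14 * 5)
  band <- attr(corr, "rho_range")
  expect_gt(band[1], 0.5)
  expect_lte(band[2], 1)
})

test_that("presence discordance follows the all-WB / no-subset definitions", {
  mirnas <- paste0("m", 1:4)
  samples <- c(paste0("wb", 1:3), paste0("sub", 1:10))
  d <- matrix(FALSE, 4, 13, dimnames = list(mirnas, samples))
  d["m1", paste0("wb", 1:3)] <- TRUE # all WB, no subset -> wb_only
  d["m2", paste0("sub", 1:10)] <- TRUE # 100% subsets, no WB -> subset_only
  d["m3", paste0("sub", 1:9)] <- TRUE # 90% subsets: not > 0.9 -> excluded
  d["m4", c("wb1", "sub1")] <- TRUE # mixed -> neither
  sheet <- sample_sheet(tibble::tibble(
    sample_id = samples,
    donor_id = paste0("d", seq_along(samples)),
    cell_type = c(rep("WB", 3), rep(c("CD3", "CD14"), 5)),
    condition = "control"
  ))
  pd <- presence_discordance(d, sheet, "control", subset_fraction = 0.9)
  expect_equal(pd$wb_only, "m1")
  expect_equal(pd$subset_only, "m2")
  expect_length(intersect(pd$wb_only, pd$subset_only), 0)
  expect_error(
    presence_discordance(d, sheet, "cancer"),
    "no whole-blood samples"
  )
})

test_that("planted hidden components are recovered as whole-blood-only", {
  co <- generate_cohort(small_cfg(seed = 48, n_hidden = 10, noise_sd = 0))
  det <- call_detection(co$matrix)
  pd <- presence_discordance(det, co$sheet, "control")
  expect_setequal(pd$wb_only, co$truth$hidden_ids)
})
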