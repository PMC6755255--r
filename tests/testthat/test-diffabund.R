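test_that("welch_t matches stats::t.test and is antisymmetric", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  w <- welch_t(a, b)
  o <- t.test(a, b)
  expect_equal(w$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(o$parameter), tolerance = 1e-10)
  expect_equal(w$p, o$p.value, tolerance = 1e-10)

  withr::with_seed(3, {
    A <- matrix(rnorm(40), 8)
    B <- matrix(rnorm(30, 1), 6)
  })
  wm <- welch_t(A, B)
  for (j in 1:5) {
    o <- t.test(A[, j], B[, j])
    expect_equal(wm$t[j], unname(o$statistic), tolerance = 1e-10)
    expect_equal(wm$p[j], o$p.value, tolerance = 1e-10)
  }
  flip <- welch_t(B, A)
  expect_equal(flip$t, -wm$t)
  expect_equal(flip$p, wm$p)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- welch_t(c(2, 2), c(5, 5))
  expect_equal(degen$p, 0)
  const <- welch_t(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
})

test_that("bh_adjust applies the step-up rule and bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(4, p <- runif(50))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("aldex_da recovers a planted fold change with positive effect", {
  cfg <- sim_config(D = 100L, group_sizes = c(14L, 14L), n_da = 5L,
                    da_fold = 4, seed = 19L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  res <- aldex_da(counts, truth$annotation, B = 64L, seed = 20L)
  planted <- res[res$feature %in% truth$da_features, ]
  expect_true(all(planted$effect > 0))
  expect_true(all(planted$expected_p_bh < 0.05))
  expect_true(all(res$diff_win >= 0))
  # diff_btw of a 4-fold feature is near 2 on the log2 scale
  expect_equal(median(planted$diff_btw), 2, tolerance = 0.5)
})

test_that("aldex_da makes few calls under a global null", {
  for (s in c(2L, 3L, 4L)) {
    cfg <- sim_config(D = 200L, group_sizes = c(14L, 14L), seed = s)
    truth <- simulate_absolute(cfg)
    counts <- sequence_counts(truth)
    res <- aldex_da(counts, truth$annotation, B = 64L, seed = s + 100L)
    expect_lte(length(da_calls(res, 0.05, "both")), 1L)
    # expected BH p under the null is conservative
    expect_gt(mean(res$expected_p_bh), 0.5)
  }
})

test_that("shifting the reference in one group shifts every diff_btw by exactly -delta", {
  cfg <- sim_config(D = 20L, group_sizes = c(5L, 5L), seed = 7L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  ann <- truth$annotation
  ref <- ref_spec("alr", "gene_0001")
  e <- draw_ensemble(counts, B = 8L, seed = 11L)
  base <- aldex_da(counts, ann, ref = ref, seed = 5L, ensemble = e)
  delta <- 1.5
  e2 <- e
  g2 <- ann$group == "group2"
  e2$instances[g2, "gene_0001", ] <- e2$instances[g2, "gene_0001", ] * 2^delta
  shifted <- aldex_da(counts, ann, ref = ref, seed = 5L, ensemble = e2)
  others <- base$feature != "gene_0001"
  expect_equal(shifted$diff_btw[others], base$diff_btw[others] - delta,
               tolerance = 1e-12)
})

test_that("library-size rescaling leaves effects approximately unchanged at high depth", {
  cfg <- sim_config(D = 50L, group_sizes = c(6L, 6L), n_da = 3L,
                    depth_fixed = 1e6, seed = 23L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  r1 <- aldex_da(counts, truth$annotation, B = 32L, seed = 1L)
  scaled <- count_table(round(counts$values * rep(c(1, 3), 6)),
                        unit = "raw_count")
  r2 <- aldex_da(scaled, truth$annotation, B = 32L, seed = 1L)
  expect_equal(r1$diff_btw, r2$diff_btw, tolerance = 0.05)
})

test_that("linear_model_da matches a per-instance least-squares oracle and aldex_da's calls", {
  cfg <- sim_config(D = 30L, group_sizes = c(7L, 7L), n_da = 3L, seed = 29L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  ann <- truth$annotation
  X <- cbind(intercept = 1, groupB = as.numeric(ann$group == "group2"))

  # B = 1 oracle: replicate the single instance and fit lm per feature
  fit <- linear_model_da(counts, X, B = 1L, seed = 31L)
  e <- draw_ensemble(counts, B = 1L, prior = 0.5, seed = 31L)
  A <- lr_transform(count_table(e$instances[, , 1L], unit = "proportion"),
                    base = 2)$values
  for (j in c(1L, 5L, 12L)) {
    o <- lm(A[, j] ~ X[, 2L])
    expect_equal(unname(fit$coefficients[j, ]), unname(coef(o)),
                 tolerance = 1e-8)
  }

  # group design agrees with aldex_da on sign and calls
  fit2 <- linear_model_da(counts, X, B = 64L, seed = 31L)
  da <- aldex_da(counts, ann, B = 64L, seed = 31L)
  planted <- match(truth$da_features, rownames(fit2$coefficients))
  expect_true(all(fit2$coefficients[planted, "groupB"] > 0))
  expect_true(all(fit2$p_bh[planted, "groupB"] < 0.05))
  expect_true(all(sign(fit2$coefficients[planted, "groupB"]) ==
                    sign(da$diff_btw[planted])))

  # degenerate designs
  expect_error(linear_model_da(counts, cbind(1, 1, X[, 2L]), B = 1L,
                               seed = 1L), "rank deficient")
  only_int <- linear_model_da(counts, matrix(1, 14L, 1L), B = 2L, seed = 1L)
  expect_equal(ncol(only_int$coefficients), 1L)
})
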