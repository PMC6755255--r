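test_that("vlr matches hand arithmetic and is scaling invariant", {
  expect_equal(vlr(c(1, 2, 4), c(2, 8, 32)), 0.4805, tolerance = 1e-4)
  expect_equal(vlr(c(1, 2, 4), 3 * c(1, 2, 4)), 0)
  x <- c(1, 5, 2, 9)
  y <- c(3, 1, 4, 2)
  s <- c(10, 0.1, 2, 7)
  expect_equal(vlr(s * x, s * y), vlr(x, y), tolerance = 1e-12)
  expect_error(vlr(c(0, 1), c(1, 2)), "zeros")
  expect_gte(vlr(x, y, alpha = 0.5), 0)
})

test_that("proportionality matrices match the brute-force oracle", {
  t <- random_table(6, 5, seed = 61)
  rho <- proportionality(t, "rho")$values
  expect_equal(rho, oracle_rho(t$values), tolerance = 1e-10)
  expect_true(all(abs(rho - t(rho)) < 1e-12))
  expect_true(all(rho >= -1 - 1e-12 & rho <= 1 + 1e-12))
  expect_equal(unname(diag(rho)), rep(1, 5))

  phis <- proportionality(t, "phi_s")$values
  expect_equal(phis, (1 - rho) / (1 + rho), tolerance = 1e-12)
  expect_equal(unname(diag(phis)), rep(0, 5))

  # phi's documented asymmetric relation to vlr and the row variance
  phi <- proportionality(t, "phi")$values
  A <- oracle_clr(t$values)
  expect_equal(phi[2L, 4L], var(A[, 2L] - A[, 4L]) / var(A[, 2L]),
               tolerance = 1e-10)
  expect_equal(phi[4L, 2L], var(A[, 2L] - A[, 4L]) / var(A[, 4L]),
               tolerance = 1e-10)
})

test_that("perfectly proportional features reach rho = 1 and constants go missing", {
  t <- random_table(8, 4, seed = 63)
  v <- cbind(t$values, e = 5 * t$values[, 2L])
  rho <- proportionality(count_table(v, unit = "pseudo_count"), "rho")$values
  expect_equal(rho["f02", "e"], 1, tolerance = 1e-12)

  v2 <- cbind(t$values, const = 7)
  # a constant feature is not constant after clr; force the degenerate
  # case with an alr reference so its transformed variance is exactly 0
  expect_warning(
    pm <- proportionality(count_table(v2, unit = "pseudo_count"), "rho",
                          ref = ref_spec("alr", "const")),
    "constant")
  expect_true(is.na(pm$values["const", "f01"]))
})

test_that("rho is invariant under per-sample scaling with the clr reference", {
  t <- random_table(7, 6, seed = 65)
  lam <- exp(rnorm(7))
  t2 <- count_table(t$values * lam, unit = t$unit)
  expect_equal(proportionality(t2, "rho")$values,
               proportionality(t, "rho")$values, tolerance = 1e-10)
})

test_that("permutation FDR saturates at a cutoff everything passes and under the null", {
  t <- random_table(10, 8, seed = 67)
  f <- permutation_fdr(t, "rho", cutoffs = c(-1, 0.9), n_perm = 30L,
                       seed = 68L)
  expect_equal(f$fdr[f$cutoff == -1], 1)  # null and observed both saturate
  expect_equal(f$observed[1L], choose(8, 2))
  # independent features: high cutoffs yield no or fully-null discoveries
  high <- f[f$cutoff == 0.9, ]
  expect_true(is.na(high$fdr) || high$fdr > 0.5)
  # observed counts non-increasing in the cutoff
  expect_true(all(diff(f$observed) <= 0))
})

test_that("planted proportional modules survive the FDR cutoff as cliques", {
  cfg <- sim_config(D = 60L, group_sizes = c(8L, 8L),
                    prop_modules = c(3L), seed = 71L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  tw <- bayesian_multiplicative_replace(counts)
  pm <- proportionality(tw, "rho")
  el <- edge_list(pm, 0.9)
  expect_true(all(pair_key(truth$prop_pairs) %in% pair_key(el$edges)))

  f <- permutation_fdr(tw, "rho", n_perm = 30L, seed = 72L)
  expect_equal(f$observed[f$cutoff == 0.9], nrow(el$edges))
  cut <- select_cutoff(f, 0.05)
  expect_false(is.na(cut))
  rec <- edge_list(pm, cut)
  expect_true(all(pair_key(truth$prop_pairs) %in% pair_key(rec$edges)))
})

test_that("expected proportionality stays in range and matches the point estimate at depth", {
  withr::with_seed(73, {
    abund <- exp(matrix(rnorm(5 * 12, 4, 1), 5, 12))
    m <- t(vapply(1:5, function(i) {
      rmultinom(1, 5e5, prob = abund[i, ])[, 1]
    }, numeric(12)))
    rownames(m) <- paste0("s", 1:5)
    colnames(m) <- sprintf("f%02d", 1:12)
  })
  t <- count_table(m, unit = "raw_count")
  e <- draw_ensemble(t, B = 32L, seed = 74L)
  er <- expected_proportionality(e, "rho")
  point <- proportionality(bayesian_multiplicative_replace(t), "rho")
  expect_lt(max(abs(er$values - point$values)), 1e-2)
  expect_true(all(er$values >= -1 - 1e-9 & er$values <= 1 + 1e-9))

  e1 <- draw_ensemble(t, B = 1L, seed = 75L)
  single <- proportionality(count_table(e1$instances[, , 1L],
                                        unit = "proportion"), "rho")
  expect_equal(expected_proportionality(e1, "rho")$values, single$values,
               tolerance = 1e-12)
})

test_that("edge_list orders deterministically, annotates nodes and warns when empty", {
  t <- random_table(6, 5, seed = 77)
  pm <- proportionality(t, "rho")
  expect_warning(el <- edge_list(pm, 1.01), "no pair")
  expect_equal(nrow(el$edges), 0L)

  el2 <- edge_list(pm, -1)
  expect_equal(nrow(el2$edges), choose(5, 2))
  expect_true(!is.unsorted(el2$edges$g))

  ann <- two_group_annotation(t)
  da <- aldex_da(count_table(round(t$values) + 1, unit = "raw_count"),
                 ann, B = 8L, seed = 9L)
  el3 <- edge_list(pm, -1, node_annotations = da)
  expect_true(all(c("effect", "expected_p_bh") %in% names(el3$nodes)))
})
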