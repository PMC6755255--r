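make_pair_table <- function(lr_a, lr_b) {
  # two-feature table whose only log-ratio is the given per-group values
  v <- cbind(x = exp(c(lr_a, lr_b)), y = 1)
  rownames(v) <- paste0("s", seq_len(length(lr_a) + length(lr_b)))
  t <- count_table(v, unit = "pseudo_count")
  ann <- sample_annotation(data.frame(
    sample_id = rownames(v),
    group = rep(c("A", "B"), c(length(lr_a), length(lr_b)))
  ), t = t)
  list(t = t, ann = ann)
}

test_that("theta matches its defining variance decomposition on hand examples", {
  # constant within groups, different between: maximal difference
  p1 <- make_pair_table(c(1, 1, 1), c(2, 2, 2))
  r1 <- theta_d(p1$t, p1$ann)
  expect_equal(r1$theta, 0)

  # identical groups: no difference at all
  p2 <- make_pair_table(c(1, 2, 3), c(1, 2, 3))
  r2 <- theta_d(p2$t, p2$ann)
  expect_equal(r2$theta, 1, tolerance = 1e-12)
  expect_equal(r2$vlr1, 1, tolerance = 1e-12)
  expect_equal(r2$vlr_total, 4 / 5, tolerance = 1e-12)
})

test_that("theta matches the brute-force oracle on a seeded table", {
  t <- random_table(8, 6, seed = 81)
  ann <- two_group_annotation(t)
  r <- theta_d(t, ann)
  oracle <- oracle_theta(t$values, ann$group)
  for (k in seq_len(nrow(r))) {
    expect_equal(r$theta[k], oracle[r$g[k], r$h[k]], tolerance = 1e-10)
  }
})

test_that("theta is symmetric in the pair and invariant under per-sample scaling", {
  t <- random_table(9, 5, seed = 83)
  ann <- two_group_annotation(t)
  r1 <- theta_d(t, ann)
  t2 <- count_table(t$values * exp(rnorm(9)), unit = t$unit)
  r2 <- theta_d(t2, ann)
  expect_equal(r1$theta, r2$theta, tolerance = 1e-9)
  # swapping the pair orientation never changes theta
  swapped <- count_table(t$values[, rev(feature_ids(t))], unit = t$unit)
  r3 <- theta_d(swapped, ann)
  expect_equal(sort(r1$theta), sort(r3$theta), tolerance = 1e-12)
})

test_that("update_f converts theta to the exact one-way ANOVA", {
  p <- make_pair_table(c(0.9, 1.4, 1.1), c(2.2, 1.9, 2.4))
  r <- update_f(theta_d(p$t, p$ann))
  lr <- log(p$t$values[, "x"] / p$t$values[, "y"])
  o <- anova(lm(lr ~ p$ann$group))
  expect_equal(r$F_stat, o$`F value`[1L], tolerance = 1e-9)
  expect_equal(r$p, o$`Pr(>F)`[1L], tolerance = 1e-9)

  # theta = 0.5, n = 6 -> F = 4 and the F(1, 4) upper tail
  expect_equal((6 - 2) * (1 - 0.5) / 0.5, 4)
  expect_equal(pf(4, 1, 4, lower.tail = FALSE), 0.1161165, tolerance = 1e-6)

  # theta = 1 -> F = 0, p = 1; oracle equivalence on a random table
  p2 <- make_pair_table(c(1, 2, 3), c(1, 2, 3))
  r2 <- update_f(theta_d(p2$t, p2$ann))
  expect_equal(r2$F_stat, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)

  t <- random_table(10, 4, seed = 85)
  ann <- two_group_annotation(t)
  r3 <- update_f(theta_d(t, ann))
  for (k in c(1L, 3L, 6L)) {
    lr <- log(t$values[, r3$g[k]] / t$values[, r3$h[k]])
    o <- anova(lm(lr ~ ann$group))
    expect_equal(r3$p[k], o$`Pr(>F)`[1L], tolerance = 1e-9)
  }
})

test_that("null-label p-values are calibrated", {
  cfg <- sim_config(D = 50L, group_sizes = c(14L, 14L), seed = 2L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  tw <- bayesian_multiplicative_replace(counts)
  pd <- update_f(theta_d(tw, truth$annotation))
  # marginal calibration: KS on mutually independent (disjoint) pairs;
  # overlapping pairs share features and have dependent p-values
  ids <- feature_ids(counts)
  disj <- pd$g %in% ids[seq(1L, 49L, 2L)] &
    pd$h == ids[match(pd$g, ids) + 1L]
  expect_gt(suppressWarnings(ks.test(pd$p[disj], "punif")$p.value), 0.01)
  expect_lt(abs(mean(pd$p < 0.05) - 0.05), 0.05)
})

test_that("planted stoichiometry shifts are recovered with high sensitivity", {
  cfg <- sim_config(D = 80L, group_sizes = c(14L, 14L), n_diff_pairs = 10L,
                    diff_ratio_shift = 2, seed = 87L)
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  tw <- bayesian_multiplicative_replace(counts)
  pd <- update_f(theta_d(tw, truth$annotation))
  sig <- pd[!is.na(pd$p_bh) & pd$p_bh < 0.05, ]
  expect_gte(mean(pair_key(truth$diff_pairs) %in% pair_key(sig)), 0.8)
})

test_that("lr_design_fit nests update_f and finds planted time trends", {
  t <- random_table(10, 4, seed = 89)
  ann <- two_group_annotation(t)
  r <- update_f(theta_d(t, ann))
  X <- cbind(intercept = 1, groupB = as.numeric(ann$group == "B"))
  fit <- lr_design_fit(t, r[, c("g", "h")], X)
  expect_equal(fit$F_stat, r$F_stat, tolerance = 1e-9)
  expect_equal(fit$p, r$p, tolerance = 1e-9)

  # intercept-only: no test, coefficient = mean log-ratio
  fit0 <- lr_design_fit(t, r[1:2, c("g", "h")], matrix(1, 10L, 1L))
  expect_true(all(is.na(fit0$p)))
  lr <- log(t$values[, r$g[1L]] / t$values[, r$h[1L]])
  expect_equal(fit0[[3L]][1L], mean(lr), tolerance = 1e-10)

  # planted time-varying ratio: the time model catches what group misses
  cfg <- sim_config(D = 40L, group_sizes = c(14L, 14L), time_points = 7L,
                    replicates = 2L, n_trend_pairs = 1L, trend_slope = 0.4,
                    diff_pair_sdlog = 0.15, seed = 91L)
  truth <- simulate_absolute(cfg)
  counts <- bayesian_multiplicative_replace(sequence_counts(truth))
  ann2 <- truth$annotation
  pair <- truth$trend_pairs
  Xg <- cbind(1, as.numeric(ann2$group == "group2"))
  Xt <- cbind(1, as.numeric(ann2$group == "group2"), time = ann2$time)
  fg <- lr_design_fit(counts, pair, Xg)
  ft <- lr_design_fit(counts, pair, Xt)
  expect_lt(ft$p[1L], 0.01)
  expect_gt(fg$p[1L], ft$p[1L])
})

test_that("pair_plot_data orients pairs toward the second group and ranks by theta", {
  cfg <- sim_config(D = 30L, group_sizes = c(10L, 10L), n_diff_pairs = 3L,
                    seed = 93L)
  truth <- simulate_absolute(cfg)
  counts <- bayesian_multiplicative_replace(sequence_counts(truth))
  ann <- truth$annotation
  pd <- update_f(theta_d(counts, ann))
  probe <- truth$diff_pairs$g[1L]
  out <- pair_plot_data(pd, counts, ann, probe, top_k = 5L)
  expect_gt(nrow(out), 0L)
  expect_true(!is.unsorted(out$theta))
  # orientation: second group's mean log-ratio is never below the first's
  for (pr in unique(out$pair)) {
    sub <- out[out$pair == pr, ]
    expect_gte(mean(sub$log_ratio[sub$group == "group2"]),
               mean(sub$log_ratio[sub$group == "group1"]))
  }
  # the planted pair containing the probe ranks first
  first <- strsplit(out$pair[1L], "/", fixed = TRUE)[[1L]]
  expect_true(setequal(
    first,
    unlist(truth$diff_pairs[truth$diff_pairs$g == probe |
                              truth$diff_pairs$h == probe, ][1L, ])))

  expect_equal(nrow(pair_plot_data(pd, counts, ann, probe, top_k = 0L)), 0L)
})
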