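# Reference-relative differential abundance. Each Dirichlet instance is
# log-ratio transformed (base 2) and tested feature-wise between the two
# groups; expected Benjamini-Hochberg p-values and median effect sizes are
# reported. "Up-regulated" always means up-regulated *relative to the
# chosen reference*, never in absolute terms.

#' Welch's unequal-variance t-test (vectorised)
#'
#' Direct evaluation of the Welch statistic and Welch-Satterthwaite degrees
#' of freedom, vectorised over the columns of two matrices so it can run
#' across thousands of features per Dirichlet instance. For two plain
#' vectors it matches `stats::t.test`.
#'
#' @param a,b numeric vectors, or matrices with samples as rows and
#'   features as columns (>= 2 rows each).
#' @return list with `t`, `df`, `p` (two-sided), one element per column.
#'   Zero variance in both groups yields `t = 0, p = 1` when the means are
#'   equal, and `p = 0` with infinite `t` when they differ.
#' @export
welch_t <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2L || nrow(b) < 2L) stopf("each group needs >= 2 values")
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  se2 <- va / na + vb / nb
  d <- ma - mb
  tt <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  tt[degenerate & d == 0] <- 0
  tt[degenerate & d != 0] <- sign(d[degenerate & d != 0]) * Inf
  df[degenerate] <- na + nb - 2
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[degenerate & d == 0] <- 1
  p[degenerate & d != 0] <- 0
  list(t = unname(tt), df = unname(df), p = unname(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wrapper over `stats::p.adjust`), rejecting
#' missing inputs rather than silently dropping them.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) stopf("NA/NaN p-values not allowed")
  if (any(p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dirichlet Monte-Carlo differential abundance
#'
#' For each of `B` Dirichlet instances the proportions are transformed with
#' the chosen reference (base 2), a Welch t-test compares the two groups
#' feature-wise, and p-values are BH-adjusted within the instance. Reported
#' per feature: the expected (mean) BH p-value, the median between-group
#' difference `diff_btw`, the median within-group difference `diff_win`
#' (per instance: the larger of one random intra-group absolute difference
#' from each group), and the median effect size `diff_btw / diff_win`.
#'
#' @param t [count_table]; non-integer values are ceiled with a warning.
#' @param ann [sample_annotation] with exactly 2 group levels, >= 2 samples
#'   each. `diff_btw > 0` means higher in the *second* group level.
#' @param ref a [ref_spec] (default clr).
#' @param B Monte-Carlo instances (default 128).
#' @param prior Dirichlet prior mass per cell (default 0.5).
#' @param seed integer seed.
#' @param ensemble optional precomputed [draw_ensemble] (overrides `t`'s
#'   counts, `B` and `prior`); instances may be any positive matrices,
#'   which permits controlled reference-perturbation experiments.
#' @return a `data.frame` (class `da_result`) with columns `feature`,
#'   `effect`, `diff_btw`, `diff_win`, `expected_p_bh`; attributes record
#'   the reference, `B`, `seed` and group levels.
#' @export
aldex_da <- function(t, ann, ref = ref_spec("clr"), B = 128L, prior = 0.5,
                     seed = NULL, ensemble = NULL) {
  stopifnot(inherits(t, "count_table"))
  ann <- sample_annotation(ann, t = t)
  grp <- check_two_groups(ann)
  if (!is.null(ref$features)) {
    if (any(t$values[, intersect(ref$features, feature_ids(t))] == 0)) {
      stopf("reference features contain zeros; choose a reference observed in every sample")
    }
  }
  if (is.null(ensemble)) {
    v <- t$values
    if (any(v != floor(v))) {
      warnf("non-integer counts ceiled before Dirichlet sampling")
      v <- ceiling(v)
      t <- count_table(v, unit = t$unit)
    }
    ensemble <- draw_ensemble(t, B = B, prior = prior, seed = seed)
  }
  inst <- ensemble$instances
  B <- dim(inst)[3L]
  D <- dim(inst)[2L]
  i1 <- which(grp == levels(grp)[1L])
  i2 <- which(grp == levels(grp)[2L])
  p_acc <- matrix(NA_real_, D, B)
  db_acc <- matrix(NA_real_, D, B)
  dw_acc <- matrix(NA_real_, D, B)
  # pair sampling gets its own offset seed so it never replays the
  # ensemble's gamma stream
  pair_seed <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  with_seed(pair_seed, {
    for (b in seq_len(B)) {
      m <- inst[, , b, drop = TRUE]
      lt <- lr_transform(count_table(m, unit = "proportion"), ref = ref,
                         base = 2)
      A <- lt$values
      wt <- welch_t(A[i1, , drop = FALSE], A[i2, , drop = FALSE])
      p_acc[, b] <- bh_adjust(wt$p)
      med1 <- apply(A[i1, , drop = FALSE], 2L, stats::median)
      med2 <- apply(A[i2, , drop = FALSE], 2L, stats::median)
      db_acc[, b] <- med2 - med1
      pr1 <- sample(i1, 2L)
      pr2 <- sample(i2, 2L)
      w1 <- abs(A[pr1[1L], ] - A[pr1[2L], ])
      w2 <- abs(A[pr2[1L], ] - A[pr2[2L], ])
      dw_acc[, b] <- pmax(w1, w2)
    }
  })
  eff <- db_acc / dw_acc
  out <- data.frame(
    feature = colnames(inst[, , 1L]),
    effect = apply(eff, 1L, stats::median),
    diff_btw = apply(db_acc, 1L, stats::median),
    diff_win = apply(dw_acc, 1L, stats::median),
    expected_p_bh = rowMeans(p_acc),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "ref") <- describe_ref(if (inherits(ref, "ref_spec")) ref else ref_spec("clr"))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "groups") <- levels(grp)
  class(out) <- c("da_result", "data.frame")
  out
}

#' Significant features relative to the reference
#'
#' @param r a [aldex_da] result.
#' @param alpha expected-BH threshold (default 0.05).
#' @param direction `"up"` (effect > 0), `"down"` (< 0), or `"both"`.
#' @return character vector of feature ids.
#' @export
da_calls <- function(r, alpha = 0.05, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  keep <- r$expected_p_bh < alpha
  keep <- switch(direction,
                 up = keep & r$effect > 0,
                 down = keep & r$effect < 0,
                 both = keep)
  r$feature[keep]
}

#' Dirichlet Monte-Carlo linear models per feature
#'
#' Generalizes [aldex_da] to arbitrary designs: per instance, each
#' transformed feature is regressed on the design by ordinary least
#' squares; expected coefficients and expected within-instance BH-adjusted
#' p-values are returned.
#'
#' @param t [count_table] (non-integer values ceiled).
#' @param design numeric design matrix, rows matching samples, full rank.
#' @param ref a [ref_spec].
#' @param B,prior,seed as in [aldex_da].
#' @return list with matrices `coefficients` (D x p expected OLS
#'   coefficients) and `p_bh` (D x p expected adjusted p per coefficient;
#'   intercept column included).
#' @export
linear_model_da <- function(t, design, ref = ref_spec("clr"), B = 128L,
                            prior = 0.5, seed = NULL) {
  stopifnot(inherits(t, "count_table"))
  design <- as.matrix(design)
  if (nrow(design) != nrow(t$values)) {
    stopf("design rows (%d) must match samples (%d)",
          nrow(design), nrow(t$values))
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(colnames(design)[-keep], collapse = ", "))
  }
  v <- t$values
  if (any(v != floor(v))) {
    warnf("non-integer counts ceiled before Dirichlet sampling")
    t <- count_table(ceiling(v), unit = t$unit)
  }
  e <- draw_ensemble(t, B = B, prior = prior, seed = seed)
  n <- nrow(design); pcoef <- ncol(design)
  XtXinv <- chol2inv(chol(crossprod(design)))
  D <- ncol(t$values)
  coef_acc <- matrix(0, D, pcoef)
  p_acc <- matrix(0, D, pcoef)
  for (b in seq_len(dim(e$instances)[3L])) {
    m <- ensemble_instance(e, b)
    A <- lr_transform(count_table(m, unit = "proportion"), ref = ref,
                      base = 2)$values
    bet <- XtXinv %*% crossprod(design, A)          # p x D
    res <- A - design %*% bet
    sigma2 <- colSums(res^2) / (n - pcoef)           # per feature
    se <- sqrt(outer(sigma2, diag(XtXinv)))          # D x p
    tt <- t(bet) / se
    pv <- 2 * stats::pt(abs(tt), n - pcoef, lower.tail = FALSE)
    pv_bh <- apply(pv, 2L, bh_adjust)
    coef_acc <- coef_acc + t(bet)
    p_acc <- p_acc + pv_bh
  }
  B_eff <- dim(e$instances)[3L]
  cn <- colnames(design) %||% paste0("coef_", seq_len(pcoef))
  out_coef <- coef_acc / B_eff
  out_p <- p_acc / B_eff
  dimnames(out_coef) <- dimnames(out_p) <- list(feature_ids(t), cn)
  list(coefficients = out_coef, p_bh = out_p,
       ref = describe_ref(ref), B = B_eff, seed = seed)
}
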