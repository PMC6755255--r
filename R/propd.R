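# Differential proportionality. The VLR of the same pair can be compared
# across groups without any reference: theta is the within-group share of a
# pair's total log-ratio variance. theta = 0 means a maximal difference in
# the pair's ratio between groups (a stoichiometry shift); theta = 1 means
# none. Differential proportionality is the differential abundance
# analysis of all pairwise log-ratios, and its F-test is a two-group
# one-way ANOVA on the log-ratio.

#' Differential proportionality (theta) for all feature pairs
#'
#' For each pair (g, h), with per-group log-ratio variances `VLR^k` and the
#' pooled total `VLR_tot` over all `n` samples:
#' \deqn{\theta = \frac{\sum_k (N^k - 1)\,VLR^k}{(n - 1)\,VLR_{tot}}}
#'
#' @param t positive [count_table] (or any nonnegative table with
#'   `alpha > 0`).
#' @param ann [sample_annotation] with exactly 2 groups, >= 2 samples each.
#' @param alpha Box-Cox exponent (default 0 = log; `0.5` works well with
#'   zeros).
#' @return a `propd_result` data.frame, one row per unordered pair:
#'   `g`, `h`, `theta`, `vlr1`, `vlr2`, `vlr_total`, `lrm1`, `lrm2`
#'   (per-group mean log-ratios `ln(g/h)`), with group sizes, levels and
#'   `alpha` as attributes. Pairs with zero total variance are `NA`.
#' @export
theta_d <- function(t, ann, alpha = 0) {
  stopifnot(inherits(t, "count_table"))
  ann <- sample_annotation(ann, t = t)
  grp <- check_two_groups(ann)
  v <- t$values
  if (alpha == 0 && any(v <= 0)) {
    stopf("zeros present: run the zeros module or set alpha > 0")
  }
  L <- boxcox_or_log(v, alpha)
  lv <- levels(grp)
  i1 <- grp == lv[1L]; i2 <- grp == lv[2L]
  n1 <- sum(i1); n2 <- sum(i2); n <- n1 + n2
  vlr1 <- vlr_matrix_from(L[i1, , drop = FALSE])
  vlr2 <- vlr_matrix_from(L[i2, , drop = FALSE])
  vlrt <- vlr_matrix_from(L)
  theta <- ((n1 - 1) * vlr1 + (n2 - 1) * vlr2) / ((n - 1) * vlrt)
  theta[vlrt == 0] <- NA_real_
  # numerical guard: theta is a variance ratio in [0, 1]
  theta <- pmin(pmax(theta, 0), 1)
  pi <- pair_index(colnames(v))
  ij <- cbind(pi$i, pi$j)
  m1 <- colMeans(L[i1, , drop = FALSE])
  m2 <- colMeans(L[i2, , drop = FALSE])
  out <- data.frame(
    g = pi$g, h = pi$h,
    theta = theta[ij],
    vlr1 = vlr1[ij], vlr2 = vlr2[ij], vlr_total = vlrt[ij],
    lrm1 = m1[pi$i] - m1[pi$j],
    lrm2 = m2[pi$i] - m2[pi$j],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "group_levels") <- lv
  attr(out, "group_sizes") <- c(n1, n2)
  attr(out, "alpha") <- alpha
  class(out) <- c("propd_result", "data.frame")
  out
}

#' Exact F-test for differential proportionality
#'
#' Converts theta to an F statistic, `F = (n - 2)(1 - theta)/theta`, with
#' an upper-tail p-value from `F(1, n - 2)` — exactly the two-group one-way
#' ANOVA on the pair's log-ratio values — and BH-adjusts across all pairs.
#'
#' @param r a [theta_d] result.
#' @return `r` with added columns `F_stat`, `p`, `p_bh`.
#' @export
update_f <- function(r) {
  stopifnot(inherits(r, "propd_result"))
  n <- sum(attr(r, "group_sizes"))
  if (n <= 2L) stopf("F-test needs n > 2")
  th <- r$theta
  Fst <- (n - 2) * (1 - th) / th
  Fst[!is.na(th) & th == 0] <- Inf
  p <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
  p[!is.na(th) & th == 0] <- 0
  r$F_stat <- Fst
  r$p <- p
  ok <- !is.na(p)
  r$p_bh <- NA_real_
  r$p_bh[ok] <- bh_adjust(p[ok])
  r
}

#' Linear models on pairwise log-ratios
#'
#' Extends differential proportionality to arbitrary designs by modelling
#' each pair's log-ratio `ln(x_g / x_h)` as an ordinary least squares
#' function of the design; the overall F compares against the
#' intercept-only model, BH-adjusted across pairs.
#'
#' @param t positive [count_table].
#' @param pairs data.frame with character columns `g`, `h` naming feature
#'   pairs (e.g. a subset of a [theta_d] result).
#' @param design numeric design matrix with an intercept column, rows
#'   matching samples, full rank.
#' @return data.frame: `g`, `h`, one coefficient column per design column,
#'   `F_stat`, `p`, `p_bh` (all `NA` for an intercept-only design).
#' @export
lr_design_fit <- function(t, pairs, design) {
  stopifnot(inherits(t, "count_table"))
  design <- as.matrix(design)
  n <- nrow(t$values)
  if (nrow(design) != n) stopf("design rows must match samples")
  if (qr(design)$rank < ncol(design)) stopf("design is rank deficient")
  v <- t$values
  if (any(v <= 0)) stopf("zeros present: run the zeros module first")
  miss <- setdiff(unique(c(pairs$g, pairs$h)), feature_ids(t))
  if (length(miss) > 0L) stopf("unknown feature(s): %s",
                               paste(miss, collapse = ", "))
  L <- log(v)
  Y <- L[, pairs$g, drop = FALSE] - L[, pairs$h, drop = FALSE]  # n x npair
  p <- ncol(design)
  XtXinv <- chol2inv(chol(crossprod(design)))
  bet <- XtXinv %*% crossprod(design, Y)   # p x npair
  res <- Y - design %*% bet
  rss1 <- colSums(res^2)
  cn <- colnames(design) %||% paste0("coef_", seq_len(p))
  out <- data.frame(g = pairs$g, h = pairs$h, stringsAsFactors = FALSE)
  for (k in seq_len(p)) out[[cn[k]]] <- bet[k, ]
  if (p > 1L) {
    mu <- colMeans(Y)
    rss0 <- colSums((Y - rep(mu, each = n))^2)
    df1 <- p - 1L
    df2 <- n - p
    Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pv <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
    out$F_stat <- Fst
    out$p <- pv
    out$p_bh <- bh_adjust(pv)
  } else {
    out$F_stat <- NA_real_
    out$p <- NA_real_
    out$p_bh <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Per-sample log-ratio series for the top differential pairs of a feature
#'
#' Long-format data for parallel-coordinate plots: the `top_k`
#' significant pairs containing `feature`, sorted by ascending theta, with
#' numerator/denominator oriented so the second group's mean log-ratio is
#' always >= the first group's.
#'
#' @param r an [update_f]-augmented `propd_result`.
#' @param t the positive [count_table] the result came from.
#' @param ann the matching [sample_annotation].
#' @param feature feature id that every returned pair must contain.
#' @param top_k number of pairs (default 10).
#' @param fdr BH significance threshold (default 0.05).
#' @return data.frame: `pair`, `rank`, `theta`, `sample_id`, `group`,
#'   `log_ratio` (oriented); empty with a warning when the feature is in no
#'   significant pair.
#' @export
pair_plot_data <- function(r, t, ann, feature, top_k = 10L, fdr = 0.05) {
  stopifnot(inherits(r, "propd_result"))
  if (!"p_bh" %in% names(r)) stopf("run update_f() first")
  if (!feature %in% feature_ids(t)) stopf("unknown feature '%s'", feature)
  ann <- sample_annotation(ann, t = t)
  lv <- attr(r, "group_levels")
  sel <- r[(r$g == feature | r$h == feature) & !is.na(r$p_bh) &
             r$p_bh < fdr, , drop = FALSE]
  if (top_k == 0L || nrow(sel) == 0L) {
    if (nrow(sel) == 0L) warnf("feature '%s' is in no significant pair", feature)
    return(data.frame(pair = character(), rank = integer(),
                      theta = numeric(), sample_id = character(),
                      group = character(), log_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  sel <- sel[order(sel$theta), , drop = FALSE]
  sel <- utils::head(sel, top_k)
  L <- log(t$values)
  g2 <- ann$group == lv[2L]
  rows <- lapply(seq_len(nrow(sel)), function(k) {
    gg <- sel$g[k]; hh <- sel$h[k]
    lr <- L[, gg] - L[, hh]
    if (mean(lr[g2]) < mean(lr[!g2])) {
      lr <- -lr
      tmp <- gg; gg <- hh; hh <- tmp
    }
    data.frame(pair = paste0(gg, "/", hh), rank = k, theta = sel$theta[k],
               sample_id = sample_ids(t), group = as.character(ann$group),
               log_ratio = lr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
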