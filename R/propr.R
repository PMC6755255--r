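# Proportionality analysis. Correlation on relative data is spurious:
# closure alone can make independent features look tightly correlated. The
# variance of the log-ratio (VLR) of a pair is reference-free and
# normalization-invariant; the proportionality coefficients rho, phi and
# phi_s rescale it against the log-ratio variances of the transformed data
# so pairs become comparable.

# Box-Cox power in place of the log: (x^alpha - 1)/alpha, limit alpha -> 0
# is ln(x). Pragmatic zero handling outside the strict CoDA framework.
boxcox_or_log <- function(m, alpha = 0) {
  if (alpha > 0) (m^alpha - 1) / alpha else log(m)
}

#' Variance of the log-ratio of two features
#'
#' `var(ln(x/y))` across samples (n - 1 denominator). Zero means perfect
#' proportionality; any per-sample scaling factor cancels exactly.
#'
#' @param x,y strictly positive numeric vectors of equal length >= 2 (or
#'   any positive vectors with `alpha > 0`).
#' @param alpha optional Box-Cox exponent replacing the log (default 0 =
#'   log; `0.5` works well when zeros are present).
#' @return nonnegative scalar.
#' @export
vlr <- function(x, y, alpha = 0) {
  if (length(x) != length(y) || length(x) < 2L) {
    stopf("x and y must have equal length >= 2")
  }
  if (alpha == 0 && (any(x <= 0) || any(y <= 0))) {
    stopf("zeros present: run the zeros module or set alpha > 0")
  }
  stats::var(boxcox_or_log(x, alpha) - boxcox_or_log(y, alpha))
}

# D x D VLR matrix from a transformed (or plain log) value matrix:
# VLR(g,h) = var(A_g - A_h) = S_gg + S_hh - 2 S_gh.
vlr_matrix_from <- function(A) {
  S <- stats::cov(A)
  d <- diag(S)
  outer(d, d, "+") - 2 * S
}

#' Pairwise proportionality matrix
#'
#' With `A` the transformed table: `rho(g,h) = 1 - VLR(g,h) /
#' (var A_g + var A_h)` (in `[-1, 1]`, 1 = perfect proportionality),
#' `phi(g,h) = VLR(g,h) / var A_g` (asymmetric), and
#' `phi_s = (1 - rho)/(1 + rho)` (a dissimilarity). Like differential
#' abundance, proportionality is relative to the transformation reference.
#'
#' @param t positive [count_table] (or any table with `alpha > 0`).
#' @param metric `"rho"`, `"phi"`, or `"phi_s"`.
#' @param ref a [ref_spec] (default clr).
#' @param alpha Box-Cox exponent (default 0 = log).
#' @return a `pair_matrix`: list with `values` (D x D), `metric`, `ref`
#'   description, `alpha`. `phi` is stored directed: entry (g, h) uses
#'   `var A_g` (the row feature) as the reference variance. Constant
#'   features yield `NA` entries with a warning.
#' @export
proportionality <- function(t, metric = c("rho", "phi", "phi_s"),
                            ref = ref_spec("clr"), alpha = 0) {
  metric <- match.arg(metric)
  stopifnot(inherits(t, "count_table"))
  A <- transformed_values(t, ref, alpha)
  S <- stats::cov(A)
  d <- diag(S)
  vl <- outer(d, d, "+") - 2 * S
  if (any(d == 0)) {
    warnf("constant feature(s) after transformation: %s; their entries are NA",
          paste(colnames(A)[d == 0], collapse = ", "))
  }
  denom_rho <- outer(d, d, "+")
  rho <- 1 - vl / denom_rho
  rho[d == 0, ] <- NA_real_   # undefined for zero-variance features
  rho[, d == 0] <- NA_real_
  diag(rho) <- ifelse(d == 0, NA_real_, 1)
  m <- switch(metric,
    rho = rho,
    phi = {
      ph <- vl / d  # recycles d down rows: entry (g,h) = vl/var(A_g)
      ph[d == 0, ] <- NA_real_
      ph
    },
    phi_s = {
      ps <- (1 - rho) / (1 + rho)
      ps[!is.na(rho) & rho == -1] <- Inf
      ps
    }
  )
  dimnames(m) <- dimnames(vl)
  structure(list(values = m, metric = metric, ref = describe_ref(ref),
                 alpha = alpha),
            class = "pair_matrix")
}

# internal: transformed values with Box-Cox support
transformed_values <- function(t, ref, alpha) {
  if (alpha > 0) {
    v <- t$values
    if (any(v < 0)) stopf("negative values")
    # Box-Cox clr analogue: power-transformed values centred on the
    # reference mean of power-transformed values
    b <- boxcox_or_log(v, alpha)
    fidx <- if (is.null(ref$features)) NULL else match(ref$features, colnames(v))
    ctr <- if (is.null(fidx)) rowMeans(b) else rowMeans(b[, fidx, drop = FALSE])
    b - ctr
  } else {
    lr_transform(t, ref = ref, base = exp(1))$values
  }
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %s over %d features, relative to %s (alpha %g)\n",
              x$metric, ncol(x$values), x$ref, x$alpha))
  invisible(x)
}

# count upper-triangle pairs beyond a cutoff ("beyond" depends on metric
# direction: >= for rho, <= for dissimilarity-type metrics)
count_beyond <- function(m, metric, cutoff) {
  ut <- m[upper.tri(m)]
  ut <- ut[!is.na(ut)]
  if (metric == "rho") sum(ut >= cutoff) else sum(ut <= cutoff)
}

#' Permutation false discovery rate across cutoffs
#'
#' For each permutation, every feature's values are shuffled across samples
#' independently (destroying inter-feature association while preserving
#' marginals), and the metric is recomputed. The estimated FDR at a cutoff
#' is the mean permuted count of pairs beyond it divided by the observed
#' count ("beyond" = `>=` for rho, `<=` for phi/phi_s), capped at 1; when
#' no observed pair passes, the FDR is reported `NA`.
#'
#' @param t positive [count_table].
#' @param metric,ref,alpha as in [proportionality].
#' @param cutoffs cutoff grid (default `seq(0, 1, 0.05)`).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return an `fdr_table` data.frame: `cutoff`, `observed`,
#'   `permuted_mean`, `fdr`; attributes `n_perm`, `seed`, `metric`.
#' @export
permutation_fdr <- function(t, metric = "rho", ref = ref_spec("clr"),
                            alpha = 0, cutoffs = seq(0, 1, 0.05),
                            n_perm = 100L, seed = NULL) {
  stopifnot(inherits(t, "count_table"))
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  obs <- proportionality(t, metric, ref = ref, alpha = alpha)$values
  observed <- vapply(cutoffs, function(cc) count_beyond(obs, metric, cc),
                     numeric(1L))
  v <- t$values
  n <- nrow(v)
  perm_counts <- matrix(0, n_perm, length(cutoffs))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      vp <- apply(v, 2L, function(col) col[sample.int(n)])
      rownames(vp) <- rownames(v)
      pm <- proportionality(count_table(vp, unit = t$unit), metric,
                            ref = ref, alpha = alpha)$values
      perm_counts[k, ] <- vapply(cutoffs, function(cc) {
        count_beyond(pm, metric, cc)
      }, numeric(1L))
    }
  })
  permuted_mean <- colMeans(perm_counts)
  fdr <- ifelse(observed > 0, pmin(permuted_mean / observed, 1), NA_real_)
  out <- data.frame(cutoff = cutoffs, observed = observed,
                    permuted_mean = permuted_mean, fdr = fdr)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "metric") <- metric
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' Smallest cutoff controlling the permutation FDR
#'
#' @param f an [permutation_fdr] table.
#' @param target FDR bound (default 0.05).
#' @return the smallest cutoff with estimated FDR below `target` (for rho:
#'   smallest rho cutoff; `NA` if none qualifies).
#' @export
select_cutoff <- function(f, target = 0.05) {
  ok <- which(!is.na(f$fdr) & f$fdr < target)
  if (length(ok) == 0L) return(NA_real_)
  f$cutoff[min(ok)]
}

#' Expected proportionality over a Dirichlet ensemble
#'
#' Element-wise mean of the per-instance proportionality matrix — the
#' ensemble analogue of a point-estimate pair matrix, addressing low-count
#' imprecision. Per-instance `NA` entries propagate.
#'
#' @param e a [draw_ensemble] ensemble.
#' @param metric,ref,alpha as in [proportionality].
#' @return a `pair_matrix` of expected coefficients.
#' @export
expected_proportionality <- function(e, metric = "rho",
                                     ref = ref_spec("clr"), alpha = 0) {
  stopifnot(inherits(e, "dirichlet_ensemble"))
  B <- dim(e$instances)[3L]
  acc <- NULL
  for (b in seq_len(B)) {
    m <- proportionality(count_table(ensemble_instance(e, b),
                                     unit = "proportion"),
                         metric, ref = ref, alpha = alpha)$values
    acc <- if (is.null(acc)) m else acc + m
  }
  structure(list(values = acc / B, metric = metric, ref = describe_ref(ref),
                 alpha = alpha),
            class = "pair_matrix")
}

#' Edge list of a proportionality network
#'
#' Undirected edges for all pairs beyond the cutoff, ordered
#' lexicographically by pair id; optionally annotates nodes with
#' differential-abundance calls for network colouring.
#'
#' @param m a [proportionality] `pair_matrix`.
#' @param cutoff threshold (`>=` for rho, `<=` for phi/phi_s).
#' @param node_annotations optional [aldex_da] result; adds per-node
#'   `effect` and `expected_p_bh`.
#' @return list with `edges` (data.frame `g`, `h`, `value`) and `nodes`
#'   (data.frame `feature` plus DA columns when given).
#' @export
edge_list <- function(m, cutoff, node_annotations = NULL) {
  stopifnot(inherits(m, "pair_matrix"))
  vals <- m$values
  ids <- colnames(vals)
  pi <- pair_index(ids)
  val <- vals[cbind(pi$i, pi$j)]
  pass <- if (m$metric == "rho") {
    !is.na(val) & val >= cutoff
  } else {
    !is.na(val) & val <= cutoff
  }
  edges <- data.frame(g = pi$g[pass], h = pi$h[pass], value = val[pass],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$g, edges$h), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) warnf("no pair passes the cutoff %g", cutoff)
  node_ids <- sort(unique(c(edges$g, edges$h)))
  nodes <- data.frame(feature = node_ids, stringsAsFactors = FALSE)
  if (!is.null(node_annotations)) {
    idx <- match(nodes$feature, node_annotations$feature)
    nodes$effect <- node_annotations$effect[idx]
    nodes$expected_p_bh <- node_annotations$expected_p_bh[idx]
  }
  list(edges = edges, nodes = nodes)
}
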