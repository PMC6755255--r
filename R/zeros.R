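# Zero handling. Sequencing zeros are "count zeros": the feature was seen
# in some sample, so its expected value here is positive but the depth was
# too shallow to observe it. Logarithms cannot take zeros, so features are
# either removed (sub-composition) or zeros are replaced multiplicatively,
# preserving every ratio among the observed parts.

#' Remove zero-laden features
#'
#' Feature removal yields a sub-composition that any CoDA method can
#' analyze. Features whose zero fraction exceeds `max_zero_fraction` are
#' dropped; all-zero features are always dropped (they carry no
#' information). Surviving values are untouched, so all ratios among
#' surviving features are preserved exactly.
#'
#' @param t a [count_table].
#' @param max_zero_fraction maximum tolerated fraction of zero samples per
#'   feature, in `[0, 1]`. `0` keeps only zero-free features; `1` removes
#'   only all-zero features.
#' @return a [count_table]; removed ids are attached as
#'   `attr(, "removed_features")`.
#' @export
drop_zero_features <- function(t, max_zero_fraction) {
  stopifnot(inherits(t, "count_table"))
  if (max_zero_fraction < 0 || max_zero_fraction > 1) {
    stopf("max_zero_fraction must be in [0, 1]")
  }
  zf <- colMeans(t$values == 0)
  drop <- zf > max_zero_fraction | zf == 1
  if (all(drop)) stopf("all features would be removed at threshold %g",
                       max_zero_fraction)
  if (sum(!drop) < 2L) stopf("fewer than 2 features would survive")
  out <- count_table(t$values[, !drop, drop = FALSE], unit = t$unit)
  attr(out, "removed_features") <- colnames(t$values)[drop]
  out
}

#' Simple multiplicative zero replacement
#'
#' Per sample, zero proportions are set to a fixed small value `delta` and
#' the non-zero proportions are shrunk by the factor `1 - z_i * delta`
#' (`z_i` = number of zeros in sample i), so ratios among the originally
#' non-zero parts are preserved exactly.
#'
#' @param t a [count_table].
#' @param delta replacement value in proportion units, in `(0, 1)`.
#' @param output `"pseudo_count"` (rescale each sample by its original
#'   total; default) or `"proportion"`.
#' @return a strictly positive [count_table].
#' @export
simple_multiplicative_replace <- function(t, delta = 0.001,
                                          output = c("pseudo_count",
                                                     "proportion")) {
  output <- match.arg(output)
  stopifnot(inherits(t, "count_table"))
  if (delta <= 0 || delta >= 1) stopf("delta must be in (0, 1)")
  v <- t$values
  tot <- rowSums(v)
  if (any(tot == 0)) stopf("all-zero sample(s): %s",
                           paste(rownames(v)[tot == 0], collapse = ", "))
  p <- v / tot
  z <- rowSums(p == 0)
  if (any(z * delta >= 1)) {
    stopf("replacement mass z*delta >= 1 in sample(s): %s; use a smaller delta",
          paste(rownames(v)[z * delta >= 1], collapse = ", "))
  }
  shrink <- 1 - z * delta
  out <- p * shrink
  out[p == 0] <- delta
  finalize_replaced(out, tot, output, t)
}

#' Bayesian-multiplicative zero replacement
#'
#' Count-zero replacement by the posterior expectation under a Dirichlet
#' prior: for sample `i` with total `n_i`, prior strength `s_i` and prior
#' weights `alpha_j`, a zero cell's proportion becomes
#' `s_i * alpha_j / (n_i + s_i)` and the non-zero proportions are shrunk by
#' one minus the total replaced mass, preserving their ratios exactly.
#' Default prior: uniform weights `alpha_j = 1/D` with the square-root
#' strength `s_i = sqrt(n_i)` (the SQ prior family); other weights or
#' strengths can be supplied.
#'
#' @param t a [count_table] with count-like values (unit `raw_count`).
#' @param prior_strength per-sample strength: `"sqrt"` (default,
#'   `s_i = sqrt(n_i)`) or a positive number used for every sample.
#' @param prior_weights optional vector of `D` positive weights summing
#'   to 1 (default uniform `1/D`).
#' @param output `"pseudo_count"` (default) or `"proportion"`.
#' @return a strictly positive [count_table].
#' @export
bayesian_multiplicative_replace <- function(t, prior_strength = "sqrt",
                                            prior_weights = NULL,
                                            output = c("pseudo_count",
                                                       "proportion")) {
  output <- match.arg(output)
  stopifnot(inherits(t, "count_table"))
  v <- t$values
  if (t$unit != "raw_count" && any(v != floor(v))) {
    warnf("Bayesian-multiplicative replacement assumes count-like totals; input unit is '%s'", t$unit)
  }
  D <- ncol(v)
  n <- rowSums(v)
  if (any(n == 0)) stopf("all-zero sample(s): %s",
                         paste(rownames(v)[n == 0], collapse = ", "))
  s <- if (identical(prior_strength, "sqrt")) sqrt(n) else {
    if (!is.numeric(prior_strength) || prior_strength <= 0) {
      stopf("prior_strength must be \"sqrt\" or a positive number")
    }
    rep(prior_strength, length(n))
  }
  alpha <- prior_weights %||% rep(1 / D, D)
  if (length(alpha) != D || any(alpha <= 0)) {
    stopf("prior_weights must be %d positive values", D)
  }
  alpha <- alpha / sum(alpha)
  p <- v / n
  zero <- p == 0
  # replaced proportion for a zero cell (i, j): s_i * alpha_j / (n_i + s_i)
  repl <- (s / (n + s)) %o% alpha
  replaced_mass <- rowSums(repl * zero)
  out <- p * (1 - replaced_mass)
  out[zero] <- repl[zero]
  min_obs <- apply(p, 1L, function(r) min(r[r > 0]))
  too_big <- rowSums(zero & repl > min_obs) > 0
  if (any(too_big)) {
    warnf("replaced value exceeds the smallest observed proportion in sample(s) %s: prior may be too strong",
          paste(rownames(v)[too_big], collapse = ", "))
  }
  finalize_replaced(out, n, output, t)
}

finalize_replaced <- function(p, totals, output, t) {
  if (output == "pseudo_count") {
    out <- count_table(p * totals, unit = "pseudo_count")
  } else {
    out <- count_table(p, unit = "proportion")
  }
  out
}
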