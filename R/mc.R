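# Dirichlet Monte-Carlo machinery. Small counts carry large technical
# imprecision: a proportion observed as 0/50 is compatible with values
# spanning orders of magnitude. Drawing B posterior proportion vectors per
# sample from Dirichlet(counts + prior) and reporting expected statistics
# propagates that uncertainty into every downstream result.

#' Draw a Dirichlet ensemble from a count table
#'
#' Instance `b`, sample `j` is one draw from
#' `Dirichlet(counts_j + prior)`, generated as per-cell Gamma draws with
#' row normalization. Zero cells always receive strictly positive sampled
#' proportions.
#'
#' @param t nonnegative [count_table].
#' @param B number of Monte-Carlo instances (default 128).
#' @param prior prior mass added to every cell (default 0.5).
#' @param seed integer seed; the same seed reproduces the ensemble exactly.
#' @return a `dirichlet_ensemble`: list with `instances` (array
#'   N x D x B of proportions), `prior`, `seed`.
#' @export
draw_ensemble <- function(t, B = 128L, prior = 0.5, seed = NULL) {
  stopifnot(inherits(t, "count_table"))
  if (B < 1L) stopf("B must be >= 1")
  if (prior <= 0) stopf("prior must be > 0")
  v <- t$values
  if (any(rowSums(v) == 0)) {
    stopf("all-zero sample(s): %s",
          paste(rownames(v)[rowSums(v) == 0], collapse = ", "))
  }
  n <- nrow(v); D <- ncol(v)
  shape <- v + prior
  inst <- with_seed(seed, {
    a <- array(stats::rgamma(n * D * B, shape = as.vector(shape)),
               dim = c(n, D, B))
    sweep(a, c(1L, 3L), apply(a, c(1L, 3L), sum), "/")
  })
  dimnames(inst) <- list(rownames(v), colnames(v), NULL)
  structure(list(instances = inst, prior = prior, seed = seed),
            class = "dirichlet_ensemble")
}

#' @export
print.dirichlet_ensemble <- function(x, ...) {
  d <- dim(x$instances)
  cat(sprintf("dirichlet_ensemble: %d instances of %d samples x %d features (prior %g)\n",
              d[3L], d[1L], d[2L], x$prior))
  invisible(x)
}

# one instance as a positive count_table-like matrix
ensemble_instance <- function(e, b) {
  e$instances[, , b, drop = TRUE]
}

#' Expected value of a statistic over a Dirichlet ensemble
#'
#' Applies `stat` to each proportion instance (an N x D positive matrix)
#' and returns the element-wise mean — the "expected statistic" that
#' replaces a zero-fragile point estimate.
#'
#' @param e a [draw_ensemble] result.
#' @param stat function of one instance matrix returning a numeric array of
#'   fixed shape.
#' @return element-wise mean of `stat` across instances.
#' @export
expected_over_ensemble <- function(e, stat) {
  stopifnot(inherits(e, "dirichlet_ensemble"))
  B <- dim(e$instances)[3L]
  acc <- NULL
  for (b in seq_len(B)) {
    s <- stat(ensemble_instance(e, b))
    if (any(!is.finite(s) & !is.na(s))) {
      stopf("statistic returned non-finite values on instance %d", b)
    }
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / B
}
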