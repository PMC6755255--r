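#' Geometric mean
#'
#' Computed in log space (`exp(mean(log(v)))`) for overflow safety.
#'
#' @param v strictly positive numeric vector.
#' @return the geometric mean.
#' @export
geometric_mean <- function(v) {
  if (length(v) < 1L || any(!is.finite(v)) || any(v <= 0)) {
    stopf("geometric mean needs a finite, strictly positive vector")
  }
  exp(mean(log(v)))
}

#' Reference specification for log-ratio transformations
#'
#' Each log-ratio transformation divides every component by a per-sample
#' reference \eqn{g(x_j)}: the geometric mean of all components (clr), a
#' single named component (alr), the geometric mean of several named
#' components (malr / user set), the components with interquartile clr
#' variance (iqlr), or the geometric mean of the non-zero components only
#' (rclr).
#'
#' @param kind one of `"clr"`, `"alr"`, `"malr"`, `"iqlr"`, `"rclr"`,
#'   `"user_set"`.
#' @param features character vector of feature ids; required for
#'   `"alr"` (exactly one), `"malr"`/`"user_set"` (one or more).
#' @return an object of class `ref_spec`.
#' @export
ref_spec <- function(kind = c("clr", "alr", "malr", "iqlr", "rclr",
                              "user_set"),
                     features = NULL) {
  kind <- match.arg(kind)
  if (kind == "alr") {
    if (length(features) != 1L) stopf("alr needs exactly one reference feature")
  } else if (kind %in% c("malr", "user_set")) {
    if (length(features) < 1L) stopf("%s needs >= 1 reference feature", kind)
  } else if (!is.null(features)) {
    stopf("'%s' reference does not take explicit features", kind)
  }
  structure(list(kind = kind, features = features), class = "ref_spec")
}

#' @export
print.ref_spec <- function(x, ...) {
  cat("log-ratio reference:", describe_ref(x), "\n")
  invisible(x)
}

describe_ref <- function(ref) {
  switch(ref$kind,
    clr = "geometric mean of all features (clr)",
    alr = sprintf("feature '%s' (alr)", ref$features),
    malr = sprintf("geometric mean of {%s} (malr)",
                   paste(ref$features, collapse = ", ")),
    user_set = sprintf("geometric mean of {%s}",
                       paste(ref$features, collapse = ", ")),
    iqlr = "features with interquartile clr variance (iqlr)",
    rclr = "geometric mean of non-zero features (rclr)"
  )
}

# log of the per-sample reference, given the positive value matrix (N x D)
# and a resolved feature set (NULL = all features).
log_ref <- function(logm, features_idx = NULL) {
  if (is.null(features_idx)) {
    rowMeans(logm)
  } else {
    rowMeans(logm[, features_idx, drop = FALSE])
  }
}

#' Resolve the iqlr reference set
#'
#' Features whose clr variance lies within the interquartile range
#' `[Q1, Q3]` of the clr-variance distribution (linear-interpolation
#' quantiles, inclusive bounds). This "robust average" reference discounts
#' both the most variable and the most stable features.
#'
#' @param t positive [count_table] (run zero handling first).
#' @return a `ref_spec` of kind `"user_set"` listing the selected features.
#' @export
iqlr_reference <- function(t) {
  v <- t$values
  if (ncol(v) < 4L) stopf("iqlr needs >= 4 features")
  if (any(v <= 0)) stopf("zeros present: run the zeros module first")
  logm <- log(v)
  clrm <- logm - rowMeans(logm)
  vars <- apply(clrm, 2L, stats::var)
  q <- stats::quantile(vars, c(0.25, 0.75), type = 7, names = FALSE)
  keep <- which(vars >= q[1L] & vars <= q[2L])
  ref_spec("user_set", features = colnames(v)[keep])
}

#' Log-ratio transform a count table
#'
#' Implements the transformation-dependent half of the workflow: each
#' sample's components are divided by the reference and logged, yielding
#' values interpretable as within-sample log-fold differences *relative to
#' the chosen reference*. Transformations are not normalizations: the
#' result never claims to be absolute abundance, and the reference is
#' recorded on the output.
#'
#' @param t positive [count_table] (rclr tolerates zeros).
#' @param ref a [ref_spec] (default clr).
#' @param base log base, `exp(1)` or `2`.
#' @return an `lr_table`: list with `values` (N x D matrix; `NA` at the
#'   original zero cells for rclr), `ref` (resolved reference), `base`.
#' @export
lr_transform <- function(t, ref = ref_spec("clr"), base = exp(1)) {
  stopifnot(inherits(t, "count_table"), inherits(ref, "ref_spec"))
  if (!base %in% c(exp(1), 2)) stopf("log base must be e or 2")
  v <- t$values
  if (ref$kind == "iqlr") {
    ref <- iqlr_reference(t)
    ref$kind <- "iqlr"  # keep the reported kind, features now resolved
  }
  if (!is.null(ref$features)) {
    missing_ref <- setdiff(ref$features, colnames(v))
    if (length(missing_ref) > 0L) {
      stopf("reference feature(s) not in table: %s",
            paste(missing_ref, collapse = ", "))
    }
    if (any(v[, ref$features] <= 0)) {
      stopf("reference features contain zeros: run the zeros module first")
    }
  }
  if (ref$kind == "rclr") {
    vals <- v
    vals[vals == 0] <- NA_real_
    logm <- log(vals)
    gm <- rowMeans(logm, na.rm = TRUE)
    out <- logm - gm
  } else {
    if (any(v <= 0)) {
      stopf("zeros present: run the zeros module (or use the rclr reference)")
    }
    logm <- log(v)
    fidx <- if (is.null(ref$features)) NULL else {
      match(ref$features, colnames(v))
    }
    out <- logm - log_ref(logm, fidx)
  }
  if (base == 2) out <- out / log(2)
  structure(list(values = out, ref = ref, base = base), class = "lr_table")
}

#' @export
print.lr_table <- function(x, ...) {
  cat(sprintf("lr_table: %d samples x %d columns, base %s, relative to %s\n",
              nrow(x$values), ncol(x$values),
              if (x$base == 2) "2" else "e", describe_ref(x$ref)))
  invisible(x)
}

#' Sequential binary partition for ilr balances
#'
#' An ordered list of binary splits of the feature set: the first split
#' partitions all features into a numerator and denominator side; each
#' later split partitions one previously created block, for `D - 1` splits
#' over `D` features.
#'
#' @param splits list of `D - 1` lists, each with character elements `num`
#'   and `den`.
#' @param feature_set character vector of all feature ids to validate
#'   coverage against.
#' @return validated partition, class `balance_partition`.
#' @export
balance_partition <- function(splits, feature_set) {
  D <- length(feature_set)
  if (length(splits) != D - 1L) {
    stopf("a sequential binary partition of %d features needs %d splits (got %d)",
          D, D - 1L, length(splits))
  }
  blocks <- list(sort(feature_set))
  for (k in seq_along(splits)) {
    s <- splits[[k]]
    both <- sort(c(s$num, s$den))
    if (length(intersect(s$num, s$den)) > 0L) {
      stopf("split %d: numerator and denominator overlap", k)
    }
    hit <- which(vapply(blocks, function(b) identical(b, both), logical(1L)))
    if (length(hit) != 1L) {
      stopf("split %d does not bisect an existing block; the partition must span all features as a binary hierarchy", k)
    }
    blocks <- c(blocks[-hit], list(sort(s$num)), list(sort(s$den)))
  }
  structure(list(splits = splits, feature_set = feature_set),
            class = "balance_partition")
}

#' A default "caterpillar" sequential binary partition
#'
#' Splits feature 1 against the rest, then feature 2 against the remainder,
#' and so on. Any valid partition yields an orthonormal basis; this one is
#' a convenient default when no domain tree is available.
#'
#' @param feature_ids character vector.
#' @return a [balance_partition].
#' @export
default_partition <- function(feature_ids) {
  D <- length(feature_ids)
  splits <- lapply(seq_len(D - 1L), function(k) {
    list(num = feature_ids[k], den = feature_ids[(k + 1L):D])
  })
  balance_partition(splits, feature_ids)
}

#' Isometric log-ratio (balance) transform
#'
#' Each balance contrasts the geometric means of the two sides of a split:
#' \deqn{b_k = \sqrt{rs/(r+s)} \, \ln( g(\mathrm{num}) / g(\mathrm{den}) )}
#' with `r`, `s` the side sizes. The `D - 1` balances are an isometry:
#' Euclidean distance between balance rows equals the Aitchison distance
#' between samples.
#'
#' @param t positive [count_table].
#' @param p a [balance_partition] covering exactly the table's features.
#' @return an `lr_table` with `D - 1` balance columns.
#' @export
ilr_balances <- function(t, p) {
  stopifnot(inherits(t, "count_table"), inherits(p, "balance_partition"))
  if (!setequal(p$feature_set, feature_ids(t))) {
    stopf("partition features do not span the table's features")
  }
  v <- t$values
  if (any(v <= 0)) stopf("zeros present: run the zeros module first")
  logm <- log(v)
  out <- vapply(p$splits, function(s) {
    num <- match(s$num, colnames(v))
    den <- match(s$den, colnames(v))
    r <- length(num); sz <- length(den)
    sqrt(r * sz / (r + sz)) *
      (rowMeans(logm[, num, drop = FALSE]) -
         rowMeans(logm[, den, drop = FALSE]))
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v),
                                paste0("balance_", seq_along(p$splits))))
  structure(list(values = out, ref = p, base = exp(1)), class = "lr_table")
}

#' Aitchison distance between samples
#'
#' Euclidean distance between clr-transformed samples. Scale invariant and
#' sub-compositionally dominant: dropping features can only shrink
#' distances, never inflate them.
#'
#' @param t positive [count_table].
#' @return a symmetric `dist`-convertible matrix, zero diagonal.
#' @export
aitchison_distance <- function(t) {
  stopifnot(inherits(t, "count_table"))
  if (any(t$values <= 0)) stopf("zeros present: run the zeros module first")
  clrm <- lr_transform(t, ref_spec("clr"))$values
  as.matrix(stats::dist(clrm))
}
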