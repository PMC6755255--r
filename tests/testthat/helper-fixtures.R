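# Shared fixtures, built in code at test time.

# small positive table with readable ids
toy_table <- function(values, unit = "raw_count") {
  m <- as.matrix(values)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- letters[seq_len(ncol(m))]
  count_table(m, unit = unit)
}

# seeded random positive table (log-normal entries)
random_table <- function(n, D, seed, meanlog = 3, sdlog = 1) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n * D, meanlog, sdlog)), n, D)
    rownames(m) <- paste0("s", seq_len(n))
    colnames(m) <- sprintf("f%02d", seq_len(D))
    count_table(m, unit = "pseudo_count")
  })
}

two_group_annotation <- function(t, n1 = NULL) {
  n <- nrow(t$values)
  n1 <- n1 %||% (n %/% 2)
  sample_annotation(data.frame(
    sample_id = sample_ids(t),
    group = rep(c("A", "B"), c(n1, n - n1)),
    stringsAsFactors = FALSE
  ), t = t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical unordered-pair keys for recovery comparisons
pair_key <- function(df) paste(pmin(df$g, df$h), pmax(df$g, df$h))

# brute-force clr oracle: per-sample loop, no shared code with lr_transform
oracle_clr <- function(m) {
  t(apply(m, 1L, function(r) log(r) - mean(log(r))))
}

# brute-force pairwise rho/phi_s oracle from first principles (Eq. of the
# proportionality coefficients), per-pair loops
oracle_rho <- function(m) {
  A <- oracle_clr(m)
  D <- ncol(A)
  out <- matrix(NA_real_, D, D, dimnames = list(colnames(m), colnames(m)))
  for (g in seq_len(D)) {
    for (h in seq_len(D)) {
      v <- var(A[, g] - A[, h])
      out[g, h] <- 1 - v / (var(A[, g]) + var(A[, h]))
    }
  }
  out
}

# brute-force theta oracle: within/total sums of squares of each pairwise
# log-ratio
oracle_theta <- function(m, groups) {
  D <- ncol(m)
  lv <- unique(groups)
  out <- matrix(NA_real_, D, D, dimnames = list(colnames(m), colnames(m)))
  for (g in seq_len(D)) {
    for (h in seq_len(D)) {
      if (g == h) next
      lr <- log(m[, g] / m[, h])
      num <- sum(vapply(lv, function(k) {
        x <- lr[groups == k]
        sum((x - mean(x))^2)
      }, numeric(1L)))
      den <- sum((lr - mean(lr))^2)
      out[g, h] <- num / den
    }
  }
  out
}
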