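# Internal helpers shared across modules.

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' functions never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# upper-triangle pair index table (g < h, lexicographic by column order)
pair_index <- function(ids) {
  D <- length(ids)
  idx <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  # order by row-major (partner, then the other): sort by col then row for
  # deterministic lexicographic pair ids
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  data.frame(
    i = idx[, 1L], j = idx[, 2L],
    g = ids[idx[, 1L]], h = ids[idx[, 2L]],
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
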