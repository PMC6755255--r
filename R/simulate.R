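# Synthetic count data with planted ground truth. The generator builds
# strictly positive absolute abundances first (the quantity no sequencer
# can observe), plants differential-abundance features, proportional
# modules and differential-stoichiometry pairs into them, then applies a
# per-sample capacity multiplier and a multinomial sequencer of finite
# depth — the two closures that make real data relative. Every downstream
# stage can therefore be tested against known truth at desk scale.

#' Simulation configuration
#'
#' @param D number of features.
#' @param group_sizes samples per group (length-2 for the standard
#'   two-condition layout).
#' @param time_points,replicates optional layout metadata; when both are
#'   given each group must have `time_points * replicates` samples and the
#'   annotation gains `time` and `replicate` covariates.
#' @param meanlog,sdlog_feature log-mean of baseline absolute abundance and
#'   the log-sd of the per-feature abundance spread.
#' @param sdlog_noise biological log-sd around each feature's baseline.
#' @param n_da,da_fold number of planted differential-abundance features
#'   and their fold change (applied in group 2).
#' @param prop_modules integer vector of planted proportional-module sizes;
#'   within a module every feature is an exact positive multiple of a
#'   shared per-sample latent factor, so all within-module pairs have
#'   absolute-data VLR of exactly 0.
#' @param module_sdlog log-sd of the shared latent factor across samples.
#' @param n_diff_pairs,diff_ratio_shift planted differential-stoichiometry
#'   pairs: the second member tracks the first with a ratio whose mean is
#'   multiplied by `diff_ratio_shift` in group 2.
#' @param diff_pair_sdlog residual log-sd of the planted pair ratios.
#' @param n_trend_pairs,trend_slope planted time-trend pairs whose
#'   log-ratio drifts linearly with the time covariate (both groups).
#' @param capacity_sdlog log-sd of the per-sample capacity multiplier (the
#'   total-RNA analogue; destroyed by closure and recoverable by no
#'   method).
#' @param depth_mean,depth_size sequencing depth drawn per sample from a
#'   negative binomial with this mean and size (dispersion).
#' @param depth_fixed optional fixed depth overriding the draw (exact
#'   conservation tests).
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(D = 100L,
                       group_sizes = c(10L, 10L),
                       time_points = NULL, replicates = NULL,
                       meanlog = log(50), sdlog_feature = 1.2,
                       sdlog_noise = 0.4,
                       n_da = 0L, da_fold = 4,
                       prop_modules = integer(0), module_sdlog = 1,
                       n_diff_pairs = 0L, diff_ratio_shift = 2,
                       diff_pair_sdlog = 0.2,
                       n_trend_pairs = 0L, trend_slope = 0.25,
                       capacity_sdlog = 0.5,
                       depth_mean = 5e4, depth_size = 20,
                       depth_fixed = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  planted <- cfg$n_da + sum(cfg$prop_modules) + 2L * cfg$n_diff_pairs +
    2L * cfg$n_trend_pairs
  if (planted > D) stopf("planted structure needs %d features but D = %d",
                         planted, D)
  if (cfg$da_fold <= 0) stopf("fold changes must be > 0")
  if (!is.null(time_points)) {
    if (is.null(replicates)) stopf("replicates required with time_points")
    if (any(group_sizes != time_points * replicates)) {
      stopf("each group must have time_points * replicates samples")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate planted absolute abundances
#'
#' @param cfg a [sim_config].
#' @return a `sim_truth` list: `abundance` (strictly positive N x D
#'   matrix), `scale_factor` (per-sample capacity multiplier),
#'   `annotation` ([sample_annotation]), `da_features`, `prop_pairs`,
#'   `prop_modules`, `diff_pairs`, `trend_pairs`.
#' @export
simulate_absolute <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    D <- cfg$D
    n <- sum(cfg$group_sizes)
    grp <- rep(seq_along(cfg$group_sizes), cfg$group_sizes)
    fid <- sprintf("gene_%04d", seq_len(D))
    sid <- sprintf("s%02d", seq_len(n))

    # disjoint planted feature sets: DA first, then differential pairs,
    # then proportional modules (precedence DA > diff pair > module)
    pool <- seq_len(D)
    take <- function(k) {
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    da_idx <- if (cfg$n_da > 0L) take(cfg$n_da) else integer(0)
    diff_idx <- if (cfg$n_diff_pairs > 0L) {
      matrix(take(2L * cfg$n_diff_pairs), ncol = 2L)
    } else matrix(integer(0), ncol = 2L)
    trend_idx <- if (cfg$n_trend_pairs > 0L) {
      matrix(take(2L * cfg$n_trend_pairs), ncol = 2L)
    } else matrix(integer(0), ncol = 2L)
    mod_idx <- lapply(cfg$prop_modules, take)

    base <- stats::rnorm(D, cfg$meanlog, cfg$sdlog_feature)
    X <- exp(matrix(stats::rnorm(n * D, 0, cfg$sdlog_noise), n, D,
                    byrow = FALSE) + rep(base, each = n))

    if (length(da_idx) > 0L) {
      X[grp == 2L, da_idx] <- X[grp == 2L, da_idx] * cfg$da_fold
    }

    time <- if (!is.null(cfg$time_points)) {
      unlist(lapply(cfg$group_sizes, function(g) {
        rep(seq_len(cfg$time_points), each = cfg$replicates)
      }))
    } else rep(NA_integer_, n)

    if (nrow(diff_idx) > 0L) {
      for (k in seq_len(nrow(diff_idx))) {
        g <- diff_idx[k, 1L]; h <- diff_idx[k, 2L]
        shift <- ifelse(grp == 2L, log(cfg$diff_ratio_shift), 0)
        X[, h] <- X[, g] * exp(shift + stats::rnorm(n, 0, cfg$diff_pair_sdlog))
      }
    }
    if (nrow(trend_idx) > 0L) {
      tnum <- if (all(is.na(time))) seq_len(n) else time
      tc <- tnum - mean(tnum)
      for (k in seq_len(nrow(trend_idx))) {
        g <- trend_idx[k, 1L]; h <- trend_idx[k, 2L]
        X[, h] <- X[, g] *
          exp(cfg$trend_slope * tc + stats::rnorm(n, 0, cfg$diff_pair_sdlog))
      }
    }
    for (m in mod_idx) {
      latent <- exp(stats::rnorm(n, 0, cfg$module_sdlog))
      slopes <- exp(stats::rnorm(length(m), cfg$meanlog, 0.5))
      X[, m] <- outer(latent, slopes)
    }

    scale_factor <- exp(stats::rnorm(n, 0, cfg$capacity_sdlog))
    X <- X * scale_factor
    dimnames(X) <- list(sid, fid)

    ann <- data.frame(sample_id = sid,
                      group = paste0("group", grp),
                      stringsAsFactors = FALSE)
    if (!is.null(cfg$time_points)) {
      ann$time <- time
      ann$replicate <- unlist(lapply(cfg$group_sizes, function(g) {
        rep(seq_len(cfg$replicates), times = cfg$time_points)
      }))
    }

    mod_pairs <- do.call(rbind, lapply(mod_idx, function(m) {
      if (length(m) < 2L) return(NULL)
      cmb <- utils::combn(sort(m), 2L)
      data.frame(g = fid[cmb[1L, ]], h = fid[cmb[2L, ]],
                 stringsAsFactors = FALSE)
    }))
    as_pairs <- function(idx) {
      if (nrow(idx) == 0L) {
        return(data.frame(g = character(), h = character(),
                          stringsAsFactors = FALSE))
      }
      lo <- pmin(idx[, 1L], idx[, 2L]); hi <- pmax(idx[, 1L], idx[, 2L])
      data.frame(g = fid[lo], h = fid[hi], stringsAsFactors = FALSE)
    }
    structure(list(
      abundance = X,
      scale_factor = stats::setNames(scale_factor, sid),
      annotation = sample_annotation(ann),
      da_features = fid[da_idx],
      prop_modules = lapply(mod_idx, function(m) fid[m]),
      prop_pairs = mod_pairs %||%
        data.frame(g = character(), h = character(), stringsAsFactors = FALSE),
      diff_pairs = as_pairs(diff_idx),
      trend_pairs = as_pairs(trend_idx),
      config = cfg
    ), class = "sim_truth")
  })
}

#' Sequence planted abundances into counts
#'
#' Each sample's absolute vector is closed to proportions (discarding its
#' scale, as the sequencer does), then a multinomial draw of size equal to
#' that sample's depth produces integer counts. Zeros arise naturally at
#' low depth ("count zeros").
#'
#' @param truth a [simulate_absolute] result.
#' @param seed optional seed for the sequencing step (defaults to the
#'   config seed offset by 1).
#' @return a [count_table] of integer counts.
#' @export
sequence_counts <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  seed <- seed %||% (as.integer(cfg$seed) + 1L)
  if (!is.null(cfg$depth_fixed) && cfg$depth_fixed <= 0) {
    stopf("sequencing depth must be positive")
  }
  X <- truth$abundance
  n <- nrow(X)
  with_seed(seed, {
    depth <- if (!is.null(cfg$depth_fixed)) {
      rep(as.integer(cfg$depth_fixed), n)
    } else {
      stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size)
    }
    if (any(depth <= 0)) {
      depth[depth <= 0] <- 1L  # nbinom can draw 0; resample minimally
    }
    counts <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1L, size = depth[i], prob = X[i, ])[, 1L]
    }, numeric(ncol(X))))
    dimnames(counts) <- dimnames(X)
    count_table(counts, unit = "raw_count")
  })
}

#' LPS-like standard fixture
#'
#' A convenience preset emulating a two-condition time-course layout:
#' 2 groups x 14 samples (7 time points x 2 replicates), 1,000 features,
#' 50 four-fold differential features, 3 proportional modules of 5
#' features, 20 differential-stoichiometry pairs (2-fold ratio shift),
#' 2 time-trend pairs, negative-binomial depth with mean 5e4.
#'
#' @param seed integer seed.
#' @return list with `counts` ([count_table]), `annotation`
#'   ([sample_annotation]), `truth` (`sim_truth`).
#' @export
make_lps_like <- function(seed = 1L) {
  cfg <- sim_config(
    D = 1000L, group_sizes = c(14L, 14L),
    time_points = 7L, replicates = 2L,
    meanlog = log(50), sdlog_feature = 1.2, sdlog_noise = 0.4,
    n_da = 50L, da_fold = 4,
    prop_modules = c(5L, 5L, 5L), module_sdlog = 1,
    n_diff_pairs = 20L, diff_ratio_shift = 2, diff_pair_sdlog = 0.2,
    n_trend_pairs = 2L, trend_slope = 0.25,
    capacity_sdlog = 0.5,
    depth_mean = 5e4, depth_size = 20,
    seed = seed
  )
  truth <- simulate_absolute(cfg)
  counts <- sequence_counts(truth)
  list(counts = counts, annotation = truth$annotation, truth = truth)
}

#' Dominance closure-bias demonstration data
#'
#' Statistically independent log-normal features plus one dominant
#' high-variance feature that occupies a large share of each sample's
#' total. After closure, the independent features share the dominant
#' denominator and acquire strong spurious Pearson correlations, while
#' their clr-based proportionality stays unremarkable.
#'
#' @param D number of independent features (the dominant one is added on
#'   top).
#' @param n samples.
#' @param seed integer seed.
#' @return list with `counts` ([count_table], closed to proportions scaled
#'   to depth), `dominant` (the dominant feature's id), `truth_abundance`
#'   (the independent absolute matrix).
#' @export
make_dominance_demo <- function(D = 30L, n = 50L, seed = 1L) {
  with_seed(seed, {
    fid <- c(sprintf("ind_%03d", seq_len(D)), "dominant")
    sid <- sprintf("s%02d", seq_len(n))
    X <- exp(matrix(stats::rnorm(n * D, log(100), 0.3), n, D))
    dom <- exp(stats::rnorm(n, log(100 * D * 3), 1.5))
    A <- cbind(X, dom)
    dimnames(A) <- list(sid, fid)
    P <- A / rowSums(A)
    counts <- count_table(round(P * 1e6) + 1, unit = "pseudo_count")
    list(counts = counts, dominant = "dominant",
         truth_abundance = A)
  })
}
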