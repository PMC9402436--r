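# Circular binary segmentation of normalized ratio profiles.

#' Segment a ratio profile by circular binary segmentation
#'
#' Recursively finds, within each chromosome, the arc maximising the
#' circular mean-shift t statistic, tests it against a within-chromosome
#' permutation null at level `alpha`, and splits at accepted change points
#' until no further split is significant.  Segments shorter than
#' `min_seg_bins` are then merged into the neighbouring segment with the
#' closer mean.  Deterministic for a fixed `seed`.
#'
#' @param ratio a `ratio_profile` from [gc_correct()] (or any list with
#'   numeric `ratio` and character `chrom` of equal length).
#' @param alpha significance level for accepting a change point.
#' @param n_perm permutations per test.
#' @param min_seg_bins minimum segment length in bins.
#' @param seed integer seed for the permutation streams.
#' @return A `segmented_profile`: list with `segments` (data.frame `chrom`,
#'   `start_bin`, `end_bin` 0-based half-open in bin units, `n_bins`,
#'   `mean_ratio`, `var_within`) and `bin_means` (per-bin segment mean),
#'   plus `cell_id` and `chrom`.
#' @export
segment_profile <- function(ratio, alpha = 0.01, n_perm = 1000L,
                            min_seg_bins = 3L, seed = 1L) {
  x <- ratio$ratio
  chrom <- ratio$chrom
  stopifnot(length(x) == length(chrom))
  if (any(!is.finite(x))) stop_bad_input("ratio contains non-finite values")
  check_fraction(alpha, "alpha")
  chroms <- unique(chrom)
  max_exc <- ceiling(alpha * (n_perm + 1)) - 1L

  seg_rows <- vector("list", length(chroms))
  bin_means <- numeric(length(x))
  for (k in seq_along(chroms)) {
    idx <- which(chrom == chroms[k])
    xc <- x[idx]
    # change points are located on an outlier-smoothed log copy: the log
    # transform stabilises the multiplicative (overdispersed) noise so
    # deletions test at their full contrast, and smoothing keeps focal
    # spikes (1-2 bin amplifications) from dominating both the observed
    # max statistic and its permutation null.  Segment means are still
    # computed from raw ratios.
    xl <- log(pmax(xc, 1e-3))
    xs <- smooth_outliers(xl)
    set.seed(derive_seed(seed, paste0("cbs:", chroms[k])))
    cps <- cbs_changepoints(xs, alpha, n_perm, max_exc)
    # refine on the unsmoothed log ratio: the running median smears step
    # edges by a few bins, which would bias the refined cut
    cps <- refine_changepoints(xl, cps, window = 8L)
    cps <- merge_short_segments(xl, cps, min_seg_bins)
    bounds <- c(0L, cps, length(xc))
    ns <- length(bounds) - 1L
    rows <- data.frame(chrom = chroms[k],
                       start_bin = idx[1] - 1L + bounds[-(ns + 1L)],
                       end_bin = idx[1] - 1L + bounds[-1L],
                       stringsAsFactors = FALSE)
    rows$n_bins <- rows$end_bin - rows$start_bin
    rows$mean_ratio <- vapply(seq_len(ns), function(s)
      mean(xc[(bounds[s] + 1L):bounds[s + 1L]]), 0)
    # within-segment per-bin variance: feeds the noise-corrected quantal fit
    rows$var_within <- vapply(seq_len(ns), function(s) {
      v <- xc[(bounds[s] + 1L):bounds[s + 1L]]
      if (length(v) > 1L) stats::var(v) else 0
    }, 0)
    for (s in seq_len(ns))
      bin_means[idx[(bounds[s] + 1L):bounds[s + 1L]]] <- rows$mean_ratio[s]
    seg_rows[[k]] <- rows
  }
  structure(list(cell_id = ratio$cell_id,
                 segments = do.call(rbind, seg_rows),
                 bin_means = bin_means, chrom = chrom),
            class = "segmented_profile")
}

# winsorise isolated outlier bins toward a running median (radius 2), at
# 4 robust SDs (MAD of successive differences); the smoothed copy is used
# only to locate change points
smooth_outliers <- function(x, k = 5L, nsd = 4) {
  if (length(x) < k + 2L) return(x)
  med <- stats::runmed(x, k, endrule = "median")
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) return(x)
  dev <- x - med
  out <- abs(dev) > nsd * sigma
  x[out] <- med[out] + sign(dev[out]) * nsd * sigma
  x
}

# recursive change-point search on one chromosome; returns sorted 0-based
# internal cut positions (cut c splits bins 1..c | c+1..n)
cbs_changepoints <- function(x, alpha, n_perm, max_exc) {
  n <- length(x)
  if (n < 2L) return(integer())
  res <- cbs_max_stat(x)
  if (res$stat <= 0) return(integer())
  exc <- cbs_perm_exceed(x, res$stat, n_perm, max_exc)
  if (exc > max_exc) return(integer())
  cps <- setdiff(c(res$i, res$j), c(0L, n))
  if (!length(cps)) return(integer())
  bounds <- c(0L, sort(cps), n)
  out <- sort(cps)
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    if (hi - lo >= 2L)
      out <- c(out, lo + cbs_changepoints(x[(lo + 1L):hi], alpha, n_perm,
                                          max_exc))
  }
  sort(unique(out))
}

# local refinement: with its neighbours fixed, each accepted cut is moved
# within +/- window bins to the position minimising the two-segment residual
# sum of squares (recursive splitting can leave cuts a few bins off when the
# flanking segments are later subdivided)
refine_changepoints <- function(x, cps, window = 5L) {
  if (!length(cps)) return(cps)
  for (pass in 1:2) {
    bounds <- c(0L, cps, length(x))
    for (i in seq_along(cps)) {
      lo <- bounds[i]
      hi <- bounds[i + 2L]
      cand <- max(lo + 1L, cps[i] - window):min(hi - 1L, cps[i] + window)
      sse <- vapply(cand, function(c_) {
        a <- x[(lo + 1L):c_]
        b <- x[(c_ + 1L):hi]
        sum((a - mean(a))^2) + sum((b - mean(b))^2)
      }, 0)
      cps[i] <- cand[which.min(sse)]
      bounds[i + 1L] <- cps[i]
    }
    cps <- sort(unique(cps))
  }
  cps
}

# iteratively merge segments shorter than min_len into the neighbour whose
# mean is closer; returns the surviving cut positions
merge_short_segments <- function(x, cps, min_len) {
  repeat {
    bounds <- c(0L, cps, length(x))
    len <- diff(bounds)
    if (length(len) <= 1L || all(len >= min_len)) return(cps)
    s <- which.min(len)  # shortest first (ties: leftmost)
    means <- vapply(seq_along(len), function(k)
      mean(x[(bounds[k] + 1L):bounds[k + 1L]]), 0)
    drop_left <- if (s == 1L) FALSE
      else if (s == length(len)) TRUE
      else abs(means[s - 1L] - means[s]) <= abs(means[s + 1L] - means[s])
    # drop the cut between segment s and its chosen neighbour
    cut <- if (drop_left) bounds[s] else bounds[s + 1L]
    cps <- setdiff(cps, cut)
  }
}
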