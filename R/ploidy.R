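# Quantal ploidy fitting: scale segment ratios so they fall near integers.

#' Default ploidy multiplier grid
#'
#' Multipliers 1.5 to 6.0 in steps of 0.05, spanning near-haploid through
#' hexaploid genomes.
#'
#' @return numeric vector.
#' @export
default_q_grid <- function() seq(1.5, 6.0, by = 0.05)

#' Fit absolute integer copy number by least-squares quantal scaling
#'
#' Selects the multiplier `q` on a grid minimising the sum over bins of
#' `(q * r - round(q * r))^2`, where `r` is the bin's segment-mean ratio:
#' the scale at which scaled segment means sit closest to integers.  Because
#' the residual is summed over bins, segments are implicitly weighted by
#' their length.  Ties are broken toward the smaller `q` (the conservative,
#' lower-ploidy reading).
#'
#' Scale selection factors in the integer-assignment distribution of the
#' segments: candidate scales are compared by the Gaussian (weighted
#' least-squares) misfit of the segment means to the quantal lattice
#' `c / q`, each segment weighted by its sampling precision
#' (`n_bins / var_within`, variances shrunk toward the pooled coefficient
#' of variation).  At the correct scale this statistic is approximately
#' chi-square with one df per segment; the smallest `q` within 1.5 times
#' the minimum plus one standard error is selected, a band wide enough to
#' absorb the bounded overfitting gain of denser harmonic lattices.  An
#' even-ploidy genome with no odd states fits the 2n and 4n lattices
#' identically, so the rule resolves the quantal degeneracy to the lower
#' scale, while a single sizeable odd-state segment rejects the halved
#' scale decisively.
#' `fit_error` reports the residual sum `sum((q r - round(q r))^2)` over
#' bins at the selected `q`.
#'
#' @param seg a `segmented_profile` from [segment_profile()].
#' @param q_grid finite increasing multiplier grid.
#' @param noise_correct logical; use the precision-weighted scale
#'   selection with the one-standard-error rule (default TRUE).  With
#'   FALSE the selection is the raw per-bin objective with smaller-q
#'   tie-breaking.
#' @param polyploid_threshold fitted mean ploidy at or above which a cell is
#'   labelled `"polyploid"` (default 3.0, separating 2n from 4n with margin).
#' @return An `integer_cn_profile`: list with `states` (per-bin integer copy
#'   number), `multiplier`, `ploidy` (mean state), `ploidy_label`,
#'   `fit_error`, `segments` (with fitted `state` column), `breakpoints`
#'   (within-chromosome state-change boundaries), `cell_id`, `chrom`.
#' @examples
#' r <- list(cell_id = "c", ratio = rep(c(2, 3, 4) / 3, each = 50),
#'           chrom = rep("chr1", 150))
#' s <- segment_profile(r, seed = 7)
#' fit_ploidy(s)$multiplier  # 3.0: states 2, 3, 4
#' @export
fit_ploidy <- function(seg, q_grid = default_q_grid(),
                       polyploid_threshold = 3.0, noise_correct = TRUE) {
  if (length(q_grid) == 0L) stop_bad_input("q_grid must be non-empty")
  if (is.unsorted(q_grid, strictly = TRUE))
    stop_bad_input("q_grid must be strictly increasing")
  sg <- seg$segments
  rbar <- sg$mean_ratio
  nb <- sg$n_bins
  vw <- if (!is.null(sg$var_within)) sg$var_within else rep(0, nrow(sg))
  errs <- vapply(q_grid, function(q)
    sum(nb * (q * rbar - round(q * rbar))^2), 0)
  if (noise_correct) {
    # Gaussian scale selection: weighted least squares of segment means
    # against the quantal lattice c/q, each segment weighted by
    # n_bins / var_within (its sampling precision).  Per-segment variances
    # are shrunk toward the pooled coefficient of variation (prior df 10)
    # so short segments do not enter with unstable weights.  At the true
    # scale the statistic is a chi-square with one df per segment, so the
    # smallest q within one standard error, sqrt(2 * n_segments), of the
    # minimum is selected: exact-lattice ties (2n vs 4n with no odd
    # states) resolve to the lower scale, while genuine odd-state
    # segments reject the halved scale overwhelmingly.
    pooled_cv2 <- {
      dfree <- pmax(nb - 1, 0)
      if (sum(dfree) > 0) sum(dfree * vw / pmax(rbar, 1e-6)^2) / sum(dfree)
      else 0
    }
    prior_df <- 10
    vshrunk <- (pmax(nb - 1, 0) * vw +
                  prior_df * pooled_cv2 * pmax(rbar, 1e-6)^2) /
      (pmax(nb - 1, 0) + prior_df)
    w <- nb / pmax(vshrunk, 1e-8)
    wls <- vapply(q_grid, function(q)
      sum(w * (rbar - round(q * rbar) / q)^2), 0)
    # harmonic lattices (integer multiples of the true scale) always fit
    # the data too, improving only by overfitting off-lattice noise with a
    # denser lattice -- a bounded relative gain; a genuinely wrong scale
    # misfits whole segments and exceeds any such band.  Take the smallest
    # scale within 1.5x of the minimum plus one chi-square standard error.
    se <- sqrt(2 * length(nb))
    q_i <- which(wls <= 1.5 * min(wls) + se + 1e-9)[1]
  } else {
    best <- min(errs)
    q_i <- which(errs <= best + 1e-9)[1]  # ties toward smaller q
  }
  q <- q_grid[q_i]
  r <- seg$bin_means
  states <- as.integer(round(q * r))
  segments <- seg$segments
  segments$state <- as.integer(round(q * segments$mean_ratio))
  ci <- match(seg$chrom, unique(seg$chrom))
  structure(list(cell_id = seg$cell_id, states = states, multiplier = q,
                 ploidy = mean(states),
                 ploidy_label = if (mean(states) >= polyploid_threshold)
                   "polyploid" else "diploid",
                 fit_error = errs[q_i],
                 segments = segments,
                 breakpoints = profile_breakpoints(states, ci),
                 chrom = seg$chrom),
            class = "integer_cn_profile")
}

#' @export
print.integer_cn_profile <- function(x, ...) {
  cat(sprintf(
    "integer_cn_profile '%s': q = %.2f, ploidy = %.2f (%s), %d segments\n",
    x$cell_id, x$multiplier, x$ploidy, x$ploidy_label, nrow(x$segments)))
  invisible(x)
}

#' Call integer copy-number profiles for a whole count matrix
#'
#' Per cell: QC filter, GC correction, circular binary segmentation, quantal
#' ploidy fit.  Cells failing QC or erroring at any stage are returned as
#' flagged records; the batch never aborts.
#'
#' @param counts bins x cells numeric matrix with cell ids as column names
#'   (or a `sim_counts` object).
#' @param scaffold the `bin_scaffold`.
#' @param min_reads inclusive QC threshold on total reads.
#' @param lowess_fraction LOWESS span for [gc_correct()].
#' @param alpha,n_perm,min_seg_bins [segment_profile()] parameters.
#' @param q_grid,polyploid_threshold,noise_correct [fit_ploidy()]
#'   parameters.
#' @param seed root seed; per-cell segmentation streams derive from it.
#' @return A `cn_call_set`: list with `profiles` (named list of
#'   `integer_cn_profile` for successful cells) and `report` (one row per
#'   input cell: total_reads, qc_pass, multiplier, ploidy, ploidy_label,
#'   n_segments, fit_error, status).
#' @export
call_cells <- function(counts, scaffold, min_reads = 250000,
                       lowess_fraction = 0.3, alpha = 0.01, n_perm = 1000L,
                       min_seg_bins = 3L, q_grid = default_q_grid(),
                       polyploid_threshold = 3.0, noise_correct = TRUE,
                       seed = 1L) {
  if (inherits(counts, "sim_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  cells <- colnames(counts)
  if (is.null(cells)) cells <- sprintf("cell_%03d", seq_len(ncol(counts)))
  if (ncol(counts) == 0L) {
    return(structure(list(profiles = list(),
                          report = data.frame(cell_id = character(),
                                              total_reads = numeric(),
                                              qc_pass = logical(),
                                              multiplier = numeric(),
                                              ploidy = numeric(),
                                              ploidy_label = character(),
                                              n_segments = integer(),
                                              fit_error = numeric(),
                                              status = character())),
                     class = "cn_call_set"))
  }
  if (nrow(counts) != nrow(scaffold))
    stop_bad_input("count matrix rows must match the scaffold bins")

  profs <- lapply(seq_along(cells), function(j)
    cell_profile(cells[j], counts[, j]))
  qc <- qc_filter(profs, min_reads)

  out <- list()
  rows <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    p <- profs[[j]]
    pass <- qc$log$qc_pass[j]
    row <- data.frame(cell_id = p$cell_id, total_reads = p$total_reads,
                      qc_pass = pass, multiplier = NA_real_,
                      ploidy = NA_real_, ploidy_label = NA_character_,
                      n_segments = NA_integer_, fit_error = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (!pass) {
      row$status <- "excluded_qc"
    } else {
      fit <- tryCatch({
        rp <- gc_correct(p, scaffold, lowess_fraction)
        sp <- segment_profile(rp, alpha = alpha, n_perm = n_perm,
                              min_seg_bins = min_seg_bins,
                              seed = derive_seed(seed, p$cell_id))
        fit_ploidy(sp, q_grid, polyploid_threshold, noise_correct)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        row$status <- paste0("error: ", conditionMessage(fit))
      } else {
        out[[p$cell_id]] <- fit
        row$multiplier <- fit$multiplier
        row$ploidy <- fit$ploidy
        row$ploidy_label <- fit$ploidy_label
        row$n_segments <- nrow(fit$segments)
        row$fit_error <- fit$fit_error
      }
    }
    rows[[j]] <- row
  }
  structure(list(profiles = out, report = do.call(rbind, rows)),
            class = "cn_call_set")
}

#' @export
print.cn_call_set <- function(x, ...) {
  cat(sprintf("cn_call_set: %d/%d cells profiled (%d excluded at QC)\n",
              length(x$profiles), nrow(x$report),
              sum(!x$report$qc_pass)))
  invisible(x)
}

#' Integer copy-number matrix from a call set
#'
#' @param calls a `cn_call_set`.
#' @return bins x cells integer matrix of absolute copy states.
#' @export
cn_matrix <- function(calls) {
  stopifnot(inherits(calls, "cn_call_set"))
  if (!length(calls$profiles)) return(matrix(integer(), nrow = 0, ncol = 0))
  do.call(cbind, lapply(calls$profiles, function(p) p$states))
}
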