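# Per-cell copy-number profiling: QC, GC correction, normalization.

#' Construct a per-cell bin-count profile
#'
#' @param cell_id character scalar.
#' @param counts non-negative integer vector, one entry per scaffold bin.
#' @return A `cell_count_profile` (cell_id, counts, total_reads, qc_pass).
#' @export
cell_profile <- function(cell_id, counts) {
  if (any(is.na(counts)) || any(counts < 0))
    stop_bad_input("counts must be non-negative and complete")
  structure(list(cell_id = as.character(cell_id),
                 counts = as.numeric(counts),
                 total_reads = sum(counts), qc_pass = NA),
            class = "cell_count_profile")
}

#' Read-depth quality filter
#'
#' Cells sequenced below `min_reads` total reads are excluded from all
#' downstream analyses; the boundary is inclusive (a cell at exactly
#' `min_reads` passes).  The default of 250,000 reads is the conventional
#' floor for usable sparse-WGS copy-number profiles at ~600-kb bins.
#'
#' @param profiles list of `cell_count_profile`s.
#' @param min_reads inclusive threshold on total reads.
#' @return list with `kept` and `excluded` (both lists of profiles, with
#'   `qc_pass` filled in) and `log`, a data.frame recording every exclusion
#'   with its reason.
#' @export
qc_filter <- function(profiles, min_reads = 250000) {
  check_positive(min_reads, "min_reads", strict = FALSE)
  totals <- vapply(profiles, function(p) p$total_reads, 0)
  pass <- totals >= min_reads
  profiles <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]; p$qc_pass <- pass[i]; p
  })
  log <- data.frame(
    cell_id = vapply(profiles, function(p) p$cell_id, ""),
    total_reads = totals, qc_pass = pass,
    reason = ifelse(pass, "",
                    sprintf("total_reads %d < min_reads %d",
                            as.integer(totals), as.integer(min_reads))),
    stringsAsFactors = FALSE)
  list(kept = profiles[pass], excluded = profiles[!pass], log = log)
}

#' GC-bias correction and normalization
#'
#' Fits a LOWESS curve of bin count against bin GC fraction, divides each
#' count by the fitted value (floored at a small positive epsilon), and
#' rescales the corrected profile to mean exactly 1.  The result is a
#' dimensionless ratio profile: flat at 1 for an unrearranged genome,
#' proportional to copy number otherwise.
#'
#' @param profile a `cell_count_profile`.
#' @param scaffold the `bin_scaffold` the counts were taken on.
#' @param lowess_fraction LOWESS smoother span (default 0.3).
#' @return A `ratio_profile`: list with `cell_id`, `ratio` (mean 1),
#'   `lowess_fraction`, and the per-bin `chrom` vector.
#' @export
gc_correct <- function(profile, scaffold, lowess_fraction = 0.3) {
  counts <- profile$counts
  if (length(counts) != nrow(scaffold))
    stop_bad_input("counts length must match the scaffold")
  if (all(counts == 0))
    stop_bad_input(sprintf("degenerate profile '%s': all counts are zero",
                           profile$cell_id))
  fit_curve <- function(idx) {
    lw <- lowess(scaffold$gc[idx], counts[idx], f = lowess_fraction)
    pmax(approx(lw$x, lw$y, xout = scaffold$gc, rule = 2, ties = mean)$y,
         1e-6 * mean(counts))
  }
  # two-pass fit: copy-number structure confounds a single fit wherever an
  # altered region occupies its own GC stratum, so the curve is re-fitted
  # on bins near the modal level of the first-pass ratio
  fitted <- fit_curve(seq_along(counts))
  r0 <- counts / fitted
  mode0 <- median(r0)
  neutral <- which(r0 > 0.8 * mode0 & r0 < 1.2 * mode0)
  if (length(neutral) >= 0.2 * length(counts)) fitted <- fit_curve(neutral)
  ratio <- counts / fitted
  ratio <- ratio / mean(ratio)
  structure(list(cell_id = profile$cell_id, ratio = ratio,
                 lowess_fraction = lowess_fraction,
                 chrom = scaffold$chrom),
            class = "ratio_profile")
}
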