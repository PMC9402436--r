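# Bin scaffold: the fixed genomic coordinate frame shared by every profile.

#' Build a genomic bin scaffold
#'
#' Partitions a genome into a fixed number of bins: bins are apportioned to
#' chromosomes proportionally to chromosome length (largest-remainder method,
#' so the total is exact) and are equal length within a chromosome (to within
#' one base).  Coordinates are 0-based half-open throughout the package.
#'
#' The per-bin GC fraction comes either from a user-supplied vector/table or,
#' when `gc_source = "synthetic"`, from a smooth deterministic curve over the
#' genome (isochore-like undulation around 0.42) so that simulated data carry
#' a realistic, correctable GC bias.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bases
#'   (names are chromosome ids, order is preserved), or a data.frame with
#'   columns `chrom` and `length`.
#' @param n_bins total number of bins over the genome.
#' @param gc_source `"synthetic"`, or a numeric vector of per-bin GC
#'   fractions of length `n_bins`.
#' @return A `bin_scaffold`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, one row per bin, ordered by (chromosome, start).
#' @examples
#' sc <- build_scaffold(c(chrA = 1000, chrB = 1000), n_bins = 10)
#' table(sc$chrom)
#' @export
build_scaffold <- function(chrom_lengths, n_bins, gc_source = "synthetic") {
  if (is.data.frame(chrom_lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
    chrom_lengths <- setNames(as.numeric(chrom_lengths$length),
                              as.character(chrom_lengths$chrom))
  }
  check_positive(chrom_lengths, "chrom_lengths")
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop_bad_input("'chrom_lengths' must have unique chromosome names")
  n_chrom <- length(chrom_lengths)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < n_chrom)
    stop_bad_input("'n_bins' must be at least the number of chromosomes")
  n_bins <- as.integer(n_bins)

  # largest-remainder apportionment, every chromosome gets >= 1 bin
  quota <- n_bins * chrom_lengths / sum(chrom_lengths)
  base <- pmax(1L, as.integer(floor(quota)))
  rem <- n_bins - sum(base)
  if (rem > 0) {
    frac <- quota - floor(quota)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  } else if (rem < 0) {
    # floors + minimum-1 overran the total: shave from the largest quotas
    take <- order(base, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      j <- take[i]
      if (base[j] > 1L) { base[j] <- base[j] - 1L; rem <- rem + 1L }
      i <- if (i == n_chrom) 1L else i + 1L
    }
  }

  rows <- vector("list", n_chrom)
  for (k in seq_len(n_chrom)) {
    nb <- base[k]
    len <- chrom_lengths[k]
    # equal-length bins +/- 1 base: cut at rounded multiples of len/nb
    edges <- round(len * (0:nb) / nb)
    rows[[k]] <- data.frame(chrom = names(chrom_lengths)[k],
                            start = edges[-(nb + 1L)], end = edges[-1L],
                            stringsAsFactors = FALSE)
  }
  sc <- do.call(rbind, rows)
  rownames(sc) <- NULL

  if (identical(gc_source, "synthetic")) {
    sc$gc <- synthetic_gc(nrow(sc))
  } else {
    gc <- as.numeric(gc_source)
    if (length(gc) != nrow(sc))
      stop_bad_input("'gc_source' must supply one GC fraction per bin")
    if (any(gc < 0 | gc > 1)) stop_bad_input("GC fractions must lie in [0, 1]")
    sc$gc <- gc
  }
  class(sc) <- c("bin_scaffold", "data.frame")
  sc
}

# deterministic smooth GC curve: mean 0.42, two incommensurate harmonics
# so adjacent bins are correlated (isochore-like) but the range is broad
synthetic_gc <- function(n_bins) {
  i <- seq_len(n_bins)
  gc <- 0.42 + 0.05 * sin(2 * pi * i / 97) + 0.04 * sin(2 * pi * i / 331)
  pmin(pmax(gc, 0.2), 0.8)
}

#' Mouse and human scaffold presets
#'
#' `scaffold_preset("mouse")` partitions the packaged mm9 chromosome lengths
#' into 5,000 bins (~600 kb); `scaffold_preset("human")` partitions hg19 into
#' 20,000 bins.
#'
#' @param preset `"mouse"` or `"human"`.
#' @param gc_source forwarded to [build_scaffold()].
#' @return A `bin_scaffold`.
#' @export
scaffold_preset <- function(preset = c("mouse", "human"),
                            gc_source = "synthetic") {
  preset <- match.arg(preset)
  file <- system.file("extdata",
                      if (preset == "mouse") "mm9_chrom_sizes.tsv"
                      else "hg19_chrom_sizes.tsv",
                      package = "cnaphase", mustWork = TRUE)
  build_scaffold(read_chrom_sizes(file),
                 n_bins = if (preset == "mouse") 5000L else 20000L,
                 gc_source = gc_source)
}

#' @export
print.bin_scaffold <- function(x, ...) {
  cat(sprintf("bin_scaffold: %d bins over %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  cat(sprintf("  bin length: %.0f-%.0f bases; GC %.2f-%.2f\n",
              min(x$end - x$start), max(x$end - x$start),
              min(x$gc), max(x$gc)))
  invisible(x)
}

# integer chromosome index per bin, and the boundary structure used by
# breakpoint analyses: boundary b separates bin b and b+1 (1-based bins)
scaffold_chrom_index <- function(scaffold) {
  match(scaffold$chrom, unique(scaffold$chrom))
}

# eligible (non chromosome-terminal) boundary indices: b in 1..(n-1) with
# bin b and b+1 on the same chromosome
eligible_boundaries <- function(scaffold) {
  ci <- scaffold_chrom_index(scaffold)
  n <- nrow(scaffold)
  which(ci[-n] == ci[-1])
}
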