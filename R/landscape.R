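# Population-level CNA statistics: event classification, recurrent cores,
# frequency tracks, homogeneity, and event-class enrichment tests.

#' Classify CNA events of one cell against its ploidy reference
#'
#' Maximal runs of bins at a constant state different from the reference
#' (2 for diploid cells, 4 for polyploid cells) become events.  States below
#' the reference are deletions; states above are gains, except focal
#' high-level events -- state at least twice the reference spanning at most
#' `amp_max_bins` bins -- which are amplifications.
#'
#' @param profile an `integer_cn_profile`.
#' @param ploidy_label `"diploid"` or `"polyploid"`; defaults to the
#'   profile's own label.
#' @param amp_max_bins focality bound of the amplification rule (default 10).
#' @return data.frame of `cna_event`s: cell_id, chrom, start_bin, end_bin
#'   (0-based half-open, bin units), state, class, reference.
#' @export
classify_events <- function(profile, ploidy_label = NULL,
                            amp_max_bins = 10L) {
  ploidy_label <- ploidy_label %||% profile$ploidy_label
  if (!ploidy_label %in% c("diploid", "polyploid"))
    stop_bad_input("ploidy_label must be 'diploid' or 'polyploid'")
  rho <- if (ploidy_label == "diploid") 2L else 4L
  runs <- constant_runs(profile$states, profile$chrom)
  runs <- runs[runs$value != rho, , drop = FALSE]
  if (!nrow(runs))
    return(data.frame(cell_id = character(), chrom = character(),
                      start_bin = integer(), end_bin = integer(),
                      state = integer(), class = character(),
                      reference = integer(), stringsAsFactors = FALSE))
  span <- runs$end_bin - runs$start_bin
  class <- ifelse(runs$value < rho, "deletion",
                  ifelse(runs$value >= 2L * rho & span <= amp_max_bins,
                         "amplification", "gain"))
  data.frame(cell_id = profile$cell_id, chrom = runs$chrom,
             start_bin = runs$start_bin, end_bin = runs$end_bin,
             state = as.integer(runs$value), class = class,
             reference = rho, stringsAsFactors = FALSE)
}

#' Event tables for a whole call set
#'
#' @param calls a `cn_call_set`.
#' @param amp_max_bins forwarded to [classify_events()].
#' @return row-bound event data.frame over all profiled cells.
#' @export
classify_events_all <- function(calls, amp_max_bins = 10L) {
  stopifnot(inherits(calls, "cn_call_set"))
  do.call(rbind, c(lapply(calls$profiles, classify_events,
                          amp_max_bins = amp_max_bins),
                   make.row.names = FALSE))
}

# Jaccard overlap of two half-open bin intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  ifelse(uni > 0, inter / uni, 0)
}

# score of a candidate interval: sum over cells of the best Jaccard overlap
# with that cell's same-chromosome events
core_score <- function(cand, events) {
  ev <- events[events$chrom == cand$chrom, , drop = FALSE]
  if (!nrow(ev)) return(0)
  j <- interval_jaccard(cand$start_bin, cand$end_bin, ev$start_bin,
                        ev$end_bin)
  sum(vapply(split(j, ev$cell_id), max, 0))
}

#' Cores of recurrent CNA events
#'
#' Greedy recurrence analysis over one event class: every observed event
#' interval is a candidate core; a candidate's score is the sum over cells
#' of the Jaccard overlap with the cell's best-overlapping event of that
#' class (so a core present in `n` cells with identical boundaries scores
#' `n`).  The top-scoring interval is extracted, the explained overlap is
#' trimmed out of the remaining events, and the procedure repeats.
#' Significance per core is assessed against a null in which event positions
#' are placed uniformly at random within their chromosome, preserving event
#' lengths and per-cell event counts.
#'
#' @param events event data.frame (as from [classify_events_all()]).
#' @param class event class to analyse (`"deletion"`, `"gain"`, or
#'   `"amplification"`; gains and amplifications can be pooled with
#'   `c("gain", "amplification")`).
#' @param chrom_bins named vector of per-chromosome bin counts (for the
#'   permutation null), e.g. a `sim_config()$chrom_lengths` or a table of a
#'   scaffold's chromosomes.
#' @param n_perm permutations for significance (default 500).
#' @param max_cores maximum cores to extract.
#' @param min_score stop when the best remaining score falls below this.
#' @param seed integer seed.
#' @return A `core_result` data.frame: chrom, start_bin, end_bin, class,
#'   score, p_value, ranked by score (non-increasing).
#' @export
core_recurrence <- function(events, class = "deletion", chrom_bins,
                            n_perm = 500L, max_cores = 20L, min_score = 1,
                            seed = 1L) {
  ev <- events[events$class %in% class, , drop = FALSE]
  cores <- greedy_cores(ev, max_cores, min_score)
  if (!nrow(cores)) {
    cores$p_value <- numeric()
    class(cores) <- c("core_result", "data.frame")
    return(cores)
  }
  if (length(unique(events$cell_id)) < 2L)
    stop_bad_input("core_recurrence needs events from at least 2 cells")
  # null distribution of the maximal core score under positional shuffling
  set.seed(derive_seed(seed, "core_null"))
  null_max <- vapply(seq_len(n_perm), function(p) {
    sh <- ev
    for (i in seq_len(nrow(sh))) {
      len <- sh$end_bin[i] - sh$start_bin[i]
      cl <- chrom_bins[[sh$chrom[i]]]
      if (len >= cl) { sh$start_bin[i] <- 0L; sh$end_bin[i] <- cl; next }
      s <- sample.int(cl - len + 1L, 1L) - 1L
      sh$start_bin[i] <- s
      sh$end_bin[i] <- s + len
    }
    top <- greedy_cores(sh, 1L, 0)
    if (nrow(top)) top$score[1] else 0
  }, 0)
  cores$p_value <- vapply(cores$score, function(s)
    (1 + sum(null_max >= s)) / (n_perm + 1), 0)
  cores <- cores[order(-cores$score), , drop = FALSE]
  rownames(cores) <- NULL
  class(cores) <- c("core_result", "data.frame")
  cores
}

# greedy extraction without significance
greedy_cores <- function(ev, max_cores, min_score) {
  out <- data.frame(chrom = character(), start_bin = integer(),
                    end_bin = integer(), class = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  ev <- ev[ev$end_bin > ev$start_bin, , drop = FALSE]
  while (nrow(ev) && nrow(out) < max_cores) {
    cand <- unique(ev[c("chrom", "start_bin", "end_bin")])
    scores <- vapply(seq_len(nrow(cand)), function(i)
      core_score(cand[i, ], ev), 0)
    best <- max(scores)
    if (best < min_score) break
    # ties: earliest genomic position
    ties <- which(scores >= best - 1e-12)
    ties <- ties[order(cand$chrom[ties], cand$start_bin[ties],
                       cand$end_bin[ties])]
    top <- cand[ties[1], ]
    out <- rbind(out, data.frame(top, class = ev$class[1], score = best,
                                 stringsAsFactors = FALSE))
    ev <- peel_interval(ev, top)
  }
  rownames(out) <- NULL
  out
}

# subtract a core interval from all overlapping events (splitting events
# that straddle it); events consumed entirely disappear
peel_interval <- function(ev, core) {
  keep <- list()
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$chrom != core$chrom || e$end_bin <= core$start_bin ||
        e$start_bin >= core$end_bin) {
      keep[[length(keep) + 1L]] <- e
      next
    }
    if (e$start_bin < core$start_bin) {
      left <- e; left$end_bin <- core$start_bin
      keep[[length(keep) + 1L]] <- left
    }
    if (e$end_bin > core$end_bin) {
      right <- e; right$start_bin <- core$end_bin
      keep[[length(keep) + 1L]] <- right
    }
  }
  if (!length(keep)) return(ev[0, , drop = FALSE])
  do.call(rbind, c(keep, make.row.names = FALSE))
}

#' Gain/deletion frequency track from segmented profiles
#'
#' Each sample's per-bin segment values are centred to mean 1; a bin counts
#' as gained when its centred value is at least `1 + theta` and deleted when
#' at most `1 - theta` (boundaries inclusive).  Frequencies are fractions of
#' samples.
#'
#' @param seg_values bins x samples numeric matrix of per-bin segment means
#'   (e.g. `bin_means` of [segment_profile()] outputs, column-bound).
#' @param theta designation threshold (default 0.1).
#' @return A `frequency_track` data.frame: bin (1-based), gain_freq,
#'   del_freq; attribute `theta`.
#' @export
frequency_track <- function(seg_values, theta = 0.1) {
  check_positive(theta, "theta")
  m <- as.matrix(seg_values)
  centred <- sweep(m, 2, colMeans(m), "/")
  gain <- rowMeans(centred >= 1 + theta)
  del <- rowMeans(centred <= 1 - theta)
  structure(data.frame(bin = seq_len(nrow(m)), gain_freq = gain,
                       del_freq = del),
            theta = theta, class = c("frequency_track", "data.frame"))
}

#' Per-bin single-cell homogeneity score
#'
#' The frequency of the modal (major) integer copy-number state at each bin
#' across cells: 1 means the state is fixed in the population, values near
#' `1/n` mean maximal heterogeneity.
#'
#' @param cn_mat bins x cells integer matrix of absolute copy states.
#' @return numeric vector of per-bin homogeneity in `(0, 1]`.
#' @export
bin_homogeneity <- function(cn_mat) {
  cn_mat <- as.matrix(cn_mat)
  if (ncol(cn_mat) < 1L) stop_bad_input("need at least one cell")
  apply(cn_mat, 1, function(s) max(tabulate(s + 1L)) / length(s))
}

#' Bulk segment homogeneity from cell-fraction/purity tables
#'
#' Normalized clonality of each segment is its estimated cell fraction
#' divided by sample purity (`cf / purity`); ~1 means the alteration is
#' present in essentially every tumour cell.  Values are clipped at 1.25 to
#' absorb estimation noise above clonality 1 (raw values are kept in a
#' diagnostic column).  Gain and deletion distributions are compared with a
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param segments data.frame with columns `cf`, `purity`, and either a
#'   `class` column (`"gain"`/`"deletion"`) or a `cn` column compared to
#'   `reference`.
#' @param reference copy-number reference used when `class` is absent
#'   (default 2).
#' @param clip upper clip on cf/purity (default 1.25).
#' @return A `homogeneity_report`: list with `segments` (input plus
#'   `clonality` and `clonality_raw`), `ks_statistic`, `ks_p_value` (NA when
#'   only one class is present), and per-class summaries.
#' @export
segment_homogeneity <- function(segments, reference = 2, clip = 1.25) {
  stopifnot(all(c("cf", "purity") %in% names(segments)))
  if (any(segments$purity <= 0)) stop_bad_input("purity must be positive")
  if (any(segments$cf < 0)) stop_bad_input("cf must be non-negative")
  if (!"class" %in% names(segments)) {
    if (!"cn" %in% names(segments))
      stop_bad_input("segments need a 'class' or 'cn' column")
    segments$class <- ifelse(segments$cn < reference, "deletion",
                             ifelse(segments$cn > reference, "gain",
                                    "neutral"))
  }
  segments$clonality_raw <- segments$cf / segments$purity
  segments$clonality <- pmin(segments$clonality_raw, clip)
  g <- segments$clonality[segments$class %in% c("gain", "amplification")]
  d <- segments$clonality[segments$class == "deletion"]
  if (length(g) && length(d)) {
    ks <- suppressWarnings(ks.test(g, d))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- NA_real_
    ks_p <- NA_real_
  }
  structure(list(segments = segments, ks_statistic = ks_stat,
                 ks_p_value = ks_p,
                 summary = data.frame(
                   class = c("gain", "deletion"),
                   n = c(length(g), length(d)),
                   median_clonality = c(if (length(g)) median(g) else NA_real_,
                                        if (length(d)) median(d) else NA_real_))),
            class = "homogeneity_report")
}

#' Compare per-cell event counts between two groups
#'
#' For each event class, reports group means and medians, a two-sided
#' Welch t-test, and a two-tailed Mann-Whitney U test (exact for small
#' tie-free samples, normal approximation with tie correction otherwise, as
#' implemented by [stats::wilcox.test()]).
#'
#' @param counts data.frame with columns `cell_id`, `class`, `count`.
#' @param groups named vector mapping cell ids to one of two group labels.
#' @return data.frame: class, group means/medians, t, t_p, U, mwu_p.  Tests
#'   are NA when degenerate (both groups constant).
#' @export
compare_event_counts <- function(counts, groups) {
  stopifnot(all(c("cell_id", "class", "count") %in% names(counts)))
  g <- groups[counts$cell_id]
  lev <- sort(unique(unname(groups)))
  if (length(lev) != 2L) stop_bad_input("exactly two groups are required")
  rows <- lapply(split(seq_len(nrow(counts)), counts$class), function(idx) {
    x <- counts$count[idx][g[idx] == lev[1]]
    y <- counts$count[idx][g[idx] == lev[2]]
    if (length(x) < 2L || length(y) < 2L)
      stop_bad_input("each group needs at least 2 cells")
    degenerate <- var(x) == 0 && var(y) == 0
    tt <- if (degenerate) NULL else t.test(x, y)
    mw <- suppressWarnings(wilcox.test(x, y))
    data.frame(class = counts$class[idx][1],
               mean_1 = mean(x), mean_2 = mean(y),
               median_1 = median(x), median_2 = median(y),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               t_p = if (is.null(tt)) NA_real_ else tt$p.value,
               U = unname(mw$statistic), mwu_p = mw$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "groups") <- lev
  out
}

#' Per-cell event counts by class
#'
#' @param events event data.frame from [classify_events_all()].
#' @param cells optional character vector of cell ids to report (cells with
#'   no events get zero counts).
#' @param classes classes to tabulate.
#' @return data.frame cell_id, class, count.
#' @export
event_counts <- function(events, cells = NULL,
                         classes = c("deletion", "gain", "amplification")) {
  cells <- cells %||% unique(events$cell_id)
  grid <- expand.grid(cell_id = cells, class = classes,
                      stringsAsFactors = FALSE)
  tab <- table(events$cell_id, events$class)
  grid$count <- mapply(function(c_, k_)
    if (c_ %in% rownames(tab) && k_ %in% colnames(tab)) tab[c_, k_] else 0L,
    grid$cell_id, grid$class)
  grid
}

#' Median ploidy from DAPI area measurements
#'
#' The ratio of the polyploid to the diploid gate's median DAPI area, scaled
#' by the diploid reference ploidy of 2.
#'
#' @param median_diploid_area,median_polyploid_area positive medians.
#' @return estimated ploidy (2 when the gates coincide).
#' @export
ploidy_from_dapi <- function(median_diploid_area, median_polyploid_area) {
  check_positive(median_diploid_area, "median_diploid_area")
  check_positive(median_polyploid_area, "median_polyploid_area")
  2 * median_polyploid_area / median_diploid_area
}

#' Marker-locus RPKM and aggregate LOH genotyping
#'
#' RPKM = count / (feature length in kb x total mapped reads in millions).
#' The LOH call compares the lost-marker locus (GFP-analog) to the retained
#' marker (mKate-analog): a cell is LOH-positive when the former's RPKM
#' falls below `loh_fraction` of the latter's.
#'
#' @param counts named numeric vector of per-feature read counts.
#' @param lengths named numeric vector of feature lengths in bases.
#' @param total_reads total mapped reads of the sample.
#' @param marker_lost,marker_retained feature names for the LOH call
#'   (optional; both must be in `counts`).
#' @param loh_fraction LOH threshold (default 0.2).
#' @return list with `rpkm` (named vector) and `loh_positive` (logical or
#'   NA when markers are not given).
#' @export
marker_rpkm <- function(counts, lengths, total_reads,
                        marker_lost = NULL, marker_retained = NULL,
                        loh_fraction = 0.2) {
  check_positive(lengths, "lengths")
  check_positive(total_reads, "total_reads")
  rpkm <- counts / (lengths / 1e3) / (total_reads / 1e6)
  loh <- NA
  if (!is.null(marker_lost) && !is.null(marker_retained)) {
    stopifnot(marker_lost %in% names(rpkm), marker_retained %in% names(rpkm))
    loh <- unname(rpkm[marker_lost] < loh_fraction * rpkm[marker_retained])
  }
  list(rpkm = rpkm, loh_positive = loh)
}
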