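chrom20 <- rep(sprintf("chr%d", 1:4), each = 50)

test_that("event classes follow the ploidy reference", {
  st <- rep(4L, 200)
  st[11:30] <- 3L    # below reference 4: deletion
  st[61:80] <- 5L    # above: gain
  st[121:123] <- 9L  # >= 2x reference, focal: amplification
  ev <- classify_events(profile_stub("p", st, chrom20), "polyploid")
  ev <- ev[order(ev$start_bin), ]
  expect_equal(ev$class, c("deletion", "gain", "amplification"))
  expect_equal(ev$reference, rep(4L, 3))

  # the same states against a diploid reference
  st2 <- rep(2L, 200)
  st2[61:80] <- 3L
  st2[121:123] <- 9L
  ev2 <- classify_events(profile_stub("q", st2, chrom20), "diploid")
  expect_equal(sort(ev2$class), c("amplification", "gain"))

  # flat diploid: no events
  expect_equal(nrow(classify_events(profile_stub("f", rep(2L, 200), chrom20),
                                    "diploid")), 0L)

  # wide high-state run is a gain, not an amplification
  st3 <- rep(2L, 200)
  st3[61:100] <- 4L
  expect_equal(classify_events(profile_stub("w", st3, chrom20),
                               "diploid")$class, "gain")
})

test_that("events plus reference fill reconstruct the profile exactly", {
  set.seed(12)
  for (r in 1:10) {
    st <- rep(2L, 200)
    for (e in 1:5) {
      i <- sample(180, 1)
      st[i:(i + sample(2:15, 1))] <- sample(c(0:1, 3:9), 1)
    }
    st <- st[1:200]
    ev <- classify_events(profile_stub("x", st, chrom20), "diploid")
    rebuilt <- rep(2L, 200)
    for (i in seq_len(nrow(ev)))
      rebuilt[(ev$start_bin[i] + 1):ev$end_bin[i]] <- ev$state[i]
    expect_identical(rebuilt, st)
  }
})

test_that("CORE finds the shared interval and matches the exhaustive oracle", {
  set.seed(3)
  mk_ev <- function(cell, s, e) data.frame(cell_id = cell, chrom = "chr1",
                                           start_bin = s, end_bin = e,
                                           state = 1L, class = "deletion",
                                           reference = 2L,
                                           stringsAsFactors = FALSE)
  ev <- do.call(rbind, c(lapply(1:8, function(i)
    mk_ev(sprintf("c%d", i), 100L, 200L)),
    list(mk_ev("c9", 300L, 340L), mk_ev("c10", 10L, 35L))))
  chrom_bins <- c(chr1 = 400L)
  res <- core_recurrence(ev, "deletion", chrom_bins, n_perm = 100, seed = 4)
  expect_equal(res$start_bin[1], 100L)
  expect_equal(res$end_bin[1], 200L)
  expect_equal(res$score[1], 8.0)
  expect_true(all(diff(res$score) <= 1e-9))
  expect_lt(res$p_value[1], 0.05)
  oracle <- core_top_oracle(ev)
  expect_equal(res$score[1], oracle$score, tolerance = 1e-9)
  expect_equal(res$start_bin[1], oracle$interval$start_bin)

  # a single event shared by all n cells scores n
  ev2 <- do.call(rbind, lapply(1:5, function(i)
    mk_ev(sprintf("c%d", i), 50L, 90L)))
  res2 <- core_recurrence(ev2, "deletion", chrom_bins, n_perm = 100,
                          seed = 5)
  expect_equal(res2$score[1], 5.0)

  # no events of the class: empty result
  res3 <- core_recurrence(ev[0, ], "deletion", chrom_bins, n_perm = 100,
                          seed = 6)
  expect_equal(nrow(res3), 0L)
})

test_that("greedy top core equals exhaustive search on random instances", {
  set.seed(17)
  for (r in 1:10) {
    ev <- do.call(rbind, lapply(1:8, function(i) {
      n <- sample(1:3, 1)
      s <- sample(0:150, n)
      data.frame(cell_id = sprintf("c%d", i), chrom = "chr1",
                 start_bin = s, end_bin = s + sample(5:40, n, replace = TRUE),
                 state = 1L, class = "deletion", reference = 2L,
                 stringsAsFactors = FALSE)
    }))
    ev$end_bin <- pmin(ev$end_bin, 200L)
    top <- cnaphase:::greedy_cores(ev, 1L, 0)
    oracle <- core_top_oracle(ev)
    expect_equal(top$score[1], oracle$score, tolerance = 1e-9)
  }
})

test_that("frequency designation respects the inclusive 0.1 threshold", {
  segv <- matrix(1, nrow = 5, ncol = 1)
  segv[2, 1] <- 1.05
  segv[3, 1] <- 1.12
  segv[4, 1] <- 1.10
  segv[5, 1] <- 0.90
  segv <- segv / mean(segv) * 1  # leave uncentred; function centres per sample
  ft <- frequency_track(segv, theta = 0.1)
  centred <- segv[, 1] / mean(segv[, 1])
  expect_equal(ft$gain_freq, as.numeric(centred >= 1.1))
  expect_equal(ft$del_freq, as.numeric(centred <= 0.9))

  # identical samples with one deleted region
  m <- matrix(rep(c(1, 0.5, 1), c(10, 5, 10)), ncol = 3, nrow = 25)
  ft2 <- frequency_track(m, 0.1)
  expect_equal(ft2$del_freq[11:15], rep(1, 5))
  expect_equal(sum(ft2$del_freq), 5)
})

test_that("bin homogeneity is the modal state frequency", {
  m <- cbind(c(2L, 2L, 2L, 2L), c(2L, 2L, 3L, 3L), c(3L, 2L, 3L, 3L))
  h <- bin_homogeneity(t(m))
  expect_equal(bin_homogeneity(matrix(c(2L, 2L, 3L), 1, 3)), 2 / 3)
  expect_equal(bin_homogeneity(matrix(c(2L, 2L, 2L), 1, 3)), 1.0)
  expect_equal(bin_homogeneity(matrix(c(2L, 2L, 3L, 3L), 1, 4)), 0.5)
  expect_true(all(h >= 1 / 3 & h <= 1))
})

test_that("bulk segment homogeneity: clipping, KS, degenerate classes", {
  segs <- data.frame(cf = c(0.8, 0.8, 0.4, 0.2), purity = 0.8,
                     class = c("deletion", "deletion", "gain", "gain"))
  rep_ <- segment_homogeneity(segs)
  expect_equal(rep_$segments$clonality, c(1, 1, 0.5, 0.25))
  expect_true(is.finite(rep_$ks_statistic))

  # cf == purity everywhere: all clonality 1, KS statistic 0
  segs2 <- data.frame(cf = 0.7, purity = 0.7,
                      class = rep(c("gain", "deletion"), 5))
  rep2 <- segment_homogeneity(segs2)
  expect_true(all(rep2$segments$clonality == 1))
  expect_equal(unname(rep2$ks_statistic), 0)

  # raw values above the clip are preserved in the diagnostic column
  segs3 <- data.frame(cf = 1.2, purity = 0.8, class = "gain")
  rep3 <- segment_homogeneity(segs3)
  expect_equal(rep3$segments$clonality, 1.25)
  expect_equal(rep3$segments$clonality_raw, 1.5)
  expect_true(is.na(rep3$ks_p_value))  # single class: KS not applicable

  expect_error(segment_homogeneity(data.frame(cf = 1, purity = 0,
                                              class = "gain")),
               "positive")
})

test_that("clonal deletions and subclonal gains separate by KS", {
  set.seed(9)
  segs <- data.frame(
    cf = c(rnorm(60, 0.78, 0.02), runif(60, 0.16, 0.8)),
    purity = 0.8,
    class = rep(c("deletion", "gain"), each = 60))
  segs$cf <- pmax(segs$cf, 0.01)
  rep_ <- segment_homogeneity(segs)
  expect_lt(rep_$ks_p_value, 0.005)
})

test_that("event-count comparisons match exact references", {
  counts <- data.frame(cell_id = sprintf("c%d", 1:6),
                       class = "gain",
                       count = c(1, 2, 3, 11, 12, 13))
  groups <- setNames(rep(c("g1", "g2"), each = 3), counts$cell_id)
  res <- compare_event_counts(counts, groups)
  expect_equal(res$mwu_p, 0.1, tolerance = 1e-9)
  expect_equal(res$mwu_p, mwu_exact_oracle(c(1, 2, 3), c(11, 12, 13)),
               tolerance = 1e-9)
  expect_lt(res$t_p, 0.01)

  # identical groups: exact two-sided MWU p of 1
  counts2 <- counts
  counts2$count <- rep(c(5, 6, 7), 2)
  res2 <- compare_event_counts(counts2, groups)
  expect_equal(res2$mwu_p, 1.0)

  # degenerate zero-variance groups: t reported as NA
  counts3 <- counts
  counts3$count <- rep(2, 6)
  res3 <- compare_event_counts(counts3, groups)
  expect_true(is.na(res3$t_p))
})

test_that("MWU and KS agree with reference implementations on random data", {
  set.seed(23)
  for (r in 1:50) {
    x <- rnorm(sample(8:20, 1))
    y <- rnorm(sample(8:20, 1), mean = runif(1, -1, 1))
    mw <- suppressWarnings(wilcox.test(x, y))
    u_direct <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(mw$statistic), u_direct, tolerance = 1e-8)
    ks <- suppressWarnings(ks.test(x, y))
    d_direct <- max(abs(ecdf(x)(sort(c(x, y))) - ecdf(y)(sort(c(x, y)))))
    expect_equal(unname(ks$statistic), d_direct, tolerance = 1e-8)
  }
})

test_that("DAPI ploidy and RPKM formulas", {
  expect_equal(ploidy_from_dapi(100, 200), 4.0)
  expect_equal(ploidy_from_dapi(100, 190), 3.8)
  expect_equal(ploidy_from_dapi(77.3, 77.3), 2.0)
  expect_error(ploidy_from_dapi(0, 10), "positive")

  r <- marker_rpkm(c(gfp = 100, mkate = 100), c(gfp = 1000, mkate = 1000),
                   1e6, "gfp", "mkate")
  expect_equal(unname(r$rpkm["gfp"]), 100)
  expect_false(r$loh_positive)  # equal coverage at both markers
  r2 <- marker_rpkm(c(gfp = 0, mkate = 80), c(gfp = 1000, mkate = 1000),
                    1e6, "gfp", "mkate")
  expect_equal(unname(r2$rpkm["gfp"]), 0)
  expect_true(r2$loh_positive)
  expect_error(marker_rpkm(c(a = 1), c(a = 1000), 0), "positive")
})
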