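# Independent oracles and small fixtures used across the suite.

# adjusted Rand index (direct from the contingency-table definition)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# hypergeometric upper tail by direct summation of the pmf (log scale),
# independent of phyper
hyper_tail_oracle <- function(shared, ka, kb, N) {
  lo <- max(0L, ka + kb - N)
  hi <- min(ka, kb)
  if (shared > hi) return(0)
  terms <- vapply(max(shared, lo):hi, function(x)
    exp(lchoose(ka, x) + lchoose(N - ka, kb - x) - lchoose(N, kb)), 0)
  sum(terms)
}

# brute-force quantal fit over the same grid and selection criterion as
# fit_ploidy (plain objective, smaller-q ties), written independently
brute_force_fit <- function(bin_means, q_grid) {
  best_q <- NA
  best_err <- Inf
  for (q in q_grid) {
    err <- 0
    for (r in bin_means) err <- err + (q * r - round(q * r))^2
    if (err < best_err - 1e-9) {
      best_err <- err
      best_q <- q
    }
  }
  list(q = best_q, err = best_err)
}

# exhaustive single-changepoint least-squares oracle: best split position
# c (1..n-1) minimising two-segment SSE
single_cp_oracle <- function(x) {
  n <- length(x)
  sse <- vapply(1:(n - 1), function(c_) {
    a <- x[1:c_]
    b <- x[(c_ + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, 0)
  which.min(sse)
}

# exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (tiny n only)
mwu_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(i)
    sum(rank(pooled)[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# exhaustive CORE top-core oracle over all candidate (event) intervals
core_top_oracle <- function(ev) {
  cand <- unique(ev[c("chrom", "start_bin", "end_bin")])
  best <- NULL
  best_score <- -Inf
  for (i in seq_len(nrow(cand))) {
    sc <- 0
    for (cell in unique(ev$cell_id)) {
      e <- ev[ev$cell_id == cell & ev$chrom == cand$chrom[i], , drop = FALSE]
      if (!nrow(e)) next
      inter <- pmax(0, pmin(e$end_bin, cand$end_bin[i]) -
                       pmax(e$start_bin, cand$start_bin[i]))
      uni <- (e$end_bin - e$start_bin) +
        (cand$end_bin[i] - cand$start_bin[i]) - inter
      sc <- sc + max(inter / uni)
    }
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- cand[i, ]
    }
  }
  list(interval = best, score = best_score)
}

# small simulation configuration: 8 chromosomes x 50 bins, light noise,
# cheap enough for unit tests
tiny_cfg <- function(...) {
  defaults <- list(n_bins = 400L,
                   chrom_lengths = setNames(rep(50L, 8), paste0("chr", 1:8)),
                   n_dp_cells = 3L, n_sp_cells = 12L,
                   reads_per_cell_mean = 2e5, dispersion = 0.02,
                   gc_bias_strength = 0.1, n_loh_lineages = 2L,
                   seed = 42L)
  args <- modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# integer_cn_profile stub from an explicit state vector (for clone tests
# that do not need the calling chain)
profile_stub <- function(cell_id, states, chrom) {
  ci <- match(chrom, unique(chrom))
  structure(list(cell_id = cell_id, states = as.integer(states),
                 multiplier = 2, ploidy = mean(states),
                 ploidy_label = if (mean(states) >= 3) "polyploid"
                                else "diploid",
                 fit_error = 0,
                 segments = data.frame(),
                 breakpoints = which(states[-length(states)] != states[-1] &
                                       ci[-length(ci)] == ci[-1]),
                 chrom = chrom),
            class = "integer_cn_profile")
}

# segmented_profile built from explicit per-bin means (one segment per
# constant run), for ploidy-fit tests
seg_obj <- function(bin_means, chrom, var_within = NULL) {
  runs <- rle(paste(bin_means, chrom))
  ends <- cumsum(runs$lengths)
  starts <- c(0L, head(ends, -1L))
  segs <- data.frame(chrom = chrom[ends], start_bin = starts,
                     end_bin = ends, n_bins = runs$lengths,
                     mean_ratio = bin_means[ends],
                     stringsAsFactors = FALSE)
  segs$var_within <- if (is.null(var_within)) 0 else var_within
  structure(list(cell_id = "t", segments = segs, bin_means = bin_means,
                 chrom = chrom), class = "segmented_profile")
}
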