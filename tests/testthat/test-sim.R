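test_that("invalid configurations are rejected", {
  expect_error(tiny_cfg(n_loh_lineages = 20, n_sp_cells = 5), "exceed")
  expect_error(tiny_cfg(wgd_probability = 1.5), "\\[0, 1\\]")
  expect_error(tiny_cfg(chrom_lengths = setNames(rep(10L, 8),
                                                 paste0("c", 1:8))),
               "equal n_bins")
  expect_error(tiny_cfg(dispersion = -1), "non-negative")
})

test_that("gains are gated on genome doubling", {
  cfg <- tiny_cfg(wgd_probability = 0)
  truth <- simulate_lineages(cfg)
  expect_false(any(vapply(truth$lineages, function(l) l$is_polyploid, TRUE)))
  ev <- truth$events
  sp <- grepl("^SP", ev$lineage_id)
  expect_equal(sum(ev$class %in% c("gain", "amplification") & sp), 0L)
})

test_that("with no extra events SP profiles differ from diploid only at the LOH chromosome", {
  cfg <- tiny_cfg(deletions_per_phase = 0, gains_post_wgd_rate = 0,
                  focal_amp_rate = 0, wgd_probability = 0,
                  dp_gain_probability = 0)
  truth <- simulate_lineages(cfg)
  ci <- rep(names(cfg$chrom_lengths), cfg$chrom_lengths)
  for (l in truth$lineages) {
    if (l$founder_id == "DP_flat") next
    off <- which(l$true_profile != 2L)
    expect_true(all(ci[off] == truth$loh_chrom))
    expect_gt(length(off), 0)
  }
})

test_that("independent founders carry distinct LOH breakpoints spanning the p53 bin", {
  cfg <- tiny_cfg(n_loh_lineages = 3, n_sp_cells = 12)
  truth <- simulate_lineages(cfg)
  founders <- Filter(function(l) l$phase_label == "LOH", truth$lineages)
  expect_length(founders, 3L)
  keys <- vapply(founders, function(l)
    paste(l$founder_loh_breakpoints, collapse = ","), "")
  expect_equal(length(unique(keys)), 3L)
  for (l in founders)
    expect_true(l$true_profile[truth$p53_bin] < 2L)
})

test_that("phase ordering and ancestry invariants hold across seeds", {
  for (seed in c(1, 7, 19)) {
    cfg <- tiny_cfg(seed = seed, wgd_probability = 1,
                    polyploid_fraction_target = 0.3)
    truth <- simulate_lineages(cfg)
    ev <- truth$events
    # no gains in diploid SP lineages; deletions at least one per founder
    dip_sp <- names(Filter(function(l)
      !l$is_polyploid && l$founder_id != "DP_flat" &&
        l$founder_id != "DP_gain", truth$lineages))
    expect_equal(sum(ev$class == "gain" & ev$lineage_id %in% dip_sp), 0L)
    expect_gte(sum(ev$class == "deletion"), cfg$n_loh_lineages)
    # POST_WGD breakpoints contain the diploid ancestor's
    for (l in truth$lineages) {
      if (l$phase_label != "POST_WGD") next
      anc <- truth$lineages[[l$parent_id]]
      expect_true(all(anc$breakpoint_set %in% l$breakpoint_set))
    }
  }
})

test_that("simulation is deterministic and per-cell streams are stable", {
  cfg <- tiny_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$sim$counts, b$sim$counts)
  expect_identical(a$truth$cell_assignments, b$truth$cell_assignments)
  # adding cells does not perturb existing cells' counts
  cfg2 <- tiny_cfg(n_sp_cells = 16L)
  c2 <- simulate_dataset(cfg2)
  shared <- intersect(colnames(a$sim$counts), colnames(c2$sim$counts))
  shared_same_lineage <- shared[
    a$truth$cell_assignments[shared] == c2$truth$cell_assignments[shared]]
  expect_gt(length(shared_same_lineage), 0)
  expect_identical(a$sim$counts[, shared_same_lineage],
                   c2$sim$counts[, shared_same_lineage])
})

test_that("total reads are calibrated to the configured mean", {
  cfg <- tiny_cfg(n_dp_cells = 0L, n_sp_cells = 100L,
                  reads_per_cell_mean = 2e5)
  ds <- simulate_dataset(cfg)
  expect_lt(abs(mean(ds$sim$cell_meta$total_reads) - 2e5) / 2e5, 0.02)
})

test_that("counts converge to copy-number proportions at high depth", {
  cfg <- tiny_cfg(n_bins = 100L,
                  chrom_lengths = setNames(rep(50L, 2), c("chr1", "chr2")),
                  n_dp_cells = 0L, n_sp_cells = 2L, n_loh_lineages = 1L,
                  reads_per_cell_mean = 1e7, dispersion = 0,
                  gc_bias_strength = 0)
  truth <- simulate_lineages(cfg)
  sim <- profiles_to_counts(truth, sim_scaffold(cfg), cfg)
  cell <- colnames(sim$counts)[1]
  cn <- truth$lineages[[truth$cell_assignments[[cell]]]]$true_profile
  obs <- sim$counts[, cell] / sum(sim$counts[, cell])
  expected <- cn / sum(cn)
  keep <- expected > 0
  expect_true(all(abs(obs[keep] - expected[keep]) / expected[keep] < 0.01))
})

test_that("a flat diploid cell has uniform mean counts without GC bias", {
  cfg <- tiny_cfg(n_dp_cells = 1L, n_sp_cells = 1L, n_loh_lineages = 1L,
                  reads_per_cell_mean = 1e6, dispersion = 0,
                  gc_bias_strength = 0)
  ds <- simulate_dataset(cfg)
  x <- ds$sim$counts[, "DP_001"]
  expect_lt(max(abs(x - mean(x))) / mean(x), 0.1)  # Poisson at mu = 2500
})

test_that("truth_from_profiles builds a usable bundle", {
  cfg <- tiny_cfg(n_dp_cells = 0L, n_sp_cells = 4L)
  profs <- list(A = rep(c(2L, 1L), c(300, 100)),
                B = rep(c(2L, 3L), c(200, 200)))
  asg <- setNames(c("A", "A", "B", "B"), sprintf("c%d", 1:4))
  truth <- truth_from_profiles(profs, asg, cfg)
  expect_equal(truth$cell_meta$true_ploidy,
               c(1.75, 1.75, 2.5, 2.5))
  sim <- profiles_to_counts(truth, sim_scaffold(cfg), cfg)
  expect_equal(dim(sim$counts), c(400L, 4L))
})
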