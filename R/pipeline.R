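# Top-level orchestration: simulate -> profile -> clones -> landscape.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the four stages with its documented
#' default; round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim a [sim_config()] for the simulation stage.
#' @param min_reads QC threshold (inclusive; default 250,000 reads).
#' @param lowess_fraction GC LOWESS span (default 0.3).
#' @param alpha,n_perm_cbs,min_seg_bins segmentation parameters (defaults
#'   0.01, 1000, 3).
#' @param q_grid ploidy multiplier grid (default 1.5-6.0 step 0.05).
#' @param polyploid_threshold ploidy label cutoff (default 3.0).
#' @param min_delta,tolerance breakpoint extraction (defaults 1, 1).
#' @param n_perm_clone clone-null permutations (default 500).
#' @param t clone FDR threshold (default 0.01).
#' @param theta frequency-track designation threshold (default 0.1).
#' @param amp_max_bins amplification focality bound (default 10).
#' @param n_perm_core CORE permutations (default 500).
#' @param seed root seed for all stage streams.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_reads = 250000,
                            lowess_fraction = 0.3,
                            alpha = 0.01, n_perm_cbs = 1000L,
                            min_seg_bins = 3L,
                            q_grid = default_q_grid(),
                            polyploid_threshold = 3.0,
                            min_delta = 1L, tolerance = 1L,
                            n_perm_clone = 500L, t = 0.01,
                            theta = 0.1, amp_max_bins = 10L,
                            n_perm_core = 500L,
                            seed = 1L) {
  structure(list(sim = sim, min_reads = min_reads,
                 lowess_fraction = lowess_fraction, alpha = alpha,
                 n_perm_cbs = as.integer(n_perm_cbs),
                 min_seg_bins = as.integer(min_seg_bins), q_grid = q_grid,
                 polyploid_threshold = polyploid_threshold,
                 min_delta = as.integer(min_delta),
                 tolerance = as.integer(tolerance),
                 n_perm_clone = as.integer(n_perm_clone), t = t,
                 theta = theta, amp_max_bins = as.integer(amp_max_bins),
                 n_perm_core = as.integer(n_perm_core),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @return reader: the reconstructed `pipeline_config` (classes restored).
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$chrom_lengths <- as.list(cfg$sim$chrom_lengths)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- cfg$sim
  chrom_lengths <- unlist(sim$chrom_lengths)
  sim$chrom_lengths <- NULL
  sim <- do.call(sim_config, c(sim, list(chrom_lengths = chrom_lengths)))
  cfg$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), cfg))
}

#' Run the full pipeline and write all stage outputs
#'
#' Stages: simulate ground truth and counts; call integer copy-number
#' profiles; infer clonal structure and WGD precursors; compute the CNA
#' landscape.  Each stage writes its files under `out_dir` and contributes
#' counts to the machine-readable run report (`run_report.json`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the run report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion(
    "cnaphase")), seed = config$seed, stages = list())
  pth <- function(f) file.path(out_dir, f)

  # -- stage 1: simulate -----------------------------------------------------
  config$sim$seed <- derive_seed(config$seed, "stage:sim")
  ds <- simulate_dataset(config$sim)
  write_counts_tsv(ds$sim, path = pth("counts.tsv"))
  write_tsv_table(ds$sim$cell_meta, pth("cell_meta.tsv"))
  write_truth_json(ds$truth, pth("truth.json"))
  report$stages$simulate <- list(
    cells = nrow(ds$sim$cell_meta), bins = nrow(ds$scaffold),
    lineages = length(ds$truth$lineages),
    mean_total_reads = mean(ds$sim$cell_meta$total_reads))

  # -- stage 2: profile ------------------------------------------------------
  calls <- call_cells(ds$sim$counts, ds$scaffold,
                      min_reads = config$min_reads,
                      lowess_fraction = config$lowess_fraction,
                      alpha = config$alpha, n_perm = config$n_perm_cbs,
                      min_seg_bins = config$min_seg_bins,
                      q_grid = config$q_grid,
                      polyploid_threshold = config$polyploid_threshold,
                      seed = derive_seed(config$seed, "stage:profile"))
  report$stages$profile <- list(
    cells_in = nrow(calls$report), cells_kept = length(calls$profiles),
    cells_excluded_qc = sum(!calls$report$qc_pass))
  if (!length(calls$profiles)) {
    write_json_report(report, pth("run_report.json"))
    stop_bad_input("profile stage kept 0 cells: all below min_reads; ",
                   "pipeline stopped")
  }
  write_tsv_table(calls$report, pth("qc_report.tsv"))
  write_seg(calls, ds$scaffold, pth("segments.seg"))
  cn <- cn_matrix(calls)
  write_cn_tsv(cn, ds$scaffold, pth("cn_matrix.tsv"))

  # -- stage 3: clones -------------------------------------------------------
  seed_cl <- derive_seed(config$seed, "stage:clones")
  bp <- extract_breakpoints(calls, min_delta = config$min_delta,
                            tolerance = config$tolerance)
  d <- dissimilarity_matrix(bp)
  tree <- build_tree(d)
  null <- permutation_null(bp, n_perm = config$n_perm_clone, seed = seed_cl)
  tree <- call_clones(tree, null, t = config$t)
  links <- trace_wgd_precursors(calls, bp, tree, t = config$t)
  write_newick(tree, pth("clone_tree.nwk"))
  write_tsv_table(tree$assignments, pth("clone_assignments.tsv"))
  write_tsv_table(as.data.frame(d), pth("dissimilarity.tsv"))
  write_tsv_table(links, pth("wgd_precursors.tsv"))
  n_clones <- length(unique(grep("^clone_", tree$assignments$clone,
                                 value = TRUE)))
  report$stages$clones <- list(
    canonical_boundaries = length(bp$canonical), clones = n_clones,
    singletons = sum(!grepl("^clone_", tree$assignments$clone)),
    wgd_links_supported = sum(links$supported))

  # -- stage 4: landscape ----------------------------------------------------
  seed_ls <- derive_seed(config$seed, "stage:landscape")
  events <- classify_events_all(calls, amp_max_bins = config$amp_max_bins)
  write_events_bed(events, ds$scaffold, pth("events.bed"))
  chrom_bins <- table(factor(ds$scaffold$chrom,
                             levels = unique(ds$scaffold$chrom)))
  cores <- list()
  for (cl in c("deletion", "gain")) {
    res <- core_recurrence(events, class = if (cl == "gain")
      c("gain", "amplification") else cl, chrom_bins = chrom_bins,
      n_perm = config$n_perm_core, seed = seed_ls)
    if (nrow(res)) cores[[cl]] <- res
  }
  if (length(cores)) {
    allc <- do.call(rbind, c(lapply(names(cores), function(cl)
      data.frame(cores[[cl]], core_class = cl)), make.row.names = FALSE))
    write_tsv_table(allc, pth("cores.tsv"))
  }
  hom <- bin_homogeneity(cn)
  write_tsv_table(data.frame(bin = seq_along(hom), homogeneity = hom),
                  pth("homogeneity.tsv"))
  segv <- do.call(cbind, lapply(calls$profiles, function(p) {
    # recover the per-bin segment means for the frequency track
    rep(p$segments$mean_ratio, p$segments$n_bins)
  }))
  freq <- frequency_track(segv, theta = config$theta)
  write_tsv_table(as.data.frame(freq), pth("frequency_track.tsv"))
  report$stages$landscape <- list(
    events = nrow(events), cores = sum(vapply(cores, nrow, 0L)),
    mean_homogeneity = mean(hom))

  write_json_report(report, pth("run_report.json"))
  invisible(report)
}

write_json_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
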