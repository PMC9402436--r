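# Synthetic clonal-evolution generator.
#
# Ground-truth lineages evolve through four ordered phases -- LOH deletion on
# a designated chromosome, accumulation of further deletions while diploid,
# whole-genome doubling of a rearranged diploid precursor, then gains and
# focal amplifications -- and are observed through a sparse-WGS noise model
# (gamma-Poisson bin counts with a quadratic GC bias).

#' Simulation configuration
#'
#' Defaults describe the reference study conditions: a 5,000-bin mouse-like
#' genome at one million reads per cell, negative-binomial overdispersion
#' giving a per-bin coefficient of variation of ~0.3, three independent LOH
#' founder lineages, and 10-20% of the rearranged-cell population polyploid.
#'
#' @param n_bins total genomic bins.
#' @param chrom_lengths named integer vector of per-chromosome bin counts
#'   summing to `n_bins`; `NULL` apportions `n_bins` over the packaged mm9
#'   chromosome lengths.
#' @param n_dp_cells,n_sp_cells cells of the two marker classes: DP cells
#'   retain wild-type p53 (near-flat diploid genomes); SP cells descend from
#'   a p53-LOH founder.
#' @param reads_per_cell_mean expected total reads per cell.
#' @param dispersion negative-binomial overdispersion `a` in
#'   `Var = mu + a * mu^2`; the default 0.085 gives a per-bin CV of ~0.3 at
#'   `10^6` reads over 5,000 bins.
#' @param gc_bias_strength unitless amplitude of the quadratic GC bias curve
#'   (0 disables it).
#' @param n_loh_lineages independent LOH founder lineages among SP cells.
#' @param deletions_per_phase expected new deletions added per lineage
#'   generation while diploid.
#' @param wgd_probability per-founder probability that the lineage undergoes
#'   whole-genome doubling.
#' @param polyploid_fraction_target fraction of SP cells drawn from doubled
#'   lineages (when any exist).
#' @param gains_post_wgd_rate,focal_amp_rate expected counts of broad gains
#'   and of focal amplifications added after doubling (never before).
#' @param n_wgd_branches sublineages spawned by a doubling event; each
#'   branch diversifies with private post-doubling events, so gains are
#'   subclonal within the doubled population while doubled deletions stay
#'   clonal.
#' @param dp_gain_probability probability that a second DP lineage carrying
#'   one whole-chromosome gain exists.
#' @param loh_chrom chromosome carrying the founder LOH deletions;
#'   `NULL` picks `"chr11"` when present, otherwise a mid-genome chromosome.
#' @param p53_locus_frac fractional position of the p53-locus bin along
#'   `loh_chrom`; every founder deletion spans this bin.
#' @param seed root random seed; all child streams derive from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_bins = 5000L,
                       chrom_lengths = NULL,
                       n_dp_cells = 50L,
                       n_sp_cells = 100L,
                       reads_per_cell_mean = 1e6,
                       dispersion = 0.085,
                       gc_bias_strength = 0.2,
                       n_loh_lineages = 3L,
                       deletions_per_phase = 3,
                       wgd_probability = 0.33,
                       polyploid_fraction_target = 0.15,
                       gains_post_wgd_rate = 3,
                       focal_amp_rate = 1,
                       n_wgd_branches = 3L,
                       dp_gain_probability = 0.1,
                       loh_chrom = NULL,
                       p53_locus_frac = 0.57,
                       seed = 1L) {
  n_bins <- as.integer(n_bins)
  if (is.null(chrom_lengths)) {
    sizes <- read_chrom_sizes(system.file("extdata", "mm9_chrom_sizes.tsv",
                                          package = "cnaphase",
                                          mustWork = TRUE))
    sc <- build_scaffold(sizes, n_bins, gc_source = "synthetic")
    tab <- table(factor(sc$chrom, levels = unique(sc$chrom)))
    chrom_lengths <- setNames(as.integer(tab), names(tab))
  }
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  cfg <- list(n_bins = n_bins, chrom_lengths = chrom_lengths,
              n_dp_cells = as.integer(n_dp_cells),
              n_sp_cells = as.integer(n_sp_cells),
              reads_per_cell_mean = reads_per_cell_mean,
              dispersion = dispersion,
              gc_bias_strength = gc_bias_strength,
              n_loh_lineages = as.integer(n_loh_lineages),
              deletions_per_phase = deletions_per_phase,
              wgd_probability = wgd_probability,
              polyploid_fraction_target = polyploid_fraction_target,
              gains_post_wgd_rate = gains_post_wgd_rate,
              focal_amp_rate = focal_amp_rate,
              n_wgd_branches = as.integer(n_wgd_branches),
              dp_gain_probability = dp_gain_probability,
              loh_chrom = loh_chrom,
              p53_locus_frac = p53_locus_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  check_positive(cfg$n_bins, "n_bins")
  check_positive(cfg$chrom_lengths, "chrom_lengths")
  if (sum(cfg$chrom_lengths) != cfg$n_bins)
    stop_bad_input("sum(chrom_lengths) must equal n_bins")
  if (is.null(names(cfg$chrom_lengths)))
    stop_bad_input("chrom_lengths must be named by chromosome")
  check_positive(cfg$n_dp_cells + cfg$n_sp_cells, "total cells")
  check_positive(cfg$reads_per_cell_mean, "reads_per_cell_mean")
  check_positive(cfg$dispersion, "dispersion", strict = FALSE)
  check_positive(cfg$gc_bias_strength, "gc_bias_strength", strict = FALSE)
  check_positive(cfg$n_loh_lineages, "n_loh_lineages")
  if (cfg$n_loh_lineages > cfg$n_sp_cells)
    stop_bad_input("n_loh_lineages must not exceed n_sp_cells")
  check_positive(cfg$deletions_per_phase, "deletions_per_phase",
                 strict = FALSE)
  check_fraction(cfg$wgd_probability, "wgd_probability")
  check_fraction(cfg$polyploid_fraction_target, "polyploid_fraction_target")
  check_positive(cfg$gains_post_wgd_rate, "gains_post_wgd_rate",
                 strict = FALSE)
  check_positive(cfg$focal_amp_rate, "focal_amp_rate", strict = FALSE)
  check_positive(cfg$n_wgd_branches, "n_wgd_branches")
  check_fraction(cfg$dp_gain_probability, "dp_gain_probability")
  check_fraction(cfg$p53_locus_frac, "p53_locus_frac")
  invisible(cfg)
}

#' Scaffold matching a simulation configuration
#'
#' Builds a [build_scaffold()] whose per-chromosome bin counts equal the
#' configuration's `chrom_lengths` exactly (nominal 600-kb bins).
#'
#' @param config a [sim_config()].
#' @return A `bin_scaffold` with `config$n_bins` bins.
#' @export
sim_scaffold <- function(config) {
  build_scaffold(config$chrom_lengths * 6e5, config$n_bins,
                 gc_source = "synthetic")
}

# -- lineage machinery -------------------------------------------------------

# per-bin chromosome index vector for a config
cfg_chrom_index <- function(cfg) {
  rep(seq_along(cfg$chrom_lengths), cfg$chrom_lengths)
}

# breakpoints of an integer profile: boundary b (between bin b and b+1,
# 1-based bins) is set when the state changes within a chromosome
profile_breakpoints <- function(profile, chrom_index) {
  n <- length(profile)
  which(profile[-n] != profile[-1] & chrom_index[-n] == chrom_index[-1])
}

# log-uniform integer in [lo, hi]
rlogunif_int <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(round(exp(runif(1, log(lo), log(hi)))))
}

new_true_lineage <- function(id, parent, founder, phase, profile, chrom_index,
                             is_polyploid = FALSE, loh_bp = NULL) {
  structure(list(lineage_id = id, parent_id = parent, founder_id = founder,
                 phase_label = phase, true_profile = as.integer(profile),
                 breakpoint_set = profile_breakpoints(profile, chrom_index),
                 is_polyploid = is_polyploid,
                 founder_loh_breakpoints = loh_bp),
            class = "true_lineage")
}

# apply an interval event to a profile, rejecting applications that would
# erase an ancestral breakpoint (keeps descendant breakpoint sets supersets
# of their ancestors'); returns NULL when rejected
apply_event <- function(profile, chrom_index, start_bin, end_bin, delta,
                        set_state = NULL, protect = integer()) {
  idx <- (start_bin + 1L):end_bin
  new <- profile
  if (is.null(set_state)) {
    new[idx] <- pmax(0L, new[idx] + as.integer(delta))
  } else {
    new[idx] <- as.integer(set_state)
  }
  if (length(protect)) {
    kept <- profile_breakpoints(new, chrom_index)
    if (!all(protect %in% kept)) return(NULL)
  }
  new
}

# draw a random interval of n_bins_event bins on a uniformly chosen chromosome
draw_interval <- function(cfg, min_bins, max_frac = 1) {
  k <- sample.int(length(cfg$chrom_lengths), 1L)
  cl <- cfg$chrom_lengths[k]
  offset <- sum(cfg$chrom_lengths[seq_len(k - 1L)])
  size <- min(rlogunif_int(min_bins, max(min_bins, floor(cl * max_frac))), cl)
  start <- sample.int(cl - size + 1L, 1L) - 1L
  c(start_bin = offset + start, end_bin = offset + start + size)
}

#' Simulate ground-truth clonal lineages
#'
#' Generates the lineage forest of the four-phase model.  Every SP founder
#' carries a contiguous LOH deletion spanning the p53-locus bin with
#' founder-specific boundaries; while diploid, lineages accumulate only
#' deletions; doubling copies a recorded diploid ancestor profile times two;
#' gains and focal amplifications are applied only after doubling (each
#' doubled lineage acquires at least one, since the fourth phase is defined
#' by their emergence).  DP lineages are flat diploid, except an optional
#' lineage carrying one whole-chromosome gain.
#'
#' @param config a [sim_config()].
#' @return A `truth_bundle`: list with `lineages` (list of `true_lineage`),
#'   `cell_assignments` (named character vector, cell id to lineage id),
#'   `cell_meta` (data.frame: cell_id, marker_class, lineage_id, founder_id,
#'   true_ploidy, is_polyploid), `events` (data.frame of every event with its
#'   class and phase of origin), and the `config`.
#' @export
simulate_lineages <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, "lineages"))
  ci <- cfg_chrom_index(cfg)
  chroms <- names(cfg$chrom_lengths)
  offsets <- cumsum(c(0L, unname(cfg$chrom_lengths)))

  # designated LOH chromosome and p53-locus bin
  loh_k <- if (!is.null(cfg$loh_chrom)) {
    match(cfg$loh_chrom, chroms)
  } else if ("chr11" %in% chroms) {
    match("chr11", chroms)
  } else {
    max(1L, ceiling(length(chroms) * 0.55))
  }
  if (is.na(loh_k)) stop_bad_input("loh_chrom not found in chrom_lengths")
  loh_len <- cfg$chrom_lengths[loh_k]
  loh_off <- offsets[loh_k]
  p53_bin <- loh_off + max(1L, min(loh_len,
                                   ceiling(cfg$p53_locus_frac * loh_len)))

  lineages <- list()
  events <- list()
  add_event <- function(lid, phase, class, start_bin, end_bin, state) {
    events[[length(events) + 1L]] <<- data.frame(
      lineage_id = lid, phase = phase, class = class,
      start_bin = as.integer(start_bin), end_bin = as.integer(end_bin),
      state = as.integer(state), stringsAsFactors = FALSE)
  }

  # -- DP lineages -----------------------------------------------------------
  flat <- rep(2L, cfg$n_bins)
  lineages$DP_flat <- new_true_lineage("DP_flat", NA_character_, "DP_flat",
                                       "DP", flat, ci)
  dp_ids <- "DP_flat"
  if (runif(1) < cfg$dp_gain_probability && length(chroms) > 1L) {
    k <- sample(setdiff(seq_along(chroms), loh_k), 1L)
    idx <- (offsets[k] + 1L):offsets[k + 1L]
    prof <- flat; prof[idx] <- 3L
    lineages$DP_gain <- new_true_lineage("DP_gain", "DP_flat", "DP_gain",
                                         "DP", prof, ci)
    add_event("DP_gain", "DP", "gain", offsets[k], offsets[k + 1L], 3L)
    dp_ids <- c(dp_ids, "DP_gain")
  }

  # -- SP lineage forest -----------------------------------------------------
  diploid_sp <- character()   # lineages eligible to host diploid SP cells
  wgd_ids <- character()
  used_loh <- character()     # founder boundary pairs must be distinct:
                              # independent competing lineages
  for (f in seq_len(cfg$n_loh_lineages)) {
    fid <- sprintf("SP%d_LOH", f)
    # founder-specific LOH boundaries, contiguous, spanning the p53 bin
    for (try in 1:50) {
      left <- loh_off + sample.int(p53_bin - loh_off, 1L) - 1L
      right <- p53_bin + sample.int(loh_off + loh_len - p53_bin + 1L, 1L) - 1L
      if (right - left < 5L)  # keep the founder deletion visible at bin scale
        right <- min(loh_off + loh_len, left + 5L)
      key <- paste(left, right)
      if (!key %in% used_loh) { used_loh <- c(used_loh, key); break }
    }
    prof <- apply_event(flat, ci, left, right, -1L)
    loh_bp <- profile_breakpoints(prof, ci)
    lineages[[fid]] <- new_true_lineage(fid, NA_character_, fid, "LOH",
                                        prof, ci, loh_bp = loh_bp)
    add_event(fid, "LOH", "deletion", left, right, prof[left + 1L])

    # deletion-accumulation child
    did <- sprintf("SP%d_DEL", f)
    dprof <- prof
    n_del <- rpois(1, cfg$deletions_per_phase)
    for (d in seq_len(n_del)) {
      for (try in 1:25) {
        iv <- draw_interval(cfg, min_bins = 5L)
        cand <- apply_event(dprof, ci, iv[1], iv[2], -1L, protect = loh_bp)
        if (!is.null(cand) && any(cand != dprof)) {
          add_event(did, "DELETION_ACCUM", "deletion", iv[1], iv[2],
                    cand[iv[1] + 1L])
          dprof <- cand
          break
        }
      }
    }
    lineages[[did]] <- new_true_lineage(did, fid, fid, "DELETION_ACCUM",
                                        dprof, ci, loh_bp = loh_bp)
    diploid_sp <- c(diploid_sp, did)

    # optional genome doubling of the rearranged diploid precursor; the
    # doubled population diversifies into branches, each with private
    # post-doubling events (so gains are subclonal, doubled deletions
    # clonal).  Single-copy losses continue after doubling (4 -> 3); only
    # the onset of gains is phase-gated.
    if (runif(1) < cfg$wgd_probability) {
      base <- 2L * dprof
      anc_bp <- profile_breakpoints(dprof, ci)
      for (b in seq_len(cfg$n_wgd_branches)) {
        wid <- sprintf("SP%d_WGD%d", f, b)
        wprof <- base
        n_del_w <- rpois(1, cfg$deletions_per_phase)
        for (d in seq_len(n_del_w)) {
          for (try in 1:25) {
            iv <- draw_interval(cfg, min_bins = 5L)
            cand <- apply_event(wprof, ci, iv[1], iv[2], -1L,
                                protect = anc_bp)
            if (!is.null(cand) && any(cand != wprof)) {
              add_event(wid, "POST_WGD", "deletion", iv[1], iv[2],
                        cand[iv[1] + 1L])
              wprof <- cand
              break
            }
          }
        }
        n_gain <- rpois(1, cfg$gains_post_wgd_rate)
        n_amp <- rpois(1, cfg$focal_amp_rate)
        if (n_gain + n_amp == 0L) n_gain <- 1L  # phase 4 is gain emergence
        for (g in seq_len(n_gain)) {
          for (try in 1:25) {
            iv <- draw_interval(cfg, min_bins = 5L, max_frac = 0.5)
            cand <- apply_event(wprof, ci, iv[1], iv[2], +1L,
                                protect = anc_bp)
            if (!is.null(cand)) {
              add_event(wid, "POST_WGD", "gain", iv[1], iv[2],
                        cand[iv[1] + 1L])
              wprof <- cand
              break
            }
          }
        }
        for (a in seq_len(n_amp)) {
          for (try in 1:25) {
            iv <- draw_interval(cfg, min_bins = 1L)
            size <- min(iv[2] - iv[1], sample(1:5, 1L))
            iv[2] <- iv[1] + size
            amp_state <- 8L + sample(0:4, 1L)
            cand <- apply_event(wprof, ci, iv[1], iv[2], 0L,
                                set_state = amp_state, protect = anc_bp)
            if (!is.null(cand) && any(cand != wprof)) {
              add_event(wid, "POST_WGD", "amplification", iv[1], iv[2],
                        amp_state)
              wprof <- cand
              break
            }
          }
        }
        lineages[[wid]] <- new_true_lineage(wid, did, fid, "POST_WGD",
                                            wprof, ci, is_polyploid = TRUE,
                                            loh_bp = loh_bp)
        wgd_ids <- c(wgd_ids, wid)
      }
    }
  }

  # -- cell assignment -------------------------------------------------------
  dp_cells <- sprintf("DP_%03d", seq_len(cfg$n_dp_cells))
  sp_cells <- sprintf("SP_%03d", seq_len(cfg$n_sp_cells))
  assign <- character()
  if (cfg$n_dp_cells > 0L) {
    w <- if (length(dp_ids) == 2L) c(0.8, 0.2) else 1
    assign[dp_cells] <- sample(dp_ids, cfg$n_dp_cells, replace = TRUE,
                               prob = w)
  }
  n_poly <- if (length(wgd_ids)) {
    round(cfg$polyploid_fraction_target * cfg$n_sp_cells)
  } else 0L
  n_poly <- min(n_poly, cfg$n_sp_cells - cfg$n_loh_lineages)
  poly_cells <- if (n_poly > 0L) sp_cells[seq_len(n_poly)] else character()
  dipl_cells <- setdiff(sp_cells, poly_cells)
  if (length(poly_cells))
    assign[poly_cells] <- rep_len(wgd_ids, length(poly_cells))
  # round-robin over the expanded diploid SP clones (founder states are
  # ancestral, not sampled), so every founder clade is populated
  assign[dipl_cells] <- rep_len(diploid_sp, length(dipl_cells))

  all_cells <- c(dp_cells, sp_cells)
  lin_of <- assign[all_cells]
  ploidy <- vapply(lineages, function(l) mean(l$true_profile), 0)
  founder <- vapply(lineages, function(l) l$founder_id, "")
  polyp <- vapply(lineages, function(l) l$is_polyploid, TRUE)
  cell_meta <- data.frame(
    cell_id = all_cells,
    marker_class = rep(c("DP", "SP"), c(cfg$n_dp_cells, cfg$n_sp_cells)),
    lineage_id = unname(lin_of),
    founder_id = unname(founder[lin_of]),
    true_ploidy = unname(ploidy[lin_of]),
    is_polyploid = unname(polyp[lin_of]),
    stringsAsFactors = FALSE)

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(lineage_id = character(), phase = character(),
               class = character(), start_bin = integer(),
               end_bin = integer(), state = integer())
  structure(list(lineages = lineages, cell_assignments = assign[all_cells],
                 cell_meta = cell_meta, events = ev,
                 loh_chrom = chroms[loh_k], p53_bin = p53_bin,
                 config = cfg),
            class = "truth_bundle")
}

#' Assemble a truth bundle from explicit profiles
#'
#' Low-level constructor for controlled experiments: given integer profiles
#' (one per lineage) and a cell-to-lineage assignment, builds the same
#' `truth_bundle` structure [simulate_lineages()] emits, so any hand-designed
#' clonal structure can be pushed through [profiles_to_counts()] and the
#' downstream pipeline.
#'
#' @param profiles named list of integer per-bin profiles (shared length).
#' @param cell_assignments named character vector mapping cell ids to names
#'   of `profiles`.
#' @param config a [sim_config()] with matching `n_bins`.
#' @param marker_class optional named vector ("DP"/"SP") per cell; default SP.
#' @return A `truth_bundle`.
#' @export
truth_from_profiles <- function(profiles, cell_assignments, config,
                                marker_class = NULL) {
  stopifnot(is.list(profiles), !is.null(names(profiles)),
            all(cell_assignments %in% names(profiles)))
  if (!all(lengths(profiles) == config$n_bins))
    stop_bad_input("all profiles must have length config$n_bins")
  ci <- cfg_chrom_index(config)
  lineages <- lapply(names(profiles), function(id) {
    p <- as.integer(profiles[[id]])
    new_true_lineage(id, NA_character_, id,
                     if (mean(p) >= 3) "POST_WGD" else "DELETION_ACCUM",
                     p, ci, is_polyploid = mean(p) >= 3)
  })
  names(lineages) <- names(profiles)
  cells <- names(cell_assignments)
  mk <- if (is.null(marker_class)) setNames(rep("SP", length(cells)), cells)
        else marker_class
  ploidy <- vapply(lineages, function(l) mean(l$true_profile), 0)
  cell_meta <- data.frame(
    cell_id = cells, marker_class = unname(mk[cells]),
    lineage_id = unname(cell_assignments[cells]),
    founder_id = unname(cell_assignments[cells]),
    true_ploidy = unname(ploidy[cell_assignments[cells]]),
    is_polyploid = unname(vapply(lineages, function(l) l$is_polyploid,
                                 TRUE)[cell_assignments[cells]]),
    stringsAsFactors = FALSE)
  structure(list(lineages = lineages, cell_assignments = cell_assignments,
                 cell_meta = cell_meta,
                 events = data.frame(), loh_chrom = NA_character_,
                 p53_bin = NA_integer_, config = config),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("truth_bundle: %d lineages, %d cells (%d DP / %d SP)\n",
              length(x$lineages), nrow(x$cell_meta),
              sum(x$cell_meta$marker_class == "DP"),
              sum(x$cell_meta$marker_class == "SP")))
  ph <- table(vapply(x$lineages, function(l) l$phase_label, ""))
  cat("  lineage phases:",
      paste(sprintf("%s=%d", names(ph), ph), collapse = ", "), "\n")
  invisible(x)
}

# -- observation model -------------------------------------------------------

# quadratic GC response, centred at GC 0.45, floored to stay positive
gc_bias_factor <- function(gc, strength) {
  pmax(0.05, 1 - strength * ((gc - 0.45) / 0.2)^2)
}

#' Draw noisy bin counts for every cell of a truth bundle
#'
#' Observation model for sparse single-cell WGS: each cell's expected bin
#' count is proportional to true copy number times the GC-bias factor,
#' normalised to the cell's expected total reads; counts are gamma-Poisson
#' (negative binomial) with the configured overdispersion.  Each cell has its
#' own random stream derived by stable hashing of its id, so output is
#' reproducible cell-by-cell and adding cells never perturbs existing ones.
#'
#' @param truth a `truth_bundle`.
#' @param scaffold a `bin_scaffold` with `config$n_bins` bins.
#' @param config the [sim_config()] used for `truth`.
#' @return A `sim_counts` list: `counts` (bins x cells integer matrix),
#'   `cell_meta` (truth cell metadata plus observed `total_reads`), and the
#'   `scaffold`.
#' @export
profiles_to_counts <- function(truth, scaffold, config) {
  stopifnot(inherits(truth, "truth_bundle"))
  if (nrow(scaffold) != config$n_bins)
    stop_bad_input("scaffold bin count must equal config$n_bins")
  gcf <- gc_bias_factor(scaffold$gc, config$gc_bias_strength)
  cells <- truth$cell_meta$cell_id
  counts <- matrix(0L, nrow = config$n_bins, ncol = length(cells),
                   dimnames = list(NULL, cells))
  shape <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (j in seq_along(cells)) {
    lid <- truth$cell_assignments[[cells[j]]]
    cn <- truth$lineages[[lid]]$true_profile
    set.seed(derive_seed(config$seed, paste0("counts:", cells[j])))
    p <- cn * gcf
    p <- p / sum(p)
    mu <- config$reads_per_cell_mean * p
    if (is.finite(shape)) {
      g <- rgamma(length(mu), shape = shape, rate = shape)
      counts[, j] <- rpois(length(mu), mu * g)
    } else {
      counts[, j] <- rpois(length(mu), mu)
    }
  }
  meta <- truth$cell_meta
  meta$total_reads <- colSums(counts)
  structure(list(counts = counts, cell_meta = meta, scaffold = scaffold),
            class = "sim_counts")
}

#' Run the generator end to end
#'
#' Convenience wrapper: [simulate_lineages()] then [profiles_to_counts()] on
#' the matching [sim_scaffold()].
#'
#' @param config a [sim_config()].
#' @return A list with `truth`, `scaffold`, and `sim` (the `sim_counts`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_lineages(config)
  scaffold <- sim_scaffold(config)
  sim <- profiles_to_counts(truth, scaffold, config)
  list(truth = truth, scaffold = scaffold, sim = sim)
}

#' Simulate planted clones with disjoint breakpoint signatures
#'
#' Controlled benchmark for clone calling: `n_clones` diploid clones, each
#' defined by `events_per_clone` hemizygous deletions (two breakpoints per
#' event) on its own private set of chromosomes, observed under the
#' configured noise model.  Signatures are disjoint across clones by
#' construction.
#'
#' @param config a [sim_config()]; `n_sp_cells` is overridden by
#'   `n_clones * cells_per_clone`.
#' @param n_clones number of clones (must not exceed the number of
#'   chromosomes divided by `events_per_clone`... chromosomes are dealt
#'   round-robin).
#' @param cells_per_clone cells sampled per clone.
#' @param events_per_clone deletions per clone signature (default 5, i.e.
#'   10 breakpoints).
#' @param event_bins deletion length in bins (default 30).
#' @return list with `truth` (a `truth_bundle`), `scaffold`, and `sim`
#'   (the `sim_counts`), as [simulate_dataset()].
#' @export
simulate_planted_clones <- function(config, n_clones = 2L,
                                    cells_per_clone = 30L,
                                    events_per_clone = 5L,
                                    event_bins = 30L) {
  cfg <- config
  cfg$n_dp_cells <- 0L
  cfg$n_sp_cells <- as.integer(n_clones * cells_per_clone)
  validate_sim_config(cfg)
  n_chrom <- length(cfg$chrom_lengths)
  if (n_clones * events_per_clone > n_chrom)
    stop_bad_input("not enough chromosomes for disjoint clone signatures")
  offsets <- cumsum(c(0L, unname(cfg$chrom_lengths)))
  set.seed(derive_seed(cfg$seed, "planted_clones"))
  flat <- rep(2L, cfg$n_bins)
  profiles <- list()
  for (cl in seq_len(n_clones)) {
    prof <- flat
    chroms <- seq(cl, by = n_clones, length.out = events_per_clone)
    for (k in chroms) {
      len <- cfg$chrom_lengths[k]
      size <- min(event_bins, len - 2L)
      start <- offsets[k] + sample.int(len - size - 1L, 1L)
      prof[(start + 1L):(start + size)] <- 1L
    }
    profiles[[sprintf("clone%02d", cl)]] <- prof
  }
  cells <- sprintf("cell_%03d", seq_len(cfg$n_sp_cells))
  asg <- setNames(rep(names(profiles), each = cells_per_clone), cells)
  truth <- truth_from_profiles(profiles, asg, cfg)
  scaffold <- sim_scaffold(cfg)
  list(truth = truth, scaffold = scaffold,
       sim = profiles_to_counts(truth, scaffold, cfg))
}
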