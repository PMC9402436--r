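# Breakpoint-coincidence clonal inference.
#
# Cells are compared by the coincidence of their copy-number change points:
# two cells sharing more breakpoints than expected by chance are likely
# clonally related.  Dissimilarity is the one-sided Fisher exact p-value for
# enrichment of shared breakpoints; cells are clustered hierarchically and
# tree nodes are accepted as clones when their FDR against a
# breakpoint-interchange permutation null does not exceed a threshold.

#' Extract a breakpoint matrix from integer copy-number profiles
#'
#' Boundary `b` (the junction between bin `b` and `b + 1`; chromosome-
#' terminal junctions are never eligible) is a change point for a cell when
#' the absolute copy-state difference across it is at least `min_delta`.
#' Change points within `tolerance` bins of one another across cells are
#' snapped to a common canonical boundary (union merge, leftmost
#' representative) so that the same event called with one bin of jitter in
#' different cells still registers as coincident.
#'
#' The boundary universe size `N` used by the Fisher test is the number of
#' eligible boundaries reduced by the merging (each merge group counts once).
#'
#' @param profiles a `cn_call_set` or list of `integer_cn_profile`s sharing
#'   one scaffold.
#' @param min_delta minimum absolute state change (default 1).
#' @param tolerance merge radius in bins (default 1).
#' @return A `breakpoint_matrix`: list with `matrix` (cells x canonical
#'   boundaries, 0/1), `canonical` (boundary indices), `n_boundaries` (N),
#'   `k` (per-cell breakpoint counts), `cells`, `tolerance`, `min_delta`.
#' @export
extract_breakpoints <- function(profiles, min_delta = 1L, tolerance = 1L) {
  if (inherits(profiles, "cn_call_set")) profiles <- profiles$profiles
  stopifnot(length(profiles) >= 1L)
  chrom <- profiles[[1]]$chrom
  for (p in profiles)
    if (!identical(p$chrom, chrom))
      stop_bad_input("profiles must share one scaffold")
  n <- length(chrom)
  ci <- match(chrom, unique(chrom))
  eligible <- which(ci[-n] == ci[-1])

  cells <- vapply(profiles, function(p) p$cell_id, "")
  raw <- lapply(profiles, function(p) {
    s <- p$states
    b <- which(abs(s[-n] - s[-1]) >= min_delta & ci[-n] == ci[-1])
    b
  })
  used <- sort(unique(unlist(raw)))
  if (length(used)) {
    gap <- c(Inf, diff(used))
    grp <- cumsum(gap > tolerance)
    canonical <- vapply(split(used, grp), min, 0L)
    names(canonical) <- NULL
    map <- setNames(rep(seq_along(canonical), tabulate(grp)), used)
    M <- matrix(0L, nrow = length(cells), ncol = length(canonical),
                dimnames = list(cells, NULL))
    for (i in seq_along(raw))
      if (length(raw[[i]])) M[i, unique(map[as.character(raw[[i]])])] <- 1L
    n_merged_away <- length(used) - length(canonical)
  } else {
    canonical <- integer()
    M <- matrix(0L, nrow = length(cells), ncol = 0L,
                dimnames = list(cells, NULL))
    n_merged_away <- 0L
  }
  structure(list(matrix = M, canonical = canonical,
                 n_boundaries = length(eligible) - n_merged_away,
                 k = rowSums(M), cells = cells,
                 tolerance = tolerance, min_delta = min_delta),
            class = "breakpoint_matrix")
}

#' @export
print.breakpoint_matrix <- function(x, ...) {
  cat(sprintf(
    "breakpoint_matrix: %d cells, %d canonical boundaries (N = %d)\n",
    length(x$cells), length(x$canonical), x$n_boundaries))
  invisible(x)
}

# one-sided Fisher (hypergeometric upper tail) for shared breakpoints
fisher_coincidence <- function(shared, ka, kb, N) {
  phyper(shared - 1, ka, N - ka, kb, lower.tail = FALSE)
}

#' Breakpoint-coincidence dissimilarity between two cells
#'
#' Builds the 2x2 table over the `N` boundaries -- shared, a-only, b-only,
#' neither -- and returns the one-sided Fisher exact p-value for enrichment
#' of shared change points (the hypergeometric upper tail).  Small values
#' mean similar cells.  A cell with no breakpoints carries no evidence of
#' relatedness: the value is 1 and a warning flag is attached.
#'
#' @param bp a `breakpoint_matrix`.
#' @param a,b cell ids or indices.
#' @return p-value in `[0, 1]`; attribute `no_evidence` is TRUE when either
#'   cell has zero breakpoints.
#' @export
pair_dissimilarity <- function(bp, a, b) {
  ia <- if (is.character(a)) match(a, bp$cells) else a
  ib <- if (is.character(b)) match(b, bp$cells) else b
  if (is.na(ia) || is.na(ib)) stop_bad_input("unknown cell id")
  ka <- bp$k[ia]; kb <- bp$k[ib]
  if (ka == 0L || kb == 0L)
    return(structure(1.0, no_evidence = TRUE))
  shared <- sum(bp$matrix[ia, ] & bp$matrix[ib, ])
  fisher_coincidence(shared, ka, kb, bp$n_boundaries)
}

#' All-pairs dissimilarity matrix
#'
#' @param bp a `breakpoint_matrix`.
#' @return symmetric cells x cells matrix of one-sided Fisher p-values;
#'   pairs involving a breakpoint-free cell are 1.
#' @export
dissimilarity_matrix <- function(bp) {
  M <- bp$matrix
  k <- bp$k
  N <- bp$n_boundaries
  shared <- M %*% t(M)
  nc <- length(k)
  ka <- matrix(k, nc, nc)
  kb <- t(ka)
  d <- matrix(fisher_coincidence(as.vector(shared), as.vector(ka),
                                 as.vector(kb), N), nc, nc)
  d[k == 0L, ] <- 1
  d[, k == 0L] <- 1
  dimnames(d) <- list(bp$cells, bp$cells)
  # exact symmetry (phyper is symmetric in (ka, kb) analytically; enforce
  # against floating asymmetry)
  (d + t(d)) / 2
}

#' Hierarchical clone tree from a dissimilarity matrix
#'
#' Agglomerative clustering with the configured linkage.  Cells are ordered
#' lexicographically before clustering so the result is invariant to input
#' order (tie-breaks fall to cell id).
#'
#' @param d symmetric dissimilarity matrix with cell-id dimnames.
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @return A `clone_tree` (unlabelled): list with `hclust`, `cells`,
#'   `linkage`, `d`.
#' @export
build_tree <- function(d, linkage = "average") {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop_bad_input("d must have cell-id dimnames")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop_bad_input("d must be symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(hclust = hc, cells = rownames(d), linkage = linkage, d = d),
            class = "clone_tree")
}

# member leaf indices per internal node of an hclust
hclust_members <- function(hc) {
  n <- length(hc$order) + 1L  # leaves = n, internal nodes = n - 1
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    m <- hc$merge[k, ]
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- c(get(m[1]), get(m[2]))
  }
  members
}

#' Permutation null of breakpoint-coincidence dissimilarities
#'
#' Each permutation randomly interchanges the pooled multiset of observed
#' change points among cells while preserving every cell's breakpoint count
#' exactly (duplicate assignments within a cell are resolved by swaps, so
#' row sums and the pooled multiset are both conserved), then recomputes all
#' pairwise dissimilarities.
#'
#' @param bp a `breakpoint_matrix`.
#' @param n_perm number of permutations (>= 100; default 500).
#' @param seed integer seed.
#' @return A `bp_null`: list with `values` (sorted pooled null
#'   dissimilarities over distinct pairs), `n_perm`, `n_pairs_per_perm`.
#' @export
permutation_null <- function(bp, n_perm = 500L, seed = 1L) {
  if (n_perm < 100L) stop_bad_input("n_perm must be at least 100")
  M <- bp$matrix
  nc <- nrow(M)
  ncol_m <- ncol(M)
  N <- bp$n_boundaries
  k <- bp$k
  set.seed(derive_seed(seed, "bp_null"))
  pool0 <- rep(seq_len(ncol_m), colSums(M))
  upper <- upper.tri(matrix(0, nc, nc))
  vals <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    toks <- permute_tokens(pool0, k, ncol_m)
    Mp <- matrix(0L, nc, ncol_m)
    for (i in seq_len(nc)) if (length(toks[[i]])) Mp[i, toks[[i]]] <- 1L
    shared <- Mp %*% t(Mp)
    d <- fisher_coincidence(shared[upper], matrix(k, nc, nc)[upper],
                            t(matrix(k, nc, nc))[upper], N)
    d[(matrix(k, nc, nc)[upper] == 0) | (t(matrix(k, nc, nc))[upper] == 0)] <- 1
    vals[[p]] <- d
  }
  structure(list(values = sort(unlist(vals)), n_perm = n_perm,
                 n_pairs_per_perm = sum(upper)),
            class = "bp_null")
}

# deal the pooled tokens to cells by count, then repair within-cell
# duplicates by swapping with other cells (preserves both per-cell counts
# and the pooled multiset)
permute_tokens <- function(pool, k, n_cols) {
  pool <- sample(pool)
  ends <- cumsum(k)
  starts <- c(1L, head(ends, -1L) + 1L)
  toks <- lapply(seq_along(k), function(i)
    if (k[i] == 0L) integer() else pool[starts[i]:ends[i]])
  nc <- length(toks)
  for (i in seq_len(nc)) {
    guard <- 0L
    repeat {
      dup <- which(duplicated(toks[[i]]))
      if (!length(dup)) break
      t_val <- toks[[i]][dup[1]]
      repaired <- FALSE
      for (o in sample(seq_len(nc)[-i])) {
        if (t_val %in% toks[[o]]) next
        cand <- which(!(toks[[o]] %in% toks[[i]]))
        if (length(cand)) {
          u_i <- cand[1]
          toks[[i]][dup[1]] <- toks[[o]][u_i]
          toks[[o]][u_i] <- t_val
          repaired <- TRUE
          break
        }
      }
      if (!repaired) {
        # no conserving swap exists; fall back to any unused column
        free <- setdiff(seq_len(n_cols), toks[[i]])
        toks[[i]][dup[1]] <- free[sample.int(length(free), 1L)]
      }
      guard <- guard + 1L
      if (guard > 10L * length(toks[[i]])) break
    }
  }
  toks
}

#' Call clones on a tree at an FDR threshold
#'
#' For each internal node at height `h`, the FDR is the expected count of
#' null pairwise dissimilarities at or below `h` per permutation (over all
#' cell pairs) divided by the observed count of within-node pairwise
#' dissimilarities at or below `h`, clipped to `[0, 1]`.  Counting the
#' null over all pairs controls the multiplicity across nodes: an isolated
#' lucky pair is expected about once per permutation and scores an FDR
#' near 1, while a clone's many coincident pairs are never reproduced by
#' the null.  Nodes with FDR at or below `t` are accepted;
#' clones are the maximal accepted nodes; cells outside every accepted node
#' are singletons (labelled by their own id).
#'
#' @param tree a `clone_tree` from [build_tree()].
#' @param null a `bp_null` from [permutation_null()].
#' @param t FDR threshold in (0, 1]; default 0.01.
#' @return The `clone_tree` with `nodes` (per-node height, size, fdr,
#'   accepted, is_clone), `assignments` (cell, clone, node_fdr), and `t`
#'   filled in.
#' @export
call_clones <- function(tree, null, t = 0.01) {
  stopifnot(inherits(tree, "clone_tree"), inherits(null, "bp_null"))
  if (!length(null$values)) stop_bad_input("null sample is empty")
  if (!(t > 0 && t <= 1)) stop_bad_input("'t' must be in (0, 1]")
  hc <- tree$hclust
  n <- length(tree$cells)
  members <- hclust_members(hc)
  d <- tree$d
  nv <- null$values

  n_nodes <- nrow(hc$merge)
  fdr <- numeric(n_nodes)
  for (kk in seq_len(n_nodes)) {
    # average-linkage heights coincide with pair dissimilarities up to
    # floating error; widen by a relative epsilon so ties count
    h <- hc$height[kk] * (1 + 1e-9) + 1e-300
    mem <- members[[kk]]
    dm <- d[mem, mem]
    obs <- sum(dm[upper.tri(dm)] <= h)
    # expected count of null pairs at or below h per permutation, over all
    # pairs: comparing it to the node's observed count controls the
    # multiplicity over nodes (a lone lucky pair scores FDR ~ 1)
    num <- findInterval(h, nv) / null$n_perm
    fdr[kk] <- if (obs == 0) 1 else min(1, max(0, num / obs))
  }
  accepted <- fdr <= t

  # maximal accepted nodes: walk down from the root, stop at accepted nodes
  is_clone <- rep(FALSE, n_nodes)
  walk <- function(node) {
    if (node < 0) return(invisible())  # singleton leaf
    if (accepted[node]) { is_clone[node] <<- TRUE; return(invisible()) }
    walk(hc$merge[node, 1]); walk(hc$merge[node, 2])
  }
  walk(n_nodes)

  clone <- setNames(tree$cells, tree$cells)  # singletons: own id
  node_fdr <- setNames(rep(NA_real_, n), tree$cells)
  clone_nodes <- which(is_clone)
  clone_nodes <- clone_nodes[order(-vapply(members[clone_nodes], length, 0L))]
  for (ci in seq_along(clone_nodes)) {
    mem <- tree$cells[members[[clone_nodes[ci]]]]
    clone[mem] <- sprintf("clone_%02d", ci)
    node_fdr[mem] <- fdr[clone_nodes[ci]]
  }
  tree$nodes <- data.frame(node = seq_len(n_nodes), height = hc$height,
                           size = vapply(members, length, 0L),
                           fdr = fdr, accepted = accepted,
                           is_clone = is_clone)
  tree$assignments <- data.frame(cell = tree$cells,
                                 clone = unname(clone[tree$cells]),
                                 node_fdr = unname(node_fdr[tree$cells]),
                                 stringsAsFactors = FALSE)
  tree$t <- t
  tree
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d cells, %s linkage\n",
              length(x$cells), x$linkage))
  if (!is.null(x$assignments)) {
    ncl <- length(unique(x$assignments$clone[grepl("^clone_",
                                                   x$assignments$clone)]))
    cat(sprintf("  %d clones at FDR <= %g; %d singleton cells\n", ncl, x$t,
                sum(!grepl("^clone_", x$assignments$clone))))
  }
  invisible(x)
}

#' Trace polyploid cells to rearranged diploid precursors
#'
#' For every polyploid cell, finds the diploid cell sharing the most
#' canonical breakpoints (ties broken by smaller dissimilarity, then by cell
#' id), reports the pair's one-sided Fisher dissimilarity, the fraction of
#' the polyploid cell's breakpoints inherited from the match, and whether
#' the link is statistically supported (`p <= t` and at least one shared
#' breakpoint).
#'
#' @param calls a `cn_call_set` (provides diploid/polyploid labels).
#' @param bp the `breakpoint_matrix` over the same cells.
#' @param tree optional labelled `clone_tree`; adds the precursor's clone.
#' @param t support threshold on the link p-value (default 0.01).
#' @return data.frame: polyploid_cell, precursor_cell, precursor_clone,
#'   shared_breakpoints, fraction_inherited, p_value, supported.
#' @export
trace_wgd_precursors <- function(calls, bp, tree = NULL, t = 0.01) {
  stopifnot(inherits(calls, "cn_call_set"),
            inherits(bp, "breakpoint_matrix"))
  rep_ <- calls$report[!is.na(calls$report$ploidy_label), ]
  lab <- setNames(rep_$ploidy_label, rep_$cell_id)
  poly <- intersect(bp$cells, names(lab)[lab == "polyploid"])
  dipl <- intersect(bp$cells, names(lab)[lab == "diploid"])
  empty <- data.frame(polyploid_cell = character(),
                      precursor_cell = character(),
                      precursor_clone = character(),
                      shared_breakpoints = integer(),
                      fraction_inherited = numeric(),
                      p_value = numeric(), supported = logical(),
                      stringsAsFactors = FALSE)
  if (!length(dipl)) {
    warning("no diploid cells present; no precursor links can be traced")
    return(empty)
  }
  if (!length(poly)) return(empty)
  M <- bp$matrix
  clone_of <- if (!is.null(tree) && !is.null(tree$assignments))
    setNames(tree$assignments$clone, tree$assignments$cell) else NULL
  rows <- lapply(poly, function(pc) {
    ip <- match(pc, bp$cells)
    shared <- as.vector(M[dipl, , drop = FALSE] %*% M[ip, ])
    best_shared <- max(shared)
    cand <- dipl[shared == best_shared]
    if (length(cand) > 1L) {
      pv <- vapply(cand, function(dc) as.numeric(pair_dissimilarity(bp, pc,
                                                                    dc)), 0)
      cand <- cand[order(pv, cand)]
    }
    dc <- cand[1]
    p <- as.numeric(pair_dissimilarity(bp, pc, dc))
    data.frame(polyploid_cell = pc, precursor_cell = dc,
               precursor_clone = if (!is.null(clone_of))
                 unname(clone_of[dc]) else NA_character_,
               shared_breakpoints = as.integer(best_shared),
               fraction_inherited = if (bp$k[ip] > 0)
                 best_shared / bp$k[ip] else 0,
               p_value = p,
               supported = best_shared > 0 && p <= t,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
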