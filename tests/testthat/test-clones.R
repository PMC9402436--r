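chrom20 <- rep(sprintf("chr%d", 1:4), each = 50)  # 200 bins, 4 chromosomes

test_that("breakpoint extraction: flat, single deletion, tolerance snap", {
  flat <- profile_stub("f", rep(2L, 200), chrom20)
  del <- rep(2L, 200)
  del[111:120] <- 1L  # 10-bin deletion inside chr3
  pd <- profile_stub("d", del, chrom20)
  bp <- extract_breakpoints(list(flat, pd))
  expect_equal(bp$k[["f"]], 0)
  expect_equal(bp$k[["d"]], 2)

  # left edges differing by one bin snap to one canonical boundary
  del2 <- rep(2L, 200)
  del2[112:120] <- 1L
  bp2 <- extract_breakpoints(list(profile_stub("a", del, chrom20),
                                  profile_stub("b", del2, chrom20)),
                             tolerance = 1)
  expect_equal(unname(bp2$matrix[, 1]), c(1L, 1L))
  expect_equal(sum(bp2$matrix[1, ] & bp2$matrix[2, ]), 2L)
})

test_that("chromosome-terminal state changes are not breakpoints", {
  x <- rep(c(2L, 3L), each = 100)  # change exactly at the chr2/chr3 junction
  bp <- extract_breakpoints(list(profile_stub("x", x, chrom20)))
  expect_equal(bp$k[["x"]], 0)
})

test_that("mixed scaffolds are rejected", {
  a <- profile_stub("a", rep(2L, 200), chrom20)
  b <- profile_stub("b", rep(2L, 200), rep("chrZ", 200))
  expect_error(extract_breakpoints(list(a, b)), "share one scaffold")
})

test_that("Fisher dissimilarity matches the quoted worked example", {
  # N = 20, both cells with breakpoints {3, 7}: p = 1 / C(20, 2)
  M <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), NULL))
  M[] <- 1L
  bp <- structure(list(matrix = M, canonical = c(3L, 7L), n_boundaries = 20L,
                       k = setNames(c(2, 2), c("a", "b")),
                       cells = c("a", "b"), tolerance = 1L, min_delta = 1L),
                  class = "breakpoint_matrix")
  expect_equal(pair_dissimilarity(bp, "a", "b"), 1 / 190, tolerance = 1e-12)
})

test_that("disjoint singletons give p = 1 and empty cells carry no evidence", {
  M <- matrix(c(1L, 0L, 0L, 1L, 0L, 0L), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "z"), NULL))
  bp <- structure(list(matrix = M, canonical = c(3L, 7L), n_boundaries = 20L,
                       k = setNames(c(1, 1, 0), c("a", "b", "z")),
                       cells = c("a", "b", "z"), tolerance = 1L,
                       min_delta = 1L),
                  class = "breakpoint_matrix")
  expect_equal(as.numeric(pair_dissimilarity(bp, "a", "b")), 1.0)
  pz <- pair_dissimilarity(bp, "a", "z")
  expect_equal(as.numeric(pz), 1.0)
  expect_true(attr(pz, "no_evidence"))
})

test_that("Fisher p agrees with tail enumeration on all tables with N <= 30", {
  for (N in c(5L, 12L, 30L)) {
    for (ka in c(1L, 3L, min(7L, N))) {
      for (kb in c(2L, min(5L, N))) {
        for (s in 0:min(ka, kb)) {
          expect_equal(cnaphase:::fisher_coincidence(s, ka, kb, N),
                       hyper_tail_oracle(s, ka, kb, N), tolerance = 1e-12,
                       label = sprintf("N=%d ka=%d kb=%d s=%d", N, ka, kb, s))
        }
      }
    }
  }
})

test_that("p decreases as the shared count grows (fixed margins)", {
  p <- vapply(0:5, cnaphase:::fisher_coincidence, 0, ka = 5L, kb = 8L,
              N = 100L)
  expect_true(all(diff(p) < 0))
  # identical sets attain the minimum over tables with those margins
  expect_equal(which.min(p), 6L)
})

test_that("tree building: basic merges and input-order invariance", {
  d2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- build_tree(d2)
  expect_equal(length(t2$cells), 2L)

  d3 <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d3) <- 0
  d3["a", "b"] <- d3["b", "a"] <- 1e-6
  t3 <- build_tree(d3)
  first <- sort(t3$cells[cnaphase:::hclust_members(t3$hclust)[[1]]])
  expect_equal(first, c("a", "b"))

  set.seed(3)
  n <- 12
  dd <- matrix(runif(n * n), n, n)
  dd <- (dd + t(dd)) / 2
  diag(dd) <- 0
  dimnames(dd) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
  ref <- build_tree(dd)
  for (r in 1:20) {
    perm <- sample(n)
    tp <- build_tree(dd[perm, perm])
    expect_identical(tp$hclust$merge, ref$hclust$merge)
    expect_equal(tp$hclust$height, ref$hclust$height)
  }
  expect_error(build_tree(matrix(c(0, 1, 2, 0), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

random_bp <- function(n_cells, n_cols, k, N, seed) {
  set.seed(seed)
  cells <- sprintf("c%02d", seq_len(n_cells))
  M <- t(vapply(cells, function(cc) {
    v <- integer(n_cols)
    v[sample.int(n_cols, k)] <- 1L
    v
  }, integer(n_cols)))
  rownames(M) <- cells
  structure(list(matrix = M, canonical = seq_len(n_cols), n_boundaries = N,
                 k = rowSums(M), cells = cells, tolerance = 1L,
                 min_delta = 1L),
            class = "breakpoint_matrix")
}

test_that("permutation null preserves per-cell counts and the pooled total", {
  bp <- random_bp(20, 40, 6, 400, seed = 9)
  set.seed(derive_seed(1L, "bp_null"))
  pool <- rep(seq_len(40), colSums(bp$matrix))
  for (r in 1:20) {
    toks <- cnaphase:::permute_tokens(pool, bp$k, 40L)
    expect_equal(lengths(toks), unname(bp$k))
    expect_true(all(vapply(toks, anyDuplicated, 0L) == 0L))
    expect_equal(sort(unlist(toks)), sort(pool))
  }
})

test_that("the null reproduces itself under a fixed seed", {
  bp <- random_bp(10, 30, 5, 200, seed = 4)
  a <- permutation_null(bp, 120, seed = 8)
  b <- permutation_null(bp, 120, seed = 8)
  expect_identical(a$values, b$values)
  expect_error(permutation_null(bp, 50), "at least 100")
})

test_that("independent random breakpoints are distributed like the null", {
  bp <- random_bp(50, 120, 8, 500, seed = 21)
  d <- dissimilarity_matrix(bp)
  obs <- d[upper.tri(d)]
  null <- permutation_null(bp, 200, seed = 22)
  ks <- suppressWarnings(ks.test(obs, null$values))
  expect_gt(ks$p.value, 0.01)
})

test_that("clone calling: threshold extremes and null calibration", {
  bp <- random_bp(24, 60, 6, 300, seed = 31)
  d <- dissimilarity_matrix(bp)
  tree <- build_tree(d)
  null <- permutation_null(bp, 200, seed = 32)
  # t = 1 accepts the root: one clone containing every cell
  t1 <- call_clones(tree, null, t = 1.0)
  expect_equal(unique(t1$assignments$clone), "clone_01")
  # independent random breakpoints: no clone at t = 0.01 in most replicates
  reject <- 0L
  for (r in 1:10) {
    bpr <- random_bp(20, 60, 6, 300, seed = 100 + r)
    dr <- dissimilarity_matrix(bpr)
    nr <- permutation_null(bpr, 150, seed = 200 + r)
    cr <- call_clones(build_tree(dr), nr, t = 0.01)
    if (!any(cr$nodes$is_clone)) reject <- reject + 1L
  }
  expect_gte(reject, 9L)
})

test_that("two planted clones are recovered as two clone labels", {
  set.seed(51)
  n_cols <- 24
  cells <- sprintf("c%02d", 1:40)
  M <- matrix(0L, 40, n_cols, dimnames = list(cells, NULL))
  M[1:20, 1:10] <- 1L   # clone A signature
  M[21:40, 11:20] <- 1L # clone B signature, disjoint
  # sprinkle private noise breakpoints
  for (i in 1:40) M[i, sample(21:24, 1)] <- 1L
  bp <- structure(list(matrix = M, canonical = seq_len(n_cols),
                       n_boundaries = 4000L, k = rowSums(M), cells = cells,
                       tolerance = 1L, min_delta = 1L),
                  class = "breakpoint_matrix")
  d <- dissimilarity_matrix(bp)
  tree <- call_clones(build_tree(d), permutation_null(bp, 300, seed = 52),
                      t = 0.01)
  asg <- tree$assignments
  truth <- rep(c("A", "B"), each = 20)
  expect_equal(length(unique(grep("^clone", asg$clone, value = TRUE))), 2L)
  expect_equal(ari(asg$clone, truth), 1.0)
  expect_true(all(tree$nodes$fdr[tree$nodes$is_clone] <= 0.01))
})

test_that("WGD precursor tracing finds the matching diploid cell", {
  del <- rep(2L, 200)
  del[21:60] <- 1L
  poly <- del * 2L
  poly[151:170] <- 5L
  profs <- list(profile_stub("dip1", del, chrom20),
                profile_stub("dip2", rep(c(2L, 1L), c(150, 50)), chrom20),
                profile_stub("tet1", poly, chrom20))
  bp <- extract_breakpoints(profs)
  calls <- structure(list(
    profiles = profs,
    report = data.frame(cell_id = c("dip1", "dip2", "tet1"),
                        ploidy_label = c("diploid", "diploid", "polyploid"),
                        stringsAsFactors = FALSE)),
    class = "cn_call_set")
  links <- trace_wgd_precursors(calls, bp)
  expect_equal(links$precursor_cell, "dip1")
  expect_true(links$supported)
  expect_equal(links$shared_breakpoints, 2L)

  # no shared breakpoints: link unsupported
  lonely <- rep(2L, 200)
  lonely[101:110] <- 5L
  profs2 <- list(profile_stub("dip1", del, chrom20),
                 profile_stub("tet2", lonely, chrom20))
  calls2 <- structure(list(
    profiles = profs2,
    report = data.frame(cell_id = c("dip1", "tet2"),
                        ploidy_label = c("diploid", "polyploid"),
                        stringsAsFactors = FALSE)),
    class = "cn_call_set")
  links2 <- trace_wgd_precursors(calls2, extract_breakpoints(profs2))
  expect_false(links2$supported)

  # no diploid cells at all: empty result with a warning
  calls3 <- structure(list(
    profiles = profs2[2],
    report = data.frame(cell_id = "tet2", ploidy_label = "polyploid",
                        stringsAsFactors = FALSE)),
    class = "cn_call_set")
  expect_warning(l3 <- trace_wgd_precursors(calls3,
                                            extract_breakpoints(profs2[2])),
                 "no diploid")
  expect_equal(nrow(l3), 0L)
})
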