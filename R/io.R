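# Readers and writers for the pipeline's plain-text formats.
#
# Conventions: TSV with header throughout; BED is 0-based half-open; SEG is
# 1-based inclusive (start = BED start + 1); trees are Newick; configuration
# and reports are JSON.  Every writer's file parses back to equal in-memory
# values with the paired reader.

# field-count validation with file/line diagnostics
check_tsv <- function(path) {
  if (!file.exists(path)) stop_bad_input(sprintf("file not found: %s", path))
  fc <- count.fields(path, sep = "\t", quote = "")
  bad <- which(fc != fc[1])
  if (length(bad))
    stop_bad_input(sprintf(
      "malformed TSV %s: line %d has %d fields, expected %d",
      path, bad[1], fc[bad[1]], fc[1]))
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' @param path TSV with columns `chrom` and `length`.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  check_tsv(path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(df)))
    stop_bad_input(sprintf(
      "%s: expected columns 'chrom' and 'length'", path))
  if (any(df$length <= 0))
    stop_bad_input(sprintf("%s: line %d: non-positive chromosome length",
                           path, which(df$length <= 0)[1] + 1L))
  setNames(as.numeric(df$length), df$chrom)
}

#' Write / read a bin-count matrix with its scaffold
#'
#' Rows are bins (`chrom`, `start`, `end`, `gc`, then one column per cell).
#'
#' @param counts bins x cells matrix (or a `sim_counts`).
#' @param scaffold the `bin_scaffold` (taken from a `sim_counts` if given).
#' @param path output TSV path.
#' @return `write_counts_tsv`: the path, invisibly.  `read_counts_tsv`: list
#'   with `counts` (integer matrix) and `scaffold`.
#' @export
write_counts_tsv <- function(counts, scaffold = NULL, path) {
  if (inherits(counts, "sim_counts")) {
    scaffold <- counts$scaffold
    counts <- counts$counts
  }
  df <- cbind(as.data.frame(scaffold)[c("chrom", "start", "end", "gc")],
              as.data.frame(counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  check_tsv(path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "gc")
  if (!all(need %in% names(df)))
    stop_bad_input(sprintf("%s: expected scaffold columns %s", path,
                           paste(need, collapse = ", ")))
  sc <- df[need]
  class(sc) <- c("bin_scaffold", "data.frame")
  counts <- as.matrix(df[setdiff(names(df), need)])
  storage.mode(counts) <- "integer"
  rownames(counts) <- NULL
  list(counts = counts, scaffold = sc)
}

#' Write / read an integer copy-number matrix
#'
#' @param cn_mat bins x cells integer matrix.
#' @param scaffold the `bin_scaffold`.
#' @param path TSV path.
#' @return reader: list with `cn` matrix and `scaffold`.
#' @export
write_cn_tsv <- function(cn_mat, scaffold, path) {
  df <- cbind(as.data.frame(scaffold)[c("chrom", "start", "end")],
              as.data.frame(cn_mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_tsv
#' @export
read_cn_tsv <- function(path) {
  check_tsv(path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end")
  cn <- as.matrix(df[setdiff(names(df), need)])
  storage.mode(cn) <- "integer"
  rownames(cn) <- NULL
  list(cn = cn, scaffold = df[need])
}

#' Write / read per-cell segments in SEG dialect
#'
#' SEG rows are 1-based inclusive in genomic coordinates
#' (`loc.start = BED start + 1`).
#'
#' @param calls a `cn_call_set`.
#' @param scaffold the `bin_scaffold` used for profiling.
#' @param path output path.
#' @return reader: data.frame sample, chrom, loc.start, loc.end, num.bins,
#'   seg.mean.
#' @export
write_seg <- function(calls, scaffold, path) {
  rows <- lapply(calls$profiles, function(p) {
    s <- p$segments
    data.frame(sample = p$cell_id, chrom = s$chrom,
               loc.start = scaffold$start[s$start_bin + 1L] + 1L,
               loc.end = scaffold$end[s$end_bin],
               num.bins = s$n_bins, seg.mean = s$mean_ratio,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  check_tsv(path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "loc.start", "loc.end", "num.bins",
            "seg.mean")
  if (!all(need %in% names(df)))
    stop_bad_input(sprintf("%s: not a SEG table (need %s)", path,
                           paste(need, collapse = ", ")))
  df
}

#' Write / read CNA events as BED
#'
#' BED is 0-based half-open in genomic coordinates; `name` holds the event
#' class, `score` the integer state.
#'
#' @param events event data.frame in bin coordinates.
#' @param scaffold the `bin_scaffold` (maps bins to genomic coordinates).
#' @param path output path.
#' @return reader: events data.frame in bin coordinates (requires the same
#'   scaffold).
#' @export
write_events_bed <- function(events, scaffold, path) {
  df <- data.frame(chrom = events$chrom,
                   start = scaffold$start[events$start_bin + 1L],
                   end = scaffold$end[events$end_bin],
                   name = paste(events$cell_id, events$class, sep = ":"),
                   score = events$state, strand = ".",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_events_bed
#' @export
read_events_bed <- function(path, scaffold) {
  check_tsv(path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"))
  nm <- strsplit(df$name, ":", fixed = TRUE)
  data.frame(cell_id = vapply(nm, `[`, "", 1L),
             chrom = df$chrom,
             start_bin = match(paste(df$chrom, df$start),
                               paste(scaffold$chrom, scaffold$start)) - 1L,
             end_bin = match(paste(df$chrom, df$end),
                             paste(scaffold$chrom, scaffold$end)),
             state = as.integer(df$score),
             class = vapply(nm, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Export a clone tree as Newick
#'
#' Branch lengths are node heights (dissimilarity scale).
#'
#' @param tree a `clone_tree`.
#' @param path output path.
#' @return the path, invisibly; `read_newick` returns an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a generic data.frame TSV (round-trips with [read_tsv_table()])
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  check_tsv(path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the ground-truth record of a simulation as JSON
#'
#' @param truth a `truth_bundle`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  lin <- lapply(truth$lineages, function(l)
    list(lineage_id = l$lineage_id, parent_id = l$parent_id,
         founder_id = l$founder_id, phase_label = l$phase_label,
         is_polyploid = l$is_polyploid,
         breakpoint_set = l$breakpoint_set,
         founder_loh_breakpoints = l$founder_loh_breakpoints,
         true_profile = l$true_profile))
  jsonlite::write_json(
    list(lineages = lin,
         cell_assignments = as.list(truth$cell_assignments),
         events = truth$events, loh_chrom = truth$loh_chrom,
         p53_bin = truth$p53_bin),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
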