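# Internal helpers: seed derivation, validation, run-length utilities.

#' Derive a child random seed from a root seed and a string key
#'
#' One root seed governs a whole run; every stochastic sub-step draws its own
#' stream from a stable hash of a descriptive key, so adding cells (or
#' reordering stages) never perturbs the stream of an existing one.
#'
#' @param seed integer root seed.
#' @param key character scalar naming the stream (e.g. a cell id).
#' @return An integer in `[0, 2^31 - 2]`, stable across sessions.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% m
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_input <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_bad_input(sprintf("'%s' must be a single value in [0, 1]", name))
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok)
    stop_bad_input(sprintf("'%s' must be %s", name,
                           if (strict) "positive" else "non-negative"))
  invisible(x)
}

# maximal runs of constant value within each chromosome; returns a data.frame
# with chrom, start_bin, end_bin (0-based half-open in bin units), value
constant_runs <- function(values, chrom) {
  stopifnot(length(values) == length(chrom))
  if (length(values) == 0L)
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), value = numeric()))
  brk <- c(TRUE, values[-1] != values[-length(values)] |
                   chrom[-1] != chrom[-length(chrom)])
  id <- cumsum(brk)
  start <- which(brk)
  end <- c(start[-1], length(values) + 1L)
  data.frame(chrom = chrom[start], start_bin = start - 1L,
             end_bin = end - 1L, value = values[start],
             stringsAsFactors = FALSE)
}
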