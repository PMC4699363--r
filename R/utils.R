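# Internal helpers shared across modules.

# Derived RNG streams: one root seed, fixed offsets per sub-simulator, so
# adding a simulator never perturbs the draws of another.  Offsets are kept
# small so seed + offset stays far below .Machine$integer.max for any sane
# root seed.
.STREAM_OFFSETS <- c(
  genome   = 101L,
  meth     = 211L,
  signal   = 307L,
  hic_WT   = 401L,
  hic_TKO  = 409L,
  de       = 503L,
  analysis = 601L
)

stream_seed <- function(seed, stream) {
  off <- .STREAM_OFFSETS[[stream]]
  if (is.null(off)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

# Interval midpoint under the 0-based half-open convention.
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

# data.frame of chrom/start/end -> GRanges (kept 0-based by shifting,
# converted back on exit by the callers that need coordinates).
as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Midpoint-containment lookup: index of the row in `regions` whose interval
# contains the midpoint of each row of `sites`; NA where none does.
midpoint_assign <- function(sites, regions) {
  mid <- interval_midpoint(sites$start, sites$end)
  gr_mid <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = mid + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(gr_mid, as_gr(regions), select = "first")
  as.integer(hits)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("parameter '", name, "' must be a proportion in [0, 1]", call. = FALSE)
  x
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || (strict && x <= 0) ||
      (!strict && x < 0))
    stop("parameter '", name, "' must be ",
         if (strict) "positive" else "non-negative", call. = FALSE)
  x
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x))
    stop("parameter '", name, "' must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}
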