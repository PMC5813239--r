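# Internal helpers shared across modules. Intervals are 0-based half-open
# [start, end) everywhere inside the package; conversion to/from the 1-based
# closed convention happens only at GTF/SAM/GRanges boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Stochastic stages (simulation, subsampling) each draw their own seed from
#' the master seed so that stages are independently reproducible and adding a
#' stage does not perturb the random streams of the others. Values stay below
#' 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed master integer seed
#' @param k integer stage/sample offset
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919 + 1) %% 2147483587)
}

# data.table of 0-based intervals -> GRanges (1-based closed)
dt_to_gr <- function(dt, seqlengths = NULL) {
  args <- list(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if ("strand" %in% names(dt)) dt$strand else "*"
  )
  if (!is.null(seqlengths)) args$seqlengths <- seqlengths
  do.call(GenomicRanges::GRanges, args)
}

# Merge overlapping or book-ended 0-based intervals within groups.
# dt must have columns start, end; `by` names grouping columns.
merge_intervals <- function(dt, by) {
  stopifnot(all(c("start", "end") %in% names(dt)))
  if (!nrow(dt)) return(data.table::copy(dt))
  d <- data.table::copy(dt)
  data.table::setorderv(d, c(by, "start", "end"))
  d[, .grp := cumsum(start > c(-Inf, cummax(end)[-.N])), by = by]
  out <- d[, .(start = min(start), end = max(end)), by = c(by, ".grp")]
  out[, .grp := NULL]
  out[]
}

# Sum of interval lengths after merging, per group.
interval_union_length <- function(dt, by) {
  m <- merge_intervals(dt, by)
  m[, .(union_length = sum(end - start)), by = by]
}
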