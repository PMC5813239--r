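# Read-level depth normalization: all retained samples are brought to a
# common fragment depth by seeded fragment-wise subsampling (mates are kept
# or dropped together), prior to any quantification. Coverage computed
# downstream on the normalized files is the study's "normalized average
# coverage" unit; no further per-gene scaling is applied.

#' Count fragments in a SAM file
#'
#' A fragment is a distinct QNAME among mapped, primary alignment records.
#'
#' @param path SAM path
#' @return integer fragment count
#' @export
count_sam_fragments <- function(path) {
  length(unique(sam_record_qnames(path)))
}

# QNAMEs of primary mapped records, in file order.
sam_record_qnames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[!startsWith(lines, "@")]
  if (!length(rec)) return(character())
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1:2)
  flag <- as.integer(f[[2]])
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  f[[1]][keep]
}

#' Plan read-level depth normalization
#'
#' The target depth is the minimum fragment depth across samples (optionally
#' overridden downwards); each sample is then subsampled exactly to it.
#'
#' @param depths named integer vector or list: sample -> fragment count
#' @param seed integer seed driving the per-sample subsampling streams
#' @param target_depth optional override; must be <= min(depths)
#' @return an object of class `norm_plan`: per-sample table with input depth,
#'   keep probability and planned kept depth
#' @export
plan_normalization <- function(depths, seed, target_depth = NULL) {
  depths <- unlist(depths)
  if (!length(depths)) stop("empty sample set")
  if (is.null(names(depths)) || any(!nzchar(names(depths))))
    stop("depths must be named by sample")
  if (any(depths <= 0)) stop("all sample depths must be > 0")
  target <- as.integer(target_depth %||% min(depths))
  if (target > min(depths))
    stop("target_depth exceeds the minimum sample depth")
  plan <- data.table::data.table(
    sample = names(depths),
    input_depth = as.integer(depths),
    keep_prob = target / as.numeric(depths),
    kept_depth = target)
  structure(list(samples = plan, target_depth = target,
                 seed = as.integer(seed)),
            class = "norm_plan")
}

#' @export
print.norm_plan <- function(x, ...) {
  cat("norm_plan: target depth", x$target_depth, "fragments across",
      nrow(x$samples), "samples (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Subsample a SAM file to the planned fragment depth
#'
#' Selects exactly `target_depth` fragments without replacement under a
#' seeded stream derived from the plan seed and the sample's position in the
#' plan, keeping both mates of every selected fragment and preserving the
#' input record order (so a coordinate-sorted input stays sorted). Orphaned
#' records (QNAMEs without exactly two primary mapped records) are dropped
#' with a warning before sampling.
#'
#' @param in_path input SAM path
#' @param plan a [plan_normalization()] result
#' @param sample_id sample name (must be present in the plan)
#' @param out_path output SAM path
#' @return `out_path`, invisibly
#' @export
subsample_sam <- function(in_path, plan, sample_id,
                          out_path = sub("\\.sam$", ".norm.sam", in_path)) {
  stopifnot(inherits(plan, "norm_plan"))
  k <- match(sample_id, plan$samples$sample)
  if (is.na(k)) stop("sample ", sample_id, " absent from normalization plan")

  lines <- readLines(in_path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  rec <- lines[!is_hdr]
  qn <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1L)[[1]]
  tab <- table(qn)
  orphan <- names(tab)[tab != 2L]
  if (length(orphan)) {
    warning(length(orphan), " orphaned fragment(s) dropped in ", sample_id)
    keep_rec <- !(qn %in% orphan)
    rec <- rec[keep_rec]
    qn <- qn[keep_rec]
  }
  frags <- unique(qn)
  target <- plan$target_depth
  if (target > length(frags))
    stop("sample ", sample_id, " has fewer intact fragments (", length(frags),
         ") than the target depth (", target, ")")
  if (target == length(frags)) {
    chosen <- frags
  } else {
    set.seed(derive_seed(plan$seed, 1000L + k))
    chosen <- sample(frags, target)
  }
  out <- c(lines[is_hdr], rec[qn %in% chosen])
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(out_path)
}

#' Normalize a set of SAM files to common depth
#'
#' Convenience wrapper: counts fragments, plans, and subsamples every sample
#' into `out_dir`.
#'
#' @param sam_paths named character vector: sample -> SAM path
#' @param seed integer seed
#' @param out_dir output directory
#' @param target_depth optional override passed to [plan_normalization()]
#' @return list: `plan`, `sam` (named normalized paths)
#' @export
normalize_samples <- function(sam_paths, seed, out_dir,
                              target_depth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  depths <- vapply(sam_paths, count_sam_fragments, integer(1))
  plan <- plan_normalization(depths, seed, target_depth)
  out <- vapply(names(sam_paths), function(s) {
    subsample_sam(sam_paths[[s]], plan, s,
                  file.path(out_dir, paste0(s, ".norm.sam")))
  }, character(1))
  list(plan = plan, sam = out)
}
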