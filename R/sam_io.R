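# Minimal SAM text writer used by the simulator and the subsampler.
# Reading goes through Rsamtools/GenomicAlignments (see quant.R); writing is
# done here because no installed R package emits SAM text directly.

#' Write alignment records as a coordinate-sorted SAM file
#'
#' @param records data.table with columns qname, flag, chrom, pos (1-based),
#'   mapq, cigar, rnext, pnext, tlen, seq, qual
#' @param layout a [genome_layout()] providing the `@SQ` header lines
#' @param path output path
#' @param sort sort records by (chrom in layout order, pos) before writing
#' @return `path`, invisibly
#' @export
write_sam <- function(records, layout, path, sort = TRUE) {
  stopifnot(inherits(layout, "genome_layout"))
  r <- data.table::as.data.table(records)
  if (sort && nrow(r)) {
    r[, .chr_ord := match(chrom, layout$chrom_names)]
    if (anyNA(r$.chr_ord)) stop("record on contig absent from layout")
    data.table::setorder(r, .chr_ord, pos, qname, flag)
    r[, .chr_ord := NULL]
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom_names,
                   layout$chrom_lengths[layout$chrom_names]))
  body <- if (nrow(r)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
            r$rnext, r$pnext, r$tlen, r$seq, r$qual)
  } else character()
  con <- file(path, open = "wb")  # binary mode: fixed "\n", byte-stable
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

# CIGAR string from genomically sorted 0-based blocks of one read.
blocks_to_cigar <- function(starts, ends) {
  m <- ends - starts
  if (length(starts) == 1L) return(sprintf("%dM", m))
  n <- starts[-1L] - ends[-length(ends)]
  paste0(paste0(m[-length(m)], "M", n, "N", collapse = ""),
         m[length(m)], "M")
}
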