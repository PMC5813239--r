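# Core computation: classify each normalized fragment, per gene, as sense
# (consistent with an annotated splice form on the gene's strand) or
# anti-sense-exonic (consistent with a reversed splice form: exon-contained
# and junction-respecting on the opposite strand), and produce count tables,
# normalized average coverage, and strand-split coverage tracks.

#' Reconstruct fragments from a SAM file
#'
#' Reads primary mapped alignments (via Rsamtools/GenomicAlignments), pools
#' each QNAME's mates into one fragment: merged aligned blocks, splice
#' junctions from `N` CIGAR operations, and the transcription strand inferred
#' from FLAG bits under the declared library protocol (firststrand: read 2
#' carries the transcript strand; secondstrand: read 1; unstranded: unknown).
#'
#' @param sam_path SAM (or BAM) path, coordinate-sorted with mate information
#' @param protocol `"firststrand"`, `"secondstrand"` or `"unstranded"`
#' @return an object of class `fragment_set`: `fragments` (data.table: fid,
#'   qname, chrom, strand, start, end, nblocks, njunc), `blocks` (fid, start,
#'   end; merged, disjoint, 0-based half-open), `junctions` (fid, donor,
#'   acceptor; 0-based donor = end of upstream exonic block)
#' @export
reconstruct_fragments <- function(sam_path,
                                  protocol = c("firststrand", "secondstrand",
                                               "unstranded")) {
  protocol <- match.arg(protocol)
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path)) {
    bam <- Rsamtools::asBam(sam_path, tempfile("frag"),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "flag")
  ga <- GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
  qn <- names(ga)
  n_reads <- length(ga)
  if (!n_reads) {
    empty <- data.table::data.table(fid = integer(), qname = character(),
                                    chrom = character(), strand = character(),
                                    start = integer(), end = integer(),
                                    nblocks = integer(), njunc = integer())
    return(structure(list(fragments = empty,
                          blocks = data.table::data.table(fid = integer(),
                                                          start = integer(),
                                                          end = integer()),
                          junctions = data.table::data.table(fid = integer(),
                                                             donor = integer(),
                                                             acceptor = integer()),
                          protocol = protocol),
                     class = "fragment_set"))
  }
  flag <- S4Vectors::mcols(ga)$flag
  fid <- match(qn, unique(qn))
  is_read2 <- bitwAnd(flag, 0x80L) > 0L
  rstrand <- as.character(GenomicAlignments::strand(ga))
  rchrom <- as.character(GenomicAlignments::seqnames(ga))

  reads <- data.table::data.table(fid = fid, qname = qn, chrom = rchrom,
                                  rstrand = rstrand, is_read2 = is_read2)

  # per-read aligned blocks (N-aware) and junctions
  bl_grl <- GenomicAlignments::grglist(ga)
  nb <- S4Vectors::elementNROWS(bl_grl)
  bl_flat <- unlist(bl_grl, use.names = FALSE)
  blocks <- data.table::data.table(
    fid = rep(fid, nb),
    start = GenomicRanges::start(bl_flat) - 1L,
    end = GenomicRanges::end(bl_flat))
  jn_grl <- GenomicAlignments::junctions(ga)
  nj <- S4Vectors::elementNROWS(jn_grl)
  jn_flat <- unlist(jn_grl, use.names = FALSE)
  juncs <- unique(data.table::data.table(
    fid = rep(fid, nj),
    donor = GenomicRanges::start(jn_flat) - 1L,
    acceptor = GenomicRanges::end(jn_flat)))

  # fragment-level strand under the protocol
  strand_of <- function(r2_strand, r1_strand) {
    # one of the two is NA for orphan fragments
    ifelse(!is.na(r2_strand), r2_strand,
           ifelse(r1_strand == "+", "-", "+"))
  }
  per <- reads[, .(
    chrom = if (data.table::uniqueN(chrom) == 1L) chrom[1] else NA_character_,
    r2 = rstrand[is_read2][1], r1 = rstrand[!is_read2][1],
    qname = qname[1]), by = fid]
  per[, strand := switch(protocol,
    firststrand = strand_of(r2, r1),
    secondstrand = strand_of(r1, r2),
    unstranded = "*")]

  blocks <- merge_intervals(blocks, by = "fid")
  data.table::setorder(blocks, fid, start)
  span <- blocks[, .(start = min(start), end = max(end), nblocks = .N),
                 by = fid]
  njc <- juncs[, .(njunc = .N), by = fid]
  fr <- merge(per[, .(fid, qname, chrom, strand)], span, by = "fid")
  fr <- merge(fr, njc, by = "fid", all.x = TRUE)
  fr[is.na(njunc), njunc := 0L]
  data.table::setorder(fr, fid)
  structure(list(fragments = fr, blocks = blocks, junctions = juncs,
                 protocol = protocol),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "fragments (",
      x$protocol, "protocol )\n")
  invisible(x)
}

# Structurally compatible (fragment, transcript) pairs among candidates.
# cand: data.table(fid, transcript_id). Returns the compatible subset.
# Compatibility: every merged block contained in some exon of the transcript,
# every fragment junction an annotated junction of the transcript, and (when
# strict_span) every transcript junction internal to the fragment span
# observed in the fragment (no exon-skipping mismatch; junctions falling in
# an unsequenced inner-mate gap then disqualify the pair).
compatible_pairs <- function(frags, index, cand, strict_span = TRUE) {
  if (!nrow(cand)) return(cand[0])
  ex <- index$exons[, .(transcript_id, estart = start, eend = end)]
  jn <- index$junctions[, .(transcript_id, donor, acceptor)]
  fr <- frags$fragments

  bl <- merge(frags$blocks, cand, by = "fid", allow.cartesian = TRUE)
  bl[, `:=`(bstart = start, bend = end)]
  hit <- ex[bl, on = .(transcript_id, estart <= bstart, eend >= bend),
            nomatch = 0L, .(fid = i.fid, transcript_id = i.transcript_id)]
  ok1 <- hit[, .(ncont = .N), by = .(fid, transcript_id)]
  ok1 <- merge(ok1, fr[, .(fid, nblocks)], by = "fid")
  ok1 <- ok1[ncont == nblocks, .(fid, transcript_id)]
  if (!nrow(ok1)) return(ok1)

  fj <- merge(frags$junctions, ok1, by = "fid", allow.cartesian = TRUE)
  if (nrow(fj)) {
    fj[, matched := !is.na(jn[fj, on = .(transcript_id, donor, acceptor),
                              which = TRUE])]
    bad <- fj[matched == FALSE, unique(paste(fid, transcript_id))]
    ok2 <- ok1[!paste(fid, transcript_id) %in% bad]
  } else ok2 <- ok1
  if (!nrow(ok2) || !isTRUE(strict_span)) return(ok2)

  sp <- merge(ok2, fr[, .(fid, fstart = start, fend = end)], by = "fid")
  intj <- jn[sp, on = .(transcript_id), nomatch = 0L, allow.cartesian = TRUE,
             .(fid, transcript_id, donor = x.donor, acceptor = x.acceptor,
               fstart, fend)]
  intj <- intj[donor > fstart & acceptor < fend]
  if (!nrow(intj)) return(ok2)
  intj[, present := !is.na(frags$junctions[intj,
                                           on = .(fid, donor, acceptor),
                                           which = TRUE])]
  bad <- intj[present == FALSE, unique(paste(fid, transcript_id))]
  ok2[!paste(fid, transcript_id) %in% bad]
}

#' Is a fragment consistent with a transcript's splice form?
#'
#' Structural check only — the strand is deliberately not examined here, so
#' the same test serves both the sense and the anti-sense ("backwards")
#' channel.
#'
#' @param frags a `fragment_set`
#' @param index an `annotation_index`
#' @param transcript_id transcript to test against
#' @param strict_span require every annotated junction internal to the
#'   fragment span to be observed in the fragment
#' @return logical vector, one element per fragment in `frags`
#' @export
compatible_with_transcript <- function(frags, index, transcript_id,
                                       strict_span = TRUE) {
  stopifnot(inherits(frags, "fragment_set"))
  fr <- frags$fragments
  tid <- transcript_id
  tx_chrom <- index$exons[index$exons$transcript_id == tid]$chrom[1]
  cand <- data.table::data.table(fid = fr$fid, transcript_id = transcript_id)
  cand <- cand[fr$chrom == tx_chrom & !is.na(fr$chrom)]
  ok <- compatible_pairs(frags, index, cand, strict_span = strict_span)
  fr$fid %in% ok$fid
}

#' Assign fragments to genes and channels
#'
#' For every fragment, sense candidates are genes with a structurally
#' compatible splice form on the fragment's transcription strand; anti-sense
#' candidates are compatible genes on the opposite strand. Exactly one sense
#' candidate wins the sense channel (sense takes precedence over anti-sense,
#' so sense transcription of a gene can never inflate the anti-sense count of
#' an overlapping neighbour); otherwise exactly one anti-sense candidate wins
#' the anti-sense channel; multiple candidates in the winning channel are
#' ambiguous; no candidate leaves the fragment unassigned. Fragments with
#' unknown transcription strand (unstranded protocol) cannot be channelled
#' and are ambiguous whenever any candidate exists.
#'
#' @param frags a `fragment_set`
#' @param index an `annotation_index`
#' @param mode `"structural"` (splice-form compatibility, the default) or
#'   `"overlap"` (looser sensitivity mode: any exon-union overlap qualifies)
#' @param strict_span see [compatible_with_transcript()]
#' @return data.table: fid, qname, gene_id (NA unless assigned), channel in
#'   {sense, antisense, ambiguous, unassigned}
#' @export
assign_fragments <- function(frags, index,
                             mode = c("structural", "overlap"),
                             strict_span = TRUE) {
  stopifnot(inherits(frags, "fragment_set"),
            inherits(index, "annotation_index"))
  mode <- match.arg(mode)
  fr <- frags$fragments
  out <- fr[, .(fid, qname)]
  out[, `:=`(gene_id = NA_character_, channel = "unassigned")]
  if (!nrow(fr)) return(out[])

  known <- unique(index$exons$chrom)
  n_off <- sum(!fr$chrom %in% known | is.na(fr$chrom))
  if (n_off) message(n_off, " fragment(s) on contigs absent from the ",
                     "annotation routed to unassigned")

  if (mode == "structural") {
    tx <- index$exons[, .(chrom = chrom[1], start = min(start),
                          end = max(end), gene_id = gene_id[1]),
                      by = transcript_id]
    tx_gr <- dt_to_gr(tx[, .(chrom, start, end)])
    fr_gr <- dt_to_gr(fr[!is.na(chrom), .(chrom, start, end)])
    hits <- GenomicRanges::findOverlaps(fr_gr, tx_gr, ignore.strand = TRUE)
    cand <- data.table::data.table(
      fid = fr[!is.na(chrom)]$fid[S4Vectors::queryHits(hits)],
      transcript_id = tx$transcript_id[S4Vectors::subjectHits(hits)])
    comp <- compatible_pairs(frags, index, cand, strict_span = strict_span)
    comp <- merge(comp,
                  index$exons[, .(gene_id = gene_id[1]), by = transcript_id],
                  by = "transcript_id")
    cg <- unique(comp[, .(fid, gene_id)])
  } else {
    u_gr <- dt_to_gr(index$union[, .(chrom, start, end)])
    bl <- merge(frags$blocks, fr[, .(fid, chrom)], by = "fid")
    bl <- bl[!is.na(chrom)]
    bl_gr <- dt_to_gr(bl[, .(chrom, start, end)])
    hits <- GenomicRanges::findOverlaps(bl_gr, u_gr, ignore.strand = TRUE)
    cg <- unique(data.table::data.table(
      fid = bl$fid[S4Vectors::queryHits(hits)],
      gene_id = index$union$gene_id[S4Vectors::subjectHits(hits)]))
  }
  if (!nrow(cg)) return(out[])

  cg <- merge(cg, index$genes[, .(gene_id, gstrand = strand)], by = "gene_id")
  cg <- merge(cg, fr[, .(fid, fstrand = strand)], by = "fid")
  cg[, is_sense := fstrand != "*" & gstrand == fstrand]
  cg[, is_anti := fstrand != "*" & gstrand != fstrand]

  verdict <- cg[, {
    sg <- unique(gene_id[is_sense])
    ag <- unique(gene_id[is_anti])
    if (length(sg) == 1L) {
      list(gene_id = sg, channel = "sense")
    } else if (length(sg) > 1L) {
      list(gene_id = NA_character_, channel = "ambiguous")
    } else if (length(ag) == 1L) {
      list(gene_id = ag, channel = "antisense")
    } else if (length(ag) > 1L) {
      list(gene_id = NA_character_, channel = "ambiguous")
    } else {
      # candidates exist but strand unknown (unstranded protocol)
      list(gene_id = NA_character_, channel = "ambiguous")
    }
  }, by = fid]
  out[verdict, on = "fid", `:=`(gene_id = i.gene_id, channel = i.channel)]
  out[]
}

#' Quantify one sample
#'
#' Reconstructs fragments from a normalized SAM file, assigns each to a gene
#' and channel, and tallies per-channel totals.
#'
#' @param sam_path normalized SAM path
#' @param index an `annotation_index`
#' @param protocol library protocol (see [reconstruct_fragments()])
#' @param ... passed to [assign_fragments()]
#' @return list: `fragments` (`fragment_set`), `assignments`, `totals`
#'   (named counts: sense, antisense, ambiguous, unassigned, total)
#' @export
quantify_sample <- function(sam_path, index, protocol = "firststrand", ...) {
  frags <- reconstruct_fragments(sam_path, protocol)
  asn <- assign_fragments(frags, index, ...)
  totals <- c(sense = sum(asn$channel == "sense"),
              antisense = sum(asn$channel == "antisense"),
              ambiguous = sum(asn$channel == "ambiguous"),
              unassigned = sum(asn$channel == "unassigned"),
              total = nrow(asn))
  list(fragments = frags, assignments = asn, totals = totals)
}

#' Per-gene aligned bases and average coverage for one quantified sample
#'
#' Average coverage is the number of aligned bases of a gene's channel
#' fragments falling inside the gene's exon union, divided by the exon-union
#' length. Computed on normalized files this is the study's "normalized
#' average coverage".
#'
#' @param quant result of [quantify_sample()]
#' @param index an `annotation_index`
#' @return data.table: gene_id, channel, bases, avg_coverage
#' @export
average_coverage <- function(quant, index) {
  asn <- quant$assignments[channel %in% c("sense", "antisense") &
                             !is.na(gene_id)]
  ulen <- interval_union_length(index$union, by = "gene_id")
  if (!nrow(asn)) {
    return(data.table::data.table(gene_id = character(),
                                  channel = character(),
                                  bases = numeric(), avg_coverage = numeric()))
  }
  bl <- merge(quant$fragments$blocks, asn[, .(fid, gene_id, channel)],
              by = "fid", allow.cartesian = TRUE)
  u <- data.table::copy(index$union)[, .(gene_id, ustart = start, uend = end,
                                         start, end)]
  bl[, `:=`(bstart = start, bend = end)]
  ov <- u[bl, on = .(gene_id, start < bend, end > bstart), nomatch = 0L,
          .(gene_id = i.gene_id, channel = i.channel,
            w = pmin(uend, i.bend) - pmax(ustart, i.bstart))]
  out <- ov[, .(bases = sum(as.numeric(w))), by = .(gene_id, channel)]
  out <- merge(out, ulen, by = "gene_id")
  out[, avg_coverage := bases / union_length]
  out[, union_length := NULL]
  out[]
}

#' Build the three signal-class count tables
#'
#' Produces gene x sample tables of fragment counts and normalized average
#' coverage for the gene-sense and gene-anti-sense channels, plus the ncRNA
#' table (the sense table restricted to non-coding genes). Ambiguous and
#' unassigned fragments are counted in neither gene; per-sample channel
#' totals are returned as a QC sidecar.
#'
#' @param quants named list (sample -> [quantify_sample()] result)
#' @param index an `annotation_index`
#' @param sheet sample sheet containing every quantified sample
#' @return list of class `count_tables`: `sense`, `antisense`, `ncRNA`
#'   (each a `count_table` with `counts` and `avg_coverage` matrices),
#'   `sidecar` (per-sample channel totals)
#' @export
count_tables <- function(quants, index, sheet) {
  sheet <- data.table::as.data.table(sheet)
  missing <- setdiff(names(quants), sheet$sample)
  if (length(missing))
    stop("sample(s) absent from sample sheet: ", paste(missing, collapse = ", "))
  samples <- sheet[sample %in% names(quants), sample]
  genes <- sort(index$genes$gene_id)

  mk <- function() matrix(0, length(genes), length(samples),
                          dimnames = list(genes, samples))
  cnt_s <- mk(); cnt_a <- mk(); cov_s <- mk(); cov_a <- mk()
  sidecar <- list()
  for (s in samples) {
    q <- quants[[s]]
    asn <- q$assignments[channel %in% c("sense", "antisense") &
                           !is.na(gene_id)]
    tab <- asn[, .N, by = .(gene_id, channel)]
    cs <- tab[channel == "sense"]; ca <- tab[channel == "antisense"]
    cnt_s[cs$gene_id, s] <- cs$N
    cnt_a[ca$gene_id, s] <- ca$N
    cov <- average_coverage(q, index)
    vs <- cov[channel == "sense"]; va <- cov[channel == "antisense"]
    cov_s[vs$gene_id, s] <- vs$avg_coverage
    cov_a[va$gene_id, s] <- va$avg_coverage
    sidecar[[s]] <- data.table::data.table(sample = s, t(q$totals))
  }
  nc <- intersect(genes, ncrna_genes(index))
  ct <- function(class, counts, cov)
    structure(list(signal_class = class, counts = counts, avg_coverage = cov),
              class = "count_table")
  structure(list(
    sense = ct("sense", cnt_s, cov_s),
    antisense = ct("antisense", cnt_a, cov_a),
    ncRNA = ct("ncRNA", cnt_s[nc, , drop = FALSE], cov_s[nc, , drop = FALSE]),
    sidecar = data.table::rbindlist(sidecar)),
    class = "count_tables")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table [", x$signal_class, "]: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples; total fragments ", sum(x$counts), "\n",
      sep = "")
  invisible(x)
}

#' Strand-split coverage tracks
#'
#' Per-position fragment-base depth, kept separately for the plus and minus
#' transcription strands, written as bedGraph (one file per unit and strand,
#' with a track line naming both). Condition-merged tracks are per-position
#' sums of the replicate tracks — replicates are already depth-equalized by
#' read-level normalization, so no further scaling is applied.
#'
#' @param quants named list (sample -> [quantify_sample()] result)
#' @param layout a [genome_layout()]
#' @param out_dir output directory
#' @param groups optional named character vector sample -> condition label;
#'   when given, merged tracks are written per condition instead of per
#'   sample
#' @return invisible list: `coverage` (unit -> strand -> RleList), `files`
#' @export
coverage_tracks <- function(quants, layout, out_dir, groups = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sl <- layout$chrom_lengths
  cov_one <- function(q, want_strand) {
    fr <- q$fragments$fragments[strand == want_strand & !is.na(chrom) &
                                  chrom %in% names(sl)]
    bl <- merge(q$fragments$blocks, fr[, .(fid, chrom)], by = "fid")
    if (!nrow(bl)) {
      return(GenomicRanges::coverage(
        GenomicRanges::GRanges(seqlengths = sl)))
    }
    GenomicRanges::coverage(dt_to_gr(bl[, .(chrom, start, end)],
                                     seqlengths = sl))
  }
  units <- if (is.null(groups)) {
    stats::setNames(as.list(names(quants)), names(quants))
  } else {
    split(names(quants), groups[names(quants)])
  }
  coverage <- list(); files <- character()
  for (u in names(units)) {
    for (st in c("+", "-")) {
      covs <- lapply(units[[u]], function(s) cov_one(quants[[s]], st))
      total <- Reduce(`+`, covs)
      tag <- if (st == "+") "plus" else "minus"
      path <- file.path(out_dir, sprintf("%s.%s.bedGraph", u, tag))
      write_bedgraph(total, path,
                     name = sprintf("%s %s strand", u, tag))
      coverage[[u]][[st]] <- total
      files <- c(files, path)
    }
  }
  invisible(list(coverage = coverage, files = files))
}

# RleList -> bedGraph with a track line (zero-depth runs omitted).
write_bedgraph <- function(cov, path, name) {
  gr <- as(cov, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score > 0]
  tmp <- tempfile(fileext = ".bedGraph")
  rtracklayer::export(gr, tmp, format = "bedGraph")
  body <- readLines(tmp, warn = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("track type=bedGraph name=\"%s\"", name), body),
             con, sep = "\n")
  invisible(path)
}
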