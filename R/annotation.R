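# Annotation handling: GTF (ENSEMBL dialect) parsing into gene models,
# pseudogene filtering, biotype classification, exon unions and junction sets.

#' Construct a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths the
#' pipeline works against. Genes on contigs absent from the layout are dropped
#' (with a warning) when an annotation is loaded against it.
#'
#' @param chrom_names character vector of unique chromosome names, in order
#' @param chrom_lengths integer vector of positive lengths (bp), same length
#' @return an object of class `genome_layout`
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length")
  chrom_lengths <- as.integer(chrom_lengths)
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "contigs,",
      sum(x$chrom_lengths), "bp total\n")
  invisible(x)
}

#' Load a GTF annotation into an annotation index
#'
#' Parses an ENSEMBL-dialect GTF (gene / transcript / exon features carrying
#' `gene_id`, `transcript_id` and `gene_biotype` attributes) into gene models:
#' per-gene exon unions, per-transcript splice junctions, and a biotype
#' classification. Internal coordinates are 0-based half-open; the GTF's
#' 1-based closed coordinates are converted on the way in.
#'
#' Pseudogene-class genes are removed by default because their alignments are
#' unreliable; the filter matches any biotype containing the substring
#' `"pseudogene"` so that processed/unprocessed/transcribed variants are all
#' caught.
#'
#' @param path path to a GTF file
#' @param filter_pseudogenes drop genes whose biotype contains "pseudogene"
#' @param layout optional [genome_layout()]; genes on contigs absent from it
#'   are dropped with a warning
#' @return an object of class `annotation_index` with elements
#'   `genes` (data.table: gene_id, gene_name, chrom, strand, start, end,
#'   biotype, n_transcripts), `exons` (per-transcript exons),
#'   `union` (per-gene merged exon intervals), `junctions`
#'   (per-transcript donor/acceptor pairs, 0-based: donor = end of the
#'   upstream exon, acceptor = start of the downstream exon), and `layout`.
#' @export
load_gtf <- function(path, filter_pseudogenes = TRUE, layout = NULL) {
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  need <- c("type", "gene_id")
  if (!all(need %in% names(md))) stop("GTF lacks required attributes: ",
                                      paste(setdiff(need, names(md)), collapse = ", "))
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = md$gene_id,
    transcript_id = if ("transcript_id" %in% names(md)) md$transcript_id else NA_character_,
    gene_name = if ("gene_name" %in% names(md)) md$gene_name else NA_character_,
    biotype = if ("gene_biotype" %in% names(md)) md$gene_biotype else NA_character_
  )

  exons <- dt[type == "exon"]
  txs <- dt[type == "transcript"]
  if (nrow(exons) && anyNA(exons$transcript_id))
    stop("structural error: exon feature without transcript_id")
  orphan <- setdiff(exons$transcript_id, txs$transcript_id)
  if (length(orphan))
    stop("structural error: exon without parent transcript feature: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  genes <- dt[type == "gene",
              .(gene_id, gene_name, chrom, strand, start, end, biotype)]
  if (!nrow(genes)) {
    # tolerate annotations without explicit gene features
    genes <- exons[, .(gene_name = gene_name[1], chrom = chrom[1],
                       strand = strand[1], start = min(start), end = max(end),
                       biotype = biotype[1]), by = gene_id]
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in GTF")

  if (isTRUE(filter_pseudogenes)) {
    keep <- !grepl("pseudogene", genes$biotype, fixed = TRUE)
    genes <- genes[keep]
  }
  if (!is.null(layout)) {
    off <- setdiff(unique(genes$chrom), layout$chrom_names)
    if (length(off)) {
      warning("dropping ", sum(genes$chrom %in% off),
              " gene(s) on contigs absent from layout: ",
              paste(off, collapse = ", "))
      genes <- genes[!chrom %in% off]
    }
  }

  exons <- exons[gene_id %in% genes$gene_id,
                 .(gene_id, transcript_id, chrom, strand, start, end)]
  data.table::setorder(exons, transcript_id, start)
  if (nrow(exons[, if (any(end <= start)) .SD, by = transcript_id]))
    stop("structural error: exon with end <= start")

  eu <- merge_intervals(exons[, .(gene_id, chrom, start, end)],
                        by = c("gene_id", "chrom"))
  eu <- merge(eu, genes[, .(gene_id, strand)], by = "gene_id")
  data.table::setorder(eu, gene_id, start)

  jn <- junction_table(exons)
  if (nrow(jn) && any(jn$acceptor <= jn$donor))
    stop("structural error: overlapping exons within a transcript")

  ntx <- exons[, .(n_transcripts = data.table::uniqueN(transcript_id)), by = gene_id]
  genes <- merge(genes, ntx, by = "gene_id", all.x = TRUE)
  genes[is.na(n_transcripts), n_transcripts := 0L]
  data.table::setorder(genes, chrom, start)

  structure(list(genes = genes, exons = exons, union = eu,
                 junctions = jn, layout = layout),
            class = "annotation_index")
}

# Donor/acceptor pairs from adjacent exons within each transcript; always
# returns the full four-column shape even when no transcript is spliced.
junction_table <- function(exons) {
  jn <- exons[, if (.N > 1L) .(donor = end[-.N], acceptor = start[-1L]),
              by = .(gene_id, transcript_id)]
  if (!"donor" %in% names(jn)) {
    jn <- data.table::data.table(gene_id = character(),
                                 transcript_id = character(),
                                 donor = integer(), acceptor = integer())
  }
  jn
}

# Cheap structural validation so malformed lines are reported by number,
# which rtracklayer's parser does not do.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 9L]
  if (length(bad))
    stop("malformed GTF line ", bad[1], ": expected 9 tab-separated fields, got ",
         nf[match(bad[1], body)])
  invisible(TRUE)
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$genes), "genes,",
      data.table::uniqueN(x$exons$transcript_id), "transcripts,",
      nrow(x$junctions), "junctions\n")
  bt <- sort(table(x$genes$biotype), decreasing = TRUE)
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Partition genes by biotype
#'
#' @param index an `annotation_index`
#' @return named list mapping each biotype present to the character vector of
#'   its gene ids; unknown biotype strings are retained under their literal
#'   name.
#' @export
classify_biotypes <- function(index) {
  stopifnot(inherits(index, "annotation_index"))
  if (!nrow(index$genes)) return(stats::setNames(list(), character()))
  split(index$genes$gene_id, index$genes$biotype)
}

#' Non-coding gene ids
#'
#' The non-coding universe defaults to every biotype except `protein_coding`
#' (pseudogenes having already been filtered at load time). The ENSEMBL
#' "antisense" biotype (intronic opposite-strand genes) is included by
#' default and can be excluded via `exclude`.
#'
#' @param index an `annotation_index`
#' @param coding biotypes considered coding (default `"protein_coding"`)
#' @param exclude further biotypes to drop from the non-coding set
#' @return character vector of gene ids
#' @export
ncrna_genes <- function(index, coding = "protein_coding", exclude = character()) {
  stopifnot(inherits(index, "annotation_index"))
  g <- index$genes
  g[!biotype %in% c(coding, exclude), gene_id]
}

#' Write an annotation index back to GTF
#'
#' Emits gene / transcript / exon features with `gene_id`, `transcript_id`,
#' `gene_name` and `gene_biotype` attributes (ENSEMBL dialect); coordinates
#' are converted back to 1-based closed. Re-reading the file with
#' [load_gtf()] reproduces the same gene models.
#'
#' @param index an `annotation_index`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(index, path) {
  stopifnot(inherits(index, "annotation_index"))
  g <- index$genes
  e <- index$exons
  tx <- e[, .(chrom = chrom[1], strand = strand[1],
              start = min(start), end = max(end)),
          by = .(gene_id, transcript_id)]
  rows <- data.table::rbindlist(list(
    g[, .(chrom, start, end, strand, type = "gene", gene_id,
          transcript_id = NA_character_, gene_name, biotype)],
    merge(tx, g[, .(gene_id, gene_name, biotype)], by = "gene_id")[
      , .(chrom, start, end, strand, type = "transcript", gene_id,
          transcript_id, gene_name, biotype)],
    merge(e, g[, .(gene_id, gene_name, biotype)], by = "gene_id")[
      , .(chrom, start, end, strand, type = "exon", gene_id,
          transcript_id, gene_name, biotype)]
  ))
  data.table::setorder(rows, chrom, start, gene_id, transcript_id, type, end,
                       na.last = FALSE)
  gr <- dt_to_gr(rows)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "antisenseq", type = rows$type, gene_id = rows$gene_id,
    transcript_id = rows$transcript_id, gene_name = rows$gene_name,
    gene_biotype = rows$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Tabulate biotypes as a TSV-ready table
#'
#' @param index an `annotation_index`
#' @return data.table with columns biotype, n_genes, gene_ids
#'   (comma-separated)
#' @export
biotype_table <- function(index) {
  m <- classify_biotypes(index)
  data.table::data.table(
    biotype = names(m),
    n_genes = lengths(m),
    gene_ids = vapply(m, paste, "", collapse = ",")
  )
}
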