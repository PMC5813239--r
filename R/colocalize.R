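# Cis co-localization of differentially expressed non-coding genes to
# protein-coding neighbours via a GREAT-style "basal plus extension"
# regulatory-domain rule (basal 5 kb upstream / 1 kb downstream of the TSS,
# strand-aware, extended to the nearest flanking basal domain up to 1 Mb).
# Only the gene mapping is produced; ontology enrichment is out of scope.

#' Build regulatory domains for protein-coding genes
#'
#' @param index an `annotation_index`
#' @param basal_up bp upstream of the TSS in the basal domain (default 5000)
#' @param basal_down bp downstream (default 1000)
#' @param max_ext maximum extension from the TSS on either side (default 1e6)
#' @return data.table: gene_id, chrom, strand, tss, basal_start, basal_end,
#'   ext_start, ext_end (0-based half-open, clipped to chromosome bounds
#'   when the index carries a layout)
#' @export
build_domains <- function(index, basal_up = 5000L, basal_down = 1000L,
                          max_ext = 1000000L) {
  stopifnot(inherits(index, "annotation_index"))
  g <- index$genes[biotype == "protein_coding",
                   .(gene_id, chrom, strand, start, end)]
  if (!nrow(g)) stop("no protein-coding genes in the annotation")
  g[, tss := ifelse(strand == "+", start, end)]
  g[, basal_start := ifelse(strand == "+", tss - basal_up, tss - basal_down)]
  g[, basal_end := ifelse(strand == "+", tss + basal_down, tss + basal_up)]
  if (!is.null(index$layout)) {
    len <- index$layout$chrom_lengths[g$chrom]
    g[, basal_start := pmax(basal_start, 0L)]
    g[, basal_end := pmin(basal_end, len)]
  } else {
    g[, basal_start := pmax(basal_start, 0L)]
  }

  # extension: out to the nearest flanking basal domain, capped at max_ext,
  # never shrinking below the gene's own basal domain
  g[, `:=`(ext_start = NA_real_, ext_end = NA_real_)]
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    bs <- g$basal_start[idx]; be <- g$basal_end[idx]; tss <- g$tss[idx]
    for (k in seq_along(idx)) {
      others_end <- be[-k]; others_start <- bs[-k]
      left_stop <- suppressWarnings(max(others_end[others_end <= bs[k]]))
      right_stop <- suppressWarnings(min(others_start[others_start >= be[k]]))
      es <- max(tss[k] - max_ext, if (is.finite(left_stop)) left_stop else -Inf, 0)
      ee <- min(tss[k] + max_ext, if (is.finite(right_stop)) right_stop else Inf)
      g$ext_start[idx[k]] <- min(es, bs[k])
      g$ext_end[idx[k]] <- max(ee, be[k])
    }
  }
  if (!is.null(index$layout)) {
    len <- index$layout$chrom_lengths[g$chrom]
    g[, ext_start := pmax(ext_start, 0)]
    g[, ext_end := pmin(ext_end, as.numeric(len))]
  }
  g[, .(gene_id, chrom, strand, tss, basal_start, basal_end,
        ext_start = as.integer(ext_start), ext_end = as.integer(ext_end))]
}

#' Assign non-coding genes to protein-coding genes in cis
#'
#' Each query gene is represented by the midpoint of its locus and is
#' assigned to every protein-coding gene whose regulatory domain contains
#' that point; genes hit by no domain are reported unassigned.
#'
#' @param ncrna_ids character vector of (typically DE non-coding) gene ids
#' @param index an `annotation_index`
#' @param domains result of [build_domains()]
#' @param position `"midpoint"` (default) or `"tss"`
#' @return data.table: ncrna_id, coding_gene (NA when unassigned),
#'   distance_to_tss
#' @export
assign_cis <- function(ncrna_ids, index, domains, position = c("midpoint", "tss")) {
  position <- match.arg(position)
  q <- index$genes[gene_id %in% ncrna_ids, .(gene_id, chrom, strand, start, end)]
  missing <- setdiff(ncrna_ids, q$gene_id)
  if (length(missing))
    stop("gene id(s) absent from annotation: ", paste(missing, collapse = ", "))
  q[, pos := if (position == "midpoint") (start + end) %/% 2L
    else ifelse(strand == "+", start, end - 1L)]
  d <- data.table::copy(domains)
  d[, `:=`(ds = ext_start, de = ext_end)]
  q[, `:=`(ps = pos, pe = pos + 1L)]
  hit <- d[q, on = .(chrom, ds <= ps, de > ps), nomatch = NA, allow.cartesian = TRUE,
           .(ncrna_id = i.gene_id, coding_gene = gene_id,
             distance_to_tss = abs(i.pos - tss))]
  data.table::setorder(hit, ncrna_id, distance_to_tss, na.last = TRUE)
  hit[]
}
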