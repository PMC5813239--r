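# Shared fixtures: hand-written toy GTFs, synthetic fragment sets, and a
# small cached simulation reused across test files.

# GTF text (1-based closed coordinates, ENSEMBL-style attributes) for three
# genes: GA protein-coding two-exon on +, GB lincRNA single-exon on -, and
# GP a processed pseudogene. In 0-based half-open terms GA's exons are
# [100,200) and [300,400); GB's is [1000,1200); GP's is [2000,2100).
toy_gtf_text <- function() {
  attr1 <- 'gene_id "GA"; gene_name "NA1"; gene_biotype "protein_coding";'
  attr1t <- 'gene_id "GA"; transcript_id "GA.T1"; gene_name "NA1"; gene_biotype "protein_coding";'
  attr2 <- 'gene_id "GB"; gene_name "NB1"; gene_biotype "lincRNA";'
  attr2t <- 'gene_id "GB"; transcript_id "GB.T1"; gene_name "NB1"; gene_biotype "lincRNA";'
  attr3 <- 'gene_id "GP"; gene_name "NP1"; gene_biotype "processed_pseudogene";'
  attr3t <- 'gene_id "GP"; transcript_id "GP.T1"; gene_name "NP1"; gene_biotype "processed_pseudogene";'
  c(
    paste("chr1\ttest\tgene\t101\t400\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\ttest\ttranscript\t101\t400\t.\t+\t.", attr1t, sep = "\t"),
    paste("chr1\ttest\texon\t101\t200\t.\t+\t.", attr1t, sep = "\t"),
    paste("chr1\ttest\texon\t301\t400\t.\t+\t.", attr1t, sep = "\t"),
    paste("chr1\ttest\tgene\t1001\t1200\t.\t-\t.", attr2, sep = "\t"),
    paste("chr1\ttest\ttranscript\t1001\t1200\t.\t-\t.", attr2t, sep = "\t"),
    paste("chr1\ttest\texon\t1001\t1200\t.\t-\t.", attr2t, sep = "\t"),
    paste("chr1\ttest\tgene\t2001\t2100\t.\t+\t.", attr3, sep = "\t"),
    paste("chr1\ttest\ttranscript\t2001\t2100\t.\t+\t.", attr3t, sep = "\t"),
    paste("chr1\ttest\texon\t2001\t2100\t.\t+\t.", attr3t, sep = "\t"))
}

toy_gtf_file <- function() {
  p <- tempfile(fileext = ".gtf")
  writeLines(toy_gtf_text(), p)
  p
}

# annotation_index straight from in-memory tables (genes: data.frame with
# gene_id, strand, biotype, and exon rows start/end 0-based half-open).
make_index <- function(genes, exons, layout = NULL) {
  g <- data.table::as.data.table(genes)
  e <- data.table::as.data.table(exons)
  if (!"chrom" %in% names(g)) g[, chrom := "chr1"]
  if (!"chrom" %in% names(e)) e[, chrom := "chr1"]
  if (!"gene_name" %in% names(g)) g[, gene_name := gene_id]
  if (!"strand" %in% names(e))
    e <- merge(e, g[, .(gene_id, strand)], by = "gene_id")
  if (!"start" %in% names(g))
    g <- merge(g, e[, .(start = min(start), end = max(end)), by = gene_id],
               by = "gene_id")
  antisenseq:::build_annotation_index(g, e, layout)
}

# Synthetic fragment_set: one row per fragment; blocks is a list of
# 2-column matrices (start, end), junctions a list of 2-column matrices
# (donor, acceptor) or NULL.
make_fragments <- function(blocks, strand, chrom = "chr1", junctions = NULL) {
  n <- length(blocks)
  strand <- rep_len(strand, n)
  chrom <- rep_len(chrom, n)
  bl <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    m <- blocks[[i]]
    data.table::data.table(fid = i, start = as.integer(m[, 1]),
                           end = as.integer(m[, 2]))
  }))
  jn <- if (is.null(junctions)) {
    data.table::data.table(fid = integer(), donor = integer(),
                           acceptor = integer())
  } else {
    data.table::rbindlist(lapply(seq_len(n), function(i) {
      m <- junctions[[i]]
      if (is.null(m) || !nrow(m)) return(NULL)
      data.table::data.table(fid = i, donor = as.integer(m[, 1]),
                             acceptor = as.integer(m[, 2]))
    }))
  }
  nj <- jn[, .N, by = fid]
  fr <- bl[, .(start = min(start), end = max(end), nblocks = .N), by = fid]
  fr[, `:=`(qname = paste0("f", fid), chrom = chrom[fid], strand = strand[fid])]
  fr <- merge(fr, nj, by = "fid", all.x = TRUE)
  fr[is.na(N), N := 0L]
  data.table::setnames(fr, "N", "njunc")
  data.table::setcolorder(fr, c("fid", "qname", "chrom", "strand", "start",
                                "end", "nblocks", "njunc"))
  structure(list(fragments = fr[], blocks = bl, junctions = jn,
                 protocol = "firststrand"),
            class = "fragment_set")
}

# One small simulated study, built once per test run and shared.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(seed = 101, n_replicates = 1L,
                      fragments_per_sample = 2500L)
    ann <- simulate_annotation(cfg, file.path(tempdir(), "tt_small_ann"))
    design <- sim_design(cfg, ann$index)
    sheet <- sim_sample_sheet(cfg)
    reads <- simulate_reads(cfg, ann$layout, ann$index, design, sheet,
                            file.path(tempdir(), "tt_small_reads"))
    filtered <- load_gtf(ann$gtf, filter_pseudogenes = TRUE,
                         layout = ann$layout)
    list(cfg = cfg, ann = ann, design = design, sheet = sheet,
         reads = reads, index = filtered)
  })
}

# qname-encoded planted truth of a simulated SAM: sample:gene:channel:class
qname_truth <- function(qnames) {
  parts <- data.table::tstrsplit(qnames, ":", fixed = TRUE)
  data.table::data.table(sample = parts[[1]], gene_id = parts[[2]],
                         channel = ifelse(parts[[3]] == "s", "sense",
                                          "antisense"),
                         class = parts[[4]])
}
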