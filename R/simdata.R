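# Seeded simulator of a small genome, ENSEMBL-style annotation, sample sheet
# and stranded paired-end alignments with planted sense/anti-sense expression
# structure and contamination. The emitted SAM files plus the machine-readable
# truth table are the pipeline's complete test surface.
#
# The emulated design mirrors a two-tissue (PR = peripheral retina,
# PRCS = peripheral RPE-choroid-sclera), two-state (normal vs AMD) donor-eye
# study sequenced with a dUTP ("firststrand") stranded protocol at 100 bp
# paired ends: anti-sense transcription of annotated genes is activated in
# disease samples only, on tissue-specific gene sets, while sense expression
# differs between tissues (marker genes) but not, by default, between disease
# states.

#' Simulator configuration
#'
#' Returns the study conditions used by the simulator. Defaults: 100 bp
#' paired-end fragments of 180 +/- 25 bp from a dUTP-stranded protocol
#' (read 2 carries the transcript strand), 5 replicates per (tissue, disease)
#' cell, multi-exon genes (2-6 exons) across the biotypes the study
#' profiles, disease-only anti-sense activation on tissue-specific gene
#' sets, and rRNA / chrM / cross-tissue contamination at low baseline
#' fractions. Counts are drawn Poisson around rate x library size
#' (`overdispersion > 0` switches to negative binomial for DE power tests).
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   child seed from it
#' @param n_genes named integer vector: genes per biotype
#' @param n_replicates replicates per (tissue, disease) cell
#' @param fragments_per_sample sequenced fragments per sample
#' @param fragment_length_mean,fragment_length_sd fragment length (bp)
#' @param read_length read length (bp); must not exceed fragment length
#' @param protocol one of `"firststrand"`, `"secondstrand"`, `"unstranded"`
#' @param multi_exon_fraction fraction of spliceable genes with >= 2 exons
#' @param rate_meanlog,rate_sdlog log-normal per-gene sense expression rates
#' @param n_markers tissue marker genes per tissue
#' @param marker_boost sense-rate multiplier for a marker in its own tissue
#' @param off_tissue_factor marker sense rate in the other tissue (relative)
#' @param antisense_baseline_fraction fraction of genes with constitutive
#'   low-level anti-sense transcription
#' @param antisense_baseline_ratio anti-sense rate relative to the gene's
#'   sense rate for baseline genes
#' @param n_antisense_activate per tissue: genes with anti-sense transcription
#'   present only in disease (rate 0 in normals)
#' @param antisense_activation_ratio disease anti-sense rate relative to the
#'   gene's sense rate for activated genes
#' @param n_antisense_fold per tissue: baseline anti-sense genes whose
#'   anti-sense rate is multiplied by `antisense_fold` in disease
#' @param antisense_fold fold change for those genes
#' @param n_sense_de per tissue: genes with planted sense DE in disease
#' @param sense_fold sense fold change for those genes
#' @param contamination named list: baseline `rrna`, `chrm`, `cross`
#'   contamination fractions per sample
#' @param qc_failures named list: number of samples planted to fail QC per
#'   class (`rrna`, `chrm`, `cross`)
#' @param fail_fractions named list: contamination fraction used for planted
#'   failures of each class
#' @param overdispersion negative-binomial overdispersion (0 = Poisson)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes = c(protein_coding = 30L, antisense = 10L,
                                   lincRNA = 10L, snoRNA = 5L,
                                   processed_pseudogene = 5L,
                                   rRNA = 2L, Mt_rRNA = 2L),
                       n_replicates = 5L,
                       fragments_per_sample = 20000L,
                       fragment_length_mean = 180,
                       fragment_length_sd = 25,
                       read_length = 100L,
                       protocol = c("firststrand", "secondstrand", "unstranded"),
                       multi_exon_fraction = 0.7,
                       rate_meanlog = log(20), rate_sdlog = 1,
                       n_markers = 4L, marker_boost = 8,
                       off_tissue_factor = 0.02,
                       antisense_baseline_fraction = 0.3,
                       antisense_baseline_ratio = 0.05,
                       n_antisense_activate = 6L,
                       antisense_activation_ratio = 0.5,
                       n_antisense_fold = 4L,
                       antisense_fold = 4,
                       n_sense_de = 0L, sense_fold = 2,
                       contamination = list(rrna = 0.05, chrm = 0.03, cross = 0),
                       qc_failures = list(rrna = 0L, chrm = 0L, cross = 0L),
                       fail_fractions = list(rrna = 0.45, chrm = 0.30, cross = 0.20),
                       overdispersion = 0) {
  protocol <- match.arg(protocol)
  cfg <- as.list(environment())
  if (read_length > fragment_length_mean)
    stop("read_length must not exceed the mean fragment length")
  if (any(unlist(contamination) < 0) || any(unlist(contamination) > 1))
    stop("contamination fractions must lie in [0, 1]")
  if (any(n_genes < 0) || rate_sdlog < 0 || antisense_baseline_ratio < 0)
    stop("rates and gene counts must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", sum(x$n_genes), "genes |",
      2L * 2L * x$n_replicates, "samples x", x$fragments_per_sample,
      "fragments |", x$protocol, "\n")
  invisible(x)
}

#' Simulated sample sheet
#'
#' @param config a [sim_config()]
#' @return data.table: sample, tissue, disease, replicate, protocol
#' @export
sim_sample_sheet <- function(config) {
  grid <- data.table::CJ(tissue = c("PR", "PRCS"),
                         disease = c("normal", "AMD"),
                         replicate = seq_len(config$n_replicates),
                         sorted = FALSE)
  data.table::setorder(grid, tissue, disease, replicate)
  grid[, sample := sprintf("S%02d", .I)]
  grid[, protocol := config$protocol]
  grid[, .(sample, tissue, disease, replicate, protocol)]
}

#' Simulate a genome layout and gene annotation
#'
#' Builds a small genome (three nuclear contigs plus a mitochondrial contig)
#' carrying single- and multi-exon gene models on both strands for every
#' configured biotype: rRNA genes on a dedicated rDNA locus contig, Mt_rRNA
#' genes on chrM, and ENSEMBL-"antisense"-biotype genes placed inside introns
#' of protein-coding hosts on the opposite strand. Deterministic under the
#' config seed; the GTF written to `dir` is byte-identical across runs.
#'
#' @param config a [sim_config()]
#' @param dir output directory for the GTF (created if needed)
#' @return list with `layout` ([genome_layout()]), `gtf` (path) and `index`
#'   (unfiltered [load_gtf()] result, pseudogenes included)
#' @export
simulate_annotation <- function(config, dir = tempfile("simann")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(config$seed, 1L))
  layout <- genome_layout(c("chr1", "chr2", "chr3", "chrM"),
                          c(2e6, 2e6, 1e6, 16571))

  nb <- config$n_genes
  biotypes <- rep(names(nb), nb)
  n <- length(biotypes)
  gid <- sprintf("G%04d", seq_len(n))
  single_only <- c("snoRNA", "snRNA", "miRNA", "rRNA", "Mt_rRNA")

  exons_list <- vector("list", n)
  genes <- data.table::data.table(gene_id = gid, biotype = biotypes,
                                  chrom = NA_character_, strand = NA_character_)
  # chromosome assignment
  genes[biotype == "Mt_rRNA", chrom := "chrM"]
  genes[biotype == "rRNA", chrom := "chr3"]
  free <- which(is.na(genes$chrom) & genes$biotype != "antisense")
  genes[free, chrom := c("chr1", "chr2", "chr3")[(seq_along(free) %% 3L) + 1L]]

  cursors <- stats::setNames(c(10000L, 10000L, 50000L, 1000L),
                             layout$chrom_names)
  host_introns <- list()  # candidate intervals for intronic antisense genes

  place <- order(match(genes$chrom, layout$chrom_names), na.last = TRUE)
  for (i in place) {
    bt <- genes$biotype[i]
    if (bt == "antisense") next
    chrom <- genes$chrom[i]
    strand <- sample(c("+", "-"), 1L)
    multi <- !(bt %in% single_only) &&
      stats::runif(1) < config$multi_exon_fraction
    n_ex <- if (multi) sample(2:6, 1L) else 1L
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(600:1500, n_ex - 1L, replace = TRUE) else integer()
    gstart <- cursors[[chrom]]
    starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    gend <- ends[n_ex]
    if (gend > layout$chrom_lengths[[chrom]] - 1000L)
      stop("sizing error: genome too small to place genes on ", chrom)
    cursors[[chrom]] <- gend + sample(3000:8000, 1L)
    genes$strand[i] <- strand
    ex <- data.table::data.table(gene_id = gid[i],
                                 transcript_id = paste0(gid[i], ".T1"),
                                 chrom = chrom, strand = strand,
                                 start = starts, end = ends)
    # second splice form: skip one internal exon
    if (n_ex >= 3L && stats::runif(1) < 0.5) {
      skip <- sample(2:(n_ex - 1L), 1L)
      ex2 <- ex[-skip][, transcript_id := paste0(gid[i], ".T2")]
      ex <- rbind(ex, ex2)
    }
    exons_list[[i]] <- ex
    if (bt == "protein_coding" && n_ex > 1L) {
      iv <- data.table::data.table(chrom = chrom, strand = strand,
                                   start = ends[-n_ex], end = starts[-1L])
      host_introns[[length(host_introns) + 1L]] <- iv[end - start >= 700L]
    }
  }

  # intronic, opposite-strand "antisense"-biotype genes
  anti_idx <- which(genes$biotype == "antisense")
  introns <- data.table::rbindlist(host_introns)
  if (length(anti_idx) && nrow(introns) < length(anti_idx))
    stop("sizing error: not enough wide introns to host antisense-biotype genes")
  if (length(anti_idx)) {
    pick <- sample(nrow(introns), length(anti_idx))
    for (k in seq_along(anti_idx)) {
      i <- anti_idx[k]
      iv <- introns[pick[k]]
      len <- sample(200:400, 1L)
      s <- iv$start + sample.int(iv$end - iv$start - len - 100L, 1L) + 50L
      strand <- if (iv$strand == "+") "-" else "+"
      genes$chrom[i] <- iv$chrom
      genes$strand[i] <- strand
      exons_list[[i]] <- data.table::data.table(
        gene_id = gid[i], transcript_id = paste0(gid[i], ".T1"),
        chrom = iv$chrom, strand = strand, start = s, end = s + len)
    }
  }

  exons <- data.table::rbindlist(exons_list)
  genes <- merge(genes,
                 exons[, .(start = min(start), end = max(end)), by = gene_id],
                 by = "gene_id")
  genes[, gene_name := paste0("SIM", sub("^G", "", gene_id))]
  idx <- build_annotation_index(genes, exons, layout)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(idx, gtf)
  list(layout = layout, gtf = gtf, index = idx)
}

# Assemble an annotation_index from in-memory gene/exon tables
# (same invariants as load_gtf).
build_annotation_index <- function(genes, exons, layout = NULL) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  data.table::setorder(exons, transcript_id, start)
  eu <- merge_intervals(exons[, .(gene_id, chrom, start, end)],
                        by = c("gene_id", "chrom"))
  eu <- merge(eu, genes[, .(gene_id, strand)], by = "gene_id")
  data.table::setorder(eu, gene_id, start)
  jn <- junction_table(exons)
  ntx <- exons[, .(n_transcripts = data.table::uniqueN(transcript_id)),
               by = gene_id]
  g <- merge(genes[, .(gene_id, gene_name, chrom, strand, start, end, biotype)],
             ntx, by = "gene_id", all.x = TRUE)
  data.table::setorder(g, chrom, start)
  structure(list(genes = g,
                 exons = exons[, .(gene_id, transcript_id, chrom, strand, start, end)],
                 union = eu, junctions = jn, layout = layout),
            class = "annotation_index")
}

#' Plant the expression design: rates, markers, DE truth
#'
#' Draws per-gene sense rates, selects tissue marker genes, constitutive
#' anti-sense baseline genes, disease-only anti-sense activation sets and
#' anti-sense fold-change sets per tissue (all disjoint), and optional sense
#' DE sets. Deterministic under the config seed.
#'
#' @param config a [sim_config()]
#' @param index annotation index from [simulate_annotation()]
#' @return an object of class `sim_design`
#' @export
sim_design <- function(config, index) {
  stopifnot(inherits(config, "sim_config"), inherits(index, "annotation_index"))
  set.seed(derive_seed(config$seed, 2L))
  g <- data.table::copy(index$genes)[, .(gene_id, biotype)]
  n <- nrow(g)
  g[, base_rate := stats::rlnorm(n, config$rate_meanlog, config$rate_sdlog)]
  # rRNA / Mt_rRNA fragments come only from the contamination component
  g[biotype %in% c("rRNA", "Mt_rRNA"), base_rate := 0]
  # pseudogene loci transcribe at low level (they are filtered downstream)
  g[grepl("pseudogene", biotype, fixed = TRUE), base_rate := base_rate * 0.1]

  pc <- g[biotype == "protein_coding", gene_id]
  if (length(pc) < 2L * config$n_markers +
      2L * (config$n_antisense_activate + config$n_sense_de))
    stop("config error: not enough protein-coding genes for markers/DE sets")
  pool <- sample(pc)  # shuffled, consumed left to right -> disjoint sets
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  markers <- list(PR = take(config$n_markers), PRCS = take(config$n_markers))
  activate <- list(PR = take(config$n_antisense_activate),
                   PRCS = take(config$n_antisense_activate))
  sense_de <- list(PR = take(config$n_sense_de), PRCS = take(config$n_sense_de))

  eligible <- g[base_rate > 0 & !grepl("pseudogene", biotype, fixed = TRUE),
                gene_id]
  if (config$antisense_baseline_fraction > 0) {
    n_base <- max(2L * config$n_antisense_fold,
                  round(config$antisense_baseline_fraction * length(eligible)))
    reserved <- unlist(activate)
    base_pool <- setdiff(eligible, reserved)
    baseline <- unique(c(unlist(markers),
                         sample(base_pool, min(n_base, length(base_pool)))))
  } else {
    baseline <- character()
  }
  fold_pool <- setdiff(baseline, c(unlist(markers), unlist(sense_de)))
  if (length(fold_pool) < 2L * config$n_antisense_fold)
    stop("config error: not enough baseline anti-sense genes for fold sets")
  fold_sets <- list(PR = fold_pool[seq_len(config$n_antisense_fold)],
                    PRCS = fold_pool[config$n_antisense_fold +
                                       seq_len(config$n_antisense_fold)])
  overlap <- intersect(unlist(activate), unlist(fold_sets))
  if (length(overlap)) stop("config error: overlapping DE assignments")

  structure(list(config = config, rates = g, markers = markers,
                 baseline = baseline, activate = activate,
                 fold_sets = fold_sets, sense_de = sense_de),
            class = "sim_design")
}

#' Planted differential-expression truth per contrast
#'
#' For each within-tissue disease-vs-normal contrast, lists the genes with
#' planted anti-sense DE (disease-only activation, fold recorded as `Inf`,
#' and finite anti-sense fold changes) and planted sense DE; all sets are
#' disjoint. Genes listed for neither channel in a tissue are that contrast's
#' nulls.
#'
#' @param x a [sim_config()] or a [sim_design()] (a config is expanded by
#'   simulating its annotation and design)
#' @return data.table: tissue, gene_id, channel, fold, kind
#' @export
plant_de_design <- function(x) {
  if (inherits(x, "sim_config")) {
    ann <- simulate_annotation(x)
    x <- sim_design(x, ann$index)
  }
  stopifnot(inherits(x, "sim_design"))
  cfg <- x$config
  rows <- list()
  for (ts in c("PR", "PRCS")) {
    if (length(x$activate[[ts]]))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tissue = ts, gene_id = x$activate[[ts]], channel = "antisense",
        fold = Inf, kind = "activation")
    if (length(x$fold_sets[[ts]]))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tissue = ts, gene_id = x$fold_sets[[ts]], channel = "antisense",
        fold = cfg$antisense_fold, kind = "fold")
    if (length(x$sense_de[[ts]]))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tissue = ts, gene_id = x$sense_de[[ts]], channel = "sense",
        fold = cfg$sense_fold, kind = "sense")
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) && anyDuplicated(out[, .(tissue, gene_id)]))
    stop("config error: overlapping DE assignments")
  out
}

# Expected per-gene fragment rates (unnormalized weights) for one sample.
sample_rates <- function(design, tissue, disease) {
  cfg <- design$config
  r <- data.table::copy(design$rates)
  other <- setdiff(c("PR", "PRCS"), tissue)
  r[gene_id %in% design$markers[[tissue]], base_rate := base_rate * cfg$marker_boost]
  r[gene_id %in% design$markers[[other]], base_rate := base_rate * cfg$off_tissue_factor]
  r[, sense := base_rate]
  if (disease == "AMD")
    r[gene_id %in% design$sense_de[[tissue]], sense := sense * cfg$sense_fold]
  r[, anti := 0]
  r[gene_id %in% design$baseline, anti := sense * cfg$antisense_baseline_ratio]
  if (disease == "AMD") {
    r[gene_id %in% design$fold_sets[[tissue]], anti := anti * cfg$antisense_fold]
    r[gene_id %in% design$activate[[tissue]],
      anti := sense * cfg$antisense_activation_ratio]
  }
  r[, .(gene_id, biotype, sense, anti)]
}

#' Simulate stranded paired-end alignments for every sample
#'
#' Emits one coordinate-sorted SAM per sample: sense fragments sampled from
#' annotated splice forms, anti-sense fragments from reversed-strand copies
#' of the same splice forms (exonic, junction-respecting), and contamination
#' fragments (rRNA locus, chrM, cross-tissue markers). FLAGs encode the
#' configured protocol; CIGARs carry `N` operations across junctions. The
#' returned truth table records every planted count.
#'
#' @param config a [sim_config()]
#' @param layout genome layout from [simulate_annotation()]
#' @param index annotation index from [simulate_annotation()]
#' @param design a [sim_design()]; built from `config` + `index` if missing
#' @param sheet sample sheet; defaults to [sim_sample_sheet()]
#' @param dir output directory for SAM/TSV files
#' @return list: `sam` (named paths), `truth` (sample x gene sense/antisense
#'   counts), `contam` (per-sample class counts), `sheet`, `paths`
#' @export
simulate_reads <- function(config, layout, index, design = NULL,
                           sheet = NULL, dir = tempfile("simreads")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- sim_design(config, index)
  if (is.null(sheet)) sheet <- sim_sample_sheet(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  fail_plan <- plan_qc_failures(config, sheet)
  txinfo <- transcript_info(index)
  rrna_genes <- index$genes[biotype == "rRNA", gene_id]
  chrm_genes <- index$genes[chrom == "chrM", gene_id]

  sam_paths <- character(0)
  truth <- list()
  contam <- list()
  for (i in seq_len(nrow(sheet))) {
    smp <- sheet[i]
    set.seed(derive_seed(config$seed, 100L + i))
    n_total <- config$fragments_per_sample
    fr <- fail_plan[sample == smp$sample]
    fracs <- c(rrna = fr$rrna, chrm = fr$chrm, cross = fr$cross)
    n_contam <- round(n_total * fracs)
    n_expr <- n_total - sum(n_contam)
    if (n_expr <= 0) stop("config error: contamination leaves no expression")

    rates <- sample_rates(design, smp$tissue, smp$disease)
    wsum <- sum(rates$sense) + sum(rates$anti)
    if (wsum <= 0) stop("config error: zero total expression in sample ",
                        smp$sample)
    lam_s <- rates$sense / wsum * n_expr
    lam_a <- rates$anti / wsum * n_expr
    draw <- function(lam) {
      if (config$overdispersion > 0)
        stats::rnbinom(length(lam), mu = lam, size = 1 / config$overdispersion)
      else stats::rpois(length(lam), lam)
    }
    cnt_s <- draw(lam_s)
    cnt_a <- draw(lam_a)

    # contamination source genes (sense-channel fragments)
    other <- setdiff(c("PR", "PRCS"), smp$tissue)
    cross_genes <- design$markers[[other]]
    spread <- function(total, gene_set) {
      if (total == 0L || !length(gene_set)) return(integer(length(gene_set)))
      as.integer(stats::rmultinom(1, total, rep(1, length(gene_set))))
    }
    add_s <- stats::setNames(integer(nrow(rates)), rates$gene_id)
    cl_of <- stats::setNames(rep("expr", nrow(rates)), rates$gene_id)
    for (cls in c("rrna", "chrm", "cross")) {
      gs <- switch(cls, rrna = rrna_genes, chrm = chrm_genes, cross = cross_genes)
      cc <- spread(n_contam[[cls]], gs)
      add_s[gs] <- add_s[gs] + cc
      cl_of[gs[cc > 0]] <- cls
    }

    emit <- list()
    serial <- 0L
    for (k in seq_len(nrow(rates))) {
      gidk <- rates$gene_id[k]
      for (ch in c("sense", "antisense")) {
        cnt <- if (ch == "sense") cnt_s[k] + add_s[[gidk]] else cnt_a[k]
        if (cnt == 0L) next
        cls <- if (ch == "sense") cl_of[[gidk]] else "expr"
        emit[[length(emit) + 1L]] <-
          emit_gene_fragments(gidk, ch, cls, cnt, txinfo, index, config,
                              smp$sample, serial)
        serial <- serial + cnt
      }
    }
    recs <- data.table::rbindlist(emit)
    sam <- file.path(dir, paste0(smp$sample, ".sam"))
    write_sam(recs, layout, sam)
    sam_paths[smp$sample] <- sam

    tr <- data.table::data.table(gene_id = rates$gene_id,
                                 sense = cnt_s + as.integer(add_s),
                                 antisense = cnt_a)
    tr[, sample := smp$sample]
    truth[[i]] <- tr
    contam[[i]] <- data.table::data.table(
      sample = smp$sample, class = names(n_contam),
      count = as.integer(n_contam),
      planted_fail = fr$planted_fail)
  }

  truth <- data.table::rbindlist(truth)[, .(sample, gene_id, sense, antisense)]
  contam <- data.table::rbindlist(contam)
  paths <- list(
    truth = file.path(dir, "truth_counts.tsv"),
    contam = file.path(dir, "truth_contamination.tsv"),
    sheet = file.path(dir, "sample_sheet.tsv"))
  data.table::fwrite(truth, paths$truth, sep = "\t")
  data.table::fwrite(contam, paths$contam, sep = "\t")
  data.table::fwrite(sheet, paths$sheet, sep = "\t")
  list(sam = sam_paths, truth = truth, contam = contam,
       sheet = sheet, paths = paths, dir = dir)
}

# Which samples are planted to fail QC, and with what fractions.
# Failures are spread across (tissue, disease) cells deterministically.
plan_qc_failures <- function(config, sheet) {
  fp <- data.table::data.table(sample = sheet$sample,
                               rrna = config$contamination$rrna,
                               chrm = config$contamination$chrm,
                               cross = config$contamination$cross,
                               planted_fail = "none")
  nf <- config$qc_failures
  classes <- rep(c("rrna", "chrm", "cross"),
                 c(nf$rrna %||% 0L, nf$chrm %||% 0L, nf$cross %||% 0L))
  if (!length(classes)) return(fp)
  if (length(classes) > nrow(sheet))
    stop("config error: more planted failures than samples")
  # deterministic spread: every k-th sample
  idx <- round(seq(1, nrow(sheet), length.out = length(classes) + 1L))[-1L]
  idx <- unique(pmin(idx, nrow(sheet)))
  while (length(idx) < length(classes))
    idx <- unique(c(idx, setdiff(seq_len(nrow(sheet)), idx)[1L]))
  for (j in seq_along(classes)) {
    cls <- classes[j]
    fp[idx[j], (cls) := config$fail_fractions[[cls]]]
    fp[idx[j], planted_fail := cls]
  }
  fp
}

# Per-transcript structure used for fragment placement: exons in transcript
# (5'->3') order with transcript-coordinate offsets.
transcript_info <- function(index) {
  ex <- data.table::copy(index$exons)
  ex[, fwd := strand == "+"]
  data.table::setorder(ex, transcript_id, start)
  ex[fwd == FALSE, ord := rev(seq_len(.N)), by = transcript_id]
  ex[fwd == TRUE, ord := seq_len(.N), by = transcript_id]
  data.table::setorder(ex, transcript_id, ord)
  ex[, len := end - start]
  ex[, toff := cumsum(c(0L, len[-.N])), by = transcript_id]
  tx <- ex[, .(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
               txlen = sum(len)), by = transcript_id]
  list(exons = ex, tx = tx)
}

# Map transcript-coordinate windows [a, b) to genomic 0-based blocks.
# win: data.table(wid, transcript_id, a, b). Returns data.table(wid, start, end)
# with blocks sorted genomically within wid.
tx_windows_to_blocks <- function(win, txinfo) {
  ex <- txinfo$exons
  pieces <- ex[win, on = .(transcript_id), allow.cartesian = TRUE][
    toff < b & toff + len > a]
  pieces[, ia := pmax(a, toff)]
  pieces[, ib := pmin(b, toff + len)]
  pieces[fwd == TRUE, `:=`(gs = start + (ia - toff), ge = start + (ib - toff))]
  pieces[fwd == FALSE, `:=`(gs = end - (ib - toff), ge = end - (ia - toff))]
  out <- pieces[, .(wid, start = gs, end = ge)]
  data.table::setorder(out, wid, start)
  out
}

# Emit SAM records for `cnt` fragments of one gene/channel.
emit_gene_fragments <- function(gene_id, channel, class, cnt, txinfo, index,
                                config, sample_id, serial0) {
  gid_target <- gene_id
  txs <- txinfo$tx[txinfo$tx[["gene_id"]] == gid_target]
  pick <- txs[sample.int(nrow(txs), cnt, replace = TRUE)]
  rl <- config$read_length
  fl <- pmax(rl, pmin(round(stats::rnorm(cnt, config$fragment_length_mean,
                                         config$fragment_length_sd)),
                      pick$txlen))
  fl <- pmin(fl, pick$txlen)
  fs <- floor(stats::runif(cnt, 0, pick$txlen - fl + 1))

  trans_strand <- if (channel == "sense") pick$strand else
    ifelse(pick$strand == "+", "-", "+")
  qname <- sprintf("%s:%s:%s:%s:%06d", sample_id, gene_id,
                   substr(channel, 1, 1), class, serial0 + seq_len(cnt))

  win <- data.table::rbindlist(list(
    data.table::data.table(wid = seq_len(cnt), mate = 1L,
                           transcript_id = pick$transcript_id,
                           a = fs, b = fs + rl),
    data.table::data.table(wid = seq_len(cnt), mate = 2L,
                           transcript_id = pick$transcript_id,
                           a = fs + fl - rl, b = fs + fl)))
  win[, wid2 := wid * 2L + mate - 2L]
  blocks <- tx_windows_to_blocks(
    win[, .(wid = wid2, transcript_id, a, b)], txinfo)
  reads <- blocks[, .(pos = start[1L] + 1L,
                      cigar = blocks_to_cigar(start, end),
                      rend = end[.N]), by = wid]
  reads[, fid := (wid - 1L) %/% 2L]           # zero-based fragment idx + 1 fix
  reads[, mate := wid - fid * 2L - 1L + 1L]   # 1 or 2 (transcript 5' / 3')
  reads[, fid := fid - 0L]
  data.table::setorder(reads, wid)
  w1 <- reads[mate == 1L]
  w2 <- reads[mate == 2L]

  # genomic left/right mate (transcript windows are genomically swapped on -)
  left_is_w1 <- w1$pos <= w2$pos
  lpos <- ifelse(left_is_w1, w1$pos, w2$pos)
  lcig <- ifelse(left_is_w1, w1$cigar, w2$cigar)
  lend <- ifelse(left_is_w1, w1$rend, w2$rend)
  rpos <- ifelse(left_is_w1, w2$pos, w1$pos)
  rcig <- ifelse(left_is_w1, w2$cigar, w1$cigar)
  rend <- ifelse(left_is_w1, w2$rend, w1$rend)
  tlen <- pmax(rend, lend) - (lpos - 1L)

  # read labelling: under firststrand, read 2 carries the transcription
  # strand, i.e. it is the mate at the fragment's 5' end — genomically the
  # left mate when the transcription strand is "+", the right mate when "-".
  proto <- config$protocol
  left_is_read2 <- switch(proto,
    firststrand = trans_strand == "+",
    secondstrand = trans_strand == "-",
    unstranded = stats::runif(cnt) < 0.5)
  # left mate maps forward, right mate reverse (FR orientation)
  base <- 1L + 2L
  lflag <- base + 32L + ifelse(left_is_read2, 128L, 64L)
  rflag <- base + 16L + ifelse(left_is_read2, 64L, 128L)

  seq <- strrep("A", rl)
  qual <- strrep("I", rl)
  chrom <- pick$chrom
  data.table::data.table(
    qname = rep(qname, 2L),
    flag = c(lflag, rflag),
    chrom = rep(chrom, 2L),
    pos = c(lpos, rpos),
    mapq = 60L,
    cigar = c(lcig, rcig),
    rnext = "=",
    pnext = c(rpos, lpos),
    tlen = c(tlen, -tlen),
    seq = seq, qual = qual)
}

#' Simulate count matrices for differential-expression calibration
#'
#' Direct count-level generator (no reads) for null-calibration and power
#' studies of the moderated-t pipeline: two groups, per-gene log-normal mean
#' counts, Poisson or negative-binomial sampling, and an optional planted
#' fold change on a subset of genes in group 2.
#'
#' @param seed integer seed
#' @param n_genes number of genes
#' @param n_per_group replicates per group
#' @param meanlog,sdlog log-normal distribution of baseline mean counts
#' @param n_de number of genes with planted fold change (first `n_de` genes)
#' @param fold fold change applied in group 2
#' @param overdispersion NB overdispersion (0 = Poisson)
#' @return list: `counts` (genes x samples integer matrix), `group` (factor),
#'   `de_genes` (character vector of planted gene ids)
#' @export
sim_counts_matrix <- function(seed, n_genes, n_per_group,
                              meanlog = log(100), sdlog = 1,
                              n_de = 0L, fold = 1,
                              overdispersion = 0) {
  set.seed(derive_seed(seed, 3L))
  mu <- stats::rlnorm(n_genes, meanlog, sdlog)
  group <- factor(rep(c("A", "B"), each = n_per_group), levels = c("A", "B"))
  de <- seq_len(n_de)
  m <- matrix(0L, n_genes, 2L * n_per_group)
  for (j in seq_len(ncol(m))) {
    muj <- mu
    if (group[j] == "B" && n_de > 0L) muj[de] <- muj[de] * fold
    m[, j] <- if (overdispersion > 0)
      stats::rnbinom(n_genes, mu = muj, size = 1 / overdispersion)
    else stats::rpois(n_genes, muj)
  }
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- paste0(group, rep(seq_len(n_per_group), 2L))
  list(counts = m, group = group, de_genes = rownames(m)[de])
}
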