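test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_replicates = 1L, fragments_per_sample = 800L)
  a1 <- simulate_annotation(cfg, tempfile("det1"))
  a2 <- simulate_annotation(cfg, tempfile("det2"))
  expect_identical(readLines(a1$gtf), readLines(a2$gtf))
  r1 <- simulate_reads(cfg, a1$layout, a1$index, dir = tempfile("det1r"))
  r2 <- simulate_reads(cfg, a2$layout, a2$index, dir = tempfile("det2r"))
  for (s in names(r1$sam))
    expect_identical(readLines(r1$sam[[s]]), readLines(r2$sam[[s]]))
  expect_identical(r1$truth, r2$truth)
})

test_that("simulated annotation honours the configured biotypes and layout", {
  s <- small_sim()
  idx <- load_gtf(s$ann$gtf, filter_pseudogenes = FALSE)
  expect_equal(table(idx$genes$biotype)[names(s$cfg$n_genes)],
               table(rep(names(s$cfg$n_genes), s$cfg$n_genes))[names(s$cfg$n_genes)])
  expect_true(all(idx$genes[biotype == "Mt_rRNA", chrom] == "chrM"))
  expect_false(any(idx$genes[biotype == "rRNA", chrom] == "chrM"))
  # intronic antisense-biotype genes sit opposite to their host's strand
  anti <- idx$genes[biotype == "antisense"]
  hosts <- idx$genes[biotype == "protein_coding"]
  for (i in seq_len(nrow(anti))) {
    host <- hosts[chrom == anti$chrom[i] & start < anti$start[i] &
                    end > anti$end[i]]
    expect_gte(nrow(host), 1L)
    expect_true(all(host$strand != anti$strand[i]))
  }
})

test_that("multi-exon fraction lands within binomial 99% bounds", {
  cfg <- sim_config(seed = 9,
                    n_genes = c(protein_coding = 60L, lincRNA = 40L),
                    multi_exon_fraction = 0.5,
                    n_markers = 2L, n_antisense_activate = 2L,
                    n_antisense_fold = 2L)
  ann <- simulate_annotation(cfg, tempfile("mef"))
  multi <- ann$index$exons[, .(multi = data.table::uniqueN(start) > 1L),
                           by = gene_id]
  n_multi <- sum(multi$multi)
  bounds <- qbinom(c(0.005, 0.995), 100L, 0.5)
  expect_gte(n_multi, bounds[1])
  expect_lte(n_multi, bounds[2])
})

test_that("planted design is disjoint and null-only designs are empty", {
  s <- small_sim()
  de <- plant_de_design(s$design)
  expect_false(any(duplicated(de[, .(tissue, gene_id)])))
  expect_equal(nrow(de[tissue == "PR" & kind == "activation"]),
               s$cfg$n_antisense_activate)
  expect_equal(de[kind == "fold", unique(fold)], s$cfg$antisense_fold)

  null_cfg <- sim_config(seed = 3, antisense_baseline_fraction = 0,
                         n_antisense_activate = 0L, n_antisense_fold = 0L)
  expect_equal(nrow(plant_de_design(null_cfg)), 0L)
})

test_that("zero anti-sense rates yield zero anti-sense truth everywhere", {
  cfg <- sim_config(seed = 13, n_replicates = 1L,
                    fragments_per_sample = 600L,
                    antisense_baseline_fraction = 0,
                    n_antisense_activate = 0L, n_antisense_fold = 0L)
  ann <- simulate_annotation(cfg, tempfile("zaa"))
  rd <- simulate_reads(cfg, ann$layout, ann$index, dir = tempfile("zar"))
  expect_true(all(rd$truth$antisense == 0L))
})

test_that("truth table records exactly the fragments emitted to SAM", {
  s <- small_sim()
  sam <- s$reads$sam[["S01"]]
  qn <- unique(antisenseq:::sam_record_qnames(sam))
  tr <- qname_truth(qn)
  emitted <- tr[, .N, by = .(gene_id, channel)]
  truth <- data.table::melt(s$reads$truth[sample == "S01"],
                            id.vars = c("sample", "gene_id"),
                            measure.vars = c("sense", "antisense"),
                            variable.name = "channel", value.name = "N")
  truth <- truth[N > 0][, .(gene_id, channel = as.character(channel), N)]
  m <- merge(emitted, truth, by = c("gene_id", "channel"), all = TRUE)
  expect_false(anyNA(m))
  expect_equal(m$N.x, m$N.y)
  # sample totals equal emitted fragment totals
  expect_equal(sum(s$reads$truth[sample == "S01", sense + antisense]),
               length(qn))
})

test_that("firststrand flags put read 2 on the transcription strand", {
  s <- small_sim()
  frags <- reconstruct_fragments(s$reads$sam[["S01"]], "firststrand")
  tr <- qname_truth(frags$fragments$qname)
  gstrand <- s$ann$index$genes[match(tr$gene_id, gene_id), strand]
  planted <- ifelse(tr$channel == "sense", gstrand,
                    ifelse(gstrand == "+", "-", "+"))
  # 100% of fragments carry the planted transcription strand
  expect_equal(frags$fragments$strand, planted)
})

test_that("emitted fragments respect their source gene's exon structure", {
  s <- small_sim()
  frags <- reconstruct_fragments(s$reads$sam[["S02"]], "firststrand")
  tr <- qname_truth(frags$fragments$qname)
  idx <- s$ann$index
  bl <- merge(frags$blocks,
              data.table::data.table(fid = frags$fragments$fid,
                                     gene_id = tr$gene_id),
              by = "fid")
  u <- data.table::copy(idx$union)[, .(gene_id, us = start, ue = end,
                                       start, end)]
  bl[, `:=`(bs = start, be = end)]
  cont <- u[bl, on = .(gene_id, start <= bs, end >= be), nomatch = NA,
            .(fid = i.fid, hit = !is.na(x.us))]
  expect_true(all(cont$hit))
  # every emitted junction is annotated for the source gene
  jn <- merge(frags$junctions,
              data.table::data.table(fid = frags$fragments$fid,
                                     gene_id = tr$gene_id), by = "fid")
  gj <- unique(idx$junctions[, .(gene_id, donor, acceptor)])
  miss <- jn[!gj, on = .(gene_id, donor, acceptor)]
  expect_equal(nrow(miss), 0L)
})

test_that("a planted anti-sense fold change is realized in truth counts", {
  cfg <- sim_config(seed = 31, n_replicates = 5L,
                    fragments_per_sample = 8000L)
  ann <- simulate_annotation(cfg, tempfile("fc"))
  design <- sim_design(cfg, ann$index)
  sheet <- sim_sample_sheet(cfg)
  pr <- sheet[tissue == "PR"]
  rd <- simulate_reads(cfg, ann$layout, ann$index, design, pr,
                       tempfile("fcr"))
  fold_genes <- design$fold_sets$PR
  tr <- merge(rd$truth, pr[, .(sample, disease)], by = "sample")
  x_d <- tr[gene_id %in% fold_genes & disease == "AMD", sum(antisense)]
  x_n <- tr[gene_id %in% fold_genes & disease == "normal", sum(antisense)]
  # X_d | total ~ Binomial(total, 4/5) under the planted 4x fold
  total <- x_d + x_n
  ci <- qbinom(c(0.005, 0.995), total, cfg$antisense_fold /
                 (cfg$antisense_fold + 1))
  expect_gte(x_d, ci[1])
  expect_lte(x_d, ci[2])
  # activation genes: zero anti-sense truth in normals, nonzero in disease
  act <- design$activate$PR
  expect_equal(tr[gene_id %in% act & disease == "normal", sum(antisense)], 0L)
  expect_true(all(tr[gene_id %in% act & disease == "AMD",
                     sum(antisense), by = sample]$V1 > 0L))
})

test_that("count-matrix generator plants the requested structure", {
  x <- sim_counts_matrix(seed = 4, n_genes = 50, n_per_group = 3,
                         n_de = 10, fold = 4)
  expect_equal(dim(x$counts), c(50L, 6L))
  expect_equal(length(x$de_genes), 10L)
  expect_true(all(x$counts >= 0) && all(x$counts == round(x$counts)))
  y <- sim_counts_matrix(seed = 4, n_genes = 50, n_per_group = 3,
                         n_de = 10, fold = 4)
  expect_identical(x$counts, y$counts)
})
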