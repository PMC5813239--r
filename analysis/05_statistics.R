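#!/usr/bin/env Rscript

# Stage 5: downstream statistics.
#
# Expression calls at normalized average coverage >= 1, biotype
# distributions, the most-variable ncRNAs by coefficient of variation,
# Jensen-Shannon-divergence hierarchical clustering of all three signal
# classes, and moderated-t differential expression (disease vs normal within
# tissue) with the per-tissue q-value presets.

suppressMessages(library(antisenseq))
suppressMessages(library(data.table))

out <- "results/study"
for (d in c("clusters", "de")) dir.create(file.path(out, d),
                                          recursive = TRUE,
                                          showWarnings = FALSE)
retained <- fread(file.path(out, "qc", "retained_samples.tsv"))
idx <- load_gtf(file.path(out, "sim", "annotation.gtf"),
                filter_pseudogenes = TRUE)
target_depth <- fread(file.path(out, "normalized",
                                "norm_plan.tsv"))$kept_depth[1]

read_mat <- function(f) {
  d <- fread(file.path(out, "counts", f))
  m <- as.matrix(d[, -1]); rownames(m) <- d[[1]]
  m
}
cov <- list(sense = read_mat("sense_avg_coverage.tsv"),
            antisense = read_mat("antisense_avg_coverage.tsv"),
            ncRNA = read_mat("ncRNA_avg_coverage.tsv"))
cnt <- list(sense = read_mat("sense_counts.tsv"),
            antisense = read_mat("antisense_counts.tsv"),
            ncRNA = read_mat("ncRNA_counts.tsv"))

groups <- setNames(paste(retained$tissue, retained$disease, sep = "."),
                   retained$sample)
calls <- call_expressed(cov$ncRNA, cutoff = 1, groups = groups)
bio <- biotype_distribution(calls, classify_biotypes(idx), groups)
fwrite(bio$by_group, file.path(out, "counts", "biotype_distribution.tsv"),
       sep = "\t")
cat("ncRNA expressed in >= 1 sample:", bio$universe, "genes\n")

topv <- top_variable(cov$ncRNA, n = 1000L)
fwrite(topv, file.path(out, "counts", "top_variable_ncrna.tsv"), sep = "\t")

grp2 <- setNames(retained$tissue, retained$sample)
for (cls in names(cov)) {
  m <- cov[[cls]]; m <- m[rowSums(m) > 0, , drop = FALSE]
  d <- jsd_matrix(m)
  tr <- hcluster(d)
  fwrite(as.data.table(d, keep.rownames = "sample"),
         file.path(out, "clusters", paste0(cls, "_jsd.tsv")), sep = "\t")
  write_newick(tr, file.path(out, "clusters", paste0(cls, "_tree.nwk")))
  c4 <- cut_purity(tr, 4, groups); c2 <- cut_purity(tr, 2, grp2)
  cat(sprintf("%-10s 4-cut purity %.2f (separates: %s); tissue 2-cut: %s\n",
              cls, c4$purity, c4$separates, c2$separates))
}

presets <- de_q_presets()
for (ts in unique(retained$tissue)) {
  sub <- retained[tissue == ts]
  grp <- factor(sub$disease, levels = c("normal", "AMD"))
  for (cls in names(cnt)) {
    m <- cnt[[cls]][, sub$sample, drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    res <- voom_de(round(m), grp, lib_size = target_depth)
    qcut <- presets[tissue == ts & signal_class == cls, q_cutoff]
    res[, significant := q_value <= qcut]
    fwrite(res, file.path(out, "de", paste0(ts, ".", cls, ".tsv")),
           sep = "\t")
    cat(sprintf("DE %s/%s: %d up, %d down at q <= %g\n", ts, cls,
                nrow(res[significant == TRUE & direction == "up"]),
                nrow(res[significant == TRUE & direction == "down"]), qcut))
  }
}
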