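#!/usr/bin/env Rscript

# Stage 1: simulate the study.
#
# Emulates a two-tissue (PR / PRCS), two-state (normal / AMD) donor-eye
# design: 8 replicates per cell (32 stranded paired-end libraries, 100 bp
# reads), disease-only anti-sense activation on tissue-specific gene sets,
# and six samples planted to fail QC (one rRNA-heavy, three chrM-heavy, two
# cross-tissue contaminated) — the structure the downstream stages are meant
# to recover. Everything below results/study/sim is derived from the seed.

suppressMessages(library(antisenseq))
suppressMessages(library(data.table))

seed <- 20L
out <- "results/study"
dir.create(file.path(out, "sim"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_replicates = 8L,
                  fragments_per_sample = 8000L,
                  qc_failures = list(rrna = 1L, chrm = 3L, cross = 2L))
ann <- simulate_annotation(cfg, file.path(out, "sim"))
design <- sim_design(cfg, ann$index)
sheet <- sim_sample_sheet(cfg)
rd <- simulate_reads(cfg, ann$layout, ann$index, design, sheet,
                     file.path(out, "sim"))

# persist what later stages need beyond the SAM/GTF/truth files
markers <- rbindlist(lapply(names(design$markers), function(ts)
  data.table(tissue = ts, gene_id = design$markers[[ts]])))
fwrite(markers, file.path(out, "sim", "tissue_markers.tsv"), sep = "\t")
fwrite(plant_de_design(design), file.path(out, "sim", "planted_de.tsv"),
       sep = "\t")
writeLines(as.character(seed), file.path(out, "sim", "seed.txt"))

cat("simulated", nrow(sheet), "samples x", cfg$fragments_per_sample,
    "fragments over", nrow(ann$index$genes), "genes\n")
cat("planted QC failures:",
    paste(rd$contam[planted_fail != "none", unique(sample)], collapse = " "),
    "\n")
cat("planted anti-sense DE genes per tissue: PR =",
    length(design$activate$PR) + length(design$fold_sets$PR),
    ", PRCS =", length(design$activate$PRCS) + length(design$fold_sets$PRCS),
    "\n")
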