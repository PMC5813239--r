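#!/usr/bin/env Rscript

# Stage 2: sample quality control.
#
# Computes mapping rate, rRNA fraction, chrM fraction and the cross-tissue
# contamination score for every library, then excludes samples by the fixed
# rule precedence (mapping < rRNA < chrM < contamination). On the simulated
# study exactly the six planted failures should fall out, leaving 26.

suppressMessages(library(antisenseq))
suppressMessages(library(data.table))

out <- "results/study"
dir.create(file.path(out, "qc"), recursive = TRUE, showWarnings = FALSE)

sheet <- fread(file.path(out, "sim", "sample_sheet.tsv"))
markers_tab <- fread(file.path(out, "sim", "tissue_markers.tsv"))
markers <- split(markers_tab$gene_id, markers_tab$tissue)
idx <- load_gtf(file.path(out, "sim", "annotation.gtf"),
                filter_pseudogenes = TRUE)
thr <- qc_thresholds()

reports <- rbindlist(lapply(sheet$sample, function(s)
  compute_qc(file.path(out, "sim", paste0(s, ".sam")), idx,
             sheet[sample == s, tissue], markers, thr, sample_id = s)))
fwrite(reports, file.path(out, "qc", "qc_report.tsv"), sep = "\t")
retained <- filter_samples(reports, sheet)
fwrite(retained, file.path(out, "qc", "retained_samples.tsv"), sep = "\t")

cat("retained", nrow(retained), "of", nrow(sheet), "samples\n")
print(reports[verdict != "pass",
              .(sample, verdict, rrna_fraction = round(rrna_fraction, 3),
                chrm_fraction = round(chrm_fraction, 3),
                contamination_score = round(contamination_score, 3))])
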