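#!/usr/bin/env Rscript

# Stage 3: read-level depth normalization.
#
# Every retained library is subsampled fragment-wise (mates together) to the
# minimum fragment depth, so that "average coverage" downstream is computed
# on directly comparable files and needs no further per-gene scaling.

suppressMessages(library(antisenseq))
suppressMessages(library(data.table))

out <- "results/study"
seed <- as.integer(readLines(file.path(out, "sim", "seed.txt")))
retained <- fread(file.path(out, "qc", "retained_samples.tsv"))

sam <- setNames(file.path(out, "sim", paste0(retained$sample, ".sam")),
                retained$sample)
norm <- normalize_samples(sam, seed = seed,
                          out_dir = file.path(out, "normalized"))
fwrite(norm$plan$samples, file.path(out, "normalized", "norm_plan.tsv"),
       sep = "\t")

cat("normalized", nrow(retained), "samples to",
    norm$plan$target_depth, "fragments each\n")
cat("keep probabilities ranged",
    round(min(norm$plan$samples$keep_prob), 3), "-",
    round(max(norm$plan$samples$keep_prob), 3), "\n")
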