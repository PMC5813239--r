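#!/usr/bin/env Rscript

# Stage 6: cis co-localization of DE non-coding genes.
#
# Builds GREAT-style regulatory domains (basal 5 kb up / 1 kb down of each
# protein-coding TSS, extended to the nearest flanking basal domain up to
# 1 Mb) and assigns every differentially expressed non-coding gene, by locus
# midpoint, to the coding genes whose domain contains it — the gene mapping
# a pathway tool would consume.

suppressMessages(library(antisenseq))
suppressMessages(library(data.table))

out <- "results/study"
dir.create(file.path(out, "colocalization"), recursive = TRUE,
           showWarnings = FALSE)
idx <- load_gtf(file.path(out, "sim", "annotation.gtf"),
                filter_pseudogenes = TRUE)

domains <- build_domains(idx)
fwrite(domains, file.path(out, "colocalization", "regulatory_domains.tsv"),
       sep = "\t")

de_nc <- unique(unlist(lapply(c("PR", "PRCS"), function(ts) {
  f <- file.path(out, "de", paste0(ts, ".ncRNA.tsv"))
  if (!file.exists(f)) return(character())
  fread(f)[significant == TRUE, gene_id]
})))
if (!length(de_nc)) {
  cat("no DE ncRNA at the preset q cutoffs; nothing to co-localize\n")
} else {
  hits <- assign_cis(de_nc, idx, domains)
  fwrite(hits, file.path(out, "colocalization", "de_ncrna_cis.tsv"),
         sep = "\t")
  assigned <- hits[!is.na(coding_gene), data.table::uniqueN(ncrna_id)]
  cat("co-localized", assigned, "of", length(de_nc),
      "DE ncRNA to protein-coding neighbours\n")
  print(head(hits[!is.na(coding_gene)], 10))
}
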