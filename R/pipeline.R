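# Orchestration: simulate (or ingest) -> QC -> read-level normalization ->
# sense/anti-sense quantification -> statistics -> cis co-localization,
# from one config, with a fixed output layout and a manifest recording every
# seed and threshold actually used. Rerunning the same config reproduces
# byte-identical TSV outputs.

#' Default pipeline configuration
#'
#' @param seed master seed for every stochastic stage
#' @param outdir output directory
#' @param sim named list of overrides passed to [sim_config()]
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L, outdir = tempfile("antisenseq"),
                           sim = list()) {
  list(
    seed = seed,
    outdir = outdir,
    simulate = TRUE,
    sim = sim,
    annotation = NULL,      # GTF path when not simulating
    alignments = NULL,      # named sample -> SAM path when not simulating
    sample_sheet = NULL,    # TSV path when not simulating
    markers = NULL,         # named list tissue -> gene ids (required w/o sim)
    protocol = "firststrand",
    qc = list(min_mapped_fraction = 0.93, max_rrna_fraction = 0.35,
              max_chrm_fraction = 0.20, max_contamination_score = 0.10),
    chrm_contig = "chrM",
    coverage_cutoff = 1,
    top_n = 1000L,
    linkage = "average",
    strict_span = TRUE,
    q_presets = de_q_presets()
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML path
#' @return configuration list
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (k %in% c("qc", "sim") && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages write into `qc/`, `normalized/`, `counts/`, `tracks/`, `de/`,
#' `clusters/`, `colocalization/` and `logs/` under `config$outdir`;
#' `manifest.yaml` records seeds, thresholds and decided defaults. Any stage
#' failure aborts with the stage name in the error.
#'
#' @param config list from [default_config()] / [read_pipeline_config()]
#' @return invisible list of key in-memory results (`index`, `sheet`,
#'   `tables`, `de`, `clusters`, `coloc`, `qc`, `sim`)
#' @export
run_pipeline <- function(config) {
  out <- config$outdir
  dirs <- file.path(out, c("qc", "normalized", "counts", "tracks", "de",
                           "clusters", "colocalization", "logs"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "logs", "pipeline.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----------------------------------------------------------
  sim_out <- NULL
  if (isTRUE(config$simulate)) {
    scfg <- stage("simulate", do.call(sim_config, c(list(seed = config$seed),
                                                    config$sim)))
    ann <- stage("simulate", simulate_annotation(scfg, file.path(out, "sim")))
    design <- stage("simulate", sim_design(scfg, ann$index))
    sheet <- sim_sample_sheet(scfg)
    say("simulating ", nrow(sheet), " samples x ",
        scfg$fragments_per_sample, " fragments")
    sim_out <- stage("simulate",
                     simulate_reads(scfg, ann$layout, ann$index, design,
                                    sheet, file.path(out, "sim")))
    gtf <- ann$gtf
    layout <- ann$layout
    alignments <- sim_out$sam
    markers <- design$markers
  } else {
    gtf <- config$annotation
    layout <- NULL
    alignments <- unlist(config$alignments)
    sheet <- data.table::fread(config$sample_sheet)
    markers <- config$markers
    if (is.null(markers)) stop("pipeline stage [input] failed: markers ",
                               "required when not simulating")
  }
  index <- stage("annotation",
                 load_gtf(gtf, filter_pseudogenes = TRUE, layout = layout))
  say("annotation: ", nrow(index$genes), " genes after pseudogene filter")

  # ---- qc --------------------------------------------------------------
  thr <- do.call(qc_thresholds, config$qc)
  qc_rep <- stage("qc", data.table::rbindlist(lapply(sheet$sample, function(s)
    compute_qc(alignments[[s]], index, sheet[sample == s, tissue],
               markers, thr, sample_id = s,
               chrm_contig = config$chrm_contig))))
  qc_hdr <- sprintf("# thresholds: min_mapped=%.2f max_rrna=%.2f max_chrm=%.2f max_contamination=%.2f",
                    thr$min_mapped_fraction, thr$max_rrna_fraction,
                    thr$max_chrm_fraction, thr$max_contamination_score)
  writeLines(qc_hdr, file.path(out, "qc", "qc_report.tsv"))
  data.table::fwrite(qc_rep, file.path(out, "qc", "qc_report.tsv"),
                     sep = "\t", append = TRUE, col.names = TRUE)
  retained <- stage("qc", filter_samples(qc_rep, sheet))
  say("qc: retained ", nrow(retained), " of ", nrow(sheet), " samples")
  data.table::fwrite(retained, file.path(out, "qc", "retained_samples.tsv"),
                     sep = "\t")

  # ---- normalize -------------------------------------------------------
  norm <- stage("normalize",
                normalize_samples(alignments[retained$sample],
                                  seed = config$seed,
                                  out_dir = file.path(out, "normalized")))
  data.table::fwrite(norm$plan$samples,
                     file.path(out, "normalized", "norm_plan.tsv"), sep = "\t")
  say("normalized all samples to ", norm$plan$target_depth, " fragments")

  # ---- quantify --------------------------------------------------------
  quants <- stage("quant", {
    qs <- lapply(retained$sample, function(s)
      quantify_sample(norm$sam[[s]], index, protocol = config$protocol,
                      strict_span = config$strict_span))
    stats::setNames(qs, retained$sample)
  })
  tables <- stage("quant", count_tables(quants, index, retained))
  for (cls in c("sense", "antisense", "ncRNA")) {
    data.table::fwrite(
      data.table::as.data.table(tables[[cls]]$counts, keep.rownames = "gene_id"),
      file.path(out, "counts", paste0(cls, "_counts.tsv")), sep = "\t")
    data.table::fwrite(
      data.table::as.data.table(tables[[cls]]$avg_coverage,
                                keep.rownames = "gene_id"),
      file.path(out, "counts", paste0(cls, "_avg_coverage.tsv")), sep = "\t")
  }
  data.table::fwrite(tables$sidecar,
                     file.path(out, "counts", "channel_totals.tsv"), sep = "\t")
  say("quantified ", sum(tables$sidecar$total), " fragments across ",
      nrow(retained), " samples")

  if (!is.null(layout)) {
    grp <- stats::setNames(paste(retained$tissue, retained$disease, sep = "."),
                           retained$sample)
    stage("tracks", coverage_tracks(quants, layout, file.path(out, "tracks"),
                                    groups = grp))
  }

  # ---- statistics ------------------------------------------------------
  groups <- stats::setNames(paste(retained$tissue, retained$disease, sep = "."),
                            retained$sample)
  calls <- stage("stats", call_expressed(tables$ncRNA$avg_coverage,
                                         cutoff = config$coverage_cutoff,
                                         groups = groups))
  bio <- stage("stats", biotype_distribution(calls, classify_biotypes(index),
                                             groups))
  data.table::fwrite(bio$by_group,
                     file.path(out, "counts", "biotype_distribution.tsv"),
                     sep = "\t")
  say("expressed ncRNA universe: ", bio$universe, " genes")
  topv <- stage("stats", top_variable(tables$ncRNA$avg_coverage,
                                      n = config$top_n))
  data.table::fwrite(topv, file.path(out, "counts", "top_variable_ncrna.tsv"),
                     sep = "\t")

  clusters <- list()
  for (cls in c("sense", "antisense", "ncRNA")) {
    expr <- tables[[cls]]$avg_coverage
    expr <- expr[rowSums(expr) > 0, , drop = FALSE]
    if (!nrow(expr) || any(colSums(expr) == 0)) {
      say("clustering skipped for ", cls, " (empty signal)")
      next
    }
    d <- stage("cluster", jsd_matrix(expr))
    tr <- stage("cluster", hcluster(d, linkage = config$linkage))
    clusters[[cls]] <- tr
    data.table::fwrite(data.table::as.data.table(d, keep.rownames = "sample"),
                       file.path(out, "clusters", paste0(cls, "_jsd.tsv")),
                       sep = "\t")
    write_newick(tr, file.path(out, "clusters", paste0(cls, "_tree.nwk")))
  }

  de <- list()
  for (ts in unique(retained$tissue)) {
    sub <- retained[tissue == ts]
    if (length(unique(sub$disease)) < 2L || any(table(sub$disease) < 2L)) {
      say("DE skipped for ", ts, " (insufficient replication)")
      next
    }
    grp <- factor(sub$disease, levels = c("normal", "AMD"))
    for (cls in c("sense", "antisense", "ncRNA")) {
      cnt <- tables[[cls]]$counts[, sub$sample, drop = FALSE]
      keep <- rowSums(cnt) > 0
      if (sum(keep) < 2L) next
      # samples are depth-equalized, so the common normalized depth is the
      # library size for every channel (absolute scale, no compositional bias)
      res <- stage("de", voom_de(round(cnt[keep, , drop = FALSE]), grp,
                                 lib_size = norm$plan$target_depth))
      qcut <- config$q_presets[tissue == ts & signal_class == cls, q_cutoff]
      res[, significant := q_value <= qcut]
      res[, `:=`(tissue = ts, signal_class = cls, q_cutoff = qcut)]
      key <- paste(ts, cls, sep = ".")
      de[[key]] <- res
      data.table::fwrite(res, file.path(out, "de", paste0(key, ".tsv")),
                         sep = "\t")
      say("DE ", key, ": ", sum(res$significant), " genes at q <= ", qcut)
    }
  }

  # ---- co-localization -------------------------------------------------
  coloc <- NULL
  domains <- stage("colocalize", build_domains(index))
  data.table::fwrite(domains,
                     file.path(out, "colocalization", "regulatory_domains.tsv"),
                     sep = "\t")
  de_nc <- unique(unlist(lapply(de[grep("ncRNA$", names(de))],
                                function(r) r[significant == TRUE, gene_id])))
  if (length(de_nc)) {
    coloc <- stage("colocalize", assign_cis(de_nc, index, domains))
    data.table::fwrite(coloc,
                       file.path(out, "colocalization", "de_ncrna_cis.tsv"),
                       sep = "\t")
    say("co-localized ", length(de_nc), " DE ncRNA to coding neighbours")
  }

  manifest <- list(
    package = "antisenseq",
    version = as.character(utils::packageVersion("antisenseq")),
    seed = config$seed,
    protocol = config$protocol,
    simulate = isTRUE(config$simulate),
    qc_thresholds = config$qc,
    coverage_cutoff = config$coverage_cutoff,
    top_n = config$top_n,
    linkage = config$linkage,
    strict_span = config$strict_span,
    assignment = list(mode = "structural",
                      sense_precedence_over_antisense = TRUE,
                      ambiguous_counted = FALSE,
                      unit = "fragments"),
    cv = list(sd = "sample (n-1)", zero_mean_genes = "excluded"),
    q_presets = as.data.frame(config$q_presets))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  say("pipeline complete: ", out)
  invisible(list(index = index, sheet = retained, tables = tables, de = de,
                 clusters = clusters, coloc = coloc, qc = qc_rep,
                 sim = sim_out, norm = norm, quants = quants, outdir = out))
}
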