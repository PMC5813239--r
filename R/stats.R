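# Downstream statistics: coverage-based expression calls, biotype
# distributions, most-variable ncRNA selection, Jensen-Shannon-divergence
# hierarchical clustering, and voom-style precision-weighted moderated-t
# differential expression with Benjamini-Hochberg q-values.

#' Call expressed genes from average coverage
#'
#' A gene is called expressed in a sample when its normalized average
#' coverage reaches the cutoff (inclusive: coverage exactly 1.0 is expressed
#' under the default cutoff of 1).
#'
#' @param cov gene x sample matrix of average coverage
#' @param cutoff non-negative coverage cutoff (default 1)
#' @param groups optional named vector sample -> group label for the summary
#' @return object of class `expression_call`: `calls` (logical matrix),
#'   `cutoff`, `n_expressed` (per sample), `group_means` (mean expressed-gene
#'   count per group, when `groups` given)
#' @export
call_expressed <- function(cov, cutoff = 1, groups = NULL) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  stopifnot(is.matrix(cov), all(cov >= 0))
  calls <- cov >= cutoff
  n_expr <- colSums(calls)
  gm <- NULL
  if (!is.null(groups)) {
    g <- groups[colnames(cov)]
    gm <- tapply(n_expr, g, mean)
  }
  structure(list(calls = calls, cutoff = cutoff, n_expressed = n_expr,
                 group_means = gm),
            class = "expression_call")
}

#' @export
print.expression_call <- function(x, ...) {
  cat("expression_call: cutoff", x$cutoff, "|",
      sum(rowSums(x$calls) > 0), "of", nrow(x$calls),
      "genes expressed in >= 1 sample\n")
  invisible(x)
}

#' Rank genes by coefficient of variation, keep the top n
#'
#' CV = sample (n-1) standard deviation / mean of average coverage across all
#' samples. Genes with zero mean are excluded before ranking; ties are broken
#' by gene id, lexicographically, so the ranking is deterministic.
#'
#' @param cov gene x sample matrix (>= 2 columns)
#' @param n how many genes to keep (default 1000, the study's choice)
#' @return data.table: gene_id, mean, sd, cv, in descending CV order,
#'   truncated to `n` rows (all rows, with a message, if fewer are available)
#' @export
top_variable <- function(cov, n = 1000L) {
  if (ncol(cov) < 2L) stop("need >= 2 samples to estimate variability")
  mu <- rowMeans(cov)
  sd_ <- apply(cov, 1L, stats::sd)
  d <- data.table::data.table(gene_id = rownames(cov), mean = mu, sd = sd_)
  d <- d[mean > 0]
  d[, cv := sd / mean]
  data.table::setorder(d, -cv, gene_id)
  if (n > nrow(d)) {
    message("only ", nrow(d), " genes with nonzero mean; returning all")
    n <- nrow(d)
  }
  d[seq_len(n)]
}

#' Jensen-Shannon divergence matrix between samples
#'
#' Each column is normalized to a probability vector P; JSD(P, Q) =
#' KL(P||M)/2 + KL(Q||M)/2 with M = (P+Q)/2, logarithms base 2 (so the
#' divergence is bounded by 1, attained on disjoint supports), and the
#' convention 0 * log 0 = 0.
#'
#' @param expr non-negative gene x sample matrix; every column must have a
#'   positive sum
#' @return symmetric sample x sample matrix of divergences
#' @export
jsd_matrix <- function(expr) {
  stopifnot(is.matrix(expr))
  if (any(expr < 0)) stop("expression values must be non-negative")
  cs <- colSums(expr)
  if (any(cs == 0))
    stop("zero-sum expression column for sample(s): ",
         paste(colnames(expr)[cs == 0], collapse = ", "))
  p <- sweep(expr, 2L, cs, "/")
  n <- ncol(p)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  h <- function(x) -colSums(plogp(x))  # Shannon entropy, bits
  hp <- h(p)
  d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      m <- (p[, i] + p[, j]) / 2
      d[i, j] <- d[j, i] <- -sum(plogp(m)) - (hp[i] + hp[j]) / 2
    }
  }
  pmax(d, 0)
}

#' Hierarchical clustering of samples from a distance matrix
#'
#' @param dist_mat symmetric non-negative distance matrix (e.g.
#'   [jsd_matrix()])
#' @param linkage linkage method for [stats::hclust()] (default "average")
#' @return object of class `cluster_tree`: `hclust` fit, `dist_mat`,
#'   `linkage`
#' @export
hcluster <- function(dist_mat, linkage = "average") {
  if (!isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  fit <- stats::hclust(stats::as.dist(dist_mat), method = linkage)
  structure(list(hclust = fit, dist_mat = dist_mat, linkage = linkage),
            class = "cluster_tree")
}

#' Cut a cluster tree and report purity against known labels
#'
#' @param tree a [hcluster()] result
#' @param k number of flat clusters
#' @param labels named vector sample -> label (e.g. "PR.AMD")
#' @return list: `clusters` (named cluster ids), `table` (cluster x label),
#'   `purity` (weighted mean of per-cluster majority fractions),
#'   `separates` (TRUE when the k-cut recovers the labels exactly: every
#'   cluster is pure and distinct labels never share a cluster)
#' @export
cut_purity <- function(tree, k, labels) {
  stopifnot(inherits(tree, "cluster_tree"))
  cl <- stats::cutree(tree$hclust, k = k)
  lab <- labels[names(cl)]
  tab <- table(cluster = cl, label = lab)
  maj <- apply(tab, 1L, max)
  purity <- sum(maj) / sum(tab)
  pure <- all(rowSums(tab > 0) == 1L)
  one_cluster_per_label <- all(colSums(tab > 0) == 1L)
  list(clusters = cl, table = tab, purity = purity,
       separates = pure && one_cluster_per_label)
}

#' Export a cluster tree as Newick
#'
#' @param tree a [hcluster()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  rec <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6f", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6f",
              rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- nrow(hc$merge)
  txt <- paste0("(", rec(hc$merge[n, 1], hc$height[n]), ",",
                rec(hc$merge[n, 2], hc$height[n]), ");")
  writeLines(txt, path)
  invisible(path)
}

#' Benjamini-Hochberg q-values
#'
#' @param p vector of p-values in [0, 1]
#' @return q-values (same order as input)
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Moderated-t differential expression (voom-style)
#'
#' Two-group contrast on a count table: log2-CPM with a 0.5 offset, a lowess
#' mean-variance trend yielding inverse-variance observation weights,
#' per-gene weighted least squares, empirical-Bayes shrinkage of residual
#' variances toward a pooled prior (moderated t with augmented degrees of
#' freedom), two-sided p-values and BH q-values. Implemented on limma
#' (voom / lmFit / eBayes). With `weights = "none"` and `shrink = FALSE` the
#' fit reduces to ordinary per-gene least squares t-tests on log2-CPM.
#'
#' @param counts gene x sample matrix of non-negative integer counts
#' @param group factor/character of length ncol(counts) with exactly two
#'   levels; the reported log2 fold change is level 2 minus level 1
#' @param weights `"voom"` (precision weights, default) or `"none"`
#' @param shrink apply empirical-Bayes variance moderation (default TRUE)
#' @param span lowess span for the voom trend (default 0.5); with fewer than
#'   10 genes the trend cannot be fit and uniform weights are used
#' @param lib_size library sizes for the CPM scale: `NULL` (column sums of
#'   `counts`) or a single number / vector. After read-level depth
#'   normalization every sample has the same total fragment count, so the
#'   pipeline passes that constant here; this keeps a channel's counts on an
#'   absolute scale and avoids the compositional bias that per-channel
#'   column-sum normalization would introduce when DE is asymmetric (as
#'   anti-sense activation is).
#' @return data.table of class `de_result`: gene_id, log2fc, t, p_value,
#'   q_value, direction ("up" = higher in level 2)
#' @export
voom_de <- function(counts, group, weights = c("voom", "none"),
                    shrink = TRUE, span = 0.5, lib_size = NULL) {
  weights <- match.arg(weights)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("degenerate design: need exactly two groups, got ", nlevels(group))
  if (any(table(group) < 2L))
    stop("degenerate design: need >= 2 samples per group")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  design <- stats::model.matrix(~group)
  lib <- if (is.null(lib_size)) colSums(counts) else
    rep_len(lib_size, ncol(counts))
  lib[lib == 0] <- 1
  use_voom <- weights == "voom" && nrow(counts) >= 10L
  if (use_voom) {
    v <- limma::voom(counts, design, span = span, lib.size = lib)
    fit <- limma::lmFit(v, design)
  } else {
    logcpm <- log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)
    fit <- limma::lmFit(logcpm, design)
  }
  if (shrink) {
    fit <- limma::eBayes(fit)
    tt <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none")
    res <- data.table::data.table(gene_id = rownames(tt),
                                  log2fc = tt$logFC, t = tt$t,
                                  p_value = tt$P.Value)
  } else {
    se <- fit$stdev.unscaled[, 2L] * fit$sigma
    tstat <- fit$coefficients[, 2L] / se
    pv <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
    res <- data.table::data.table(gene_id = rownames(counts),
                                  log2fc = fit$coefficients[, 2L],
                                  t = tstat, p_value = pv)
  }
  res[, q_value := bh_adjust(p_value)]
  res[, direction := ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none"))]
  data.table::setattr(res, "class", c("de_result", class(res)))
  res[]
}

#' The study's per-signal-class q-value presets
#'
#' Anti-sense contrasts use q <= 1e-4 (PR) and q <= 1e-3 (PRCS); sense and
#' ncRNA contrasts use q <= 0.05 (PR) and q <= 0.25 (PRCS).
#'
#' @return data.table: tissue, signal_class, q_cutoff
#' @export
de_q_presets <- function() {
  data.table::data.table(
    tissue = rep(c("PR", "PRCS"), each = 3L),
    signal_class = rep(c("antisense", "sense", "ncRNA"), 2L),
    q_cutoff = c(1e-4, 0.05, 0.05, 1e-3, 0.25, 0.25))
}

#' Biotype distribution of expressed genes
#'
#' Counts expressed genes per biotype within each sample group, plus the
#' "expressed in >= 1 sample" universe size.
#'
#' @param calls an [call_expressed()] result
#' @param biotypes named list biotype -> gene ids ([classify_biotypes()])
#' @param groups named vector sample -> group label
#' @return list: `by_group` (data.table: group, biotype, n_expressed;
#'   a gene counts once per group when expressed in any sample of it),
#'   `universe` (number of genes expressed in >= 1 sample overall)
#' @export
biotype_distribution <- function(calls, biotypes, groups) {
  stopifnot(inherits(calls, "expression_call"))
  m <- calls$calls
  bt_of <- rep(names(biotypes), lengths(biotypes))
  names(bt_of) <- unlist(biotypes)
  rows <- list()
  for (g in unique(groups[colnames(m)])) {
    cols <- colnames(m)[groups[colnames(m)] == g]
    expressed <- rownames(m)[rowSums(m[, cols, drop = FALSE]) > 0]
    tab <- table(bt_of[expressed])
    if (length(tab))
      rows[[g]] <- data.table::data.table(group = g, biotype = names(tab),
                                          n_expressed = as.integer(tab))
  }
  by_group <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(group = character(), biotype = character(),
                           n_expressed = integer())
  list(by_group = by_group,
       universe = sum(rowSums(m) > 0))
}
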