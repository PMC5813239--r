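test_that("expression calls are inclusive at the cutoff and monotone", {
  cov <- matrix(c(1.0, 0.99, 0, 2.5), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ec <- call_expressed(cov, cutoff = 1)
  expect_true(ec$calls["g1", "s1"])      # exactly 1.0 is expressed
  expect_false(ec$calls["g2", "s1"])
  expect_equal(sum(call_expressed(matrix(0, 3, 2))$calls), 0L)
  expect_error(call_expressed(cov, cutoff = -1), "non-negative")
  # monotone: raising the cutoff never adds calls
  for (cut in c(0, 0.5, 1, 2, 3)) {
    lo <- call_expressed(cov, cutoff = cut)$calls
    hi <- call_expressed(cov, cutoff = cut + 0.5)$calls
    expect_true(all(lo >= hi))
  }
})

test_that("CV ranking matches hand values and the brute-force oracle", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                10, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:3)))
  tv <- top_variable(m, n = 3)
  expect_equal(tv[gene_id == "gA", cv], 0.5)          # sd 1, mean 2
  expect_equal(tv[gene_id == "gB", cv], 0)            # constant row: last
  expect_equal(tv$gene_id[3], "gB")

  set.seed(42)
  big <- matrix(rpois(200 * 8, 20), 200, 8,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  got <- top_variable(big, n = 50)
  mu <- rowMeans(big); sdv <- apply(big, 1, sd)
  keep <- mu > 0
  ord <- order(-(sdv[keep] / mu[keep]), rownames(big)[keep])
  expect_equal(got$gene_id, rownames(big)[keep][ord][1:50])
  expect_message(top_variable(m, n = 10), "returning all")
})

test_that("Jensen-Shannon divergence has its exact landmark values", {
  p <- c(0.5, 0.5); q <- c(1, 0)
  m <- cbind(a = p, b = p, c = q, d = c(0, 1))
  d <- jsd_matrix(m)
  expect_equal(d["a", "b"], 0)                 # JSD(P,P) = 0
  expect_equal(d["c", "d"], 1)                 # disjoint supports, log2
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(jsd_matrix(cbind(a = c(0, 0))), "zero-sum.*a")
  expect_error(jsd_matrix(cbind(a = c(-1, 2))), "non-negative")
})

test_that("JSD equals the direct summation oracle and sqrt-JSD is metric", {
  set.seed(7)
  m <- matrix(rexp(5 * 30), 30, 5, dimnames = list(NULL, paste0("s", 1:5)))
  d <- jsd_matrix(m)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], oracle_jsd(m[, i], m[, j]))
  r <- sqrt(d)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(r[i, j], r[i, k] + r[k, j] + 1e-12)
})

test_that("hierarchical clustering recovers planted structure", {
  # two identical samples merge first at height zero
  m <- cbind(a = c(3, 1, 4), b = c(3, 1, 4), c = c(10, 0, 1))
  tr <- hcluster(jsd_matrix(m))
  expect_equal(tr$hclust$height[1], 0)
  expect_equal(sort(tr$hclust$labels[-tr$hclust$merge[1, ]]), c("a", "b"))
  expect_error(hcluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  # planted two-block structure is recovered exactly at the 2-cut
  set.seed(11)
  base1 <- rexp(40); base2 <- rexp(40)
  blockA <- sapply(1:4, function(i) rpois(40, 60 * base1))
  blockB <- sapply(1:4, function(i) rpois(40, 60 * base2))
  mm <- cbind(blockA, blockB)
  colnames(mm) <- c(paste0("A", 1:4), paste0("B", 1:4))
  labels <- stats::setNames(rep(c("A", "B"), each = 4), colnames(mm))
  cut <- cut_purity(hcluster(jsd_matrix(mm)), 2, labels)
  expect_true(cut$separates)
  expect_equal(cut$purity, 1)
})

test_that("newick export preserves the tree's leaves", {
  m <- cbind(a = c(3, 1, 4), b = c(2, 1, 5), c = c(10, 0, 1), d = c(1, 1, 1))
  tr <- hcluster(jsd_matrix(m))
  p <- write_newick(tr, tempfile(fileext = ".nwk"))
  txt <- readLines(p)
  for (lab in colnames(m)) expect_match(txt, lab)
  expect_match(txt, ";$")
})

test_that("BH adjustment matches the hand-stepped and brute-force values", {
  expect_equal(bh_adjust(0.02), 0.02)                       # single p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  for (i in 1:5) {
    p <- runif(25)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    # order invariance and monotonicity along sorted p
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated-t DE is calibrated and detects planted fold changes", {
  null <- sim_counts_matrix(seed = 21, n_genes = 1000, n_per_group = 5)
  lib <- sum(rowMeans(null$counts))
  de <- voom_de(null$counts, null$group, lib_size = lib)
  expect_gt(mean(de$p_value <= 0.05), 0.02)
  expect_lt(mean(de$p_value <= 0.05), 0.08)

  pw <- sim_counts_matrix(seed = 22, n_genes = 1000, n_per_group = 5,
                          n_de = 100, fold = 4)
  d2 <- voom_de(pw$counts, pw$group, lib_size = sum(rowMeans(pw$counts)))
  sig <- d2[q_value <= 0.05, gene_id]
  expect_gte(mean(pw$de_genes %in% sig), 0.9)
  expect_true(all(d2[gene_id %in% pw$de_genes & q_value <= 0.05,
                     direction] == "up"))
})

test_that("a gene with identical counts in both groups is null", {
  x <- sim_counts_matrix(seed = 30, n_genes = 99, n_per_group = 4)
  counts <- rbind(x$counts, flat = rep(50L, 8L))
  de <- voom_de(counts, x$group, lib_size = 1e6)
  expect_equal(de[gene_id == "flat", log2fc], 0, tolerance = 1e-9)
  expect_gt(de[gene_id == "flat", p_value], 0.95)
})

test_that("without weights and shrinkage the fit is an ordinary t-test", {
  x <- sim_counts_matrix(seed = 33, n_genes = 300, n_per_group = 5)
  de <- voom_de(x$counts, x$group, weights = "none", shrink = FALSE)
  # oracle: per-gene equal-variance t-test on the same log2-CPM values
  lib <- colSums(x$counts)
  logcpm <- log2(t((t(x$counts) + 0.5) / (lib + 1)) * 1e6)
  pv <- apply(logcpm, 1, function(y)
    t.test(y[x$group == "B"], y[x$group == "A"], var.equal = TRUE)$p.value)
  expect_gte(cor(rank(de$p_value), rank(pv)), 0.99)
  expect_equal(de$p_value, unname(pv), tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  x <- sim_counts_matrix(seed = 2, n_genes = 20, n_per_group = 2)
  expect_error(voom_de(x$counts, rep("A", 4)), "two groups")
  expect_error(voom_de(x$counts, c("A", "A", "A", "B")), ">= 2 samples")
  expect_error(voom_de(x$counts + 0.5, x$group), "non-negative integers")
  expect_error(voom_de(x$counts * -1L, x$group), "non-negative integers")
})

test_that("biotype distribution tallies expressed genes per group", {
  cov <- matrix(c(2, 0, 0, 2,
                  2, 2, 0, 0,
                  0, 0, 0, 0), 3, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  groups <- stats::setNames(c("X", "X", "Y", "Y"), paste0("s", 1:4))
  calls <- call_expressed(cov, 1, groups)
  biotypes <- list(lincRNA = c("g1", "g3"), snoRNA = "g2")
  bd <- biotype_distribution(calls, biotypes, groups)
  expect_equal(bd$universe, 2L)   # g1, g2 expressed somewhere; g3 never
  expect_equal(bd$by_group[group == "X" & biotype == "lincRNA", n_expressed], 1L)
  expect_equal(bd$by_group[group == "X" & biotype == "snoRNA", n_expressed], 1L)
  expect_equal(bd$by_group[group == "Y" & biotype == "lincRNA", n_expressed], 1L)
  expect_false(nrow(bd$by_group[group == "Y" & biotype == "snoRNA"]) > 0)
  # all-zero matrix -> empty table
  none <- call_expressed(matrix(0, 3, 4, dimnames = dimnames(cov)), 1, groups)
  expect_equal(nrow(biotype_distribution(none, biotypes, groups)$by_group), 0L)
})

test_that("the study's q-value presets are exposed per tissue and class", {
  qp <- de_q_presets()
  expect_equal(qp[tissue == "PR" & signal_class == "antisense", q_cutoff], 1e-4)
  expect_equal(qp[tissue == "PRCS" & signal_class == "antisense", q_cutoff], 1e-3)
  expect_equal(qp[tissue == "PR" & signal_class == "sense", q_cutoff], 0.05)
  expect_equal(qp[tissue == "PRCS" & signal_class == "ncRNA", q_cutoff], 0.25)
})
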