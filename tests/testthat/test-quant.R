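# The annotation used throughout: GA (+, exons [100,200)+[300,400)) and
# GB (-, single exon [1000,1200)) as in the toy GTF, plus designed overlap
# cases built per test.

toy_idx <- function() load_gtf(toy_gtf_file(), filter_pseudogenes = TRUE)

test_that("fragment reconstruction decodes CIGAR blocks and junctions", {
  lay <- genome_layout("chr1", 100000L)
  # one pair: read2 forward at 1001 with 50M200N50M, read1 reverse at 1290
  rec <- data.table::data.table(
    qname = "f1", flag = c(163L, 83L), chrom = "chr1",
    pos = c(1001L, 1290L), mapq = 60L,
    cigar = c("50M200N50M", "11M"), rnext = "=",
    pnext = c(1290L, 1001L), tlen = c(300L, -300L),
    seq = c(strrep("A", 100), strrep("A", 11)),
    qual = c(strrep("I", 100), strrep("I", 11)))
  sam <- tempfile(fileext = ".sam")
  write_sam(rec, lay, sam)
  fr <- reconstruct_fragments(sam, "firststrand")
  expect_equal(nrow(fr$fragments), 1L)
  # 0-based blocks: [1000,1050), [1250,1300) (read1 merges into block 2)
  expect_equal(fr$blocks[, .(start, end)],
               data.table::data.table(start = c(1000L, 1250L),
                                      end = c(1050L, 1300L)))
  expect_equal(fr$junctions[, .(donor, acceptor)],
               data.table::data.table(donor = 1050L, acceptor = 1250L))
  # firststrand: read2 (+) carries the transcription strand
  expect_equal(fr$fragments$strand, "+")
  fr2 <- reconstruct_fragments(sam, "secondstrand")
  expect_equal(fr2$fragments$strand, "-")
  fr3 <- reconstruct_fragments(sam, "unstranded")
  expect_equal(fr3$fragments$strand, "*")
})

test_that("splice-form compatibility follows exon and junction structure", {
  idx <- toy_idx()
  frags <- make_fragments(
    blocks = list(
      cbind(120, 180),                 # inside exon 1          -> compatible
      cbind(150, 250),                 # straddles exon/intron  -> no
      rbind(c(150, 200), c(300, 350)), # junction-spanning      -> compatible
      rbind(c(150, 200), c(300, 350)), # wrong junction         -> no
      rbind(c(195, 200), c(300, 305)), # detached blocks across the intron,
                                       # junction unobserved    -> no (strict)
      cbind(1100, 1150)),              # inside GB              -> no (for GA)
    junctions = list(NULL, NULL, cbind(200, 300), cbind(200, 310),
                     NULL, NULL),
    strand = "+")
  frags$blocks <- frags$blocks  # blocks already merged per construction
  got <- compatible_with_transcript(frags, idx, "GA.T1")
  expect_equal(got, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  relaxed <- compatible_with_transcript(frags, idx, "GA.T1",
                                        strict_span = FALSE)
  expect_equal(relaxed, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("channel assignment applies strand and sense precedence", {
  idx <- toy_idx()
  frags <- make_fragments(
    blocks = list(cbind(120, 180), cbind(120, 180),
                  rbind(c(150, 200), c(300, 350)),
                  cbind(1100, 1150), cbind(5000, 5100)),
    junctions = list(NULL, NULL, cbind(200, 300), NULL, NULL),
    strand = c("+", "-", "-", "-", "+"))
  asn <- assign_fragments(frags, idx)
  expect_equal(asn$channel,
               c("sense", "antisense", "antisense", "sense", "unassigned"))
  expect_equal(asn$gene_id, c("GA", "GA", "GA", "GB", NA))
})

test_that("sense precedence protects against overlapping opposite genes", {
  idx <- make_index(
    genes = data.table::data.table(
      gene_id = c("X", "Y"), strand = c("+", "-"),
      biotype = "protein_coding"),
    exons = data.table::data.table(
      gene_id = c("X", "Y"), transcript_id = c("X.T1", "Y.T1"),
      start = c(100L, 150L), end = c(400L, 450L)))
  both <- make_fragments(blocks = list(cbind(200, 300), cbind(200, 300)),
                         strand = c("+", "-"))
  asn <- assign_fragments(both, idx)
  # compatible with both genes; the same-strand gene always wins as sense
  expect_equal(asn$gene_id, c("X", "Y"))
  expect_equal(asn$channel, c("sense", "sense"))

  # two same-strand overlapping genes -> ambiguous
  idx2 <- make_index(
    genes = data.table::data.table(
      gene_id = c("X", "Y"), strand = "+", biotype = "protein_coding"),
    exons = data.table::data.table(
      gene_id = c("X", "Y"), transcript_id = c("X.T1", "Y.T1"),
      start = c(100L, 150L), end = c(400L, 450L)))
  amb <- assign_fragments(make_fragments(list(cbind(200, 300)), "+"), idx2)
  expect_equal(amb$channel, "ambiguous")
  expect_true(is.na(amb$gene_id))
})

test_that("assignments match the brute-force base-level oracle", {
  s <- small_sim()
  norm <- cached("small_norm", normalize_samples(
    s$reads$sam["S01"], seed = 3, out_dir = tempfile("qnorm"),
    target_depth = 600L))
  frags <- reconstruct_fragments(norm$sam[[1]], "firststrand")
  got <- assign_fragments(frags, s$index)
  want <- oracle_assign(frags, s$index)
  expect_equal(got$channel, want$channel)
  expect_equal(got$gene_id, want$gene_id)
})

test_that("channel totals conserve the fragment count exactly", {
  s <- small_sim()
  q <- cached("small_quant_S01",
              quantify_sample(s$reads$sam[["S01"]], s$index))
  expect_identical(sum(q$totals[c("sense", "antisense", "ambiguous",
                                  "unassigned")]),
                   q$totals[["total"]])
  expect_identical(q$totals[["total"]], nrow(q$fragments$fragments))
})

test_that("flipping every fragment strand swaps the two channels", {
  # designed annotation: no opposite-strand overlaps anywhere
  idx <- make_index(
    genes = data.table::data.table(
      gene_id = c("A", "B"), strand = c("+", "-"),
      biotype = c("protein_coding", "lincRNA")),
    exons = data.table::data.table(
      gene_id = c("A", "A", "B"), transcript_id = c("A.T1", "A.T1", "B.T1"),
      start = c(100L, 500L, 5000L), end = c(300L, 700L, 5500L)))
  frags <- make_fragments(
    blocks = list(cbind(150, 250), rbind(c(250, 300), c(500, 550)),
                  cbind(5100, 5200), cbind(5300, 5400)),
    junctions = list(NULL, cbind(300, 500), NULL, NULL),
    strand = c("+", "-", "-", "+"))
  a1 <- assign_fragments(frags, idx)
  flipped <- frags
  flipped$fragments <- data.table::copy(frags$fragments)
  flipped$fragments[, strand := ifelse(strand == "+", "-", "+")]
  a2 <- assign_fragments(flipped, idx)
  expect_equal(a1$gene_id, a2$gene_id)
  swap <- c(sense = "antisense", antisense = "sense")
  expect_equal(unname(swap[a1$channel]), a2$channel)
})

test_that("average coverage equals aligned bases over union length", {
  # gene with a 100 bp exon union; one fully covering 100-base fragment
  idx <- make_index(
    genes = data.table::data.table(gene_id = "G", strand = "+",
                                   biotype = "protein_coding"),
    exons = data.table::data.table(gene_id = "G", transcript_id = "G.T1",
                                   start = 100L, end = 200L))
  full <- make_fragments(blocks = list(cbind(100, 200)), strand = "+")
  q <- list(fragments = full, assignments = assign_fragments(full, idx))
  expect_equal(average_coverage(q, idx)$avg_coverage, 1.0)
  # 99 aligned bases over the 100 bp union: 0.99, below the >= 1 cutoff
  partial <- make_fragments(blocks = list(cbind(100, 199)), strand = "+")
  qp <- list(fragments = partial, assignments = assign_fragments(partial, idx))
  expect_equal(average_coverage(qp, idx)$avg_coverage, 0.99)
  expect_lt(average_coverage(qp, idx)$avg_coverage, 1)

  # pileup oracle on simulated data
  s <- small_sim()
  qq <- cached("small_quant_S01",
               quantify_sample(s$reads$sam[["S01"]], s$index))
  cov2 <- average_coverage(qq, s$index)
  sens <- qq$assignments[channel == "sense"]
  for (g in head(unique(sens$gene_id), 5)) {
    want <- oracle_avg_coverage(qq$fragments, sens[gene_id == g, fid],
                                s$index, g)
    expect_equal(cov2[gene_id == g & channel == "sense", avg_coverage], want)
  }
})

test_that("count tables split channels and restrict ncRNA to non-coding", {
  s <- small_sim()
  q1 <- cached("small_quant_S01",
               quantify_sample(s$reads$sam[["S01"]], s$index))
  tabs <- count_tables(list(S01 = q1), s$index, s$sheet)
  expect_true(all(rownames(tabs$ncRNA$counts) %in% ncrna_genes(s$index)))
  expect_equal(tabs$ncRNA$counts,
               tabs$sense$counts[rownames(tabs$ncRNA$counts), , drop = FALSE])
  expect_equal(sum(tabs$sense$counts) + sum(tabs$antisense$counts) +
                 tabs$sidecar$ambiguous + tabs$sidecar$unassigned,
               tabs$sidecar$total)
  expect_error(count_tables(list(ZZZ = q1), s$index, s$sheet),
               "absent from sample sheet")

  # no antisense assignments -> all-zero antisense table
  idx <- toy_idx()
  frags <- make_fragments(blocks = list(cbind(120, 180)), strand = "+")
  q <- list(fragments = frags,
            assignments = assign_fragments(frags, idx),
            totals = c(sense = 1, antisense = 0, ambiguous = 0,
                       unassigned = 0, total = 1))
  t2 <- count_tables(list(S01 = q), idx,
                     data.table::data.table(sample = "S01"))
  expect_true(all(t2$antisense$counts == 0))
})

test_that("coverage tracks split strands and merge additively", {
  lay <- genome_layout("chr1", 1000L)
  idx <- toy_idx()
  mkq <- function(bl, strand) {
    frags <- make_fragments(blocks = bl, strand = strand)
    list(fragments = frags, assignments = assign_fragments(frags, idx))
  }
  q1 <- mkq(list(cbind(10, 20)), "+")
  q2 <- mkq(list(cbind(15, 25)), "+")
  dir <- tempfile("trk")
  tk <- coverage_tracks(list(S1 = q1, S2 = q2), lay, dir)
  p1 <- tk$coverage$S1[["+"]]$chr1
  expect_equal(sum(p1), 10L)                        # depth 1 on [10,20)
  expect_equal(as.integer(p1[11:20]), rep(1L, 10))
  expect_equal(sum(tk$coverage$S1[["-"]]$chr1), 0L) # minus empty
  # condition merge equals per-position sum of replicates
  mg <- coverage_tracks(list(S1 = q1, S2 = q2), lay, tempfile("trkm"),
                        groups = c(S1 = "g", S2 = "g"))
  expect_identical(mg$coverage$g[["+"]]$chr1,
                   tk$coverage$S1[["+"]]$chr1 + tk$coverage$S2[["+"]]$chr1)
  # bedGraph files exist with track lines
  expect_true(all(file.exists(tk$files)))
  expect_match(readLines(tk$files[1], n = 1), "^track type=bedGraph")
})
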