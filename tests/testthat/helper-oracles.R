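# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops, base-level set arithmetic, and direct
# application of textbook definitions.

# Interval union length and members by explicit base enumeration.
oracle_union_bases <- function(starts, ends) {
  if (!length(starts)) return(integer())
  sort(unique(unlist(mapply(function(s, e) seq.int(s, e - 1L), starts, ends,
                            SIMPLIFY = FALSE))))
}

# Base-level fragment-vs-transcript compatibility.
oracle_compatible <- function(frag_blocks, frag_juncs, tx_exons, tx_juncs,
                              strict_span = TRUE) {
  exonic <- oracle_union_bases(tx_exons$start, tx_exons$end)
  fb <- oracle_union_bases(frag_blocks$start, frag_blocks$end)
  if (!all(fb %in% exonic)) return(FALSE)
  jkey <- function(d) if (nrow(d)) paste(d$donor, d$acceptor) else character()
  fj <- jkey(frag_juncs); tj <- jkey(tx_juncs)
  if (!all(fj %in% tj)) return(FALSE)
  if (strict_span && nrow(tx_juncs)) {
    fs <- min(fb); fe <- max(fb) + 1L
    internal <- tx_juncs[tx_juncs$donor > fs & tx_juncs$acceptor < fe, ,
                         drop = FALSE]
    if (!all(jkey(internal) %in% fj)) return(FALSE)
  }
  TRUE
}

# Full brute-force assigner: every fragment against every transcript.
oracle_assign <- function(frags, index, strict_span = TRUE) {
  fr <- as.data.frame(frags$fragments)
  bl <- as.data.frame(frags$blocks)
  jn <- as.data.frame(frags$junctions)
  ex <- as.data.frame(index$exons)
  txj <- as.data.frame(index$junctions)
  gene_strand <- stats::setNames(index$genes$strand, index$genes$gene_id)
  tx_ids <- unique(ex$transcript_id)
  tx_list <- lapply(tx_ids, function(t) ex[ex$transcript_id == t, ])
  names(tx_list) <- tx_ids
  txj_list <- lapply(tx_ids, function(t) txj[txj$transcript_id == t, ])
  names(txj_list) <- tx_ids

  out <- data.frame(fid = fr$fid, gene_id = NA_character_,
                    channel = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    fb <- bl[bl$fid == f$fid, ]
    fj <- jn[jn$fid == f$fid, , drop = FALSE]
    sense_genes <- character(); anti_genes <- character()
    for (t in tx_ids) {
      te <- tx_list[[t]]
      if (te$chrom[1] != f$chrom || is.na(f$chrom)) next
      if (max(te$end) <= f$start || min(te$start) >= f$end) next
      if (oracle_compatible(fb, fj, te, txj_list[[t]], strict_span)) {
        g <- te$gene_id[1]
        if (f$strand == "*") {
          sense_genes <- c(sense_genes, g)  # unknown strand: any candidate
          anti_genes <- c(anti_genes, g)
        } else if (gene_strand[[g]] == f$strand) {
          sense_genes <- c(sense_genes, g)
        } else {
          anti_genes <- c(anti_genes, g)
        }
      }
    }
    sg <- unique(sense_genes); ag <- unique(anti_genes)
    if (f$strand == "*") {
      if (length(sg)) out$channel[i] <- "ambiguous"
    } else if (length(sg) == 1L) {
      out$gene_id[i] <- sg; out$channel[i] <- "sense"
    } else if (length(sg) > 1L) {
      out$channel[i] <- "ambiguous"
    } else if (length(ag) == 1L) {
      out$gene_id[i] <- ag; out$channel[i] <- "antisense"
    } else if (length(ag) > 1L) {
      out$channel[i] <- "ambiguous"
    }
  }
  out
}

# Benjamini-Hochberg by direct definition.
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, p[j] * m / rank_j)
      }
    }
    q[i] <- min(cand, 1)
  }
  q
}

# Jensen-Shannon divergence by direct elementwise KL summation (log2).
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# Per-base pileup coverage of one gene restricted to its exon union.
oracle_avg_coverage <- function(frags, fids, index, gene) {
  u <- index$union[index$union$gene_id == gene, ]
  ubases <- oracle_union_bases(u$start, u$end)
  depth <- 0
  for (f in fids) {
    b <- frags$blocks[frags$blocks$fid == f, ]
    fb <- oracle_union_bases(b$start, b$end)
    depth <- depth + sum(fb %in% ubases)
  }
  depth / length(ubases)
}

# GREAT-style regulatory domains by direct nearest-basal scan.
oracle_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                           max_ext = 1e6, chrom_len = NULL) {
  g <- as.data.frame(genes)
  tss <- ifelse(g$strand == "+", g$start, g$end)
  bs <- ifelse(g$strand == "+", tss - basal_up, tss - basal_down)
  be <- ifelse(g$strand == "+", tss + basal_down, tss + basal_up)
  bs <- pmax(bs, 0)
  if (!is.null(chrom_len)) be <- pmin(be, chrom_len)
  es <- numeric(nrow(g)); ee <- numeric(nrow(g))
  for (k in seq_len(nrow(g))) {
    same <- which(g$chrom == g$chrom[k])
    others <- setdiff(same, k)
    lstop <- -Inf; rstop <- Inf
    for (o in others) {
      if (be[o] <= bs[k]) lstop <- max(lstop, be[o])
      if (bs[o] >= be[k]) rstop <- min(rstop, bs[o])
    }
    es[k] <- min(max(tss[k] - max_ext, lstop, 0), bs[k])
    ee[k] <- max(min(tss[k] + max_ext,
                     if (!is.null(chrom_len)) chrom_len else Inf, rstop),
                 be[k])
  }
  data.frame(gene_id = g$gene_id, basal_start = bs, basal_end = be,
             ext_start = es, ext_end = ee)
}
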