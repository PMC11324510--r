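# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check (full-CDS translation diffs, exhaustive 20-mer
# scans, brute-force clustering).

# --- toy transcripts -------------------------------------------------------

# 12-bp plus-strand toy: CDS ATG GTG CGA TAA (M V R Ter)
toy_plus <- function() {
  ref <- c(chrT = "ATGGTGCGATAA")
  list(ref = ref,
       tx = transcript_model("toy", "chrT", "+", cbind(0L, 12L), 0L, 12L,
                             ref, validate_cds = TRUE))
}

# same construct on the minus strand (genome reverse-complemented)
toy_minus <- function() {
  ref <- c(chrT = revcomp("ATGGTGCGATAA"))
  list(ref = ref,
       tx = transcript_model("toyM", "chrT", "-", cbind(0L, 12L), 0L, 12L,
                             ref, validate_cds = TRUE))
}

random_codon <- function() {
  repeat {
    x <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
               collapse = "")
    if (!x %in% c("TAA", "TAG", "TGA")) return(x)
  }
}

# Synthetic minus-strand reconstruction of the TP53 target region: the
# transcript carries codon 196 = CGA (Arg) and codon 197 = GTG (Val), so
# the plus-strand window over those codons reads CACTCG (three cytosines).
# A plus-strand NGG PAM is planted so a CBE guide with the window at
# protospacer positions 3-8 covers it. Purely synthetic stand-in for the
# real chr17 locus.
tp53_like <- function(seed = 42) {
  set.seed(seed)
  codons <- c("ATG", replicate(194, random_codon()), "CGA", "GTG",
              random_codon(), "TAA")           # 199 codons
  cds <- paste(codons, collapse = "")
  sense <- paste0(paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
                  paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
                  cds,
                  paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
                  paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
  L <- nchar(sense)
  genome <- c(chr17s = revcomp(sense))
  ex_s <- 60L; ex_e <- 60L + 30L + nchar(cds) + 30L
  exons <- cbind(L - ex_e, L - ex_s)
  cds_s <- L - (90L + nchar(cds)); cds_e <- L - 90L
  # plus-strand window over transcript codons 196-197 (CDS offsets 585-590)
  ws <- cds_e - (585L + 6L); we <- cds_e - 585L
  # plant an NGG PAM for a plus-strand guide with the target C (window
  # offset 2 = protospacer position 5): GG at the PAM positions of the
  # placement that puts the window at protospacer 3-8
  g <- genome
  # placement with window at protospacer 3-8 has protospacer start ws-2
  # (0-based) and PAM at 0-based [ws+18, ws+21); force its GG
  substr(g["chr17s"], ws + 20L, ws + 21L) <- "GG"
  tx <- transcript_model("TP53like", "chr17s", "-", exons, cds_s, cds_e,
                         g, validate_cds = FALSE)
  list(ref = g, tx = tx, win = window_interval("chr17s", ws, we))
}

# --- oracles ---------------------------------------------------------------

# spliced CDS of a (possibly modified) genome, by direct string surgery
oracle_spliced_cds <- function(genome_str, tx) {
  lo <- pmax(tx$exons[, "start"], tx$cds_start)
  hi <- pmin(tx$exons[, "end"], tx$cds_end)
  keep <- hi > lo
  s <- paste(substring(genome_str, lo[keep] + 1L, hi[keep]), collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

# full-protein diff oracle for window haplotype calling: rebuild the CDS
# with the alt window applied, translate both proteins with Biostrings and
# diff them (independent of genomic_to_codon / codon rebuilding)
oracle_aa_changes <- function(win, alt_hap, tx, ref) {
  g0 <- ref[[tx$chrom]]
  g1 <- g0
  substr(g1, win$start + 1L, win$end) <- alt_hap
  translate_str <- function(s) {
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1L]]
    aa[aa == "*"] <- "Ter"
    aa
  }
  p0 <- translate_str(oracle_spliced_cds(g0, tx))
  p1 <- translate_str(oracle_spliced_cds(g1, tx))
  i <- which(p0 != p1)
  data.frame(ref_aa = p0[i], codon_index = i, alt_aa = p1[i],
             label = paste0(p0[i], i, p1[i]))
}

# exhaustive protospacer-placement oracle: all 20-mers on both strands
# with a PAM match immediately 3' whose editing window covers `target_pos`
# with the editor's from-base on the guide strand
oracle_guide_scan <- function(target_pos, ref, chrom, spec) {
  g <- ref[[chrom]]
  L <- nchar(g)
  plen <- nchar(spec$pam)
  hits <- list()
  pam_ok <- function(obs) {
    cls <- c(A = "A", C = "C", G = "G", T = "T", N = "ACGT", R = "AG",
             Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
    pb <- strsplit(spec$pam, "")[[1L]]
    ob <- strsplit(obs, "")[[1L]]
    all(mapply(function(p, o) grepl(o, cls[[p]], fixed = TRUE), pb, ob))
  }
  for (p0 in 0:(L - 20L)) {
    # plus strand
    if (p0 + 20L + plen <= L) {
      k <- target_pos - p0 + 1L
      if (k >= spec$window[1L] && k <= spec$window[2L] &&
          substring(g, target_pos + 1L, target_pos + 1L) == spec$from &&
          pam_ok(substring(g, p0 + 21L, p0 + 20L + plen)))
        hits[[length(hits) + 1L]] <- c(start = p0, strand = "+")
    }
    # minus strand: protospacer occupies [p0, p0+20), 5' end at p0+19
    if (p0 - plen >= 0L) {
      k <- p0 + 20L - target_pos
      if (k >= spec$window[1L] && k <= spec$window[2L] &&
          comp_base_t(substring(g, target_pos + 1L, target_pos + 1L)) ==
            spec$from &&
          pam_ok(revcomp(substring(g, p0 - plen + 1L, p0))))
        hits[[length(hits) + 1L]] <- c(start = p0, strand = "-")
    }
  }
  if (length(hits) == 0L) return(data.frame(start = integer(),
                                            strand = character()))
  out <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  out$start <- as.integer(out$start)
  out[order(out$start, out$strand), , drop = FALSE]
}

comp_base_t <- function(x) chartr("ACGT", "TGCA", x)

# brute-force single-linkage consolidation oracle: boolean transitive
# closure of the <= max_dist graph, representative by max count then
# lexicographic
oracle_consolidate <- function(counts, max_dist = 2L) {
  umis <- names(counts)
  n <- length(umis)
  adj <- utils::adist(umis, umis) <= max_dist
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- character(n)
  for (i in seq_len(n)) {
    memb <- which(reach[i, ])
    out[i] <- umis[memb[order(-counts[memb], umis[memb])][1L]]
  }
  stats::setNames(out, umis)
}

# brute-force per-position plurality oracle over call symbols
oracle_consensus <- function(calls) {
  syms <- c("A", "C", "G", "T", "-", ".")
  hap <- character(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    cnt <- vapply(syms, function(s) sum(calls[, j] == s), integer(1L))
    mx <- max(cnt)
    win <- syms[cnt == mx]
    if (length(win) != 1L || win %in% c("-", ".")) return(NULL)
    hap[j] <- win
  }
  paste(hap, collapse = "")
}

# naive agglomerative clustering oracle (complete linkage, euclidean),
# returning the k-group partition as a membership vector
oracle_hclust_cut <- function(x, k) {
  groups <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  cluster_dist <- function(a, b) max(d[a, b])
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      dd <- cluster_dist(groups[[i]], groups[[j]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  memb <- integer(nrow(x))
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  memb
}

# adjusted Rand index (for clustering recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# one-record alignment data.frame in read_alignments() layout
aln_row <- function(pos, cigar, seq, strand = "+", qname = "r1",
                    chrom = "chrT") {
  data.frame(qname = qname, flag = if (strand == "+") 0L else 16L,
             chrom = chrom, strand = strand, pos = pos, cigar = cigar,
             seq = seq)
}

# write a minimal SAM file from alignment rows
write_test_sam <- function(aln, path, chrom_len = 1000L, chrom = "chrT") {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  recs <- vapply(seq_len(nrow(aln)), function(i)
    paste(aln$qname[i], aln$flag[i], aln$chrom[i], aln$pos[i], 60L,
          aln$cigar[i], "*", 0L, 0L, aln$seq[i], "*", sep = "\t"),
    character(1L))
  writeLines(c(hdr, recs), path)
  path
}

# minimal FASTQ writer
write_test_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("q%03d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             vapply(seqs, function(s)
                               strrep("I", nchar(s)), character(1L)))),
             path)
  path
}
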