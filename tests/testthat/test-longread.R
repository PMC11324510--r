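# Soft-clip extraction, CIGAR window calls, UMI consolidation/consensus,
# per-cell genotypes and pipeline conservation/monotonicity.

ADPT <- "CTACACGACGCTCTTCCGATCT"
CB1 <- strrep("A", 16)
UMI1 <- strrep("G", 10)

test_that("extract_cb_umi parses 5' soft clips on both strands, rejects with reasons", {
  clip <- paste0("TTTTT", ADPT, CB1, UMI1)
  body <- strrep("ACGT", 10)
  aln <- rbind(
    aln_row(100L, paste0(nchar(clip), "S", nchar(body), "M"),
            paste0(clip, body), "+"),
    # minus strand: stored SEQ is body + revcomp(clip), clip trails
    aln_row(100L, paste0(nchar(body), "M", nchar(clip), "S"),
            paste0(body, revcomp(clip)), "-", qname = "r2"),
    aln_row(100L, paste0(nchar(body) + nchar(clip), "M"),
            paste0(clip, body), "+", qname = "r3"),       # no soft clip
    aln_row(100L, paste0(5L + nchar(ADPT) + 10L, "S", nchar(body), "M"),
            paste0("TTTTT", ADPT, substr(CB1, 1, 10), body), "+",
            qname = "r4"))                                 # truncated
  res <- extract_cb_umi(aln, whitelist = CB1)
  expect_equal(res$status, c("ok", "ok", "no_softclip", "truncated"))
  expect_equal(res$cb[1:2], c(CB1, CB1))
  expect_equal(res$umi[1:2], c(UMI1, UMI1))
})

test_that("a single barcode mismatch is rejected (exact whitelist matching)", {
  cb_mm <- paste0(strrep("A", 15), "C")     # 1 mismatch vs whitelist
  clip <- paste0(ADPT, cb_mm, UMI1)
  aln <- aln_row(100L, paste0(nchar(clip), "S40M"),
                 paste0(clip, strrep("ACGT", 10)), "+")
  res <- extract_cb_umi(aln, whitelist = CB1)
  expect_equal(res$status, "cb_unmatched")
})

test_that("extract_window_calls walks CIGARs: matches, deletions, truncation, insertions", {
  win <- window_interval("chrT", 109L, 115L)   # 0-based [109,115)
  # perfect 30M read starting at 1-based pos 101 (0-based 100)
  seqs <- paste(rep("ACGTGA", 5), collapse = "")
  r1 <- aln_row(101L, "30M", seqs)
  m <- extract_window_calls(r1, win)
  expect_equal(m[1, ], strsplit(substr(seqs, 10, 15), "")[[1L]])
  # 1-bp deletion at window offset 2 (third window base):
  # 11M spans window offsets 0,1 then 1D eats offset 2, then 10M
  r2 <- aln_row(101L, "11M1D10M", substr(seqs, 1, 21))
  m2 <- extract_window_calls(r2, win)
  expect_equal(m2[1, 3], "-")
  expect_equal(m2[1, 1:2], strsplit(substr(seqs, 10, 11), "")[[1L]])
  expect_false("-" %in% m2[1, 4:6])
  # read ending mid-window: 12M covers offsets 0..2 only
  r3 <- aln_row(101L, "12M", substr(seqs, 1, 12))
  m3 <- extract_window_calls(r3, win)
  expect_equal(m3[1, 4:6], rep(".", 3))
  expect_false("." %in% m3[1, 1:3])
  # insertion between window positions does not shift downstream calls
  ins_seq <- paste0(substr(seqs, 1, 11), "TTT", substr(seqs, 12, 30))
  r4 <- aln_row(101L, "11M3I19M", ins_seq)
  m4 <- extract_window_calls(r4, win)
  expect_equal(m4[1, ], m[1, ])
})

test_that("window calls agree with GenomicAlignments stacking on simulated reads", {
  cfg <- sim_config(seed = 21, n_cells = 12, n_variants = 3,
                    reads_per_umi = c(3L, 5L))
  b <- simulate_bundle(cfg, withr::local_tempdir())
  win <- window_interval("chrT", b$locus$windows$start, b$locus$windows$end)
  aln <- read_alignments(b$paths$sam)
  ours <- extract_window_calls(aln, win)
  # oracle: stackStringsFromBam over the window region, D as '-', N as '.'
  bam <- Rsamtools::sortBam(Rsamtools::asBam(b$paths$sam,
                                             tempfile(), overwrite = TRUE),
                            tempfile())
  Rsamtools::indexBam(bam)
  rg <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(win$start + 1L, win$end))
  st <- GenomicAlignments::stackStringsFromBam(
    bam, param = rg, what = "seq", D.letter = "-", N.letter = ".",
    Lpadding.letter = ".", Rpadding.letter = ".", use.names = TRUE)
  orc <- do.call(rbind, strsplit(as.character(st), ""))
  ord_ours <- order(aln$qname)
  ord_orc <- order(names(st))
  expect_equal(unname(ours[ord_ours, ]), unname(orc[ord_orc, ]))
})

test_that("consolidate_umis merges per the edit-distance rule", {
  # distance 1 merges
  m1 <- consolidate_umis(c(AAAAAAAAAA = 50L, AAAAAAAAAT = 3L))
  expect_equal(unname(m1), rep("AAAAAAAAAA", 2))
  # distance 3 does not merge ("edit distance less than 3")
  m2 <- consolidate_umis(c(AAAAAAAAAA = 50L, AAATTTAAAA = 3L))
  expect_equal(length(unique(m2)), 2L)
  # chain A-B 2, B-C 2, A-C 4: transitive single linkage maps all to A
  counts <- c(AAAAAAAAAA = 50L, AAAAAAAATT = 3L, AAAAAATTTT = 2L)
  m3 <- consolidate_umis(counts)
  expect_equal(unname(m3), rep("AAAAAAAAAA", 3))
  expect_error(consolidate_umis(c(A = 0L)), "positive")
})

test_that("consolidation conserves mass, is idempotent and matches the oracle", {
  set.seed(2)
  for (rep_i in 1:60) {
    n <- sample(1:8, 1)
    umis <- unique(vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 10, replace = TRUE), collapse = ""),
      character(1L)))
    counts <- stats::setNames(sample(1:60, length(umis), replace = TRUE),
                              umis)
    map <- consolidate_umis(counts)
    expect_equal(sum(counts), sum(tapply(counts, map, sum)))
    expect_equal(map, oracle_consolidate(counts))
    reps <- tapply(counts, map, sum)
    map2 <- consolidate_umis(reps)
    expect_equal(unname(map2), names(reps))       # identity on representatives
  }
})

test_that("umi_consensus applies plurality, read-count filter and tie rule", {
  mkcalls <- function(haps) do.call(rbind, strsplit(haps, ""))
  calls <- mkcalls(c(rep("CACTCG", 10), rep("CACTCA", 2)))
  expect_equal(umi_consensus(calls, min_reads = 10)$consensus_hap, "CACTCG")
  expect_equal(umi_consensus(mkcalls(rep("CACTCG", 9)),
                             min_reads = 10)$status, "low_support")
  tie <- mkcalls(c(rep("CATTCG", 5), rep("CACTCG", 5)))
  expect_equal(umi_consensus(tie, min_reads = 10)$status, "no_consensus")
  # deletion plurality at a position yields no call
  del <- mkcalls(c(rep("CA-TCG", 6), rep("CACTCG", 4)))
  expect_equal(umi_consensus(del, min_reads = 10)$status, "no_consensus")
})

test_that("consensus equals the brute-force plurality oracle and is monotone in min_reads", {
  set.seed(11)
  syms <- c("A", "C", "G", "T", "-", ".")
  kept <- function(calls, mr) umi_consensus(calls, min_reads = mr)$status == "ok"
  for (rep_i in 1:200) {
    r <- sample(1:4, 1)
    calls <- matrix(sample(syms, r * 3, replace = TRUE), nrow = r)
    got <- umi_consensus(calls, min_reads = 1L)
    orc <- oracle_consensus(calls)
    if (is.null(orc)) expect_equal(got$status, "no_consensus")
    else expect_equal(got$consensus_hap, orc)
    # raising min_reads can only drop groups
    expect_true(kept(calls, 1L) >= kept(calls, r + 1L))
  }
})

test_that("cell_genotype applies unanimity zygosity and min_umis", {
  g1 <- cell_genotype(rep("V197M", 4))
  expect_equal(g1[c("genotype_label", "n_umis", "zygosity")],
               list(genotype_label = "V197M", n_umis = 4L,
                    zygosity = "homozygous"))
  g2 <- cell_genotype(c("WT", "WT", "V197M", "V197M"), majority_frac = 1.0)
  expect_equal(g2$zygosity, "heterozygous")
  expect_equal(cell_genotype(character(0))$zygosity, "unresolved")
  # relaxed majority admits the dominant label
  g3 <- cell_genotype(c("WT", "WT", "WT", "V197M"), majority_frac = 0.7)
  expect_equal(g3$zygosity, "homozygous")
  expect_equal(g3$genotype_label, "WT")
  # raising majority_frac never increases homozygous calls
  set.seed(5)
  for (rep_i in 1:50) {
    labs <- sample(c("WT", "A1B", "C2D"), sample(1:6, 1), replace = TRUE)
    hom <- vapply(c(0.5, 0.75, 1.0), function(f)
      cell_genotype(labs, majority_frac = f)$zygosity == "homozygous",
      logical(1L))
    expect_true(all(diff(hom) <= 0))
  }
})

test_that("genotype_pipeline handles empty input and disjoint whitelists", {
  cfg <- sim_config(seed = 31, n_cells = 6, n_variants = 2,
                    reads_per_umi = c(3L, 4L), umis_per_cell = c(1L, 2L))
  b <- simulate_bundle(cfg, withr::local_tempdir())
  # empty SAM
  empty_sam <- file.path(withr::local_tempdir(), "empty.sam")
  writeLines(readLines(b$paths$sam)[1:2], empty_sam)
  res0 <- genotype_pipeline(empty_sam, b$paths$fasta, b$paths$annot,
                            b$paths$whitelist, b$paths$windows,
                            min_umi_reads = 3L)
  expect_equal(nrow(res0$cells), 0L)
  expect_equal(res0$report$reads$total, 0L)
  # whitelist disjoint from the reads' barcodes
  res1 <- genotype_pipeline(b$paths$sam, b$paths$fasta, b$paths$annot,
                            c("TTTTTTTTTTTTTTTT"), b$paths$windows,
                            min_umi_reads = 3L)
  expect_equal(res1$report$reads$assigned, 0L)
  expect_equal(res1$report$reads$rejected$cb_unmatched +
                 res1$report$reads$rejected$no_softclip +
                 res1$report$reads$rejected$truncated,
               res1$report$reads$total)
  # misconfigured window errors
  badwin <- data.frame(chrom = "chrT", start = 1L, end = 7L, id = "bad")
  expect_error(genotype_pipeline(b$paths$sam, b$paths$fasta, b$paths$annot,
                                 b$paths$whitelist, badwin), "exon|window")
})

test_that("pipeline conserves reads and recovers a noiseless simulation exactly", {
  cfg <- sim_config(seed = 32, n_cells = 25, n_variants = 4,
                    sub_rate = 0, indel_rate = 0, decoy_frac = 0,
                    reads_per_umi = c(10L, 12L))
  b <- simulate_bundle(cfg, withr::local_tempdir())
  res <- genotype_pipeline(b$paths$sam, b$paths$fasta, b$paths$annot,
                           b$paths$whitelist, b$paths$windows)
  rep <- res$report$reads
  expect_equal(rep$assigned + Reduce(`+`, rep$rejected), rep$total)
  hom <- res$cells[res$cells$zygosity == "homozygous", ]
  m <- merge(hom, b$reads$cells, by = "cb")
  expect_equal(nrow(m), nrow(b$reads$cells))
  expect_equal(mean(m$genotype_label == m$label), 1.0)
})

test_that("pipeline output ordering and writers are deterministic", {
  cfg <- sim_config(seed = 33, n_cells = 8, n_variants = 2,
                    reads_per_umi = c(10L, 11L))
  b <- simulate_bundle(cfg, withr::local_tempdir())
  res <- genotype_pipeline(b$paths$sam, b$paths$fasta, b$paths$annot,
                           b$paths$whitelist, b$paths$windows)
  expect_false(is.unsorted(res$cells$cb))
  out <- withr::local_tempdir()
  write_genotype_output(res, out)
  expect_true(all(file.exists(file.path(out, c("per_umi.tsv", "per_cell.tsv",
                                               "report.json")))))
  rt <- read.delim(file.path(out, "per_cell.tsv"))
  expect_equal(nrow(rt), nrow(res$cells))
})
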