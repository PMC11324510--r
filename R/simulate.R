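# Truth-annotated synthetic data: toy locus, errored long reads with
# soft-clipped adapter+CB+UMI, and negative-binomial expression with
# genotype-dependent pathway shifts. Everything is deterministic per seed.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults describe the stated world the package is tested in: a pool of
#' base-edited cells with 3-6 captured molecules per cell and 10-20 long
#' reads per molecule, 2% substitution and 1% indel error per base, and a
#' modest ambient-barcode fraction. Expression is negative-binomial with a
#' multiplicative pathway shift per genotype; stop-gain genotypes can be
#' capture-thinned to emulate nonsense-mediated decay.
#'
#' @param seed RNG seed (mandatory; sub-stages derive seed+1, seed+2).
#' @param n_cells Number of whitelisted cells.
#' @param n_variants Number of engineered (non-WT) window genotypes.
#' @param wt_frac Fraction of unedited cells; remaining mass is split
#'   over variants unless `variant_fracs` is given.
#' @param variant_fracs Optional explicit per-variant cell fractions.
#' @param umis_per_cell,reads_per_umi Inclusive integer ranges.
#' @param sub_rate,indel_rate Per-base substitution and indel error rates.
#' @param decoy_frac Fraction of reads given a non-whitelist barcode.
#' @param whitelist_extra Whitelist entries beyond the simulated cells.
#' @param n_genes,n_mito,pathway_size Expression matrix dimensions.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param effects Per-variant multiplicative shift on pathway-gene means
#'   (recycled; 1 = null effect).
#' @param stopgain_capture cDNA capture factor applied to genotypes whose
#'   label contains "Ter" (1 = no thinning).
#' @param n_exons,strand,n_codons Locus shape.
#' @param window_codon_index Codon index of the first window codon.
#' @param window_codons The two reference codons under the editing window.
#' @param read_flank Bases of aligned context on each side of the window.
#' @param clip_prefix Random soft-clip bases 5' of the adapter.
#' @param adapter Adapter sequence preceding barcode+UMI.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_cells = 500L, n_variants = 8L, wt_frac = 0.2,
                       variant_fracs = NULL,
                       umis_per_cell = c(3L, 6L), reads_per_umi = c(10L, 20L),
                       sub_rate = 0.02, indel_rate = 0.01,
                       decoy_frac = 0.02, whitelist_extra = 50L,
                       n_genes = 2000L, n_mito = 5L, pathway_size = 100L,
                       nb_size = 2, effects = 1, stopgain_capture = 1,
                       n_exons = 1L, strand = "+", n_codons = 40L,
                       window_codon_index = 10L,
                       window_codons = c("CAC", "TCG"),
                       read_flank = 40L, clip_prefix = 5L,
                       adapter = DEFAULT_ADAPTER) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            decoy_frac >= 0, decoy_frac < 1,
            wt_frac > 0, wt_frac < 1, n_exons %in% 1:3)
  if (!is.null(variant_fracs)) {
    if (length(variant_fracs) != n_variants)
      stop("variant_fracs length must equal n_variants")
    if (abs(sum(variant_fracs) + wt_frac - 1) > 1e-9)
      stop("wt_frac + sum(variant_fracs) must equal 1")
  }
  as.list(environment())
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
rand_codon <- function() {
  repeat {
    cd <- rand_seq(3L)
    if (!cd %in% STOP_CODONS) return(cd)
  }
}

#' Simulate a toy locus: genome, transcript model, window and variants
#'
#' Builds a 1-3 exon gene on either strand with the editing window fully
#' inside one coding exon, then derives `n_variants` distinct non-WT
#' window haplotypes (single-base substitutions of the reference window)
#' with their amino-acid-change labels. When `stopgain_capture < 1` a
#' stop-gain haplotype is placed first.
#'
#' @param cfg A [sim_config()].
#' @return List with `ref_seq`, `tx`, `windows` (data.frame, 0-based
#'   half-open), `window` ([window_interval()]), `variants` (label, hap,
#'   frac, effect, capture) and `ref_hap`.
#' @export
simulate_locus <- function(cfg) {
  set.seed(cfg$seed)
  wc <- cfg$window_codon_index
  stopifnot(wc >= 2L, wc + 2L < cfg$n_codons)
  codons <- c("ATG", vapply(seq_len(cfg$n_codons - 2L),
                            function(i) rand_codon(), character(1L)), "TAA")
  codons[wc:(wc + 1L)] <- cfg$window_codons
  cds <- paste(codons, collapse = "")
  utr5 <- rand_seq(30L); utr3 <- rand_seq(30L)
  exonic <- paste0(utr5, cds, utr3)
  flank5 <- rand_seq(150L); flank3 <- rand_seq(150L)

  # intron insertion points in exonic coordinates (codon boundaries away
  # from the window)
  br <- integer(0)
  if (cfg$n_exons >= 2L) br <- c(br, 30L + 3L * 5L)
  if (cfg$n_exons >= 3L) br <- c(br, 30L + 3L * (wc + 5L))
  br <- br[br > 0L & br < nchar(exonic)]
  intron_len <- 80L
  introns <- vapply(seq_along(br), function(i)
    paste0("GT", rand_seq(intron_len - 4L), "AG"), character(1L))

  pieces <- character(0); bounds <- c(0L, br, nchar(exonic))
  for (i in seq_len(length(bounds) - 1L)) {
    pieces <- c(pieces, substr(exonic, bounds[i] + 1L, bounds[i + 1L]))
    if (i <= length(introns)) pieces <- c(pieces, introns[i])
  }
  genome_sense <- paste0(flank5, paste(pieces, collapse = ""), flank3)

  gmap <- function(x) {  # exonic coord (0-based) -> genomic (sense strand)
    150L + x + intron_len * sum(br <= x)
  }
  exon_starts <- vapply(c(0L, br), gmap, integer(1L))
  exon_ends <- vapply(c(br, nchar(exonic)), function(e)
    gmap(e - 1L) + 1L, integer(1L))
  exons <- cbind(start = exon_starts, end = exon_ends)
  cds_start <- gmap(30L)
  cds_end <- gmap(30L + 3L * cfg$n_codons - 1L) + 1L
  ws <- gmap(30L + 3L * (wc - 1L)); we <- gmap(30L + 3L * (wc - 1L) + 5L) + 1L

  L <- nchar(genome_sense)
  if (cfg$strand == "-") {
    genome <- revcomp(genome_sense)
    exons <- cbind(start = L - exons[, "end"], end = L - exons[, "start"])
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    tmp <- cds_start; cds_start <- L - cds_end; cds_end <- L - tmp
    tmp <- ws; ws <- L - we; we <- L - tmp
  } else genome <- genome_sense

  ref_seq <- c(chrT = genome)
  tx <- transcript_model("toytx", "chrT", cfg$strand, exons,
                         cds_start, cds_end, ref_seq, validate_cds = TRUE)
  win <- window_interval("chrT", ws, we, "+")
  ref_hap <- ref_slice(ref_seq, "chrT", ws, we)

  # candidate single-substitution haplotypes and their labels
  rb <- strsplit(ref_hap, "")[[1L]]
  cand <- list()
  for (i in 1:6) for (b in setdiff(BASES, rb[i])) {
    hb <- rb; hb[i] <- b
    hap <- paste(hb, collapse = "")
    lab <- genotype_label(call_aa_changes(win, ref_hap, hap, tx, ref_seq))
    if (lab != "WT") cand[[length(cand) + 1L]] <- c(hap = hap, label = lab)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, "label"]), , drop = FALSE]
  if (nrow(cand) < cfg$n_variants)
    stop("window context yields only ", nrow(cand), " distinct variants")
  is_ter <- grepl("Ter", cand[, "label"])
  ord <- sample(nrow(cand))                 # seeded, deterministic
  if (cfg$stopgain_capture < 1 && any(is_ter))
    ord <- c(which(is_ter)[1L], setdiff(ord, which(is_ter)[1L]))
  sel <- cand[ord[seq_len(cfg$n_variants)], , drop = FALSE]

  fr <- if (is.null(cfg$variant_fracs))
    rep((1 - cfg$wt_frac) / cfg$n_variants, cfg$n_variants)
  else cfg$variant_fracs
  eff <- rep_len(cfg$effects, cfg$n_variants)
  capt <- ifelse(grepl("Ter", sel[, "label"]), cfg$stopgain_capture, 1)
  variants <- data.frame(label = sel[, "label"], hap = sel[, "hap"],
                         frac = fr, effect = eff, capture = capt,
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL

  list(ref_seq = ref_seq, tx = tx, window = win, ref_hap = ref_hap,
       windows = data.frame(chrom = "chrT", start = ws, end = we, id = "g1"),
       variants = variants)
}

# random distinct barcodes
rand_barcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n)
    out <- unique(c(out, vapply(seq_len(n), function(i) rand_seq(len),
                                character(1L))))
  out[seq_len(n)]
}

# corrupt a template: per-base iid substitution + indel errors
# returns query sequence and CIGAR core (M/I/D run-length encoded)
corrupt_read <- function(tmpl, sub_rate, indel_rate) {
  ch <- strsplit(tmpl, "")[[1L]]
  L <- length(ch)
  u <- stats::runif(L)
  del <- u < indel_rate / 2
  ins <- !del & u < indel_rate
  sub <- !del & stats::runif(L) < sub_rate
  if (any(sub)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T",
                    "A", "C", "T", "A", "C", "G"), nrow = 3L)
    ch[sub] <- alt[cbind(sample.int(3L, sum(sub), replace = TRUE),
                         match(ch[sub], BASES))]
  }
  ops <- ifelse(del, "D", "M")
  qb <- ifelse(del, NA_character_, ch)
  if (any(ins)) {
    ii <- which(ins)
    idx <- c(seq_len(L), ii + 0.5)
    ops <- c(ops, rep("I", length(ii)))[order(idx)]
    qb <- c(qb, sample(BASES, length(ii), replace = TRUE))[order(idx)]
  }
  r <- rle(ops)
  list(seq = paste(qb[!is.na(qb)], collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Simulate aligned long reads with soft-clipped barcode+UMI
#'
#' Each whitelisted cell draws a genotype by the configured fractions and
#' a number of cDNA molecules (UMIs); stop-gain genotypes are thinned by
#' their capture factor. Each molecule is sequenced by several reads whose
#' aligned portion covers the window (error-corrupted, CIGAR-consistent)
#' and whose 5' soft clip carries prefix + adapter + barcode + UMI. A
#' configurable fraction of reads gets an off-whitelist (ambient) barcode.
#'
#' @param cfg A [sim_config()].
#' @param locus From [simulate_locus()].
#' @param emit_reads Generate SAM records (FALSE: molecule-level truth
#'   only, used for frequency-level analyses).
#' @return List with `whitelist`, `cells` (cb, label, hap), `umis`
#'   (cb, umi, label, hap), and when `emit_reads` a `sam` character vector
#'   of header+records.
#' @export
simulate_long_reads <- function(cfg, locus, emit_reads = TRUE) {
  set.seed(cfg$seed + 1L)
  wl <- rand_barcodes(cfg$n_cells + cfg$whitelist_extra, 16L)
  cell_cb <- wl[seq_len(cfg$n_cells)]
  labels <- c("WT", locus$variants$label)
  haps <- c(locus$ref_hap, locus$variants$hap)
  fracs <- c(cfg$wt_frac, locus$variants$frac)
  capture <- c(1, locus$variants$capture)
  gi <- sample.int(length(labels), cfg$n_cells, replace = TRUE, prob = fracs)
  cells <- data.frame(cb = cell_cb, label = labels[gi], hap = haps[gi])

  n_umis <- sample(cfg$umis_per_cell[1L]:cfg$umis_per_cell[2L],
                   cfg$n_cells, replace = TRUE)
  thin <- capture[gi] < 1
  n_umis[thin] <- stats::rbinom(sum(thin), n_umis[thin], capture[gi][thin])
  umis <- data.frame(
    cb = rep(cells$cb, n_umis),
    umi = vapply(seq_len(sum(n_umis)), function(i) rand_seq(10L),
                 character(1L)),
    label = rep(cells$label, n_umis),
    hap = rep(cells$hap, n_umis))

  out <- list(whitelist = wl, cells = cells, umis = umis)
  if (!emit_reads) return(out)

  win <- locus$window
  chromseq <- locus$ref_seq[["chrT"]]
  ex <- locus$tx$exons[check_window_in_exon(win, locus$tx), ]
  n_reads <- if (nrow(umis) > 0L)
    sample(cfg$reads_per_umi[1L]:cfg$reads_per_umi[2L], nrow(umis),
           replace = TRUE) else integer(0)
  total <- sum(n_reads)
  mol <- rep(seq_len(nrow(umis)), n_reads)

  # per-molecule plus-strand template with the genotype haplotype planted
  hap_of <- umis$hap[mol]
  jit_l <- sample(0:10, total, replace = TRUE)
  jit_r <- sample(0:10, total, replace = TRUE)
  rs <- pmax(ex[["start"]], win$start - cfg$read_flank - jit_l)
  re <- pmin(ex[["end"]], win$end + cfg$read_flank + jit_r)

  decoy <- stats::runif(total) < cfg$decoy_frac
  cbs <- umis$cb[mol]
  if (any(decoy)) {
    dk <- rand_barcodes(sum(decoy) + length(wl), 16L)
    cbs[decoy] <- setdiff(dk, wl)[seq_len(sum(decoy))]
  }
  flag_rev <- stats::runif(total) < 0.5

  recs <- character(total)
  for (i in seq_len(total)) {
    tmpl <- substring(chromseq, rs[i] + 1L, re[i])
    rel <- win$start - rs[i]
    substr(tmpl, rel + 1L, rel + nchar(hap_of[i])) <- hap_of[i]
    rd <- corrupt_read(tmpl, cfg$sub_rate, cfg$indel_rate)
    clip <- paste0(rand_seq(cfg$clip_prefix), cfg$adapter,
                   cbs[i], umis$umi[mol[i]])
    if (flag_rev[i]) {
      seq <- paste0(rd$seq, revcomp(clip))
      cigar <- paste0(rd$cigar, nchar(clip), "S")
      flag <- 16L
    } else {
      seq <- paste0(clip, rd$seq)
      cigar <- paste0(nchar(clip), "S", rd$cigar)
      flag <- 0L
    }
    recs[i] <- paste(sprintf("read%06d", i), flag, "chrT", rs[i] + 1L, 60L,
                     cigar, "*", 0L, 0L, seq, "*", sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:chrT\tLN:", nchar(chromseq)))
  out$sam <- c(header, recs)
  out
}

#' Simulate a sparse expression matrix with genotype-dependent shifts
#'
#' Negative-binomial counts over `n_genes` genes (including a few "MT-"
#' mitochondrial genes); pathway-set gene means are multiplied by each
#' cell's genotype effect. Null-effect genotypes share the wild-type
#' distribution exactly.
#'
#' @param cfg A [sim_config()].
#' @param cells data.frame with cb and label (from
#'   [simulate_long_reads()]).
#' @param variants Variant table from [simulate_locus()].
#' @return List with `counts` (dgCMatrix genes x cells), `gene_set`
#'   (pathway gene ids) and `truth` (per-variant effect and expected
#'   class).
#' @export
simulate_expression <- function(cfg, cells, variants) {
  set.seed(cfg$seed + 2L)
  n <- nrow(cells)
  n_reg <- cfg$n_genes - cfg$n_mito
  genes <- c(sprintf("GENE%04d", seq_len(n_reg)),
             sprintf("MT-%d", seq_len(cfg$n_mito)))
  mu <- c(stats::rlnorm(n_reg, meanlog = log(0.3), sdlog = 1.2),
          stats::rlnorm(cfg$n_mito, meanlog = log(3), sdlog = 0.3))
  pw <- sample(seq_len(n_reg), cfg$pathway_size)
  mu[pw] <- stats::rlnorm(cfg$pathway_size, meanlog = log(2), sdlog = 0.4)

  eff_map <- stats::setNames(c(1, variants$effect), c("WT", variants$label))
  eff <- unname(eff_map[cells$label])
  mu_mat <- matrix(mu, nrow = cfg$n_genes, ncol = n)
  mu_mat[pw, ] <- mu[pw] %o% eff
  counts <- matrix(stats::rnbinom(cfg$n_genes * n, mu = mu_mat,
                                  size = cfg$nb_size),
                   nrow = cfg$n_genes, ncol = n,
                   dimnames = list(genes, cells$cb))
  truth <- data.frame(label = c("WT", variants$label),
                      effect = c(1, variants$effect),
                      class = ifelse(c(1, variants$effect) == 1,
                                     "wild-type-like",
                                     "functionally-significant"))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       gene_set = genes[pw], truth = truth)
}

#' Simulate a complete bundle and write it to disk
#'
#' Emits reference FASTA, transcript table, windows TSV, SAM, whitelist,
#' MTX triplet, pathway gene set and truth TSVs under `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created). NULL: return objects only.
#' @return List with the simulated objects and (when written) file paths.
#' @export
simulate_bundle <- function(cfg, out_dir = NULL) {
  locus <- simulate_locus(cfg)
  lr <- simulate_long_reads(cfg, locus)
  ex <- simulate_expression(cfg, lr$cells, locus$variants)
  res <- list(cfg = cfg, locus = locus, reads = lr, expression = ex)
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  writeLines(c(">chrT", locus$ref_seq[["chrT"]]), p("ref.fa"))
  write_transcript_table(locus$tx, p("transcript.tsv"))
  wdf <- locus$windows
  utils::write.table(
    data.frame(chrom = wdf$chrom, start = wdf$start + 1L, end = wdf$end,
               id = wdf$id),
    p("windows.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(lr$sam, p("reads.sam"))
  writeLines(lr$whitelist, p("whitelist.txt"))
  write_mtx(ex$counts, p("expression"))
  writeLines(ex$gene_set, p("pathway_genes.txt"))
  utils::write.table(lr$cells, p("truth_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lr$umis, p("truth_umis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ex$truth, p("truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$paths <- list(fasta = p("ref.fa"), annot = p("transcript.tsv"),
                    windows = p("windows.tsv"), sam = p("reads.sam"),
                    whitelist = p("whitelist.txt"), mtx = p("expression"),
                    gene_set = p("pathway_genes.txt"))
  res
}

#' Simulate a matched pair of per-UMI genotype tables
#'
#' Two platforms observe the same (cb, umi, window) molecules; the second
#' table's call is flipped to a different label with the given
#' disagreement probability.
#'
#' @param n_shared Number of shared molecules.
#' @param disagree_rate Per-molecule disagreement probability.
#' @param seed RNG seed.
#' @param labels Label alphabet.
#' @return List of two [umi_genotype_table()]s `a` (long) and `b` (short).
#' @export
simulate_umi_table_pair <- function(n_shared, disagree_rate, seed,
                                    labels = c("WT", "H10Y", "S11Ter")) {
  set.seed(seed)
  cb <- vapply(seq_len(n_shared), function(i) rand_seq(16L), character(1L))
  umi <- vapply(seq_len(n_shared), function(i) rand_seq(10L), character(1L))
  call_a <- sample(labels, n_shared, replace = TRUE)
  flip <- stats::runif(n_shared) < disagree_rate
  call_b <- call_a
  call_b[flip] <- vapply(call_a[flip], function(l)
    sample(setdiff(labels, l), 1L), character(1L))
  list(a = umi_genotype_table(cb, umi, "g1", call_a, source = "long"),
       b = umi_genotype_table(cb, umi, "g1", call_b, source = "short"),
       truth_disagree = mean(flip))
}
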