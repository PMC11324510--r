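# Cross-platform validation: short-read amplicon parsing, per-UMI identity
# between platforms, variant frequency tables and DNA-vs-cDNA R^2.

#' Construct a per-UMI genotype table
#'
#' @param cb,umi,window,call Equal-length vectors; `call` is a window
#'   haplotype or genotype label.
#' @param source One of "short", "long", "dna_amplicon".
#' @return data.frame with unique (cb, umi, window) keys.
#' @export
umi_genotype_table <- function(cb, umi, window, call,
                               source = c("long", "short", "dna_amplicon")) {
  source <- match.arg(source)
  d <- data.frame(cb = cb, umi = umi, window = window, call = call)
  key <- paste(d$cb, d$umi, d$window)
  if (anyDuplicated(key)) stop("(cb, umi, window) keys must be unique")
  attr(d, "source") <- source
  d
}

#' Parse paired amplicon FASTQ into a per-UMI genotype table
#'
#' Read1 carries barcode (bases 1-16, exact whitelist match) and UMI
#' (bases 17-26); read2 covers the amplicon. The window haplotype is
#' located in read2 by exact matching of the reference anchor immediately
#' 5' of the window (no aligner involved), and per-(cb, umi) groups are
#' collapsed by plurality with their own read-count filter.
#'
#' @param r1,r2 FASTQ paths (gzipped accepted), read pairs in file order.
#' @param whitelist Barcode vector or path.
#' @param win A [window_interval()].
#' @param ref_seq Genome (object or FASTA path).
#' @param min_reads Minimum reads per UMI (default 3).
#' @param anchor_len Bases of reference anchor used to locate the window.
#' @return A [umi_genotype_table()] (source "short") with attributes
#'   `rejects` (per-read reasons) and `dropped` (per-UMI reasons).
#' @export
parse_amplicon_pairs <- function(r1, r2, whitelist, win, ref_seq,
                                 min_reads = 3L, anchor_len = 12L) {
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist)) whitelist <- read_whitelist(whitelist)
  if (is.character(ref_seq) && length(ref_seq) == 1L && file.exists(ref_seq))
    ref_seq <- read_genome_fasta(ref_seq)
  ref_seq <- as_genome(ref_seq)
  s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  s2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  if (length(s1) != length(s2)) stop("read1/read2 pair count mismatch")
  width <- win$end - win$start
  if (win$start - anchor_len < 0L) stop("window too close to reference start for anchor")
  anchor <- ref_slice(ref_seq, win$chrom, win$start - anchor_len, win$start)

  status <- rep("ok", length(s1))
  status[nchar(s1) < 26L] <- "truncated"
  cb <- substring(s1, 1L, 16L); umi <- substring(s1, 17L, 26L)
  status[status == "ok" & !(cb %in% whitelist)] <- "cb_unmatched"
  hit <- regexpr(anchor, s2, fixed = TRUE)
  wstart <- as.integer(hit) + anchor_len
  short <- status == "ok" & (hit == -1L | nchar(s2) < wstart + width - 1L)
  status[short] <- "no_anchor"
  ok <- which(status == "ok")
  hap <- substring(s2[ok], wstart[ok], wstart[ok] + width - 1L)

  keys <- paste(cb[ok], umi[ok], sep = "\r")
  rows <- list(); dropped <- c(low_support = 0L, no_consensus = 0L)
  for (kk in sort(unique(keys))) {
    i <- which(keys == kk)
    calls <- do.call(rbind, strsplit(toupper(hap[i]), ""))
    cons <- umi_consensus(calls, min_reads = min_reads)
    if (cons$status != "ok") {
      dropped[[cons$status]] <- dropped[[cons$status]] + 1L
      next
    }
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      cb = parts[1L], umi = parts[2L],
      window = fmt_coords(win$chrom, win$start, win$end),
      call = cons$consensus_hap)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cb = character(), umi = character(),
               window = character(), call = character())
  attr(out, "source") <- "short"
  attr(out, "rejects") <- as.list(table(factor(status,
    levels = c("ok", "truncated", "cb_unmatched", "no_anchor"))))
  attr(out, "dropped") <- as.list(dropped)
  out
}

#' Per-UMI concordance between two platforms
#'
#' @param a,b Per-UMI genotype tables (columns cb, umi, window, call).
#' @return List with `fraction_identical`, `n_shared` and `per_window`
#'   breakdown; errors when the tables share no (cb, umi, window) key.
#' @export
umi_concordance <- function(a, b) {
  m <- merge(a, b, by = c("cb", "umi", "window"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("tables share no (cb, umi, window) key")
  same <- m$call_a == m$call_b
  pw <- do.call(rbind, lapply(split(same, m$window), function(s)
    data.frame(n_shared = length(s), fraction_identical = mean(s))))
  pw <- cbind(window = rownames(pw), pw)
  rownames(pw) <- NULL
  list(fraction_identical = mean(same), n_shared = nrow(m), per_window = pw)
}

#' Variant frequencies from a per-UMI genotype table
#'
#' @param table Per-UMI genotype table (columns window, call).
#' @return data.frame (per window) with variant, count, total, frequency;
#'   "WT"/reference calls are included, so per-window frequencies sum to 1.
#' @export
variant_frequencies <- function(table) {
  if (nrow(table) == 0L) stop("empty genotype table")
  out <- do.call(rbind, lapply(split(table, table$window), function(d) {
    tab <- table(d$call)
    data.frame(window = d$window[1L], variant = names(tab),
               count = as.integer(tab), total = nrow(d),
               frequency = as.numeric(tab) / nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation of matched variant frequencies
#'
#' Variants present in only one table get frequency 0 in the other.
#'
#' @param x,y Frequency tables from [variant_frequencies()].
#' @param log_scale Correlate log10(frequency + pseudocount) instead of
#'   raw frequencies (the convention of log-log frequency dot plots).
#' @param pseudocount Added before log10 (default 1e-4).
#' @return R^2 (squared Pearson correlation).
#' @export
frequency_r2 <- function(x, y, log_scale = FALSE, pseudocount = 1e-4) {
  shared <- intersect(x$variant, y$variant)
  if (length(shared) < 3L)
    stop("need at least 3 variants shared between tables, got ",
         length(shared))
  all_v <- union(x$variant, y$variant)
  fx <- stats::setNames(rep(0, length(all_v)), all_v)
  fy <- fx
  fx[x$variant] <- x$frequency
  fy[y$variant] <- y$frequency
  if (log_scale) { fx <- log10(fx + pseudocount); fy <- log10(fy + pseudocount) }
  if (stats::sd(fx) == 0 || stats::sd(fy) == 0)
    stop("undefined correlation: zero variance in a frequency vector")
  stats::cor(fx, fy)^2
}
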