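# Transcript model, genomic<->codon mapping and amino-acid-change calling.
#
# All coordinates are 0-based half-open internally; user-facing output and
# log strings use 1-based inclusive coordinates (see fmt_coords()).

#' Build a transcript model
#'
#' A transcript model holds the exon structure and CDS bounds of one
#' transcript on one chromosome, and precomputes the genomic positions of
#' every CDS base in transcript (5'->3') order so that genomic positions can
#' be mapped to codons in O(1).
#'
#' @param name Transcript name.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons Two-column matrix or data.frame of genomic exon intervals,
#'   0-based half-open, sorted ascending and non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding region, 0-based
#'   half-open; the CDS is the intersection of `[cds_start, cds_end)` with
#'   the exon union.
#' @param ref_seq Optional genome (see [read_genome_fasta()]); when supplied
#'   together with `validate_cds = TRUE` the spliced CDS is checked to start
#'   with ATG and end with a stop codon.
#' @param validate_cds Check start/stop codons against `ref_seq`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(name, chrom, strand, exons, cds_start, cds_end,
                             ref_seq = NULL, validate_cds = FALSE) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript must have at least one exon")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exon intervals must be non-empty half-open [start, end)")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stop("exons must be sorted ascending")
    if (any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
      stop("exons must be disjoint")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end <= cds_start) stop("empty CDS interval")

  exon_pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, "start"], exons[i, "end"] - 1L)), use.names = FALSE)
  cds_pos <- exon_pos[exon_pos >= cds_start & exon_pos < cds_end]
  if (cds_start < min(exons[, "start"]) || cds_end > max(exons[, "end"]))
    stop("CDS interval not contained in exon span")
  if (length(cds_pos) %% 3L != 0L)
    stop("spliced CDS length (", length(cds_pos), ") not divisible by 3")
  if (strand == "-") cds_pos <- rev(cds_pos)

  tx <- structure(list(
    name = name, chrom = chrom, strand = strand, exons = exons,
    cds_start = cds_start, cds_end = cds_end,
    exon_pos = exon_pos, cds_pos = cds_pos
  ), class = "transcript_model")

  if (validate_cds) {
    if (is.null(ref_seq)) stop("validate_cds requires ref_seq")
    aa <- translate_codon(cds_codons(tx, ref_seq))
    if (aa[1L] != "M")
      stop("spliced CDS of ", name, " does not begin with a start codon")
    if (aa[length(aa)] != "Ter")
      stop("spliced CDS of ", name, " does not end with a stop codon")
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s(%s) %d exon(s), CDS %s, %d codons\n",
              x$name, x$chrom, x$strand, nrow(x$exons),
              fmt_coords(x$chrom, x$cds_start, x$cds_end),
              length(x$cds_pos) / 3L))
  invisible(x)
}

#' Format a 0-based half-open interval as 1-based inclusive text
#' @param chrom Chromosome. @param start,end 0-based half-open bounds.
#' @return A string like "chr17:7674940-7674945".
#' @export
fmt_coords <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start + 1L, end)
}

# --- genome access ---------------------------------------------------------

#' Read a reference genome (or locus) FASTA
#'
#' @param path FASTA file.
#' @return A named character vector, one uppercase sequence per chromosome
#'   (names truncated at the first whitespace token).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

as_genome <- function(ref_seq) {
  if (methods::is(ref_seq, "DNAStringSet")) {
    seqs <- toupper(as.character(ref_seq))
    names(seqs) <- sub("\\s.*$", "", names(ref_seq))
    return(seqs)
  }
  if (is.character(ref_seq)) {
    if (is.null(names(ref_seq))) stop("ref_seq character vector must be named by chromosome")
    return(toupper(ref_seq))
  }
  stop("ref_seq must be a named character vector or DNAStringSet")
}

# 0-based half-open slice of the genome
ref_slice <- function(ref_seq, chrom, start, end) {
  ref_seq <- as_genome(ref_seq)
  if (!chrom %in% names(ref_seq)) stop("chromosome ", chrom, " not in reference")
  n <- nchar(ref_seq[[chrom]])
  if (start < 0L || end > n) stop("interval ", fmt_coords(chrom, start, end),
                                  " outside reference (length ", n, ")")
  substr(ref_seq[[chrom]], start + 1L, end)
}

#' Reverse-complement a DNA string
#' @param x Character vector of A/C/G/T strings.
#' @return Reverse complement of each element.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# --- translation -----------------------------------------------------------

#' Translate codons with the standard genetic code
#'
#' @param codon Character vector of 3-base A/C/G/T codons.
#' @return Single-letter amino acids; stop codons return "Ter".
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) stop("codons must be 3 bases")
  if (any(grepl("[^ACGT]", codon)))
    stop("ambiguous or invalid base in codon: ",
         paste(codon[grepl("[^ACGT]", codon)], collapse = ", "))
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[aa == "*"] <- "Ter"
  aa
}

# codons of the spliced CDS, in transcript orientation
cds_codons <- function(tx, ref_seq) {
  ref_seq <- as_genome(ref_seq)
  chromseq <- ref_seq[[tx$chrom]]
  b <- substring(chromseq, tx$cds_pos + 1L, tx$cds_pos + 1L)
  if (tx$strand == "-") b <- comp_base(b)
  n <- length(b) / 3L
  vapply(seq_len(n), function(i)
    paste(b[(3L * i - 2L):(3L * i)], collapse = ""), character(1L))
}

# --- coordinate mapping ----------------------------------------------------

#' Map genomic positions to codon coordinates
#'
#' @param pos Integer vector of genomic positions (0-based).
#' @param tx A [transcript_model()].
#' @return data.frame with columns `pos`, `codon_index` (1-based protein
#'   position) and `offset` (0..2, position within the codon in transcript
#'   reading order); both NA for exonic positions outside the CDS.
#'   Positions outside the exon union raise an error naming the position.
#' @export
genomic_to_codon <- function(pos, tx) {
  stopifnot(inherits(tx, "transcript_model"))
  pos <- as.integer(pos)
  bad <- !(pos %in% tx$exon_pos)
  if (any(bad))
    stop("position(s) not in any exon of ", tx$name, ": ",
         paste(pos[bad] + 1L, collapse = ", "))
  i <- match(pos, tx$cds_pos)          # 1-based CDS base index or NA
  data.frame(pos = pos,
             codon_index = ifelse(is.na(i), NA_integer_, (i - 1L) %/% 3L + 1L),
             offset = ifelse(is.na(i), NA_integer_, (i - 1L) %% 3L))
}

# genomic positions (transcript order) of codon ci
codon_positions <- function(ci, tx) tx$cds_pos[(3L * ci - 2L):(3L * ci)]

# --- amino-acid changes ----------------------------------------------------

#' Construct an amino-acid change record
#'
#' @param ref_aa,alt_aa Single-letter amino acid or "Ter".
#' @param codon_index 1-based protein position.
#' @return One-row data.frame with columns ref_aa, codon_index, alt_aa and
#'   the canonical `label` "<ref><index><alt>" (e.g. "W146Ter").
#' @export
aa_change <- function(ref_aa, codon_index, alt_aa) {
  codon_index <- as.integer(codon_index)
  if (codon_index < 1L) stop("codon_index must be >= 1")
  if (identical(ref_aa, alt_aa)) stop("ref_aa and alt_aa must differ")
  data.frame(ref_aa = ref_aa, codon_index = codon_index, alt_aa = alt_aa,
             label = paste0(ref_aa, codon_index, alt_aa))
}

aa_change_empty <- function() {
  data.frame(ref_aa = character(), codon_index = integer(),
             alt_aa = character(), label = character())
}

#' Construct an sgRNA target window interval
#'
#' @param chrom Chromosome.
#' @param start,end Genomic bounds, 0-based half-open (plus strand).
#' @param guide_strand Strand of the guide whose editing window this is.
#' @return A `window_interval` list.
#' @export
window_interval <- function(chrom, start, end, guide_strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("empty window interval")
  if (!guide_strand %in% c("+", "-")) stop("guide_strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end,
                 guide_strand = guide_strand),
            class = "window_interval")
}

# window must sit inside a single exon of tx
check_window_in_exon <- function(win, tx) {
  if (!identical(win$chrom, tx$chrom))
    stop("window chromosome ", win$chrom, " does not match transcript ", tx$chrom)
  hit <- which(tx$exons[, "start"] <= win$start & tx$exons[, "end"] >= win$end)
  if (length(hit) == 0L) {
    inside <- any(tx$exons[, "start"] < win$end & tx$exons[, "end"] > win$start)
    if (inside)
      stop("window ", fmt_coords(win$chrom, win$start, win$end),
           " spans an exon boundary; multi-exon windows are not supported")
    stop("window ", fmt_coords(win$chrom, win$start, win$end),
         " does not overlap any exon of ", tx$name)
  }
  invisible(hit[1L])
}

#' Call amino-acid changes for a window haplotype
#'
#' Compares an observed (or designed) window haplotype with the reference,
#' rebuilds each affected codon with all window substitutions applied
#' simultaneously, and reports the non-synonymous consequences. Haplotypes
#' are given in genomic plus-strand orientation; complementation for
#' minus-strand transcripts is handled internally.
#'
#' @param win A [window_interval()] lying within a single exon.
#' @param ref_hap Reference bases over the window (plus strand); validated
#'   against `ref_seq`.
#' @param alt_hap Alternative window haplotype (plus strand, A/C/G/T only).
#' @param tx A [transcript_model()].
#' @param ref_seq Genome as from [read_genome_fasta()].
#' @return data.frame of changes (see [aa_change()]), sorted by codon_index
#'   then alt_aa; zero rows when all edits are synonymous or non-coding.
#' @export
call_aa_changes <- function(win, ref_hap, alt_hap, tx, ref_seq) {
  stopifnot(inherits(win, "window_interval"), inherits(tx, "transcript_model"))
  ref_seq <- as_genome(ref_seq)
  width <- win$end - win$start
  ref_hap <- toupper(ref_hap); alt_hap <- toupper(alt_hap)
  if (nchar(ref_hap) != width || nchar(alt_hap) != width)
    stop("haplotype length must equal window width (", width, ")")
  if (grepl("[^ACGT]", alt_hap) || grepl("[^ACGT]", ref_hap))
    stop("haplotypes must contain only A/C/G/T")
  genome_ref <- ref_slice(ref_seq, win$chrom, win$start, win$end)
  if (ref_hap != genome_ref)
    stop("ref_hap ", ref_hap, " does not match reference ", genome_ref,
         " at ", fmt_coords(win$chrom, win$start, win$end),
         " (stale annotation?)")
  check_window_in_exon(win, tx)
  if (ref_hap == alt_hap) return(aa_change_empty())

  rb <- strsplit(ref_hap, "")[[1L]]
  ab <- strsplit(alt_hap, "")[[1L]]
  diff_off <- which(rb != ab) - 1L
  gpos <- win$start + diff_off
  ci <- genomic_to_codon(gpos, tx)$codon_index
  ci <- sort(unique(ci[!is.na(ci)]))
  if (length(ci) == 0L) return(aa_change_empty())

  chromseq <- ref_seq[[tx$chrom]]
  base_at <- function(g, alt) {
    inwin <- g >= win$start & g < win$end
    b <- substring(chromseq, g + 1L, g + 1L)
    if (alt) b[inwin] <- ab[g[inwin] - win$start + 1L]
    b
  }
  out <- lapply(ci, function(c1) {
    g <- codon_positions(c1, tx)
    rbs <- base_at(g, alt = FALSE)
    abs_ <- base_at(g, alt = TRUE)
    if (tx$strand == "-") { rbs <- comp_base(rbs); abs_ <- comp_base(abs_) }
    raa <- translate_codon(paste(rbs, collapse = ""))
    aaa <- translate_codon(paste(abs_, collapse = ""))
    if (raa == aaa) NULL else aa_change(raa, c1, aaa)
  })
  out <- do.call(rbind, c(list(aa_change_empty()), out))
  out[order(out$codon_index, out$alt_aa), , drop = FALSE]
}

#' Label a set of amino-acid changes as a genotype string
#'
#' @param changes data.frame as returned by [call_aa_changes()].
#' @return Comma-joined labels sorted by codon index then alt_aa, or "WT"
#'   when there are no changes.
#' @export
genotype_label <- function(changes) {
  if (is.null(changes) || nrow(changes) == 0L) return("WT")
  changes <- changes[order(changes$codon_index, changes$alt_aa), , drop = FALSE]
  paste(changes$label, collapse = ",")
}

# --- annotation IO ---------------------------------------------------------

#' Read a transcript model from a minimal GTF
#'
#' Uses exon and CDS features of one transcript (GTF is 1-based inclusive
#' and is converted on load).
#'
#' @param path GTF file.
#' @param transcript Optional transcript_id to select when several present.
#' @return A [transcript_model()].
#' @export
read_transcript_gtf <- function(path, transcript = NULL) {
  g <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(g)
  tid <- if ("transcript_id" %in% colnames(md)) md$transcript_id else
    rep(if ("gene_id" %in% colnames(md)) md$gene_id else "tx", length(g))
  if (!is.null(transcript)) g <- g[tid %in% transcript] else {
    first <- tid[!is.na(tid)][1L]
    g <- g[is.na(tid) | tid == first]
  }
  ex <- g[S4Vectors::mcols(g)$type == "exon"]
  cds <- g[S4Vectors::mcols(g)$type == "CDS"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (length(cds) == 0L) stop("no CDS features in ", path)
  ord <- order(BiocGenerics::start(ex))
  exons <- cbind(start = BiocGenerics::start(ex)[ord] - 1L,
                 end = BiocGenerics::end(ex)[ord])
  strand <- as.character(BiocGenerics::strand(ex))[1L]
  # GTF CDS features exclude the stop codon; extend by 3 so the model's
  # spliced CDS ends at the stop, matching the package TSV dialect.
  cds_start <- min(BiocGenerics::start(cds)) - 1L
  cds_end <- max(BiocGenerics::end(cds))
  if (strand == "+") cds_end <- cds_end + 3L else cds_start <- cds_start - 3L
  transcript_model(
    name = if (!is.null(transcript)) transcript else tid[!is.na(tid)][1L],
    chrom = as.character(GenomeInfoDb::seqnames(ex))[1L],
    strand = strand, exons = exons, cds_start = cds_start, cds_end = cds_end)
}

#' Read or write the package transcript table dialect
#'
#' A one-row TSV with columns name, chrom, strand, exon_starts, exon_ends
#' (comma-joined, 0-based half-open) and cds_start, cds_end. The CDS bounds
#' include the stop codon.
#'
#' @param path TSV file.
#' @return A [transcript_model()].
#' @export
read_transcript_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) != 1L) stop("transcript table must have exactly one row")
  starts <- as.integer(strsplit(as.character(d$exon_starts), ",")[[1L]])
  ends <- as.integer(strsplit(as.character(d$exon_ends), ",")[[1L]])
  transcript_model(d$name, d$chrom, d$strand, cbind(starts, ends),
                   d$cds_start, d$cds_end)
}

#' @rdname read_transcript_table
#' @param tx A [transcript_model()] to serialize.
#' @export
write_transcript_table <- function(tx, path) {
  d <- data.frame(name = tx$name, chrom = tx$chrom, strand = tx$strand,
                  exon_starts = paste(tx$exons[, "start"], collapse = ","),
                  exon_ends = paste(tx$exons[, "end"], collapse = ","),
                  cds_start = tx$cds_start, cds_end = tx$cds_end)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation, dispatching on file extension
#' @param path `.gtf` or `.tsv`/`.txt` annotation file.
#' @param ... Passed to the format-specific reader.
#' @return A [transcript_model()].
#' @export
read_annotation <- function(path, ...) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
    read_transcript_gtf(path, ...)
  else read_transcript_table(path)
}
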