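# Single-cell long-read genotyping: soft-clip barcode/UMI extraction,
# CIGAR-walked window base calls, edit-distance UMI consolidation, per-UMI
# plurality consensus and per-cell genotypes with zygosity filtering.
#
# Window base calls use the symbols A/C/G/T, "-" (deleted position) and
# "." (position outside the aligned span).

DEFAULT_ADAPTER <- "CTACACGACGCTCTTCCGATCT"  # 10x 5' partial read1 adapter

#' Read primary mapped alignments from SAM or BAM
#'
#' SAM text is converted with [Rsamtools::asBam()]; secondary,
#' supplementary and unmapped records are dropped (and counted).
#'
#' @param path `.sam` or `.bam` file.
#' @return data.frame with qname, flag, chrom, strand, pos (1-based
#'   leftmost), cigar, seq; attribute `n_skipped` counts dropped records.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, dest,
                                              overwrite = TRUE,
                                              indexDestination = FALSE))
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq")))[[1L]]
  n <- length(b$qname)
  if (n == 0L) {
    out <- data.frame(qname = character(), flag = integer(),
                      chrom = character(), strand = character(),
                      pos = integer(), cigar = character(), seq = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  keep <- bitwAnd(b$flag, 0x4L) == 0L & bitwAnd(b$flag, 0x100L) == 0L &
    bitwAnd(b$flag, 0x800L) == 0L & !is.na(b$pos)
  out <- data.frame(qname = b$qname[keep], flag = b$flag[keep],
                    chrom = as.character(b$rname)[keep],
                    strand = as.character(b$strand)[keep],
                    pos = b$pos[keep], cigar = b$cigar[keep],
                    seq = as.character(b$seq)[keep])
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Read a cell-barcode whitelist
#' @param path Text file, one barcode per line; a trailing "-1" style
#'   suffix is stripped.
#' @return Character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  wl <- readLines(path)
  wl <- sub("-[0-9]+$", "", trimws(wl))
  wl[nzchar(wl)]
}

#' Read sgRNA target windows from TSV
#'
#' File columns: chrom, start, end (1-based inclusive, as printed in
#' logs/outputs) and id; converted to 0-based half-open on load.
#'
#' @param path TSV file.
#' @return data.frame with chrom, start, end (0-based half-open), id.
#' @export
read_windows <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(chrom = d$chrom, start = as.integer(d$start) - 1L,
             end = as.integer(d$end), id = as.character(d$id))
}

# cigar helpers ------------------------------------------------------------

cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[A-Z=]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    o <- cigar_ops(cg)
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

leading_clip <- function(cigar) {
  as.integer(ifelse(grepl("^[0-9]+S", cigar),
                    sub("^([0-9]+)S.*$", "\\1", cigar), "0"))
}
trailing_clip <- function(cigar) {
  as.integer(ifelse(grepl("[0-9]+S$", cigar),
                    sub("^.*?([0-9]+)S$", "\\1", cigar), "0"))
}

#' Extract cell barcode and UMI from 5' soft clips
#'
#' The 5' end of the original read (resolved from the alignment strand)
#' carries adapter + 16 nt cell barcode + 10 nt UMI in the soft-clipped
#' sequence. The barcode must match the whitelist exactly (0 mismatches).
#'
#' @param aln data.frame from [read_alignments()].
#' @param whitelist Barcode character vector.
#' @param adapter Adapter sequence expected 5' of the barcode.
#' @param cb_len,umi_len Barcode and UMI lengths.
#' @return data.frame with columns cb, umi, status; status is "ok" or a
#'   rejection reason: "no_softclip", "truncated" (adapter absent or clip
#'   too short) or "cb_unmatched".
#' @export
extract_cb_umi <- function(aln, whitelist, adapter = DEFAULT_ADAPTER,
                           cb_len = 16L, umi_len = 10L) {
  n <- nrow(aln)
  if (n == 0L)
    return(data.frame(cb = character(), umi = character(), status = character()))
  minus <- aln$strand == "-"
  cliplen <- ifelse(minus, trailing_clip(aln$cigar), leading_clip(aln$cigar))
  seqlen <- nchar(aln$seq)
  clip <- ifelse(cliplen == 0L, "",
                 ifelse(minus,
                        substring(aln$seq, seqlen - cliplen + 1L, seqlen),
                        substring(aln$seq, 1L, cliplen)))
  clip[minus & cliplen > 0L] <- revcomp(clip[minus & cliplen > 0L])

  status <- rep("ok", n)
  cb <- rep(NA_character_, n); umi <- rep(NA_character_, n)
  status[cliplen == 0L] <- "no_softclip"

  todo <- which(status == "ok")
  # last adapter occurrence in the clip; barcode+UMI follow immediately
  adpos <- vapply(clip[todo], function(s) {
    hits <- gregexpr(adapter, s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) -1L else hits[length(hits)]
  }, integer(1L), USE.NAMES = FALSE)
  tail_start <- adpos + nchar(adapter)
  enough <- adpos > 0L &
    nchar(clip[todo]) - tail_start + 1L >= cb_len + umi_len
  status[todo[!enough]] <- "truncated"
  ok <- todo[enough]
  cb[ok] <- substring(clip[ok], tail_start[enough],
                      tail_start[enough] + cb_len - 1L)
  umi[ok] <- substring(clip[ok], tail_start[enough] + cb_len,
                       tail_start[enough] + cb_len + umi_len - 1L)
  unmatched <- ok[!(cb[ok] %in% whitelist)]
  status[unmatched] <- "cb_unmatched"
  cb[status != "ok"] <- NA_character_
  umi[status != "ok"] <- NA_character_
  data.frame(cb = cb, umi = umi, status = status)
}

#' Extract per-window base calls from aligned reads
#'
#' Walks each read's CIGAR to report, at every genomic window position, the
#' read base (substitutions included), "-" for deleted positions and "."
#' outside the aligned span. Insertions between window positions are
#' ignored for calling.
#'
#' @param aln data.frame from [read_alignments()] (rows should overlap the
#'   window; non-spanning reads yield "." positions).
#' @param win A [window_interval()] or list with chrom/start/end
#'   (0-based half-open).
#' @return Character matrix, reads x window width.
#' @export
extract_window_calls <- function(aln, win) {
  width <- win$end - win$start
  out <- matrix(".", nrow = nrow(aln), ncol = width)
  for (r in seq_len(nrow(aln))) {
    o <- cigar_ops(aln$cigar[r])
    ref <- aln$pos[r] - 1L    # 0-based
    qry <- 1L                 # 1-based in seq
    for (i in seq_along(o$op)) {
      len <- o$len[i]; op <- o$op[i]
      if (op %in% c("M", "=", "X")) {
        lo <- max(ref, win$start); hi <- min(ref + len, win$end)
        if (lo < hi) {
          g <- lo:(hi - 1L)
          q <- qry + (g - ref)
          out[r, g - win$start + 1L] <- substring(aln$seq[r], q, q)
        }
        ref <- ref + len; qry <- qry + len
      } else if (op == "D") {
        lo <- max(ref, win$start); hi <- min(ref + len, win$end)
        if (lo < hi) out[r, (lo:(hi - 1L)) - win$start + 1L] <- "-"
        ref <- ref + len
      } else if (op == "N") {
        ref <- ref + len
      } else if (op %in% c("I", "S")) {
        qry <- qry + len
      }                       # H, P: no cursor movement
      if (ref >= win$end) break   # remaining ops cannot touch the window
    }
  }
  toupper(out)
}

#' Consolidate sequencing-error UMIs by edit distance
#'
#' UMIs within `max_dist` Levenshtein distance are merged by single
#' linkage (connected components of the threshold graph); each component is
#' represented by its highest-count member (ties broken lexicographically).
#' Total read counts are conserved.
#'
#' @param umi_read_counts Named integer vector, UMI -> read count.
#' @param max_dist Maximum edit distance merged (default 2, i.e. distance
#'   less than 3).
#' @return Named character vector mapping each input UMI to its
#'   representative.
#' @export
consolidate_umis <- function(umi_read_counts, max_dist = 2L) {
  if (any(umi_read_counts <= 0)) stop("read counts must be positive")
  umis <- names(umi_read_counts)
  n <- length(umis)
  if (n == 0L) return(stats::setNames(character(), character()))
  if (n == 1L) return(stats::setNames(umis, umis))
  d <- utils::adist(umis, umis)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] <= max_dist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  rep_of <- vapply(split(seq_len(n), comp), function(idx) {
    idx[order(-umi_read_counts[idx], umis[idx])][1L]
  }, integer(1L))
  stats::setNames(umis[rep_of[as.character(comp)]], umis)
}

# plurality call per window position; NA when tied or when a deletion /
# uncovered state is the plurality
consensus_from_calls <- function(calls) {
  width <- ncol(calls)
  hap <- character(width)
  for (j in seq_len(width)) {
    tab <- table(factor(calls[, j], levels = c("A", "C", "G", "T", "-", ".")))
    m <- max(tab)
    winners <- names(tab)[tab == m]
    if (m == 0L || length(winners) != 1L || winners %in% c("-", ".")) {
      return(NULL)
    }
    hap[j] <- winners
  }
  paste(hap, collapse = "")
}

#' Per-UMI consensus window haplotype
#'
#' @param calls Character matrix of window base calls (reads of one
#'   (cell, UMI) group x window positions), symbols A/C/G/T/"-"/".".
#' @param min_reads Minimum reads per UMI; groups below are dropped.
#' @param win,tx,ref_seq When supplied, the consensus haplotype is
#'   translated into a genotype label via [call_aa_changes()] (otherwise
#'   `genotype_label` is NA).
#' @return List with status ("ok", "low_support", "no_consensus"),
#'   read_count, consensus_hap and genotype_label.
#' @export
umi_consensus <- function(calls, min_reads = 10L,
                          win = NULL, tx = NULL, ref_seq = NULL) {
  rc <- nrow(calls)
  if (rc == 0L) stop("empty read group")
  if (rc < min_reads)
    return(list(status = "low_support", read_count = rc,
                consensus_hap = NA_character_, genotype_label = NA_character_))
  hap <- consensus_from_calls(calls)
  if (is.null(hap))
    return(list(status = "no_consensus", read_count = rc,
                consensus_hap = NA_character_, genotype_label = NA_character_))
  lab <- NA_character_
  if (!is.null(win) && !is.null(tx) && !is.null(ref_seq)) {
    ref_hap <- ref_slice(ref_seq, win$chrom, win$start, win$end)
    lab <- genotype_label(call_aa_changes(win, ref_hap, hap, tx, ref_seq))
  }
  list(status = "ok", read_count = rc, consensus_hap = hap,
       genotype_label = lab)
}

#' Per-cell genotype with zygosity filtering
#'
#' @param labels Genotype labels of the cell's consensus UMIs.
#' @param majority_frac Minimum UMI share of the winning label for a
#'   homozygous call (default 1.0: strict unanimity; heterozygous cells are
#'   excluded downstream).
#' @param min_umis Minimum consensus UMIs to call at all.
#' @return List with genotype_label, n_umis (supporting the winning
#'   label), n_umis_total and zygosity
#'   ("homozygous"/"heterozygous"/"unresolved").
#' @export
cell_genotype <- function(labels, majority_frac = 1.0, min_umis = 1L) {
  n <- length(labels)
  if (n < min_umis)
    return(list(genotype_label = NA_character_, n_umis = 0L,
                n_umis_total = n, zygosity = "unresolved"))
  tab <- sort(table(labels), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L || max(tab) / n < majority_frac)
    return(list(genotype_label = NA_character_, n_umis = as.integer(max(tab)),
                n_umis_total = n, zygosity = "heterozygous"))
  list(genotype_label = top, n_umis = as.integer(tab[[top]]),
       n_umis_total = n, zygosity = "homozygous")
}

#' Run the full long-read genotyping pipeline
#'
#' Composes soft-clip barcode/UMI extraction, per-window base calling, UMI
#' consolidation, per-UMI consensus and per-cell genotyping, one window at
#' a time.
#'
#' @param bam SAM/BAM path or a data.frame from [read_alignments()].
#' @param ref_seq Genome (path to FASTA or object from
#'   [read_genome_fasta()]).
#' @param tx Transcript model (path to annotation or [transcript_model()]).
#' @param whitelist Barcode whitelist (path or character vector).
#' @param windows Target windows (path to TSV or data.frame from
#'   [read_windows()]).
#' @param min_umi_reads Minimum reads per consolidated UMI (default 10).
#' @param max_umi_dist UMI consolidation edit distance (default 2).
#' @param majority_frac,min_umis Passed to [cell_genotype()].
#' @param adapter,cb_len,umi_len Passed to [extract_cb_umi()].
#' @return List with `umis` (per-UMI table), `cells` (per-cell table,
#'   ordered by cb then window) and `report` (read/UMI/cell tallies).
#' @export
genotype_pipeline <- function(bam, ref_seq, tx, whitelist, windows,
                              min_umi_reads = 10L, max_umi_dist = 2L,
                              majority_frac = 1.0, min_umis = 1L,
                              adapter = DEFAULT_ADAPTER,
                              cb_len = 16L, umi_len = 10L) {
  if (is.character(bam)) bam <- read_alignments(bam)
  if (is.character(ref_seq)) ref_seq <- read_genome_fasta(ref_seq)
  ref_seq <- as_genome(ref_seq)
  if (is.character(tx)) tx <- read_annotation(tx)
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist)) whitelist <- read_whitelist(whitelist)
  if (is.character(windows)) windows <- read_windows(windows)
  for (w in seq_len(nrow(windows))) {
    win <- window_interval(windows$chrom[w], windows$start[w], windows$end[w])
    if (!windows$chrom[w] %in% names(ref_seq))
      stop("window chromosome ", windows$chrom[w], " not in reference")
    check_window_in_exon(win, tx)
  }

  tags <- extract_cb_umi(bam, whitelist, adapter, cb_len, umi_len)
  reject_tab <- table(factor(tags$status,
    levels = c("ok", "no_softclip", "truncated", "cb_unmatched")))
  assigned <- which(tags$status == "ok")

  umi_rows <- list(); cell_rows <- list()
  umi_drop <- c(low_support = 0L, no_consensus = 0L)
  label_cache <- new.env(parent = emptyenv())

  for (w in seq_len(nrow(windows))) {
    win <- window_interval(windows$chrom[w], windows$start[w], windows$end[w])
    ref_hap <- ref_slice(ref_seq, win$chrom, win$start, win$end)
    ref_end <- bam$pos - 1L + cigar_ref_len(bam$cigar)
    idx <- assigned[bam$chrom[assigned] == win$chrom &
                    bam$pos[assigned] - 1L < win$end &
                    ref_end[assigned] > win$start]
    if (length(idx) == 0L) next
    calls <- extract_window_calls(bam[idx, , drop = FALSE], win)
    cbs <- tags$cb[idx]; umis <- tags$umi[idx]

    label_of <- function(hap) {
      if (is.null(label_cache[[hap]]))
        label_cache[[hap]] <- genotype_label(
          call_aa_changes(win, ref_hap, hap, tx, ref_seq))
      label_cache[[hap]]
    }

    for (cb in sort(unique(cbs))) {
      ci <- which(cbs == cb)
      counts <- table(umis[ci])
      cmap <- consolidate_umis(stats::setNames(as.integer(counts),
                                               names(counts)), max_umi_dist)
      reps <- cmap[umis[ci]]
      cell_labels <- character()
      for (rep_umi in sort(unique(reps))) {
        ri <- ci[reps == rep_umi]
        cons <- umi_consensus(calls[ri, , drop = FALSE],
                              min_reads = min_umi_reads)
        if (cons$status != "ok") {
          umi_drop[[cons$status]] <- umi_drop[[cons$status]] + 1L
          next
        }
        hap <- cons$consensus_hap
        lab <- if (grepl("[^ACGT]", hap)) NA_character_ else label_of(hap)
        umi_rows[[length(umi_rows) + 1L]] <- data.frame(
          cb = cb, umi = rep_umi, window = windows$id[w],
          read_count = cons$read_count, consensus_hap = hap,
          genotype_label = lab)
        cell_labels <- c(cell_labels, lab)
      }
      cg <- cell_genotype(cell_labels, majority_frac, min_umis)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        cb = cb, window = windows$id[w],
        genotype_label = cg$genotype_label, n_umis = cg$n_umis,
        n_umis_total = cg$n_umis_total, zygosity = cg$zygosity)
    }
  }

  empty_umis <- data.frame(cb = character(), umi = character(),
                           window = character(), read_count = integer(),
                           consensus_hap = character(),
                           genotype_label = character())
  empty_cells <- data.frame(cb = character(), window = character(),
                            genotype_label = character(), n_umis = integer(),
                            n_umis_total = integer(), zygosity = character())
  umis_df <- if (length(umi_rows)) do.call(rbind, umi_rows) else empty_umis
  cells_df <- if (length(cell_rows)) do.call(rbind, cell_rows) else empty_cells
  umis_df <- umis_df[order(umis_df$cb, umis_df$window, umis_df$umi), ,
                     drop = FALSE]
  cells_df <- cells_df[order(cells_df$cb, cells_df$window), , drop = FALSE]
  rownames(umis_df) <- NULL; rownames(cells_df) <- NULL

  report <- list(
    reads = list(total = nrow(bam),
                 skipped_nonprimary = attr(bam, "n_skipped"),
                 assigned = length(assigned),
                 rejected = as.list(reject_tab[-1L])),
    umis = list(kept = nrow(umis_df),
                dropped = as.list(umi_drop)),
    cells = list(total = nrow(cells_df),
                 genotyped = sum(cells_df$zygosity == "homozygous"),
                 heterozygous = sum(cells_df$zygosity == "heterozygous"),
                 unresolved = sum(cells_df$zygosity == "unresolved")))
  list(umis = umis_df, cells = cells_df, report = report)
}

#' Write genotyping pipeline outputs
#' @param res Result of [genotype_pipeline()].
#' @param dir Output directory (created if needed); writes per_umi.tsv,
#'   per_cell.tsv and report.json.
#' @return Invisibly, the directory.
#' @export
write_genotype_output <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$umis, file.path(dir, "per_umi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$cells, file.path(dir, "per_cell.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
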