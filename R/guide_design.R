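# Base-editor guide design and exhaustive edit-outcome enumeration.
#
# Protospacer positions are numbered 1..20 from the 5' (PAM-distal) end of
# the guide; the PAM sits immediately 3' of position 20. The editing window
# (default positions 3..8) therefore covers 6 genomic bases. Window
# haplotypes are always reported in genomic plus-strand orientation.

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_match <- function(pattern, seq) {
  pb <- strsplit(toupper(pattern), "")[[1L]]
  sb <- strsplit(toupper(seq), "")[[1L]]
  if (length(pb) != length(sb)) return(FALSE)
  all(mapply(function(p, s) grepl(s, IUPAC_CLASS[[p]], fixed = TRUE), pb, sb))
}

#' Describe a base editor
#'
#' @param name Editor name (free text, e.g. "NGG-CBE").
#' @param conversion Length-2 character vector `c(from, to)` on the
#'   protospacer strand: `c("C","T")` for a CBE, `c("A","G")` for an ABE.
#' @param pam IUPAC PAM pattern anchored immediately 3' of the protospacer
#'   ("NGG" or "NG").
#' @param window Inclusive protospacer positions of the editing window,
#'   numbered 1..20 from the PAM-distal 5' end (default 3..8).
#' @param include_byproduct For CBEs, also model C->G byproduct outcomes.
#' @return A `base_editor_spec` object.
#' @export
base_editor_spec <- function(name, conversion, pam = "NGG",
                             window = c(3L, 8L), include_byproduct = FALSE) {
  conversion <- toupper(conversion)
  window <- as.integer(window)
  if (length(conversion) != 2L || conversion[1L] == conversion[2L])
    stop("conversion must be two distinct bases c(from, to)")
  if (!all(conversion %in% c("A", "C", "G", "T"))) stop("invalid conversion bases")
  if (nchar(pam) < 1L) stop("pam must be non-empty")
  if (!(window[1L] >= 1L && window[1L] <= window[2L] && window[2L] <= 20L))
    stop("window must satisfy 1 <= start <= end <= 20")
  structure(list(name = name, from = conversion[1L], to = conversion[2L],
                 pam = toupper(pam), window = window,
                 include_byproduct = include_byproduct),
            class = "base_editor_spec")
}

#' Built-in editor presets
#'
#' @param editor One of "ngg-cbe", "ng-cbe", "ngg-abe", "ng-abe".
#' @param ... Overrides passed to [base_editor_spec()] (e.g. window,
#'   include_byproduct).
#' @return A [base_editor_spec()].
#' @export
editor_preset <- function(editor, ...) {
  editor <- tolower(editor)
  args <- switch(editor,
    "ngg-cbe" = list(name = "NGG-CBE", conversion = c("C", "T"), pam = "NGG"),
    "ng-cbe"  = list(name = "NG-CBE",  conversion = c("C", "T"), pam = "NG"),
    "ngg-abe" = list(name = "NGG-ABE", conversion = c("A", "G"), pam = "NGG"),
    "ng-abe"  = list(name = "NG-ABE",  conversion = c("A", "G"), pam = "NG"),
    stop("unknown editor preset: ", editor))
  do.call(base_editor_spec, utils::modifyList(args, list(...)))
}

# alternative bases the editor can install at an editable position
editor_alt_bases <- function(spec) {
  alts <- spec$to
  if (spec$include_byproduct && spec$from == "C") alts <- union(alts, "G")
  alts
}

# guide-strand base at protospacer position j (1..20)
proto_base <- function(chromseq, strand, proto_start, proto_end, j) {
  if (strand == "+") substring(chromseq, proto_start + j, proto_start + j)
  else comp_base(substring(chromseq, proto_end - j + 1L, proto_end - j + 1L))
}

# genomic 0-based position of protospacer position j
proto_gpos <- function(strand, proto_start, proto_end, j) {
  if (strand == "+") proto_start + j - 1L else proto_end - j
}

#' Find base-editor guides realizing an amino-acid substitution
#'
#' Enumerates the single-nucleotide codon changes that produce the requested
#' substitution and are achievable by the editor's conversion on either
#' genome strand, then emits every 20-nt protospacer placement that puts the
#' target base at an in-window position with a PAM match immediately 3' on
#' the guide strand.
#'
#' @param intended One-row data.frame from [aa_change()].
#' @param tx A [transcript_model()].
#' @param ref_seq Genome from [read_genome_fasta()].
#' @param spec A [base_editor_spec()].
#' @return List of `guide_design` objects, ordered by protospacer genomic
#'   coordinate then strand; empty when the substitution is not achievable.
#' @export
find_guides <- function(intended, tx, ref_seq, spec) {
  stopifnot(inherits(spec, "base_editor_spec"), inherits(tx, "transcript_model"))
  ref_seq <- as_genome(ref_seq)
  chromseq <- ref_seq[[tx$chrom]]
  ci <- intended$codon_index
  if (3L * ci > length(tx$cds_pos))
    stop("codon_index ", ci, " beyond CDS of ", tx$name)
  g <- codon_positions(ci, tx)                    # transcript order
  tb <- substring(chromseq, g + 1L, g + 1L)
  if (tx$strand == "-") tb <- comp_base(tb)       # transcript-strand bases
  ref_codon <- paste(tb, collapse = "")
  if (translate_codon(ref_codon) != intended$ref_aa)
    stop("reference codon ", ref_codon, " at position ", ci, " encodes ",
         translate_codon(ref_codon), ", not ", intended$ref_aa)

  # candidate single-nucleotide changes realizing the substitution
  cand <- list()
  for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), tb[p])) {
    nc <- tb; nc[p] <- nb
    if (translate_codon(paste(nc, collapse = "")) == intended$alt_aa) {
      gref <- if (tx$strand == "-") comp_base(tb[p]) else tb[p]
      galt <- if (tx$strand == "-") comp_base(nb) else nb
      cand[[length(cand) + 1L]] <- list(pos = g[p], gref = gref, galt = galt)
    }
  }

  alts <- editor_alt_bases(spec)
  plen <- nchar(spec$pam)
  w <- spec$window
  glen <- nchar(chromseq)
  guides <- list()
  seen <- character()

  for (cc in cand) for (s in c("+", "-")) {
    sref <- if (s == "+") cc$gref else comp_base(cc$gref)
    salt <- if (s == "+") cc$galt else comp_base(cc$galt)
    if (sref != spec$from || !(salt %in% alts)) next
    for (k in w[1L]:w[2L]) {                      # protospacer pos of target
      if (s == "+") {
        proto_start <- cc$pos - (k - 1L); proto_end <- proto_start + 20L
        pam_start <- proto_end; pam_end <- proto_end + plen
      } else {
        proto_end <- cc$pos + k; proto_start <- proto_end - 20L
        pam_start <- proto_start - plen; pam_end <- proto_start
      }
      if (proto_start < 0L || proto_end > glen ||
          pam_start < 0L || pam_end > glen) next
      pam_obs <- if (s == "+") substring(chromseq, pam_start + 1L, pam_end)
                 else revcomp(substring(chromseq, pam_start + 1L, pam_end))
      if (!iupac_match(spec$pam, pam_obs)) next
      key <- paste(s, proto_start)
      if (key %in% seen) next

      win_g <- sort(vapply(w[1L]:w[2L], function(j)
        proto_gpos(s, proto_start, proto_end, j), integer(1L)))
      win <- window_interval(tx$chrom, win_g[1L], win_g[length(win_g)] + 1L, s)
      ok <- tryCatch({ check_window_in_exon(win, tx); TRUE },
                     error = function(e) FALSE)
      if (!ok) next

      protospacer <- if (s == "+")
        substring(chromseq, proto_start + 1L, proto_end)
      else revcomp(substring(chromseq, proto_start + 1L, proto_end))
      editable <- Filter(function(j)
        proto_base(chromseq, s, proto_start, proto_end, j) == spec$from,
        w[1L]:w[2L])
      guides[[length(guides) + 1L]] <- structure(list(
        protospacer = protospacer, guide_strand = s,
        pam_seq = pam_obs, window = win,
        proto_start = proto_start, proto_end = proto_end,
        editable_offsets = as.integer(editable),
        intended_offset = k, intended = intended,
        editor = spec$name), class = "guide_design")
      seen <- c(seen, key)
    }
  }
  ord <- order(vapply(guides, function(x) x$proto_start, integer(1L)),
               vapply(guides, function(x) match(x$guide_strand, c("+", "-")),
                      integer(1L)))
  guides[ord]
}

#' @export
print.guide_design <- function(x, ...) {
  cat(sprintf("<guide> %s(%s) PAM %s window %s editable@%s intended %s\n",
              x$protospacer, x$guide_strand, x$pam_seq,
              fmt_coords(x$window$chrom, x$window$start, x$window$end),
              paste(x$editable_offsets, collapse = ","), x$intended$label))
  invisible(x)
}

#' Enumerate all achievable edit outcomes of a guide
#'
#' One outcome per assignment of each editable window position to its
#' possible states: {reference, converted} (2^k outcomes), or with CBE
#' byproducts {reference, T, G} (3^k outcomes).
#'
#' @param guide A `guide_design` from [find_guides()].
#' @param spec The [base_editor_spec()] used to design it.
#' @param tx,ref_seq Transcript model and genome.
#' @param cap Maximum number of editable positions (combinatorial guard).
#' @return List of outcomes; each has `edited_offsets` (protospacer
#'   positions), `alt_hap` (plus-strand window haplotype), `aa_changes`,
#'   `label` (see [genotype_label()]), `is_intended` and `is_reference`.
#' @export
enumerate_outcomes <- function(guide, spec, tx, ref_seq, cap = 8L) {
  stopifnot(inherits(guide, "guide_design"))
  ref_seq <- as_genome(ref_seq)
  chromseq <- ref_seq[[tx$chrom]]
  win <- guide$window
  wpos <- spec$window[1L]:spec$window[2L]
  k <- length(guide$editable_offsets)
  if (k > cap)
    stop("combinatorial cap exceeded: ", k, " editable positions > cap ", cap)

  ref_hap_plus <- ref_slice(ref_seq, win$chrom, win$start, win$end)
  # guide-strand window bases by protospacer position
  gs_ref <- vapply(wpos, function(j)
    proto_base(chromseq, guide$guide_strand, guide$proto_start,
               guide$proto_end, j), character(1L))
  names(gs_ref) <- wpos
  alts <- editor_alt_bases(spec)

  choice_sets <- rep(list("."), length(wpos))
  names(choice_sets) <- wpos
  for (j in as.character(guide$editable_offsets))
    choice_sets[[j]] <- c(gs_ref[[j]], alts)
  grid <- expand.grid(choice_sets[as.character(guide$editable_offsets)],
                      stringsAsFactors = FALSE)
  if (k == 0L) grid <- data.frame(row.names = 1L)

  intended_label <- guide$intended$label
  out <- lapply(seq_len(max(nrow(grid), 1L)), function(i) {
    gs_alt <- gs_ref
    if (k > 0L) for (j in seq_len(k)) {
      gs_alt[[as.character(guide$editable_offsets[j])]] <- grid[i, j]
    }
    edited <- guide$editable_offsets[gs_alt[as.character(guide$editable_offsets)] !=
                                     gs_ref[as.character(guide$editable_offsets)]]
    hap_guide <- paste(gs_alt, collapse = "")
    alt_hap <- if (guide$guide_strand == "+") hap_guide else revcomp(hap_guide)
    changes <- call_aa_changes(win, ref_hap_plus, alt_hap, tx, ref_seq)
    list(edited_offsets = as.integer(edited), alt_hap = alt_hap,
         aa_changes = changes, label = genotype_label(changes),
         is_intended = intended_label %in% changes$label,
         is_reference = length(edited) == 0L)
  })
  out
}

#' Tabulate outcomes as a data.frame
#' @param outcomes List from [enumerate_outcomes()].
#' @return data.frame with one row per outcome.
#' @export
outcomes_table <- function(outcomes) {
  data.frame(
    alt_hap = vapply(outcomes, `[[`, character(1L), "alt_hap"),
    edited_offsets = vapply(outcomes, function(o)
      paste(o$edited_offsets, collapse = ","), character(1L)),
    aa_changes = vapply(outcomes, `[[`, character(1L), "label"),
    is_intended = vapply(outcomes, `[[`, logical(1L), "is_intended"),
    is_reference = vapply(outcomes, `[[`, logical(1L), "is_reference"))
}

# bystanders = editable positions other than the intended target base
n_bystanders <- function(guide) length(setdiff(guide$editable_offsets,
                                               guide$intended_offset))

#' Design a guide library for a mutation list
#'
#' @param mutations data.frame with columns ref_aa, codon_index, alt_aa
#'   (extra columns ignored; duplicates by label are collapsed).
#' @param tx,ref_seq Transcript model and genome.
#' @param specs List of [base_editor_spec()]s.
#' @param best_only Keep only the best guide per mutation and editor
#'   (fewest editable bystanders, then smallest window offset of the target
#'   base, then genomic coordinate); otherwise keep all placements.
#' @param cap Passed to [enumerate_outcomes()].
#' @return List with `table` (one row per unique mutation), `guides`
#'   (chosen guide objects) and `summary` (n_targetable, guides per editor,
#'   distinct achievable amino-acid changes counted both as the
#'   library-wide union and summed per guide).
#' @export
design_library <- function(mutations, tx, ref_seq, specs, best_only = TRUE,
                           cap = 8L) {
  if (nrow(mutations) == 0L) stop("empty mutation list")
  mutations$label <- paste0(mutations$ref_aa, mutations$codon_index,
                            mutations$alt_aa)
  mutations <- mutations[!duplicated(mutations$label), , drop = FALSE]
  if (inherits(specs, "base_editor_spec")) specs <- list(specs)

  all_guides <- list()
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    mut <- aa_change(mutations$ref_aa[i], mutations$codon_index[i],
                     mutations$alt_aa[i])
    per_spec <- integer(length(specs))
    names(per_spec) <- vapply(specs, `[[`, character(1L), "name")
    for (sp in seq_along(specs)) {
      gs <- find_guides(mut, tx, ref_seq, specs[[sp]])
      if (length(gs) > 0L && best_only) {
        ord <- order(vapply(gs, n_bystanders, integer(1L)),
                     vapply(gs, `[[`, integer(1L), "intended_offset"),
                     vapply(gs, `[[`, integer(1L), "proto_start"))
        gs <- gs[ord[1L]]
      }
      per_spec[sp] <- length(gs)
      for (g in gs) {
        g$spec_index <- sp
        all_guides[[length(all_guides) + 1L]] <<- g
      }
    }
    c(list(label = mut$label, targetable = sum(per_spec) > 0L),
      as.list(per_spec))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))

  union_labels <- character()
  per_guide_sum <- 0L
  for (g in all_guides) {
    oc <- enumerate_outcomes(g, specs[[g$spec_index]], tx, ref_seq, cap = cap)
    labs <- unique(unlist(lapply(oc, function(o) o$aa_changes$label)))
    union_labels <- union(union_labels, labs)
    per_guide_sum <- per_guide_sum + length(labs)
  }
  n_by_spec <- table(factor(
    vapply(all_guides, function(g) specs[[g$spec_index]]$name, character(1L)),
    levels = vapply(specs, `[[`, character(1L), "name")))

  list(table = tab, guides = all_guides,
       summary = list(
         n_mutations = nrow(tab),
         n_targetable = sum(tab$targetable),
         n_guides = length(all_guides),
         n_guides_by_spec = as.list(n_by_spec),
         n_achievable_unique = length(union_labels),
         n_achievable_per_guide_sum = per_guide_sum))
}

#' Write guide and outcome tables as TSV
#'
#' @param guides List of guides.
#' @param specs Editor specs indexed by `spec_index` of each guide (or a
#'   single spec applied to all).
#' @param tx,ref_seq Transcript model and genome.
#' @param guides_path,outcomes_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_guide_tables <- function(guides, specs, tx, ref_seq,
                               guides_path, outcomes_path) {
  if (inherits(specs, "base_editor_spec")) specs <- list(specs)
  gt <- do.call(rbind, lapply(guides, function(g) {
    sp <- specs[[if (is.null(g$spec_index)) 1L else g$spec_index]]
    data.frame(protospacer = g$protospacer, strand = g$guide_strand,
               pam = g$pam_seq, editor = sp$name,
               window = fmt_coords(g$window$chrom, g$window$start, g$window$end),
               editable_offsets = paste(g$editable_offsets, collapse = ","),
               intended = g$intended$label,
               n_outcomes = (length(editor_alt_bases(sp)) + 1L)^
                 length(g$editable_offsets))
  }))
  utils::write.table(gt, guides_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ot <- do.call(rbind, lapply(seq_along(guides), function(i) {
    sp <- specs[[if (is.null(guides[[i]]$spec_index)) 1L else guides[[i]]$spec_index]]
    cbind(guide = i, outcomes_table(enumerate_outcomes(guides[[i]], sp, tx, ref_seq)))
  }))
  utils::write.table(ot, outcomes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(guides_path, outcomes_path))
}
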