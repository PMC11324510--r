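---
title: "Methods: design, genotyping and classification in editscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, genotyping and classification in editscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(editscreen)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. Coordinates, transcripts and amino-acid calls

All intervals are 0-based half-open internally; every printed coordinate
is 1-based inclusive, the convention of genome browsers and of target
descriptions like `chr17:7674940-7674945`. A `transcript_model` holds
sorted, disjoint exons and CDS bounds; at construction the genomic
position of every CDS base is precomputed in transcript (5′→3′) order, so
genomic→codon mapping is a single table lookup and is trivially invertible
(`codon_index*3 + offset` indexes back into that table — the round-trip is
a property test).

Window haplotypes are always expressed on the genomic **plus** strand
regardless of gene or guide strand, because that is how target windows are
described in practice (a plus-strand 6-mer over a minus-strand gene).
`call_aa_changes` complements internally: each codon touched by a
substituted window position is rebuilt with *all* window substitutions
applied simultaneously (two edits in one codon must be evaluated jointly,
not per-base), translated with the standard genetic code, and a change is
emitted only when the amino acid differs. Synonymous edits therefore emit
nothing and a fully synonymous haplotype is labelled `WT` — an explicit
choice: the genotype label describes protein consequence, not nucleotide
state. Stop codons are written `Ter` (`W146Ter` style). Multi-exon windows
are rejected rather than splice-handled; real editing windows sit inside
single exons and silent mis-handling would be worse than an error.

## 2. Guide design and outcome enumeration

Protospacers are numbered 1–20 from the PAM-distal 5′ end with the PAM
immediately 3′; the default editing window is positions 3–8 (six genomic
bases). For an intended substitution, the designer enumerates the
single-nucleotide codon changes that realize it, keeps those achievable by
the editor's conversion (C→T for CBE, A→G for ABE) on either genome
strand, and emits every placement that puts the target base in-window with
a PAM match. A placement's `editable_offsets` are all window positions
carrying the convertible base on the guide strand; the intended edit is
one of them, the rest are bystanders.

`enumerate_outcomes` materializes one outcome per assignment of each
editable position to {reference, converted} — `2^k` outcomes for `k`
editable bases, or `3^k` with the CBE C→G byproduct enabled (off by
default; byproducts are observed in practice but designs target C→T). The
subset↔haplotype bijection and the exact counts are acceptance-tested
against an independent enumeration. A combinatorial cap (default 8
editable bases, 6561 outcomes with byproducts) guards against pathological
windows. No per-base editing-efficiency model is included: achievable
outcomes are a design property; their frequencies are an observation that
belongs to data, and the genotyper measures them.

Best-guide selection orders by fewest bystanders, then smallest window
offset of the target base, then genomic coordinate — fully deterministic.
The library summary reports achievable amino-acid changes both as a
library-wide union of labels and summed per guide, since either convention
is defensible for "changes a library can introduce".

## 3. Long-read genotyping

**Barcode extraction.** After alignment, the adapter + 16 nt cell barcode
+ 10 nt UMI of a 5′ capture chemistry survive as soft-clipped sequence.
The extractor resolves read orientation from the alignment strand (for a
reverse-strand alignment the biological 5′ clip is the reverse complement
of the trailing clip), finds the last adapter occurrence in the clip and
takes the next 26 bases. Barcode matching is **exact** — zero mismatches,
no rescue — trading yield for fidelity; with ~10–20 reads per molecule the
yield cost is immaterial and the false-assignment cost is not.

**Window calls.** A CIGAR walk reports, per genomic window position, the
read base, `-` for a deletion, `.` outside the aligned span; insertions
between window positions do not shift calls. The implementation is
in-package (it is the method's core); tests compare it against
`GenomicAlignments::stackStringsFromBam` as an independent oracle.

**UMI consolidation.** UMIs within Levenshtein distance 2 ("edit distance
less than 3") are merged by transitive single linkage — connected
components of the threshold graph — with the highest-count member (ties:
lexicographic) as representative. The alternative, greedy assignment to
the first accepted representative, fails transitive chains (A–B = 2,
B–C = 2, A–C = 4 should collapse to one molecule); components also give
idempotence and mass conservation by construction, both property-tested.
Consolidation runs per cell barcode *before* the read-count filter, which
maximizes support for true molecules; the alternative order is a
documented unknown and the threshold is a parameter.

**Consensus and zygosity.** Each consolidated UMI with ≥ `min_umi_reads`
reads (default 10; an amplicon experiment with shorter reads uses 3) gets
a per-position plurality vote. A tie, or a plurality that is a deletion or
uncovered state, voids the whole UMI (`no_consensus`) rather than emitting
an ambiguous haplotype — genotype labels must be unambiguous downstream.
A cell is homozygous only if its consensus UMIs are unanimous
(`majority_frac = 1.0`, relaxable); otherwise heterozygous and excluded
from phenotype analysis. Unanimity is deliberately strict: the exclusion
rule exists to remove cells whose genotype is uncertain, and with ~3–6
UMIs per cell a 75% majority is weak evidence.

## 4. Concordance

Short-read amplicon pairs are parsed without an aligner: read1[1:16] is
the barcode (exact whitelist match), read1[17:26] the UMI, and the window
is located in read2 by exact match of the reference anchor immediately 5′
of the window (amplicons are fixed constructs; an aligner dependency buys
nothing). Per-UMI concordance is the fraction of shared
(cell, UMI, window) keys with identical calls — symmetric and bounded by
construction. Variant frequency tables include the reference class so
per-window frequencies sum to one; `frequency_r2` is squared Pearson
correlation with variants missing from one table zero-filled (stated
explicitly because it changes R² and conventions differ), optionally on
log10(f + 1e-4) to match log–log frequency plots. Both raw and log modes
are offered because published R² values rarely say which was used.

## 5. Expression integration and classification

The pipeline is: inner join on suffix-normalized barcodes → QC (cells
with <100 or >8000 detected genes or >30% mitochondrial counts removed,
then genes in fewer than 4 cells removed — cells before genes, so gene
detection is evaluated on the retained population) → per-cell scaling to
10,000 counts and log1p → clustering → module scores → cluster
proportions → classification → Welch tests.

**Clustering is pluggable.** The built-in route (top-variance genes → PCA
→ seeded k-means, defaults 2000 genes / 20 PCs / k = 10) exists so the
pipeline is self-contained and deterministic; a labels file from any
graph-clustering toolkit is accepted and used verbatim. The built-in is a
stand-in, not a reimplementation of UMAP/graph pipelines.

**Module score.** Mean normalized expression of the gene set minus the
mean of control genes sampled (seeded, without replacement) from
expression-matched bins (24 bins, 100 controls per set gene). The
bin-matched control is what makes the score robust to library-size and
expression-level composition; the exact formula is stated here because
published "gene scores" often name a tool without one.

**Classification.** Variants detected in ≥ 5 cells are profiled by their
proportion across clusters; rows are hierarchically clustered and the
tree is cut; variants sharing wild type's group are wild-type-like. Two
design points required deviation from the obvious defaults, both
discovered by testing against simulated truth:

* *Fixed k = 2 cuts are wrong.* Cutting into two groups forces a split
  even when every variant is null, so some null variant is always called
  significant; and with a range of effect sizes the two-group cut of a
  complete-linkage tree lands at the widest gap *inside* the affected
  continuum, absorbing the weakest real effect into the wild-type group.
  The default is therefore a **height** cut calibrated to sampling noise:
  under the null that a variant's nᵥ cells fall into clusters by the
  wild-type multinomial, E‖√p̂ᵥ − √p̂₍wt₎‖² = (K−1)/4 (1/nᵥ + 1/n₍wt₎);
  the tree (average linkage) is cut at twice that distance. An all-null
  panel then stays in one group, and any profile beyond noise separates.
* *Raw Euclidean distance on proportions is insensitive exactly where
  weak variants differ* — clusters where wild type has near-zero mass.
  The square-root (Hellinger-type) transform stabilizes multinomial
  variance to ≈ (1−p)/4n per cluster and amplifies those low-p
  differences. With it, the weakest planted effects in the acceptance
  suite separate cleanly where raw distance left them inside the noise
  band.

The spec-style `k_cut = 2` / complete-linkage / Euclidean mode remains
available through arguments and is exercised in tests against a
brute-force agglomerative oracle. Per-variant Welch t-tests on module
scores (two-sided, unequal variance, raw p — no multiplicity correction,
matching how such per-variant p values are conventionally reported)
accompany but do not drive the classification. The rank-sum DGE operation
is a reduced-scope stand-in for external DGE tooling: Wilcoxon per gene
detected in ≥10% of either group, BH-adjusted within tested genes.

## 6. The synthetic world

The generator emulates: a 1–3 exon toy gene on either strand; window
genotypes planted per cell with configurable fractions; long reads whose
soft clips carry prefix + adapter + barcode + UMI and whose aligned
portions span the window with i.i.d. substitution (2%) and indel (1%)
errors and CIGARs consistent with the injected indels; an ambient-barcode
read fraction (2%); negative-binomial expression (size 2) over 2000 genes
with a 100-gene pathway whose means are multiplied per cell by the
genotype's effect; and NMD emulated as binomial thinning of a stop-gain
genotype's molecule count by a capture factor. Cell counts, UMIs per cell
(3–6) and reads per UMI (10–20) default to the regime the method is
designed for: deep consensus over few molecules.

Defaults chosen once, with reasons: pathway genes are moderately expressed
(log-normal mean ≈ 2 counts) because a pathway signature one can measure
per cell must sit above dropout; background genes are log-normal around
0.3 counts, the sparse regime typical of droplet data; dispersion size 2
is mid-range for UMI counts; the pathway is 5% of genes so it does not
dominate total library size. These were fixed before the acceptance
criteria were evaluated and were not revisited afterwards.

What the generator does **not** emulate — and therefore what a green test
does not establish: nanopore error structure (errors here are i.i.d.; real
homopolymer-correlated errors make per-UMI consensus *harder* at equal
rates), doublets and ambient RNA beyond a barcode-swap fraction, batch
effects, cell-cycle structure, splice isoforms (reads are confined to the
window's exon; the genotyper is window-restricted by design), and any
correlation structure among pathway genes beyond a shared mean shift.
Recovery rates measured on this world are upper bounds on real-data
performance, which is why the validation layer (short-read concordance,
DNA/cDNA frequency comparison) is part of the package rather than an
afterthought.

## 7. Numerical and degenerate-input choices

* Plurality ties and deletion/uncovered pluralities drop the UMI; no
  N-containing haplotypes exist anywhere downstream.
* `frequency_r2` raises an explicit error on zero variance rather than
  returning NA; correlation of a constant vector is undefined, not zero.
* Zero-count cells normalize to all-zero vectors (no 0/0).
* k-means uses 10 restarts under a fixed seed; identical seeds give
  byte-identical outputs end to end (tested).
* Empty inputs (no reads, no overlap, all-filtered matrices) raise typed
  errors or return empty tables with zeroed reports, never partial state.
* All consolidation/consensus tie-breaks are lexicographic, making every
  pipeline output deterministic for a fixed input.

## 8. Known limitations

Indel genotypes are out of scope (a deletion plurality is a no-call, not
a genotype); phasing across multiple windows is not attempted; the
built-in clusterer is not a substitute for graph clustering on real data;
and the classifier assumes the wild-type profile is estimated from
substantially more cells than any single variant, which matches screen
designs but not balanced experiments.
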