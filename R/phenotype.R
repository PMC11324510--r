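# Genotype-transcriptome integration: QC, normalization, clustering,
# pathway module scores, cluster-proportion profiles and hierarchical
# wild-type-like vs functionally-significant classification.

#' Read a MatrixMarket expression triplet
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` (optionally .gz)
#' in one directory: genes x cells raw counts.
#'
#' @param dir Directory containing the triplet.
#' @return dgCMatrix with gene rownames and barcode colnames.
#' @export
read_mtx <- function(dir) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", base, " in ", dir)
  }
  m <- methods::as(Matrix::readMM(pick("matrix.mtx")), "CsparseMatrix")
  feats <- utils::read.delim(pick("features.tsv"), header = FALSE)
  bcs <- utils::read.delim(pick("barcodes.tsv"), header = FALSE)
  rownames(m) <- as.character(feats[[1L]])
  colnames(m) <- as.character(bcs[[1L]])
  m
}

#' Write a MatrixMarket expression triplet
#' @param m Genes x cells matrix with dimnames.
#' @param dir Output directory (created).
#' @return Invisibly, `dir`.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Quality-control filter an expression matrix
#'
#' Cells are filtered first (gene count bounds, mitochondrial fraction),
#' then genes (minimum number of cells with a nonzero count).
#'
#' @param m Genes x cells count matrix.
#' @param min_genes,max_genes Keep cells with gene count in
#'   `[min_genes, max_genes]` (defaults 100 and 8000; a cell with 99
#'   detected genes is removed).
#' @param max_mito_frac Maximum mitochondrial count fraction (default 0.30).
#' @param min_cells_per_gene Keep genes detected in at least this many
#'   cells (default 4, i.e. genes present in three or fewer cells are
#'   removed).
#' @param mito_prefix Prefix identifying mitochondrial genes.
#' @return Filtered matrix with a `qc_report` attribute of per-rule
#'   removal counts.
#' @export
qc_filter <- function(m, min_genes = 100L, max_genes = 8000L,
                      max_mito_frac = 0.30, min_cells_per_gene = 4L,
                      mito_prefix = "MT-") {
  genes_per_cell <- Matrix::colSums(m > 0)
  tot <- Matrix::colSums(m)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(m[mito, , drop = FALSE]) / pmax(tot, 1) else rep(0, ncol(m))
  low <- genes_per_cell < min_genes
  high <- genes_per_cell > max_genes
  mito_bad <- mito_frac > max_mito_frac
  keep_cells <- !(low | high | mito_bad)
  m2 <- m[, keep_cells, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(m2 > 0)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  m2 <- m2[keep_genes, , drop = FALSE]
  if (ncol(m2) == 0L || nrow(m2) == 0L)
    stop("no cells or genes left after QC filtering")
  attr(m2, "qc_report") <- list(
    cells_in = ncol(m), cells_removed_low_genes = sum(low),
    cells_removed_high_genes = sum(high),
    cells_removed_mito = sum(mito_bad & !(low | high)),
    cells_out = ncol(m2),
    genes_in = nrow(m), genes_removed_min_cells = sum(!keep_genes),
    genes_out = nrow(m2))
  m2
}

#' Library-size normalize and log-transform
#'
#' Per cell, counts are scaled to `scale_factor` total and log1p
#' transformed; all-zero cells stay zero.
#'
#' @param m Genes x cells count matrix.
#' @param scale_factor Target per-cell total (default 10,000).
#' @return Normalized dgCMatrix.
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  m <- methods::as(m, "CsparseMatrix")
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  out <- m %*% Matrix::Diagonal(x = scale_factor / cs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  methods::as(out, "CsparseMatrix")
}

row_vars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

#' Cluster cells by PCA + k-means (or load labels)
#'
#' A self-contained stand-in for graph-based clustering: top-variance
#' genes, PCA, seeded k-means. Precomputed labels (e.g. graph clusters
#' from another toolkit) can be supplied instead and are passed through.
#'
#' @param m_norm Normalized matrix from [normalize_counts()].
#' @param n_hvg Number of highly variable genes (default 2000).
#' @param n_pcs Number of principal components (default 20).
#' @param k Number of k-means clusters (default 10).
#' @param seed RNG seed.
#' @param labels Optional precomputed labels: named vector (by barcode) or
#'   a TSV path with columns barcode, cluster.
#' @return Named integer/character vector of cluster labels per cell.
#' @export
cluster_cells <- function(m_norm, n_hvg = 2000L, n_pcs = 20L, k = 10L,
                          seed = 1L, labels = NULL) {
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      d <- utils::read.delim(labels, header = TRUE, stringsAsFactors = FALSE)
      labels <- stats::setNames(d[[2L]], d[[1L]])
    }
    missing <- setdiff(colnames(m_norm), names(labels))
    if (length(missing) > 0L)
      stop(length(missing), " cells missing from the labels file")
    return(labels[colnames(m_norm)])
  }
  n <- ncol(m_norm)
  if (k > n) stop("k (", k, ") exceeds number of cells (", n, ")")
  v <- row_vars_sparse(m_norm)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(m_norm)))]
  x <- t(as.matrix(m_norm[hvg, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  set.seed(seed)
  km <- stats::kmeans(pc$x, centers = k, nstart = 10L, iter.max = 100L)
  stats::setNames(km$cluster, colnames(m_norm))
}

#' Expression-matched control-subtracted module score
#'
#' Per cell: mean normalized expression of the gene set minus the mean of
#' control genes sampled (seeded, without replacement) from
#' expression-matched bins.
#'
#' @param m_norm Normalized matrix.
#' @param gene_set Character vector of gene ids (or path, one per line).
#' @param n_bins Expression bins over average expression (default 24).
#' @param n_ctrl Controls sampled per set gene (default 100).
#' @param seed RNG seed.
#' @return Named numeric score per cell; attribute `missing_genes` lists
#'   set genes absent from the matrix.
#' @export
module_score <- function(m_norm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  if (is.character(gene_set) && length(gene_set) == 1L &&
      file.exists(gene_set)) gene_set <- readLines(gene_set)
  present <- intersect(gene_set, rownames(m_norm))
  if (length(present) == 0L)
    stop("gene set has empty intersection with matrix genes")
  avg <- Matrix::rowMeans(m_norm)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (length(avg) / n_bins))
  names(bin) <- rownames(m_norm)
  set.seed(seed)
  ctrl <- unique(unlist(lapply(present, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    sample(pool, min(n_ctrl, length(pool)))
  })))
  score <- Matrix::colMeans(m_norm[present, , drop = FALSE]) -
    Matrix::colMeans(m_norm[ctrl, , drop = FALSE])
  out <- stats::setNames(as.numeric(score), colnames(m_norm))
  attr(out, "missing_genes") <- setdiff(gene_set, present)
  out
}

#' Per-variant cluster-proportion matrix
#'
#' @param cell_genotypes data.frame with columns cb, genotype_label (one
#'   row per genotyped cell).
#' @param labels Named cluster vector (by barcode).
#' @param min_cells Variants genotyped in fewer than `min_cells` cells are
#'   dropped (default 5: a variant with 4 cells is removed).
#' @return Matrix (variant x cluster) with rows summing to 1.
#' @export
cluster_proportions <- function(cell_genotypes, labels, min_cells = 5L) {
  d <- cell_genotypes[cell_genotypes$cb %in% names(labels), , drop = FALSE]
  if (nrow(d) == 0L) stop("no genotyped cells among labeled cells")
  cl <- labels[d$cb]
  tab <- table(d$genotype_label, factor(cl, levels = sort(unique(labels))))
  tab <- tab[rowSums(tab) >= min_cells, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no variant passes the min_cells filter")
  prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  attr(prop, "n_cells") <- rowSums(unclass(tab))
  prop
}

#' Classify variants as wild-type-like vs functionally significant
#'
#' Hierarchically clusters the variant cluster-proportion rows and cuts the
#' tree; variants sharing the wild-type row's group are wild-type-like.
#'
#' By default the tree is cut at a noise-calibrated height rather than into
#' a fixed number of groups: under the null (a variant's cells drawn from
#' the same multinomial as wild type) the expected squared Euclidean
#' distance between the variant row and the wild-type row is
#' sum_j p_j (1 - p_j) (1/n_v + 1/n_wt); the cut height is `h_mult` times
#' the largest such null distance. This lets an all-null variant panel stay
#' in one group (no forced split) while any profile beyond sampling noise
#' separates. A fixed `k_cut` (e.g. 2) can be requested instead; it forces
#' `k_cut` non-empty groups even on homogeneous panels. Single linkage is
#' the default so the wild-type group is delimited by its largest gap to
#' the nearest shifted variant, not by the diameter of the shifted
#' continuum.
#'
#' @param prop Variant x cluster proportion matrix (rownames include
#'   `wt_row`), as from [cluster_proportions()].
#' @param wt_row Rowname of the wild-type profile (default "WT").
#' @param k_cut Number of groups to cut into; NULL (default) uses the
#'   noise-calibrated height cut.
#' @param linkage Agglomeration method (default "average").
#' @param metric Row distance: "hellinger" (default; Euclidean distance of
#'   square-root proportions, which variance-stabilizes multinomial noise
#'   to (1 - p)/4n per cluster and so sharpens differences in
#'   low-proportion clusters) or any [stats::dist()] method. Under
#'   Hellinger the null-expected squared distance has the closed,
#'   profile-free form (K - 1)/4 (1/n_v + 1/n_wt) for K clusters.
#' @param h_mult Multiplier on the null-expected wild-type distance for
#'   the height cut (default 2).
#' @param n_cells Named per-variant cell counts (defaults to the
#'   `n_cells` attribute of `prop`); required for the height cut.
#' @return List with `classes` (named "wild-type-like" /
#'   "functionally-significant"), `groups` (cutree output), `tree` and
#'   `cut_height` (NA when `k_cut` used).
#' @export
classify_variants <- function(prop, wt_row = "WT", k_cut = NULL,
                              linkage = "average", metric = "hellinger",
                              h_mult = 2, n_cells = attr(prop, "n_cells")) {
  if (!wt_row %in% rownames(prop))
    stop("wild-type row '", wt_row, "' missing from proportion matrix")
  if (nrow(prop) == 1L) {
    classes <- stats::setNames("wild-type-like", wt_row)
    return(list(classes = classes,
                groups = stats::setNames(1L, wt_row), tree = NULL,
                cut_height = NA_real_))
  }
  x <- if (metric == "hellinger") sqrt(prop) else prop
  dmethod <- if (metric == "hellinger") "euclidean" else metric
  tree <- stats::hclust(stats::dist(x, method = dmethod), method = linkage)
  cut_height <- NA_real_
  if (!is.null(k_cut)) {
    groups <- stats::cutree(tree, k = min(k_cut, nrow(prop)))
  } else {
    if (is.null(n_cells)) {
      # no counts available: fall back to a fixed two-way cut
      groups <- stats::cutree(tree, k = min(2L, nrow(prop)))
    } else {
      p <- prop[wt_row, ]
      others <- setdiff(rownames(prop), wt_row)
      d0 <- vapply(others, function(v) {
        inv_n <- 1 / n_cells[[v]] + 1 / n_cells[[wt_row]]
        if (metric == "hellinger")
          sqrt((ncol(prop) - 1L) / 4 * inv_n)
        else sqrt(sum(p * (1 - p)) * inv_n)
      }, numeric(1L))
      cut_height <- h_mult * max(d0)
      groups <- stats::cutree(tree, h = cut_height)
    }
  }
  classes <- ifelse(groups == groups[[wt_row]],
                    "wild-type-like", "functionally-significant")
  list(classes = stats::setNames(classes, rownames(prop)),
       groups = groups, tree = tree, cut_height = cut_height)
}

#' Welch two-sample t-test of module scores
#'
#' @param scores_variant,scores_wt Numeric score vectors.
#' @return List with `t` and two-sided `p` (unequal-variance Welch test;
#'   no multiplicity correction).
#' @export
score_test <- function(scores_variant, scores_wt) {
  tt <- stats::t.test(scores_variant, scores_wt, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Wilcoxon rank-sum differential expression
#'
#' @param m_norm Normalized matrix.
#' @param cells_a,cells_b Barcode vectors of the two groups.
#' @param min_frac Test genes detected in at least this fraction of either
#'   group (default 0.1).
#' @return data.frame (gene, statistic, p, q, lfc) sorted by p then
#'   decreasing |lfc|; q is Benjamini-Hochberg across tested genes; lfc is
#'   log2 fold change of de-logged group means (a over b).
#' @export
dge_rank_sum <- function(m_norm, cells_a, cells_b, min_frac = 0.1) {
  a <- m_norm[, cells_a, drop = FALSE]
  b <- m_norm[, cells_b, drop = FALSE]
  det_a <- Matrix::rowMeans(a > 0); det_b <- Matrix::rowMeans(b > 0)
  genes <- rownames(m_norm)[det_a >= min_frac | det_b >= min_frac]
  if (length(genes) == 0L) stop("no gene passes the detection filter")
  am <- as.matrix(a[genes, , drop = FALSE])
  bm <- as.matrix(b[genes, , drop = FALSE])
  res <- vapply(seq_along(genes), function(i) {
    wt <- stats::wilcox.test(am[i, ], bm[i, ], exact = FALSE, correct = TRUE)
    c(wt$statistic, wt$p.value)
  }, numeric(2L))
  lfc <- log2((rowMeans(expm1(am)) + 1) / (rowMeans(expm1(bm)) + 1))
  out <- data.frame(gene = genes, statistic = res[1L, ], p = res[2L, ],
                    q = stats::p.adjust(res[2L, ], method = "BH"),
                    lfc = as.numeric(lfc))
  out <- out[order(out$p, -abs(out$lfc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

strip_suffix <- function(bc) sub("-[0-9]+$", "", bc)

#' Integrate per-cell genotypes with expression
#'
#' Inner-joins genotypes and expression on (suffix-normalized) cell
#' barcode, then runs QC -> normalize -> cluster (or load labels) ->
#' module score -> cluster proportions -> hierarchical classification ->
#' per-variant Welch tests against wild-type cells.
#'
#' @param cell_genotypes data.frame with columns cb, genotype_label (and
#'   optionally zygosity: only homozygous rows are used).
#' @param counts Genes x cells raw count matrix (or MTX triplet dir).
#' @param gene_set Pathway gene ids (vector or file).
#' @param labels Optional precomputed cluster labels ([cluster_cells()]).
#' @param min_cells Variant cell-count filter (default 5).
#' @param wt_label Wild-type genotype label (default "WT").
#' @param k,n_hvg,n_pcs,n_bins,n_ctrl,seed Clustering/score parameters.
#' @param qc List of [qc_filter()] overrides.
#' @param k_cut,linkage,metric,h_mult Passed to [classify_variants()].
#' @return List with `phenotypes` (per-variant table), `proportions`,
#'   `cells` (per-cell barcode/genotype/cluster/score), `classes` and
#'   `report`.
#' @export
integrate_genotypes <- function(cell_genotypes, counts, gene_set,
                                labels = NULL, min_cells = 5L,
                                wt_label = "WT", k = 10L, n_hvg = 2000L,
                                n_pcs = 20L, n_bins = 24L, n_ctrl = 100L,
                                seed = 1L, qc = list(), k_cut = NULL,
                                linkage = "average", metric = "hellinger",
                                h_mult = 2) {
  if (is.character(counts) && length(counts) == 1L) counts <- read_mtx(counts)
  gt <- cell_genotypes
  if ("zygosity" %in% colnames(gt))
    gt <- gt[gt$zygosity == "homozygous", , drop = FALSE]
  gt <- gt[!is.na(gt$genotype_label), , drop = FALSE]
  gt$cb <- strip_suffix(gt$cb)
  colnames(counts) <- strip_suffix(colnames(counts))

  shared <- intersect(gt$cb, colnames(counts))
  n_gt_only <- length(setdiff(gt$cb, colnames(counts)))
  n_expr_only <- ncol(counts) - length(shared)
  if (length(shared) == 0L)
    stop("no barcode overlap between genotypes and expression matrix")
  gt <- gt[gt$cb %in% shared, , drop = FALSE]
  gt <- gt[!duplicated(gt$cb), , drop = FALSE]
  m <- counts[, gt$cb, drop = FALSE]

  m <- do.call(qc_filter, c(list(m), qc))
  qc_report <- attr(m, "qc_report")
  gt <- gt[gt$cb %in% colnames(m), , drop = FALSE]
  m_norm <- normalize_counts(m)
  cl <- cluster_cells(m_norm, n_hvg = n_hvg, n_pcs = n_pcs, k = k,
                      seed = seed, labels = labels)
  score <- module_score(m_norm, gene_set, n_bins = n_bins, n_ctrl = n_ctrl,
                        seed = seed)
  prop <- cluster_proportions(gt, cl, min_cells = min_cells)
  cls <- classify_variants(prop, wt_row = wt_label, k_cut = k_cut,
                           linkage = linkage, metric = metric,
                           h_mult = h_mult)

  cells <- data.frame(cb = gt$cb, genotype_label = gt$genotype_label,
                      cluster = as.character(cl[gt$cb]),
                      score = as.numeric(score[gt$cb]))
  cells <- cells[order(cells$cb), , drop = FALSE]
  rownames(cells) <- NULL

  wt_scores <- cells$score[cells$genotype_label == wt_label]
  variants <- rownames(prop)
  n_cells <- attr(prop, "n_cells")
  phen <- do.call(rbind, lapply(variants, function(v) {
    sv <- cells$score[cells$genotype_label == v]
    tt <- if (v == wt_label || length(sv) < 2L || length(wt_scores) < 2L)
      list(t = NA_real_, p = NA_real_) else score_test(sv, wt_scores)
    data.frame(genotype_label = v, n_cells = n_cells[[v]],
               mean_score = mean(sv), sd_score = stats::sd(sv),
               t = tt$t, p = tt$p, class = unname(cls$classes[v]))
  }))
  rownames(phen) <- NULL

  list(phenotypes = phen, proportions = prop, cells = cells,
       classes = cls$classes, tree = cls$tree,
       report = list(n_genotyped = length(shared),
                     genotype_only_barcodes = n_gt_only,
                     expression_only_barcodes = n_expr_only,
                     qc = qc_report))
}
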