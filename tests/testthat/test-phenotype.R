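# QC, normalization, clustering, module scores, proportions,
# classification, tests and DGE.

toy_counts <- function(n_genes = 60, n_cells = 30, seed = 9, mito = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(c(sprintf("G%03d", seq_len(n_genes - mito)),
                                sprintf("MT-%d", seq_len(mito))),
                              sprintf("cell%03d", seq_len(n_cells))))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("qc_filter applies the cell and gene rules at their exact thresholds", {
  m <- toy_counts(n_genes = 150, n_cells = 20)
  # cell 1: exactly 99 detected genes -> removed; cell 2: 100 -> kept
  m[, 1] <- 0; m[1:99, 1] <- 1
  m[, 2] <- 0; m[1:100, 2] <- 1
  # gene present in exactly 3 cells -> removed; in 4 -> kept
  m[101, ] <- 0; m[101, 3:5] <- 1
  m[102, ] <- 0; m[102, 3:6] <- 1
  f <- qc_filter(m, min_genes = 100, max_genes = 8000,
                 max_mito_frac = 0.30, min_cells_per_gene = 4)
  expect_false("cell001" %in% colnames(f))
  expect_true("cell002" %in% colnames(f))
  expect_false(rownames(m)[101] %in% rownames(f))
  expect_true(rownames(m)[102] %in% rownames(f))
  rep <- attr(f, "qc_report")
  expect_equal(rep$cells_removed_low_genes, 1L)
  # high-mito cell removed
  m2 <- toy_counts()
  m2["MT-1", 1] <- 1e4
  f2 <- qc_filter(m2, min_genes = 1)
  expect_false("cell001" %in% colnames(f2))
  # all-pass matrix unchanged
  m3 <- toy_counts()
  f3 <- qc_filter(m3, min_genes = 1)
  expect_equal(dim(f3), dim(m3))
  expect_error(qc_filter(m3, min_genes = 1e6), "no cells")
})

test_that("normalize_counts is scale-invariant and matches the closed form", {
  m <- toy_counts(n_genes = 4, n_cells = 2, mito = 0)
  mn <- normalize_counts(m)
  # closed form log1p(1e4 * c / sum(c))
  c1 <- as.numeric(m[, 1])
  expect_equal(as.numeric(mn[, 1]), log1p(1e4 * c1 / sum(c1)))
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 2] <- 2 * m[, 2]
  expect_equal(as.numeric(normalize_counts(m2)[, 2]),
               as.numeric(mn[, 2]))
  # all-zero cell stays zero
  m3 <- m; m3[, 1] <- 0
  expect_equal(as.numeric(normalize_counts(m3)[, 1]), rep(0, 4))
})

test_that("cluster_cells separates planted blobs, is deterministic, honors k and labels", {
  set.seed(14)
  n <- 80
  base <- matrix(rpois(200 * n, 3), 200, n,
                 dimnames = list(sprintf("G%03d", 1:200), sprintf("c%03d", 1:n)))
  base[1:50, 1:40] <- base[1:50, 1:40] + 30L   # blob 1 upshifted
  m <- normalize_counts(methods::as(Matrix::Matrix(base, sparse = TRUE),
                                    "CsparseMatrix"))
  cl <- cluster_cells(m, k = 2, seed = 4)
  truth <- rep(1:2, each = 40)
  expect_equal(adjusted_rand(cl, truth), 1.0)
  expect_equal(unname(cluster_cells(m, k = 1, seed = 4)), rep(1L, n))
  expect_equal(cluster_cells(m, k = 2, seed = 4),
               cluster_cells(m, k = 2, seed = 4))
  expect_error(cluster_cells(m, k = n + 1, seed = 1), "exceeds")
  # precomputed labels pass through (file and vector)
  lb <- stats::setNames(rep(c("a", "b"), each = 40), colnames(m))
  expect_equal(unname(cluster_cells(m, labels = lb)), unname(lb))
  lf <- tempfile(fileext = ".tsv")
  write.table(data.frame(barcode = names(lb), cluster = lb), lf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(cluster_cells(m, labels = lf)), unname(lb))
  expect_error(cluster_cells(m[, 1:10], labels = lb[1:5]), "missing")
})

test_that("module_score is centered under self-control, detects shifts, deterministic", {
  set.seed(15)
  n <- 500
  m <- matrix(rpois(400 * n, 4), 400, n,
              dimnames = list(sprintf("G%03d", 1:400), sprintf("c%03d", 1:n)))
  gset <- sprintf("G%03d", 1:40)
  mm <- normalize_counts(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                     "CsparseMatrix"))
  s0 <- module_score(mm, gset, seed = 6)
  expect_lt(abs(mean(s0)), 3 * sd(s0) / sqrt(n))
  # planted up-shift of the set in half the cells
  m2 <- m
  m2[1:40, 1:250] <- m2[1:40, 1:250] + 4L
  mm2 <- normalize_counts(methods::as(Matrix::Matrix(m2, sparse = TRUE),
                                      "CsparseMatrix"))
  s1 <- module_score(mm2, gset, seed = 6)
  expect_lt(wilcox.test(s1[1:250], s1[251:500],
                        alternative = "greater")$p.value, 1e-6)
  expect_equal(module_score(mm2, gset, seed = 6), s1)
  expect_error(module_score(mm, c("NOPE1", "NOPE2")), "empty intersection")
  # absent set members are reported
  s2 <- module_score(mm, c(gset, "NOPE1"), seed = 6)
  expect_equal(attr(s2, "missing_genes"), "NOPE1")
})

test_that("cluster_proportions normalizes rows and applies the 5-cell filter", {
  gt <- data.frame(cb = sprintf("c%02d", 1:14),
                   genotype_label = c(rep("WT", 6), rep("V1", 4), rep("V2", 4)))
  lab <- stats::setNames(sample(1:3, 14, replace = TRUE), gt$cb)
  pr <- cluster_proportions(gt, lab, min_cells = 5)
  expect_false("V1" %in% rownames(pr))           # 4 cells < 5: dropped
  expect_false("V2" %in% rownames(pr))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
  pr2 <- cluster_proportions(gt, lab, min_cells = 4)
  expect_true(all(c("WT", "V1", "V2") %in% rownames(pr2)))
  expect_equal(unname(rowSums(pr2)), rep(1, 3), tolerance = 1e-9)
  # one-hot row for a variant confined to one cluster
  lab2 <- stats::setNames(c(rep(1, 6), rep(2, 4), rep(1, 4)), gt$cb)
  pr3 <- cluster_proportions(gt, lab2, min_cells = 4)
  expect_equal(unname(pr3["V1", ]), c(0, 1))
})

test_that("classify_variants: trivial cases, fixed-k oracle and height cut", {
  # identical row to WT is always wild-type-like
  prop <- rbind(WT = c(0.5, 0.5, 0), same = c(0.5, 0.5, 0),
                far = c(0, 0, 1))
  cl <- classify_variants(prop, k_cut = 2)
  expect_equal(unname(cl$classes[c("same", "far")]),
               c("wild-type-like", "functionally-significant"))
  # two maximally separated one-hot groups
  prop2 <- rbind(WT = c(1, 0), a = c(1, 0), b = c(0, 1), c = c(0, 1))
  cl2 <- classify_variants(prop2, k_cut = 2, linkage = "complete")
  expect_equal(unname(cl2$classes), c("wild-type-like", "wild-type-like",
                                      "functionally-significant",
                                      "functionally-significant"))
  expect_error(classify_variants(prop2[2:4, ]), "missing")
  # 10 synthetic variants, 3 WT-like: fixed k=2 matches the brute-force
  # agglomerative oracle partition
  set.seed(8)
  base <- c(0.3, 0.3, 0.2, 0.1, 0.1)
  shifted <- c(0.02, 0.05, 0.13, 0.4, 0.4)
  rows <- rbind(WT = base,
                t(sapply(1:3, function(i) base + rnorm(5, 0, 0.01))),
                t(sapply(1:6, function(i) shifted + rnorm(5, 0, 0.01))))
  rows <- pmax(rows, 0); rows <- rows / rowSums(rows)
  rownames(rows) <- c("WT", paste0("null", 1:3), paste0("sig", 1:6))
  cl3 <- classify_variants(rows, k_cut = 2, linkage = "complete")
  orc <- oracle_hclust_cut(rows, 2)
  expect_equal(unname(cl3$classes == "wild-type-like"),
               orc == orc[1])
  expect_equal(sum(cl3$classes == "wild-type-like"), 4L)
  # height cut with per-variant counts: no forced split on a null panel
  nullrows <- rbind(WT = base, t(sapply(1:4, function(i) {
    p <- as.numeric(rmultinom(1, 150, base)); p / sum(p)
  })))
  rownames(nullrows) <- c("WT", paste0("v", 1:4))
  attr(nullrows, "n_cells") <- stats::setNames(c(400, rep(150, 4)),
                                               rownames(nullrows))
  cl4 <- classify_variants(nullrows)
  expect_true(all(cl4$classes == "wild-type-like"))
})

test_that("score_test matches the Welch closed form with antisymmetry", {
  a <- c(1.1, 2.3, 0.7, 1.9, 2.2, 1.4)
  b <- c(2.8, 3.1, 2.2, 3.9, 2.5)
  st <- score_test(a, b)
  # textbook Welch formula
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  tt <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                  (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(st$t, tt, tolerance = 1e-10)
  expect_equal(st$p, 2 * pt(-abs(tt), df), tolerance = 1e-10)
  sw <- score_test(b, a)
  expect_equal(sw$t, -st$t)
  expect_equal(sw$p, st$p)
  same <- c(1, 2, 3, 4)
  st0 <- score_test(same, same)
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
})

test_that("dge_rank_sum: null calibration, planted recovery, rank invariance", {
  set.seed(16)
  n <- 400
  m <- matrix(rnbinom(800 * 2 * n, mu = 3, size = 2), 800, 2 * n,
              dimnames = list(sprintf("G%03d", 1:800),
                              sprintf("c%04d", seq_len(2 * n))))
  planted <- sprintf("G%03d", 1:50)
  m[1:50, 1:n] <- rnbinom(50 * n, mu = 6, size = 2)   # 2x shift in group A
  mm <- normalize_counts(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                     "CsparseMatrix"))
  a <- colnames(m)[1:n]; b <- colnames(m)[(n + 1):(2 * n)]
  dge <- dge_rank_sum(mm, a, b)
  top100 <- dge$gene[1:100]
  expect_gte(mean(planted %in% top100), 0.9)
  # identical groups: BH-significant genes within false-positive expectation
  dge0 <- dge_rank_sum(mm, b[1:200], b[201:400])
  expect_lte(sum(dge0$q < 0.05), 5L)
  # monotone transform of normalized values leaves p unchanged
  mm2 <- mm; mm2@x <- mm2@x * 3 + 0.1 * sqrt(mm2@x)
  dge2 <- dge_rank_sum(mm2, a, b)
  expect_equal(dge2[order(dge2$gene), "p"], dge[order(dge$gene), "p"])
})

test_that("integrate_genotypes joins, classifies and reports; errors on no overlap", {
  cfg <- sim_config(seed = 55, n_cells = 700, n_variants = 4, wt_frac = 0.3,
                    effects = c(1, 0.4, 1, 0.5))
  loc <- simulate_locus(cfg)
  lr <- simulate_long_reads(cfg, loc, emit_reads = FALSE)
  ex <- simulate_expression(cfg, lr$cells, loc$variants)
  gt <- data.frame(cb = paste0(lr$cells$cb, "-1"),   # suffix normalization
                   genotype_label = lr$cells$label)
  res <- integrate_genotypes(gt, ex$counts, ex$gene_set, seed = 2)
  truth <- stats::setNames(ex$truth$class, ex$truth$label)
  expect_equal(unname(res$classes[names(truth)]), unname(truth))
  expect_equal(unname(rowSums(res$proportions)),
               rep(1, nrow(res$proportions)), tolerance = 1e-9)
  expect_true(all(res$phenotypes$n_cells >= 5))
  expect_equal(res$phenotypes$class[res$phenotypes$genotype_label == "WT"],
               "wild-type-like")
  # shifted variants are significant by the Welch test too
  sig <- res$phenotypes[res$phenotypes$class == "functionally-significant", ]
  expect_true(all(sig$p < 1e-6))
  # determinism: identical seed, identical tables
  res2 <- integrate_genotypes(gt, ex$counts, ex$gene_set, seed = 2)
  expect_identical(res$phenotypes, res2$phenotypes)
  expect_identical(res$cells, res2$cells)
  # zero overlap errors
  gt2 <- gt; gt2$cb <- paste0("X", seq_len(nrow(gt2)))
  expect_error(integrate_genotypes(gt2, ex$counts, ex$gene_set),
               "no barcode overlap")
  # WT-only input yields a single untested row
  gtw <- gt[lr$cells$label == "WT", ]
  resw <- integrate_genotypes(gtw, ex$counts, ex$gene_set, seed = 2)
  expect_equal(resw$phenotypes$genotype_label, "WT")
  expect_true(is.na(resw$phenotypes$t))
})
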