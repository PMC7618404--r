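make_three_contrasts <- function(gene_id, padj_wt, padj_dh, padj_dn,
                                 lfc_wt = NULL, lfc_dh = NULL,
                                 lfc_dn = NULL) {
  n <- length(gene_id)
  list(WT = make_contrast(gene_id, lfc_wt %||% rep(1, n), padj_wt),
       DH = make_contrast(gene_id, lfc_dh %||% rep(1, n), padj_dh),
       DN = make_contrast(gene_id, lfc_dn %||% rep(1, n), padj_dn))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("significance patterns partition genes into the 8 expected labels", {
  g <- sprintf("g%02d", 1:10)
  s <- 0.01; ns <- 0.5
  cts <- make_three_contrasts(
    g,
    padj_wt = c(ns, s, ns, ns, s, s, ns, s, ns, NA),
    padj_dh = c(ns, ns, s, ns, s, ns, s, s, ns, s),
    padj_dn = c(ns, ns, ns, s, ns, s, s, s, ns, ns))
  asg <- assign_patterns(cts, alpha = 0.05)
  expect_equal(asg$pattern,
               c("none", "WT_only", "DH_only", "DN_only", "WT_DH", "WT_DN",
                 "DH_DN", "WT_DH_DN", "none", "DH_only"))
  # partition property: labels cover all genes exactly once
  expect_equal(sum(table(asg$pattern)), length(g))

  # single-gene checks from hand thresholding
  one <- make_three_contrasts("gene", 0.20, 0.01, 0.90)
  expect_equal(assign_patterns(one)$pattern, "DH_only")
  all3 <- make_three_contrasts("gene", 0.01, 0.01, 0.01)
  expect_equal(assign_patterns(all3)$pattern, "WT_DH_DN")
})

test_that("NA statistics are treated as not-significant with sign 0", {
  ct <- make_three_contrasts("g1", NA, 0.01, 0.2,
                             lfc_wt = NA_real_, lfc_dh = 2, lfc_dn = -1)
  asg <- assign_patterns(ct)
  expect_equal(asg$pattern, "DH_only")
  expect_equal(asg$sign_WT, 0L)
  expect_equal(asg$sign_DH, 1L)
})

test_that("mismatched gene universes are rejected with the difference size", {
  a <- make_contrast(c("g1", "g2"), c(1, 1), c(0.1, 0.1))
  b <- make_contrast(c("g1", "g3"), c(1, 1), c(0.1, 0.1))
  expect_error(assign_patterns(list(WT = a, DH = b, DN = a)),
               "symmetric difference 2")
})

test_that("concordance summary matches hand arithmetic", {
  g <- paste0("g", 1:4)
  cts <- make_three_contrasts(g, rep(0.5, 4), rep(0.01, 4), rep(0.5, 4),
                              lfc_wt = c(0.5, -0.3, 0.2, 0.1),
                              lfc_dh = c(1.0, -0.6, 0.4, -0.1),
                              lfc_dn = rep(0.1, 4))
  asg <- assign_patterns(cts)
  cs <- concordance_summary(asg, "DH_only")
  expect_equal(cs$frac_same_direction, 0.75)
  expect_equal(cs$amplitude_ratio, (0.525 / 0.275), tolerance = 1e-12)
  expect_equal(cs$n_genes, 4)

  # forced doubling: every DH fold change is twice the WT one
  cts2 <- make_three_contrasts(g, rep(0.5, 4), rep(0.01, 4), rep(0.5, 4),
                               lfc_wt = c(0.5, -0.3, 0.2, 0.1),
                               lfc_dh = 2 * c(0.5, -0.3, 0.2, 0.1))
  cs2 <- concordance_summary(assign_patterns(cts2), "DH_only")
  expect_equal(cs2$frac_same_direction, 1.0)
  expect_equal(cs2$amplitude_ratio, 2.0)

  expect_error(concordance_summary(asg, "WT_only"), "empty")
})

test_that("concordance is scale invariant and amplitude scales linearly", {
  g <- paste0("g", 1:6)
  lw <- c(0.4, -0.2, 0.3, 0.5, -0.6, 0.1)
  ld <- c(0.9, -0.5, 0.7, 0.8, -1.0, -0.2)
  base <- make_three_contrasts(g, rep(0.5, 6), rep(0.01, 6), rep(0.5, 6),
                               lfc_wt = lw, lfc_dh = ld)
  cs <- concordance_summary(assign_patterns(base), "DH_only")
  scaled <- make_three_contrasts(g, rep(0.5, 6), rep(0.01, 6), rep(0.5, 6),
                                 lfc_wt = 3 * lw, lfc_dh = 3 * ld)
  cs_s <- concordance_summary(assign_patterns(scaled), "DH_only")
  expect_equal(cs_s$frac_same_direction, cs$frac_same_direction)
  expect_equal(cs_s$amplitude_ratio, cs$amplitude_ratio, tolerance = 1e-12)

  dh_only_scaled <- make_three_contrasts(g, rep(0.5, 6), rep(0.01, 6),
                                         rep(0.5, 6),
                                         lfc_wt = lw, lfc_dh = 5 * ld)
  cs_d <- concordance_summary(assign_patterns(dh_only_scaled), "DH_only")
  expect_equal(cs_d$amplitude_ratio, 5 * cs$amplitude_ratio,
               tolerance = 1e-12)
})

test_that("LFC distribution summaries are exact on fixtures", {
  g <- paste0("g", 1:5)
  cts <- make_three_contrasts(g, rep(0.5, 5), rep(0.01, 5), rep(0.5, 5),
                              lfc_wt = c(-1, -1, 0, 1, 1),
                              lfc_dh = c(1, 2, 3, 4, 5))
  asg <- assign_patterns(cts)
  d <- lfc_distributions(asg, "DH_only", conditions = c("WT", "DH"))
  expect_equal(d$summary$median[d$summary$condition == "WT"], 0)
  expect_equal(d$summary$median[d$summary$condition == "DH"], 3)
  expect_equal(d$summary$q1[d$summary$condition == "DH"],
               unname(quantile(1:5, 0.25)))
  expect_equal(d$summary$q3[d$summary$condition == "DH"],
               unname(quantile(1:5, 0.75)))
  expect_true(all(diff(d$breaks) > 0))
  expect_error(lfc_distributions(asg, "WT_only"), "empty")
})

test_that("heatmap z-matrix is standardized and clusters by similarity", {
  set.seed(9)
  x <- matrix(rnorm(60, 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  x[2, ] <- x[1, ]          # identical pair
  hm <- cluster_heatmap_matrix(x)
  expect_true(all(abs(rowMeans(hm$z)) < 1e-9))
  expect_true(all(abs(apply(hm$z, 1, sd) - 1) < 1e-9))
  # identical genes have zero correlation distance: first merge, adjacent
  expect_equal(sort(hm$row_hclust$merge[1, ]), c(-2, -1))
  pos <- match(c(1, 2), hm$row_order)
  expect_equal(abs(diff(pos)), 1)

  # zero-variance gene dropped with a warning
  x2 <- x; x2[3, ] <- 7
  expect_warning(hm2 <- cluster_heatmap_matrix(x2), "zero-variance")
  expect_equal(nrow(hm2$z), 5)
  expect_equal(hm2$n_dropped, 1)
})

test_that("three-gene dendrogram matches brute-force agglomeration", {
  # construct three genes with known pairwise correlation structure
  s <- seq(-1, 1, length.out = 8)
  g1 <- s
  g2 <- s + c(0.05, -0.05)            # nearly identical to g1
  g3 <- rev(s)                        # anti-correlated with both
  x <- rbind(g1 = g1, g2 = g2, g3 = g3)
  hm <- cluster_heatmap_matrix(x)
  z <- t(scale(t(x)))
  d <- 1 - cor(t(z))
  # brute force: smallest off-diagonal distance merges first
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dist_vals <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  first <- pairs[[which.min(dist_vals)]]
  expect_equal(sort(hm$row_hclust$merge[1, ]), sort(-first))
  expect_equal(hm$row_hclust$height[1], min(dist_vals), tolerance = 1e-12)
  # average linkage height of the final merge
  rest <- setdiff(1:3, first)
  expect_equal(hm$row_hclust$height[2],
               mean(c(d[first[1], rest], d[first[2], rest])),
               tolerance = 1e-12)
})

test_that("sample PCA satisfies its contracts and matches eigendecomposition", {
  set.seed(13)
  x <- matrix(rnorm(200, 8), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  # dominant axis: samples 3-4 strongly shifted on half the genes
  x[1:25, 3:4] <- x[1:25, 3:4] + 10
  p <- sample_pca(x, n_top_variable = 50)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_true(all(p$variance_explained >= 0 & p$variance_explained <= 1))
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  expect_gte(p$variance_explained[1], 0.9)

  # oracle: eigenvalues of the sample covariance of centered data
  xc <- scale(t(x), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc))$values
  expect_equal(p$variance_explained[1:3], (ev / sum(ev))[1:3],
               tolerance = 1e-9)

  # duplicated sample gets identical scores
  x2 <- cbind(x, s5 = x[, 4])
  p2 <- sample_pca(x2, n_top_variable = 50)
  expect_equal(p2$scores[4, ], p2$scores[5, ], ignore_attr = TRUE)

  expect_error(sample_pca(x[, 1:2]), "3 samples")
  expect_error(sample_pca(x, n_top_variable = 1), "n_top_variable")
})
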