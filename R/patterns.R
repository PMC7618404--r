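PATTERN_CONDS <- c("WT", "DH", "DN")

#' Assign genes to cross-condition significance patterns
#'
#' Each gene is placed in exactly one of the 2^3 = 8 patterns defined by
#' whether it is significantly differentially expressed (`padj < alpha`)
#' against parental in the WT, D463H and D463N conditions. Genes with `NA`
#' adjusted p in a contrast count as not significant there, with direction
#' sign 0.
#'
#' @param contrasts Named list of three `contrast_table`s (names `WT`, `DH`,
#'   `DN`) over an identical gene universe.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A `data.frame` of class `"pattern_assignment"`: `gene_id`,
#'   `sig_WT`, `sig_DH`, `sig_DN`, `pattern` (one of `none`, `WT_only`,
#'   `DH_only`, `DN_only`, `WT_DH`, `WT_DN`, `DH_DN`, `WT_DH_DN`) and
#'   per-contrast `sign_*` in `{-1, 0, 1}`.
#' @export
assign_patterns <- function(contrasts, alpha = 0.05) {
  stopifnot(all(PATTERN_CONDS %in% names(contrasts)))
  ids <- contrasts$WT$gene_id
  for (cc in PATTERN_CONDS) {
    d <- length(union(ids, contrasts[[cc]]$gene_id)) -
      length(intersect(ids, contrasts[[cc]]$gene_id))
    if (d > 0)
      stopf("contrast gene universes differ (symmetric difference %d for %s)",
            d, cc)
  }
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (cc in PATTERN_CONDS) {
    ct <- contrasts[[cc]]
    ct <- ct[match(ids, ct$gene_id), ]
    out[[paste0("sig_", cc)]] <- !is.na(ct$padj) & ct$padj < alpha
    s <- sign(ct$log2fc)
    s[is.na(s)] <- 0
    out[[paste0("sign_", cc)]] <- as.integer(s)
    out[[paste0("lfc_", cc)]] <- ct$log2fc
  }
  part <- cbind(out$sig_WT, out$sig_DH, out$sig_DN)
  lab <- apply(part, 1, function(f) {
    on <- PATTERN_CONDS[f]
    if (length(on) == 0) "none" else if (length(on) == 1)
      paste0(on, "_only") else paste(on, collapse = "_")
  })
  out$pattern <- lab
  out <- out[, c("gene_id", "sig_WT", "sig_DH", "sig_DN", "pattern",
                 "sign_WT", "sign_DH", "sign_DN",
                 "lfc_WT", "lfc_DH", "lfc_DN")]
  class(out) <- c("pattern_assignment", "data.frame")
  out
}

#' Direction concordance and amplitude ratio for a pattern cluster
#'
#' The two headline statistics of the augmented-wild-type signature,
#' computed over the genes of one significance-pattern cluster for a pair
#' of conditions (default D463H vs WT, both relative to parental):
#' `frac_same_direction`, the fraction of genes whose fold changes point
#' the same way (computed over genes with both signs nonzero), and
#' `amplitude_ratio`, the ratio of mean absolute log2 fold changes
#' `mean(|lfc_a|) / mean(|lfc_b|)` over all cluster genes with defined
#' fold changes. Direction uses the sign of the fold change regardless of
#' its significance.
#'
#' @param assign A `pattern_assignment` from [assign_patterns()].
#' @param cluster_label Pattern label of the cluster to summarize.
#' @param cond_pair Length-2 character vector `(a, b)`; amplitude is
#'   `mean|lfc_a| / mean|lfc_b|`.
#' @return A list of class `"concordance_summary"`: `cluster`, `n_genes`,
#'   `n_na_excluded`, `n_direction_used`, `frac_same_direction`,
#'   `mean_abs_lfc` (named per condition), `amplitude_ratio` and
#'   `amplitude_defined`.
#' @export
concordance_summary <- function(assign, cluster_label,
                                cond_pair = c("DH", "WT")) {
  stopifnot(inherits(assign, "pattern_assignment"), length(cond_pair) == 2)
  cl <- assign[assign$pattern == cluster_label, , drop = FALSE]
  if (nrow(cl) == 0) stopf("cluster '%s' is empty", cluster_label)
  a <- cl[[paste0("lfc_", cond_pair[1])]]
  b <- cl[[paste0("lfc_", cond_pair[2])]]
  ok <- !is.na(a) & !is.na(b)
  n_na <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  both_nonzero <- sign(a) != 0 & sign(b) != 0
  frac <- if (any(both_nonzero))
    mean(sign(a[both_nonzero]) == sign(b[both_nonzero])) else NA_real_
  mean_abs <- c(mean(abs(a)), mean(abs(b)))
  names(mean_abs) <- cond_pair
  defined <- length(a) > 0 && mean_abs[2] > 0
  ratio <- if (defined) mean_abs[[1]] / mean_abs[[2]] else NA_real_
  structure(list(cluster = cluster_label,
                 n_genes = nrow(cl),
                 n_na_excluded = n_na,
                 n_direction_used = sum(both_nonzero),
                 frac_same_direction = frac,
                 mean_abs_lfc = mean_abs,
                 amplitude_ratio = ratio,
                 amplitude_defined = defined),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Cluster '%s': %d genes (%d NA-excluded)\n",
              x$cluster, x$n_genes, x$n_na_excluded))
  cat(sprintf("  same-direction fraction: %.3f (over %d genes)\n",
              x$frac_same_direction, x$n_direction_used))
  cat(sprintf("  mean |LFC| %s = %.3f, %s = %.3f; amplitude ratio = %.3f\n",
              names(x$mean_abs_lfc)[1], x$mean_abs_lfc[1],
              names(x$mean_abs_lfc)[2], x$mean_abs_lfc[2],
              x$amplitude_ratio))
  invisible(x)
}

#' Per-condition log2-fold-change distributions for a cluster
#'
#' @param assign A `pattern_assignment`.
#' @param cluster_label Cluster to summarize.
#' @param conditions Conditions to include.
#' @param n_bins Number of shared histogram bins.
#' @return A list with `summary` (per condition: n, median, q1, q3),
#'   `breaks` (shared, strictly increasing) and `counts` (condition x bin).
#' @export
lfc_distributions <- function(assign, cluster_label,
                              conditions = PATTERN_CONDS, n_bins = 30) {
  stopifnot(inherits(assign, "pattern_assignment"))
  cl <- assign[assign$pattern == cluster_label, , drop = FALSE]
  if (nrow(cl) == 0) stopf("cluster '%s' is empty", cluster_label)
  vals <- lapply(conditions, function(cc) {
    v <- cl[[paste0("lfc_", cc)]]
    v[!is.na(v)]
  })
  names(vals) <- conditions
  rng <- range(unlist(vals))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- t(vapply(vals, function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE)$counts,
    numeric(n_bins)))
  qs <- t(vapply(vals, function(v)
    c(n = length(v), median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75))), numeric(4)))
  list(summary = data.frame(condition = conditions, qs,
                            stringsAsFactors = FALSE, row.names = NULL),
       breaks = breaks, counts = counts)
}

#' Z-scored expression matrix with hierarchical row/column orders
#'
#' Rows (genes) are standardized to mean 0, sd 1 across samples; genes with
#' zero variance are dropped with a warning. Rows are clustered by average
#' linkage on `1 - Pearson correlation`, columns by average linkage on
#' Euclidean distance of the z-matrix.
#'
#' @param expr Gene x sample (batch-corrected) log-expression matrix.
#' @param genes Optional subset of row names to use.
#' @return A list with `z` (matrix), `row_order`, `col_order` (integer
#'   permutations), `row_hclust`, `col_hclust` and `n_dropped`.
#' @export
cluster_heatmap_matrix <- function(expr, genes = NULL) {
  x <- as.matrix(expr)
  if (!is.null(genes)) x <- x[rownames(x) %in% genes, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need >= 2 genes and >= 2 samples")
  sds <- apply(x, 1, stats::sd)
  n_dropped <- sum(sds == 0)
  if (n_dropped > 0) {
    warning(sprintf("%d zero-variance gene(s) dropped", n_dropped))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stopf("fewer than 2 genes with variance")
  }
  z <- t(scale(t(x)))
  rd <- stats::as.dist(1 - stats::cor(t(z)))
  rh <- stats::hclust(rd, method = "average")
  ch <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z = z, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch, n_dropped = n_dropped)
}

#' Sample PCA on the most variable genes
#'
#' Gene-centered principal component analysis of the samples over the
#' `n_top_variable` genes with the largest variance.
#'
#' @param expr Gene x sample (batch-corrected) log-expression matrix.
#' @param n_top_variable Number of top-variance genes (>= 2).
#' @return A list with `scores` (sample x PC), `loadings` (gene x PC) and
#'   `variance_explained` (non-increasing, sums to <= 1).
#' @export
sample_pca <- function(expr, n_top_variable = 500) {
  x <- as.matrix(expr)
  if (ncol(x) < 3) stopf("need >= 3 samples for a sample PCA")
  if (n_top_variable < 2) stopf("n_top_variable must be >= 2")
  v <- apply(x, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_variable, nrow(x)))]
  x <- x[keep, , drop = FALSE]
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_explained = ve)
}
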