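BAITS <- c("control", "WT", "DH", "DN")

#' Per-protein detection counts by bait
#'
#' A protein is detected in a sample when its log2 intensity is non-missing.
#'
#' @param intensity Protein x sample matrix with `NA` for missing values.
#' @param samples Data frame with `sample_id` and `bait` (levels among
#'   `control`, `WT`, `DH`, `DN`).
#' @return Integer matrix protein x bait of detection counts.
#' @export
call_detection <- function(intensity, samples) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) == 0) stopf("intensity table is empty")
  stopifnot(ncol(intensity) == nrow(samples))
  bad <- setdiff(unique(samples$bait), BAITS)
  if (length(bad) > 0)
    stopf("unknown bait label(s): %s", paste(bad, collapse = ", "))
  baits <- intersect(BAITS, unique(samples$bait))
  det <- vapply(baits, function(b)
    rowSums(!is.na(intensity[, samples$bait == b, drop = FALSE])),
    numeric(nrow(intensity)))
  det <- matrix(as.integer(det), nrow(intensity),
                dimnames = list(rownames(intensity), baits))
  det
}

#' Remove proteins recovered in control pull-downs
#'
#' Any protein detected in at least one control (empty-vector) sample is an
#' affinity artefact and is removed from all downstream analysis.
#'
#' @param intensity Protein x sample matrix.
#' @param samples Sample metadata (needs `bait`).
#' @param detection Optional precomputed [call_detection()] matrix.
#' @return A list with `intensity` (reduced matrix) and `removed`
#'   (character vector of artefact protein ids).
#' @export
filter_artefacts <- function(intensity, samples, detection = NULL) {
  if (!any(samples$bait == "control"))
    stopf("no control samples present; cannot call artefacts")
  if (is.null(detection)) detection <- call_detection(intensity, samples)
  artefact <- detection[, "control"] > 0
  list(intensity = as.matrix(intensity)[!artefact, , drop = FALSE],
       removed = rownames(detection)[artefact])
}

#' Remove proteins recovered in only a single sample
#'
#' Proteins whose total detection count across all non-control samples is
#' exactly one are too sparsely observed to interpret and are removed.
#'
#' @inheritParams filter_artefacts
#' @return A list with `intensity` and `removed`.
#' @export
filter_single_sample <- function(intensity, samples, detection = NULL) {
  if (is.null(detection)) detection <- call_detection(intensity, samples)
  noncontrol <- setdiff(colnames(detection), "control")
  tot <- rowSums(detection[, noncontrol, drop = FALSE])
  single <- tot == 1
  list(intensity = as.matrix(intensity)[!single, , drop = FALSE],
       removed = rownames(detection)[single])
}

#' Deterministic minimum-based imputation of missing intensities
#'
#' Every missing value is replaced by the global minimum observed log2
#' intensity minus 1.0, so imputed values sit strictly below all observed
#' ones and repeated runs give identical tables. Observed cells are
#' untouched; the returned mask records what was imputed.
#'
#' @param intensity Protein x sample matrix with `NA` for missing.
#' @return A list with `intensity` (completed matrix) and `mask` (logical
#'   matrix, `TRUE` where imputed).
#' @export
impute_missing <- function(intensity) {
  x <- as.matrix(intensity)
  if (all(is.na(x))) stopf("no observed intensities to anchor imputation")
  fill <- min(x, na.rm = TRUE) - 1.0
  mask <- is.na(x)
  x[mask] <- fill
  list(intensity = x, mask = mask)
}

#' Flag proteins recovered exclusively with the D463H bait
#'
#' A protein is an exclusive D463H binder when it is detected in at least
#' `min_dh_detect` D463H replicates and in zero WT samples. D463N detection
#' does not veto exclusivity by default.
#'
#' @param detection Detection-count matrix from [call_detection()]
#'   (computed after filtering).
#' @param n_dh_reps Number of D463H replicates (to validate the gate).
#' @param min_dh_detect Minimum D463H detections (the "high-confidence"
#'   gate; default 2).
#' @param ignore_dn If `FALSE`, D463N detections also veto exclusivity.
#' @return Logical vector, one flag per protein.
#' @export
call_exclusive <- function(detection, n_dh_reps, min_dh_detect = 2,
                           ignore_dn = TRUE) {
  if (min_dh_detect > n_dh_reps)
    stopf("min_dh_detect (%d) exceeds D463H replicate count (%d)",
          min_dh_detect, n_dh_reps)
  flag <- detection[, "DH"] >= min_dh_detect & detection[, "WT"] == 0
  if (!ignore_dn && "DN" %in% colnames(detection))
    flag <- flag & detection[, "DN"] == 0
  stats::setNames(flag, rownames(detection))
}

#' Flag preferential D463H binders
#'
#' The STRING-query hit rule: a protein is a preferential D463H binder when
#' its post-imputation log2 fold change (mean D463H minus mean WT) is
#' strictly greater than `threshold`, or when it is an exclusive D463H
#' binder (exclusivity always implies preference).
#'
#' @param imputed Completed intensity matrix from [impute_missing()].
#' @param samples Sample metadata (needs `bait`).
#' @param exclusive Logical vector from [call_exclusive()].
#' @param threshold Log2 fold-change cut (strict inequality; default 0.5).
#' @return A data.frame: `protein_id`, `logfc_dh_vs_wt`, `exclusive_dh`,
#'   `preferential_dh`.
#' @export
call_preferential <- function(imputed, samples, exclusive, threshold = 0.5) {
  imputed <- as.matrix(imputed)
  mean_dh <- rowMeans(imputed[, samples$bait == "DH", drop = FALSE])
  mean_wt <- rowMeans(imputed[, samples$bait == "WT", drop = FALSE])
  logfc <- mean_dh - mean_wt
  stopifnot(length(exclusive) == nrow(imputed))
  data.frame(protein_id = rownames(imputed),
             logfc_dh_vs_wt = logfc,
             exclusive_dh = unname(exclusive),
             preferential_dh = logfc > threshold | unname(exclusive),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized two-sided Welch t-test on the rows of two matrices.
welch_rows <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, stats::var); v2 <- apply(B, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero_se <- se2 == 0
  tt[zero_se] <- 0
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  df[zero_se] <- NA_real_
  list(t = tt, df = df, p = p, diff = m1 - m2)
}

#' Differential abundance between two baits (Welch t)
#'
#' Two-sided Welch two-sample t-test per protein on post-imputation log2
#' intensities, with Benjamini-Hochberg adjustment. Proteins whose values
#' are fully imputed in both baits carry no abundance information and are
#' excluded (reported in `excluded`).
#'
#' @param imputed Completed intensity matrix.
#' @param samples Sample metadata (needs `bait`).
#' @param mask Imputation mask from [impute_missing()].
#' @param bait_a,bait_b Baits to compare (default D463H vs WT).
#' @return A data.frame: `protein_id`, `diff` (mean a - mean b), `t`, `df`,
#'   `pval`, `padj`, `tested`; attribute `excluded` lists skipped proteins.
#' @export
differential_abundance <- function(imputed, samples, mask = NULL,
                                   bait_a = "DH", bait_b = "WT") {
  imputed <- as.matrix(imputed)
  ia <- samples$bait == bait_a
  ib <- samples$bait == bait_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stopf("need >= 2 replicates per bait for a differential test")
  A <- imputed[, ia, drop = FALSE]
  B <- imputed[, ib, drop = FALSE]
  tested <- rep(TRUE, nrow(imputed))
  if (!is.null(mask))
    tested <- !(rowSums(!mask[, ia, drop = FALSE]) == 0 &
                  rowSums(!mask[, ib, drop = FALSE]) == 0)
  w <- welch_rows(A, B)
  pval <- ifelse(tested, w$p, NA_real_)
  out <- data.frame(protein_id = rownames(imputed),
                    diff = w$diff, t = w$t, df = w$df,
                    pval = pval, padj = bh_adjust(pval), tested = tested,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- rownames(imputed)[!tested]
  out
}

#' Interactome-level overview: PCA, sample clustering, presence patterns
#'
#' Reuses the expression-module machinery on the completed protein
#' intensity matrix: a sample PCA, average-linkage Euclidean clustering of
#' samples, and a protein x bait presence matrix ordered by detection
#' pattern for an overlap heatmap.
#'
#' @param imputed Completed intensity matrix.
#' @param samples Sample metadata.
#' @param detection Detection matrix from [call_detection()] (post-filter).
#' @param n_top_variable Genes for the PCA (default all).
#' @return A list with `pca`, `sample_hclust`, `sample_order` and
#'   `overlap` (0/1 protein x bait matrix, rows grouped by pattern).
#' @export
interactome_overview <- function(imputed, samples, detection,
                                 n_top_variable = Inf) {
  imputed <- as.matrix(imputed)
  ntv <- min(n_top_variable, nrow(imputed))
  pca <- sample_pca(imputed, n_top_variable = ntv)
  sh <- stats::hclust(stats::dist(t(imputed)), method = "average")
  pres <- (detection > 0) * 1L
  noncontrol <- setdiff(colnames(pres), "control")
  pres <- pres[, noncontrol, drop = FALSE]
  pat <- apply(pres, 1, paste, collapse = "")
  pres <- pres[order(pat, decreasing = TRUE), , drop = FALSE]
  list(pca = pca, sample_hclust = sh, sample_order = sh$order,
       overlap = pres)
}

#' Run the full interactor-calling pipeline on an LFQ table
#'
#' Applies, in order: artefact filtering (control detections), the
#' single-sample filter, deterministic imputation, exclusive and
#' preferential D463H binder calling, and Welch differential abundance.
#' The order matters and matches the construction of the published hit
#' lists; applying the filters twice is idempotent.
#'
#' @param intensity Protein x sample log2-intensity matrix (`NA` missing).
#' @param samples Sample metadata (`sample_id`, `bait`, `replicate`).
#' @param min_dh_detect Exclusivity gate (see [call_exclusive()]).
#' @param preferential_logfc Preference threshold (see
#'   [call_preferential()]).
#' @param alpha Significance threshold used for the significant-difference
#'   count in the summary.
#' @return A list of class `"interactor_calls"` with `table` (per-protein
#'   InteractorTable data frame), `artefacts`, `single_sample` (removed
#'   ids), `string_query` (preferential + exclusive protein ids) and
#'   `summary` (named counts).
#' @export
call_interactors <- function(intensity, samples, min_dh_detect = 2,
                             preferential_logfc = 0.5, alpha = 0.05) {
  f1 <- filter_artefacts(intensity, samples)
  f2 <- filter_single_sample(f1$intensity, samples)
  kept <- f2$intensity
  if (nrow(kept) == 0) stopf("no proteins survive filtering")
  det <- call_detection(kept, samples)
  imp <- impute_missing(kept)
  n_dh <- sum(samples$bait == "DH")
  excl <- call_exclusive(det, n_dh_reps = n_dh,
                         min_dh_detect = min_dh_detect)
  pref <- call_preferential(imp$intensity, samples, excl,
                            threshold = preferential_logfc)
  da <- differential_abundance(imp$intensity, samples, imp$mask)
  tab <- data.frame(pref,
                    welch_p = da$pval, padj = da$padj,
                    det[, setdiff(colnames(det), "control"), drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  string_query <- tab$protein_id[tab$preferential_dh]
  summary <- c(n_input = nrow(as.matrix(intensity)),
               n_artefact = length(f1$removed),
               n_single_sample = length(f2$removed),
               n_retained = nrow(kept),
               n_exclusive = sum(tab$exclusive_dh),
               n_preferential = sum(tab$preferential_dh),
               n_significant = sum(!is.na(tab$padj) & tab$padj < alpha))
  structure(list(table = tab, artefacts = f1$removed,
                 single_sample = f2$removed, string_query = string_query,
                 summary = summary),
            class = "interactor_calls")
}

#' @export
print.interactor_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Interactor calls: %d proteins in, %d artefacts, ",
                     "%d single-sample,\n  %d retained; %d exclusive, ",
                     "%d preferential, %d significant\n"),
              s["n_input"], s["n_artefact"], s["n_single_sample"],
              s["n_retained"], s["n_exclusive"], s["n_preferential"],
              s["n_significant"]))
  invisible(x)
}

#' Write an LFQ intensity table and sample metadata as TSV
#'
#' @param intensity Protein x sample matrix (`NA` for missing).
#' @param samples Sample metadata.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_lfq_tsv <- function(intensity, samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(intensity, file.path(dir, "lfq_intensity.tsv"),
                   id_col = "protein_id")
  write_tsv(samples, file.path(dir, "lfq_samples.tsv"))
  invisible(dir)
}

#' Read an LFQ table written by [write_lfq_tsv()]
#'
#' @param intensity_path,samples_path Paths to the two TSV files.
#' @return A list with `intensity` and `samples`.
#' @export
read_lfq_tsv <- function(intensity_path, samples_path) {
  intensity <- read_matrix_tsv(intensity_path)
  samples <- read_tsv(samples_path)
  if (!all(colnames(intensity) == samples$sample_id))
    stopf("sample ids in intensity and metadata disagree")
  list(intensity = intensity, samples = samples)
}
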