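#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed the standard RNA-seq way: for
#' every gene expressed in all samples, take the ratio of its count to its
#' geometric mean across samples; the sample's factor is the median of those
#' ratios. Factors are rescaled to geometric mean 1.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @return Numeric vector of positive factors, one per sample, with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos))
    stopf(paste("no gene has nonzero counts in every sample;",
                "use a pseudo-reference fallback or filter samples"))
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(stats::median(x - ref)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Normalized log2 expression
#'
#' `log2(count / size_factor + prior_count)`; monotone in the count and used
#' for PCA, heatmaps and batch correction (never for inference).
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors from [estimate_size_factors()].
#' @param prior_count Positive pseudo-count (default 1).
#' @return Matrix of log2 normalized expression.
#' @export
log2_norm_counts <- function(counts, sf, prior_count = 1) {
  if (prior_count <= 0) stopf("prior_count must be > 0")
  if (any(sf <= 0)) stopf("size factors must be positive")
  log2(sweep(as.matrix(counts), 2, sf, "/") + prior_count)
}

#' Estimate per-gene NB dispersions with a mean trend
#'
#' Three-step dispersion model for small designs. (1) A raw method-of-moments
#' estimate per gene: within every condition group the normalized-count
#' variance in excess of the mean is converted to a dispersion
#' `(s^2 - m) / m^2` and the group estimates are pooled by degrees of
#' freedom, truncated at zero. (2) A mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` fitted by robust regression over genes with a
#' positive raw estimate. (3) A final dispersion shrinking the raw estimate
#' halfway toward the trend on the log scale,
#' `exp((log trend + log raw) / 2)`, floored at `1e-8`. A raw estimate
#' truncated at zero carries no usable excess-variance information at these
#' replicate numbers, so such genes fall back to the trend value rather
#' than being shrunk toward a spuriously Poisson-like dispersion.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors.
#' @param condition Character/factor vector of per-sample condition labels.
#' @return A list of class `"dispersion_model"` with `raw`, `trend`, `final`
#'   (per-gene vectors), `trend_coef` (a0, a1) and `base_mean`.
#' @export
estimate_dispersions <- function(counts, sf, condition) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stopf("all counts are zero")
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  groups <- split(seq_len(ncol(counts)), condition)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) stopf("need >= 2 samples in at least one condition")

  num <- den <- numeric(nrow(counts))
  for (g in groups) {
    m <- rowMeans(norm[, g, drop = FALSE])
    v <- apply(norm[, g, drop = FALSE], 1, stats::var)
    ok <- m > 0
    w <- length(g) - 1
    a <- ifelse(ok, (v - m) / m^2, NA_real_)
    num <- num + ifelse(ok, w * a, 0)
    den <- den + ifelse(ok, w, 0)
  }
  raw <- ifelse(den > 0, pmax(num / den, 0), NA_real_)

  fit_ok <- !is.na(raw) & raw > 0 & base_mean > 0
  if (sum(fit_ok) >= 10) {
    df <- data.frame(a = raw[fit_ok], im = 1 / base_mean[fit_ok])
    fit <- tryCatch(MASS::rlm(a ~ im, data = df, maxit = 100),
                    error = function(e) stats::lm(a ~ im, data = df))
    co <- stats::coef(fit)
  } else if (any(fit_ok)) {
    co <- c(stats::median(raw[fit_ok]), 0)
  } else {
    co <- c(1e-8, 0)
  }
  if (!all(is.finite(co))) co <- c(1e-8, 0)
  trend <- pmax(co[1] + co[2] / pmax(base_mean, 1e-8), 1e-8)

  final <- exp((log(trend) + log(pmax(raw, 1e-8))) / 2)
  weak <- is.na(raw) | raw == 0
  final[weak] <- trend[weak]
  final <- pmax(final, 1e-8)
  structure(list(raw = raw, trend = trend, final = final,
                 trend_coef = stats::setNames(as.numeric(co), c("a0", "a1")),
                 base_mean = base_mean,
                 df = sum(vapply(groups, length, 1L) - 1L)),
            class = "dispersion_model")
}

# Vectorized IRLS for per-gene NB log-link regression at fixed dispersion.
# Y: G x n counts; X: n x p design; offset: length-n log size factors;
# alpha: length-G dispersions. Returns coefficients, standard errors and a
# convergence flag.
nb_irls <- function(Y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  B <- matrix(0, G, p)
  B[, 1] <- log(pmax(rowMeans(sweep(Y, 2, exp(offset), "/")), 0.1))
  converged <- rep(FALSE, G)
  active <- rep(TRUE, G)
  XX <- matrix(0, n, p * p)  # columns x_j * x_k for fast cross-products
  for (j in seq_len(p)) for (k in seq_len(p))
    XX[, (j - 1) * p + k] <- X[, j] * X[, k]
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (length(idx) == 0) break
    eta <- B[idx, , drop = FALSE] %*% t(X) +
      matrix(offset, length(idx), n, byrow = TRUE)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha[idx] * mu)
    Z <- (eta - matrix(offset, length(idx), n, byrow = TRUE)) +
      (Y[idx, , drop = FALSE] - mu) / mu
    XtWX <- W %*% XX                    # G_active x p^2
    XtWZ <- (W * Z) %*% X               # G_active x p
    for (ii in seq_along(idx)) {
      g <- idx[ii]
      A <- matrix(XtWX[ii, ], p, p)
      b_new <- tryCatch(solve(A + diag(1e-10, p), XtWZ[ii, ]),
                        error = function(e) NULL)
      if (is.null(b_new) || !all(is.finite(b_new))) {
        active[g] <- FALSE  # stays non-converged
        next
      }
      delta <- max(abs(b_new - B[g, ]))
      B[g, ] <- b_new
      if (delta < tol) {
        converged[g] <- TRUE
        active[g] <- FALSE
      }
    }
  }
  # observed-information standard errors at the final coefficients
  eta <- B %*% t(X) + matrix(offset, G, n, byrow = TRUE)
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  XtWX <- W %*% XX
  SE <- matrix(NA_real_, G, p)
  for (g in seq_len(G)) {
    A <- matrix(XtWX[g, ], p, p)
    Ainv <- tryCatch(solve(A + diag(1e-10, p)), error = function(e) NULL)
    if (!is.null(Ainv)) {
      d <- diag(Ainv)
      SE[g, ] <- sqrt(pmax(d, 0))
    }
  }
  list(coef = B, se = SE, converged = converged)
}

#' Negative-binomial Wald test for one contrast
#'
#' Per-gene NB regression with log link at fixed (shrunk) dispersion,
#' `~ condition` or `~ condition + batch`, fitted by iteratively reweighted
#' least squares with log size factors as offsets. The condition coefficient
#' rescaled to log2 is the reported fold change; the Wald statistic is
#' `log2fc / se`. Its reference distribution is a moderated t with
#' `d / (1 - w)^2` degrees of freedom, where `d` is the pooled
#' within-condition degrees of freedom behind the dispersion estimates and
#' `w = 0.5` the dispersion-shrinkage weight: shrinking the log dispersion
#' halfway to the trend quarters its sampling variance, so the effective
#' degrees of freedom are four times the estimation ones. (A plain
#' standard-normal reference is anticonservative
#' at triplicate scale.) Genes with all-zero counts across the two
#' conditions get `NA` statistics and are excluded from the
#' Benjamini-Hochberg adjustment, as are non-converged fits.
#'
#' @param counts Gene x sample count matrix.
#' @param samples Data frame with `sample_id`, `condition` and optionally a
#'   batch column.
#' @param sf Size factors (one per column of `counts`).
#' @param disp A `"dispersion_model"` from [estimate_dispersions()] (its
#'   `final` slot is used), or a numeric vector of per-gene dispersions.
#' @param condition_a Test condition (numerator of the fold change).
#' @param condition_b Reference condition.
#' @param batch Optional name of a batch column in `samples` to adjust for.
#' @param max_iter,tol IRLS controls.
#' @return A `data.frame` of class `"contrast_table"` with columns
#'   `gene_id`, `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj` and
#'   `contrast`.
#' @export
nb_wald_test <- function(counts, samples, sf, disp,
                         condition_a, condition_b = "parental",
                         batch = NULL, max_iter = 50, tol = 1e-8) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(samples))
  for (cond in c(condition_a, condition_b)) {
    n_c <- sum(samples$condition == cond)
    if (n_c == 0) stopf("condition '%s' absent from samples", cond)
    if (n_c < 2) stopf("condition '%s' has < 2 samples", cond)
  }
  alpha <- if (inherits(disp, "dispersion_model")) disp$final else disp
  disp_df <- if (inherits(disp, "dispersion_model")) disp$df else NULL
  stopifnot(length(alpha) == nrow(counts))

  keep <- samples$condition %in% c(condition_a, condition_b)
  Y <- counts[, keep, drop = FALSE]
  sub <- samples[keep, , drop = FALSE]
  cond_ind <- as.numeric(sub$condition == condition_a)
  X <- cbind(intercept = 1, condition = cond_ind)
  if (!is.null(batch)) {
    if (!batch %in% names(sub)) stopf("batch column '%s' not in samples", batch)
    bf <- factor(sub[[batch]])
    if (nlevels(bf) > 1) {
      bm <- stats::model.matrix(~bf)[, -1, drop = FALSE]
      # drop batch columns aliased with the condition indicator
      ok <- apply(bm, 2, function(col) {
        qr(cbind(X, col))$rank > ncol(X)
      })
      X <- cbind(X, bm[, ok, drop = FALSE])
    }
  }
  offset <- log(sf[keep])

  nonzero <- rowSums(Y) > 0
  G <- nrow(Y)
  log2fc <- se <- rep(NA_real_, G)
  conv <- rep(FALSE, G)
  if (any(nonzero)) {
    fit <- nb_irls(Y[nonzero, , drop = FALSE], X, offset,
                   alpha[nonzero], max_iter = max_iter, tol = tol)
    ln2 <- log(2)
    log2fc[nonzero] <- fit$coef[, 2] / ln2
    se[nonzero] <- fit$se[, 2] / ln2
    conv[nonzero] <- fit$converged
  }
  usable <- conv & is.finite(log2fc) & is.finite(se) & se > 0
  stat <- ifelse(usable, log2fc / se, NA_real_)
  df_eff <- max(1, 4 * (disp_df %||% (nrow(X) - ncol(X))))
  pvalue <- ifelse(usable, 2 * stats::pt(-abs(stat), df = df_eff), NA_real_)
  log2fc[!usable] <- NA_real_
  se[!usable] <- NA_real_

  base_mean <- rowMeans(sweep(Y, 2, sf[keep], "/"))
  out <- data.frame(gene_id = rownames(counts) %||% as.character(seq_len(G)),
                    base_mean = base_mean,
                    log2fc = log2fc, se = se, stat = stat,
                    pvalue = pvalue,
                    padj = bh_adjust(pvalue),
                    contrast = paste0(condition_a, "_vs_", condition_b),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; `NA` entries are
#' preserved and excluded from the ranking. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Remove batch effects from an expression matrix
#'
#' Per gene, fits a linear model with condition and batch and subtracts the
#' (centered) fitted batch terms, leaving the condition structure untouched.
#' Used only for visualization matrices (PCA, heatmaps); inference handles
#' batch as a model covariate instead. Delegates to
#' [limma::removeBatchEffect()] with a design matrix protecting condition.
#'
#' @param expr Gene x sample log-expression matrix.
#' @param batch Per-sample batch labels (>= 2 levels to have any effect).
#' @param condition Per-sample condition labels to protect.
#' @return Corrected matrix of the same shape.
#' @export
remove_batch_effect <- function(expr, batch, condition) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(batch), ncol(expr) == length(condition))
  bf <- factor(batch)
  if (nlevels(bf) < 2) return(expr)
  tab <- table(bf, factor(condition))
  nested <- rownames(tab)[rowSums(tab > 0) == 1]
  if (length(nested) > 0 && nlevels(factor(condition)) > 1)
    stopf("batch level(s) %s occur in a single condition; batch is confounded",
          paste(nested, collapse = ", "))
  design <- stats::model.matrix(~ factor(condition))
  limma::removeBatchEffect(expr, batch = bf, design = design)
}
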