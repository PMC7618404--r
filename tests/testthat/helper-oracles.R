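# Independent oracles and fixture builders. Everything here is deliberately
# naive (loops, closed forms) and separate from the package implementation.

# Exhaustive running-sum enrichment score: walk the full ranked list one
# gene at a time and track the extremum of largest magnitude.
brute_force_es <- function(gene_ids, scores, set, weight = 1) {
  N <- length(gene_ids)
  in_set <- gene_ids %in% set
  m <- sum(in_set)
  w <- abs(scores)^weight
  W <- sum(w[in_set])
  if (W == 0) {
    w[in_set] <- 1
    W <- m
  }
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) cur <- cur + w[i] / W
    else cur <- cur - 1 / (N - m)
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Closed-form hypergeometric upper tail P(X >= k) via binomial coefficients.
hyper_tail_oracle <- function(k, m, N, n) {
  lo <- max(k, 0)
  hi <- min(m, n)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(i)
    choose(m, i) * choose(N - m, n - i), numeric(1))) / choose(N, n)
}

# Naive double-loop region mean over a PAE matrix (0-based inclusive bounds).
region_mean_oracle <- function(pae, x_lo, x_hi, y_lo, y_hi) {
  tot <- 0
  cnt <- 0
  for (x in x_lo:x_hi) for (y in y_lo:y_hi) {
    tot <- tot + pae[x + 1, y + 1]
    cnt <- cnt + 1
  }
  tot / cnt
}

# Build a ranked_list directly (bypasses rank_genes) for enrichment tests.
make_ranked <- function(ids, scores) {
  o <- order(-scores, ids)
  structure(list(gene_id = ids[o], score = scores[o], n_dropped = 0L),
            class = "ranked_list")
}

# Minimal contrast_table builder for pattern/enrichment tests.
make_contrast <- function(gene_id, log2fc, padj, stat = NULL,
                          contrast = "X_vs_parental") {
  if (is.null(stat)) stat <- log2fc / 0.1
  out <- data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
                    se = abs(log2fc / pmax(abs(stat), 1e-9)),
                    stat = stat, pvalue = padj, padj = padj,
                    contrast = contrast, stringsAsFactors = FALSE)
  class(out) <- c("contrast_table", "data.frame")
  out
}

# Hand-built 12-protein AP-MS fixture with a known partition:
#   3 contaminants (control detections), 1 single-sample protein,
#   2 exclusive DH binders, 2 preferential-by-logfc, 4 plain background.
# Columns: control x2, WT x3, DH x3, DN x3.
lfq_fixture_12 <- function() {
  samples <- data.frame(
    sample_id = c("control_1", "control_2", "WT_1", "WT_2", "WT_3",
                  "DH_1", "DH_2", "DH_3", "DN_1", "DN_2", "DN_3"),
    bait = rep(c("control", "WT", "DH", "DN"), c(2, 3, 3, 3)),
    replicate = c(1:2, 1:3, 1:3, 1:3), stringsAsFactors = FALSE)
  M <- matrix(NA_real_, 12, 11,
              dimnames = list(sprintf("P%02d", 1:12), samples$sample_id))
  wt <- 3:5; dh <- 6:8; dn <- 9:11
  M["P01", c(1, wt, dh, dn)] <- 25            # contaminant (1 control hit)
  M["P02", c(2, dh)] <- 24                    # contaminant
  M["P03", 1:2] <- 23                         # contaminant, control only
  M["P04", 6] <- 22                           # single sample (1 DH rep)
  M["P05", dh] <- c(26, 26, 26)               # exclusive DH (3/3, WT 0)
  M["P06", c(6, 7)] <- c(25, 25)              # exclusive DH (2/3, WT 0)
  M["P07", c(wt, dh, dn)] <- c(24, 24, 24, 25, 25, 25, 24, 24, 24)  # pref (+1)
  M["P08", c(wt, dh, dn)] <- c(25, 25, 25, 25.6, 25.6, 25.6, 25, 25, 25) # pref (+0.6)
  M["P09", c(wt, dh, dn)] <- 25               # background (logfc 0)
  M["P10", c(wt, dh, dn)] <- c(25, 25, 25, 25.5, 25.5, 25.5, 25, 25, 25) # boundary 0.5
  M["P11", c(wt, dh)] <- c(24, 24, 24, 24, 24, 24)   # background
  M["P12", c(6, 9)] <- c(23, 23)              # two detections: retained
  list(intensity = M, samples = samples,
       expected = list(
         artefacts = c("P01", "P02", "P03"),
         single_sample = "P04",
         exclusive = c("P05", "P06"),
         preferential = c("P05", "P06", "P07", "P08"),
         retained = sprintf("P%02d", 4:12)[-1]))
}
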