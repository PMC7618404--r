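#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique members, nonempty).
#' @param description Optional named character vector of descriptions.
#' @return A list of class `"gene_set_collection"` with `sets` and
#'   `description`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("set names must be present and unique")
  if (any(vapply(sets, length, 1L) == 0)) stopf("sets must be nonempty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: name, description, then member ids.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3
  if (any(bad)) stopf("GMT line(s) with < 3 fields: %s",
                      paste(which(bad), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  descr <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
  gene_set_collection(sets, descr)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Rank genes by Wald statistic
#'
#' Produces the descending preranked list used for enrichment analysis.
#' Genes with `NA` statistics are dropped (count reported); ties are broken
#' lexicographically by gene id for determinism.
#'
#' @param ct A `contrast_table` from [nb_wald_test()].
#' @return A list of class `"ranked_list"`: `gene_id`, `score` (both in
#'   rank order) and `n_dropped`.
#' @export
rank_genes <- function(ct) {
  ok <- is.finite(ct$stat)
  n_dropped <- sum(!ok)
  ids <- ct$gene_id[ok]
  sc <- ct$stat[ok]
  if (length(sc) < 2) stopf("fewer than 2 genes with usable statistics")
  o <- order(-sc, ids)
  structure(list(gene_id = ids[o], score = sc[o], n_dropped = n_dropped),
            class = "ranked_list")
}

# Core running-sum enrichment score from member positions.
# pos: sorted 1-based positions of set members in the ranking;
# absw: |score|^weight for the full ranking. Returns the signed extremum
# (first occurrence along the profile on ties in |value|).
es_from_positions <- function(pos, absw, N) {
  m <- length(pos)
  w <- absw[pos]
  W <- sum(w)
  if (W == 0) { w <- rep(1, m); W <- m }  # all-zero scores: equal weights
  H <- cumsum(w) / W
  if (N == m) return(list(es = max(H), at = pos[which.max(H)]))
  miss <- (pos - seq_len(m)) / (N - m)
  after <- H - miss                 # value right at each hit
  before <- c(0, H[-m]) - miss      # value just before each hit
  cand <- as.vector(rbind(before, after))
  cand_i <- as.vector(rbind(pmax(pos - 1L, 0L), pos))
  k <- which.max(abs(cand))         # earliest among equal |values|
  list(es = cand[k], at = cand_i[k])
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Classic preranked GSEA statistic: walking down the ranked list, the
#' running sum gains `|score|^w / sum(|score in set|^w)` at set members and
#' loses `1/(N - m)` elsewhere; the enrichment score is the extremum of
#' largest magnitude. The leading edge is the set members at or before the
#' extremum (at or after it, for a negative score).
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param set Character vector of member gene ids.
#' @param weight Weight exponent on `|score|` (default 1, classic GSEA).
#' @return A list with `es`, `running` (length-N profile), `leading_edge`,
#'   `positions` (member positions) and `size` (members in the universe).
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- length(ranked$gene_id)
  pos <- sort(which(ranked$gene_id %in% set))
  m <- length(pos)
  if (m == 0) stopf("set is disjoint from the ranked universe")
  absw <- abs(ranked$score)^weight
  res <- es_from_positions(pos, absw, N)

  w <- absw[pos]
  if (sum(w) == 0) w <- rep(1, m)
  inc <- numeric(N)
  inc[pos] <- w / sum(w)
  dec <- if (N > m) 1 / (N - m) else 0
  step <- inc
  step[-pos] <- -dec
  running <- cumsum(step)

  le <- if (res$es >= 0) ranked$gene_id[pos[pos <= res$at]]
        else ranked$gene_id[pos[pos >= res$at]]
  list(es = res$es, running = running, leading_edge = le,
       positions = pos, size = m)
}

#' Preranked GSEA over a collection with permutation significance
#'
#' For every set of admissible size, computes the enrichment score and a
#' gene-permutation null: `n_perm` random member sets of the same size. The
#' normalized score divides by the mean `|ES|` of same-sign permutations,
#' and the p-value uses the plus-one convention
#' `(1 + #{same-sign |ES_perm| >= |ES|}) / (1 + n_same_sign)`, so it is
#' never exactly zero. Benjamini-Hochberg adjustment across tested sets.
#'
#' @param ranked A `ranked_list`.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (fixed seed gives identical output).
#' @param min_size,max_size Admissible set sizes after intersection with
#'   the universe; others are skipped and reported.
#' @param weight Weight exponent passed to the score.
#' @return A list with `results` (data.frame: set, size, es, nes, pval,
#'   padj, leading_edge) and `skipped` (named reason vector).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1L,
                           min_size = 5, max_size = 500, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  if (n_perm < 100) stopf("n_perm must be >= 100")
  set.seed(as.integer(seed))
  N <- length(ranked$gene_id)
  absw <- abs(ranked$score)^weight
  rows <- list(); skipped <- character(0)
  for (nm in names(collection$sets)) {
    pos <- sort(which(ranked$gene_id %in% collection$sets[[nm]]))
    m <- length(pos)
    if (m < min_size || m > max_size) {
      skipped[nm] <- sprintf("size %d outside [%d, %d]", m, min_size, max_size)
      next
    }
    obs <- gsea_es(ranked, collection$sets[[nm]], weight = weight)
    perm <- vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(N, m)), absw, N)$es
    }, numeric(1))
    same <- if (obs$es >= 0) perm >= 0 else perm < 0
    n_same <- sum(same)
    nes <- if (n_same > 0 && mean(abs(perm[same])) > 0)
      obs$es / mean(abs(perm[same])) else NA_real_
    pval <- (1 + sum(same & abs(perm) >= abs(obs$es))) / (1 + n_same)
    rows[[nm]] <- data.frame(set = nm, size = m, es = obs$es, nes = nes,
                             pval = pval,
                             leading_edge = paste(obs$leading_edge,
                                                  collapse = ","),
                             stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(set = character(0), size = integer(0),
                         es = numeric(0), nes = numeric(0),
                         pval = numeric(0), leading_edge = character(0))
  if (nrow(res)) res$padj <- bh_adjust(res$pval) else res$padj <- numeric(0)
  res <- res[, c("set", "size", "es", "nes", "pval", "padj", "leading_edge")]
  list(results = res, skipped = skipped)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap `k` between a
#' hit list (size `n`) and each set (size `m` in the universe of size `N`),
#' with fold enrichment `(k/n) / (m/N)` and Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param hits Character vector of hit gene ids (must be in `universe`).
#' @param universe Character vector of background gene ids.
#' @param collection A [gene_set_collection()]; sets are intersected with
#'   the universe.
#' @return A data.frame: set, k, m, n, N, fold, pval, padj.
#' @export
ora_hypergeom <- function(hits, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  bad <- setdiff(hits, universe)
  if (length(bad) > 0)
    stopf("hits not in universe: %s%s",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    m <- length(s)
    k <- length(intersect(s, hits))
    pval <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    fold <- if (n > 0 && m > 0) (k / n) / (m / N) else NA_real_
    data.frame(set = nm, k = k, m = m, n = n, N = N, fold = fold,
               pval = pval, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$padj <- bh_adjust(res$pval)
  res
}

#' Curate a gene set from the top up-regulated genes of a contrast
#'
#' Data-driven gene-set construction: among genes with a positive log2 fold
#' change, take the `n` with the strongest evidence (largest Wald statistic
#' by default; `"lfc"` and `"padj"` rankings are also available).
#'
#' @param ct A `contrast_table`.
#' @param n Set size (default 100).
#' @param rank_by One of `"stat"`, `"lfc"`, `"padj"`.
#' @param name Name for the resulting set.
#' @return A [gene_set_collection()] with the single curated set.
#' @export
curate_top_upregulated <- function(ct, n = 100, rank_by = c("stat", "lfc",
                                                            "padj"),
                                   name = "top_upregulated") {
  rank_by <- match.arg(rank_by)
  up <- ct[!is.na(ct$log2fc) & ct$log2fc > 0, , drop = FALSE]
  if (nrow(up) < n)
    stopf("only %d up-regulated genes available, %d requested", nrow(up), n)
  key <- switch(rank_by,
                stat = -up$stat,
                lfc = -up$log2fc,
                padj = up$padj)
  o <- order(key, up$gene_id)
  members <- up$gene_id[o][seq_len(n)]
  gene_set_collection(stats::setNames(list(members), name),
                      stats::setNames(sprintf("top %d up-regulated by %s", n,
                                              rank_by), name))
}

#' Write GSEA/ORA results as TSV
#'
#' @param res Result data frame (e.g. `gsea_preranked(...)$results`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) write_tsv(res, path)
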