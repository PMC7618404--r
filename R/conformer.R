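#' Construct a validated PAE model record
#'
#' @param pae Square numeric matrix of predicted aligned error (entries
#'   >= 0, conventionally capped at 31.75).
#' @param ptm Predicted template-modelling score in `[0, 1]` (`NA` allowed).
#' @param model_id Identifier string.
#' @return A list of class `"pae_model"` with `pae`, `ptm`, `model_id`,
#'   `n_res`.
#' @export
pae_model <- function(pae, ptm = NA_real_, model_id = "model") {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stopf("PAE matrix must be square (got %d x %d)", nrow(pae), ncol(pae))
  if (any(!is.finite(pae)) || any(pae < 0))
    stopf("PAE entries must be finite and non-negative")
  if (!is.na(ptm) && (ptm < 0 || ptm > 1)) stopf("ptm must lie in [0, 1]")
  structure(list(pae = pae, ptm = ptm, model_id = model_id,
                 n_res = nrow(pae)),
            class = "pae_model")
}

#' Read an AlphaFold-style PAE confidence JSON file
#'
#' Accepts the common dialects: a JSON object with the matrix under
#' `predicted_aligned_error` or `pae` (either a top-level object or the
#' first element of a top-level array) and an optional scalar `ptm`.
#'
#' @param path Path to the JSON file.
#' @param model_id Identifier; defaults to the file name.
#' @return A [pae_model()].
#' @export
read_pae_json <- function(path, model_id = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.list(obj) && is.null(names(obj)) && length(obj) >= 1)
    obj <- obj[[1]]
  key <- intersect(c("predicted_aligned_error", "pae"), names(obj))
  if (length(key) == 0)
    stopf("no PAE matrix found; accepted keys: predicted_aligned_error, pae")
  pae <- obj[[key[1]]]
  if (!is.matrix(pae)) pae <- do.call(rbind, pae)
  if (nrow(pae) != ncol(pae))
    stopf("PAE matrix must be square (got %d x %d)", nrow(pae), ncol(pae))
  ptm <- if (!is.null(obj$ptm)) as.numeric(obj$ptm) else NA_real_
  pae_model(pae, ptm = ptm,
            model_id = model_id %||% sub("\\.json$", "", basename(path)))
}

#' Write a PAE model as AlphaFold-style JSON
#'
#' @param m A [pae_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(m, path) {
  stopifnot(inherits(m, "pae_model"))
  obj <- list(predicted_aligned_error = m$pae)
  if (!is.na(m$ptm)) obj$ptm <- m$ptm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectangular residue region of a PAE matrix
#'
#' Residue indices are 0-based and bounds are inclusive, matching the
#' convention in which the first residue is index 0. X indexes rows and Y
#' indexes columns of the matrix as stored.
#'
#' @param x_lo,x_hi,y_lo,y_hi Integer bounds, `0 <= lo <= hi`.
#' @return A list of class `"region_spec"`.
#' @export
region_spec <- function(x_lo, x_hi, y_lo, y_hi) {
  v <- c(x_lo, x_hi, y_lo, y_hi)
  if (any(v < 0) || x_lo > x_hi || y_lo > y_hi)
    stopf("region bounds must satisfy 0 <= lo <= hi")
  structure(list(x_lo = as.integer(x_lo), x_hi = as.integer(x_hi),
                 y_lo = as.integer(y_lo), y_hi = as.integer(y_hi)),
            class = "region_spec")
}

#' Default classifier regions
#'
#' Region 1 covers the pseudosubstrate rows against the kinase-domain
#' columns (X in `[0, 20]`, Y in `[350, 650]`); region 2 covers the
#' C2-domain rows against the same columns (X in `[200, 250]`).
#'
#' @return A list with elements `region1` and `region2`.
#' @export
default_regions <- function() {
  list(region1 = region_spec(0, 20, 350, 650),
       region2 = region_spec(200, 250, 350, 650))
}

#' Mean PAE over a region
#'
#' Arithmetic mean of `pae[x, y]` for `x` in `[x_lo, x_hi]`, `y` in
#' `[y_lo, y_hi]` (0-based inclusive; rows = X).
#'
#' @param m A [pae_model()].
#' @param r A [region_spec()].
#' @return The mean, a single number.
#' @export
region_mean <- function(m, r) {
  stopifnot(inherits(m, "pae_model"), inherits(r, "region_spec"))
  n <- m$n_res
  if (r$x_hi >= n) stopf("region x_hi %d out of range (n_res = %d)", r$x_hi, n)
  if (r$y_hi >= n) stopf("region y_hi %d out of range (n_res = %d)", r$y_hi, n)
  mean(m$pae[(r$x_lo:r$x_hi) + 1, (r$y_lo:r$y_hi) + 1])
}

#' Classify a model as PS-in or PS-out from two region means
#'
#' The autoinhibited (PS-in) conformation docks the pseudosubstrate into
#' the kinase active site, so the pseudosubstrate-kinase block of the PAE
#' matrix (region 1) is confidently predicted (low error) while the
#' C2-kinase block (region 2) is not; the open (PS-out) conformation is
#' the reverse. The call is PS-in when `mean(region1) < mean(region2)`,
#' PS-out when greater, and `ambiguous` on exact equality (the decision
#' rule covers only strict inequalities).
#'
#' @param m A [pae_model()].
#' @param region1,region2 [region_spec()]s (defaults: [default_regions()]).
#' @param symmetrize Average the matrix with its transpose before taking
#'   region means (off by default; PAE is asymmetric as stored).
#' @return A list of class `"conformer_call"`: `model_id`, `mean_region1`,
#'   `mean_region2`, `conformer`, `median_pae`, `ptm`.
#' @export
classify_conformer <- function(m, region1 = NULL, region2 = NULL,
                               symmetrize = FALSE) {
  stopifnot(inherits(m, "pae_model"))
  if (is.null(region1)) region1 <- default_regions()$region1
  if (is.null(region2)) region2 <- default_regions()$region2
  if (isTRUE(symmetrize))
    m <- pae_model((m$pae + t(m$pae)) / 2, ptm = m$ptm,
                   model_id = m$model_id)
  m1 <- region_mean(m, region1)
  m2 <- region_mean(m, region2)
  conformer <- if (m1 < m2) "PS-in" else if (m1 > m2) "PS-out" else "ambiguous"
  structure(list(model_id = m$model_id, mean_region1 = m1,
                 mean_region2 = m2, conformer = conformer,
                 median_pae = stats::median(m$pae), ptm = m$ptm),
            class = "conformer_call")
}

#' Summarize an ensemble of conformer calls
#'
#' Class fractions are computed over the non-ambiguous calls (ambiguous
#' count reported separately); per-class pTM and median-PAE means/sds
#' describe prediction confidence by conformation.
#'
#' @param calls List of `conformer_call`s.
#' @param construct Label for the protein construct.
#' @return A list of class `"conformer_summary"` with `construct`,
#'   `n_models`, `n_ambiguous`, `frac_ps_in`, `frac_ps_out`, `per_class`
#'   (data.frame: class, n, ptm_mean, ptm_sd, median_pae_mean,
#'   median_pae_sd) and `calls_table` (per-model data.frame).
#' @export
summarize_ensemble <- function(calls, construct = "construct") {
  if (length(calls) == 0) stopf("no conformer calls to summarize")
  tab <- do.call(rbind, lapply(calls, function(cc)
    data.frame(model_id = cc$model_id, mean_region1 = cc$mean_region1,
               mean_region2 = cc$mean_region2, conformer = cc$conformer,
               median_pae = cc$median_pae, ptm = cc$ptm,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  nonamb <- tab$conformer != "ambiguous"
  n_in <- sum(tab$conformer == "PS-in")
  n_out <- sum(tab$conformer == "PS-out")
  per_class <- do.call(rbind, lapply(c("PS-in", "PS-out"), function(k) {
    sub <- tab[tab$conformer == k, , drop = FALSE]
    data.frame(class = k, n = nrow(sub),
               ptm_mean = if (nrow(sub)) mean(sub$ptm) else NA_real_,
               ptm_sd = if (nrow(sub) > 1) stats::sd(sub$ptm) else NA_real_,
               median_pae_mean = if (nrow(sub)) mean(sub$median_pae)
                                 else NA_real_,
               median_pae_sd = if (nrow(sub) > 1) stats::sd(sub$median_pae)
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(construct = construct,
                 n_models = nrow(tab),
                 n_ambiguous = sum(!nonamb),
                 frac_ps_in = if (any(nonamb)) n_in / sum(nonamb) else NA_real_,
                 frac_ps_out = if (any(nonamb)) n_out / sum(nonamb)
                               else NA_real_,
                 per_class = per_class,
                 calls_table = tab),
            class = "conformer_summary")
}

#' @export
print.conformer_summary <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d models, %.0f%% PS-in / %.0f%% PS-out (%d ambiguous)\n",
              x$construct, x$n_models, 100 * x$frac_ps_in,
              100 * x$frac_ps_out, x$n_ambiguous))
  invisible(x)
}

#' Write a PAE ensemble to a directory of JSON files plus a manifest
#'
#' @param ensemble Result of [simulate_pae_ensemble()] (or a compatible
#'   list with `models` and `labels`).
#' @param dir Output directory.
#' @param construct Construct label recorded in the manifest.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_pae_ensemble <- function(ensemble, dir, construct = "construct") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(ensemble$models), function(k) {
    m <- ensemble$models[[k]]
    f <- paste0(m$model_id, ".json")
    write_pae_json(m, file.path(dir, f))
    data.frame(file = f, construct = construct,
               label = ensemble$labels[k], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a PAE ensemble from a directory written by [write_pae_ensemble()]
#'
#' @param dir Directory with one JSON per model and `manifest.tsv`.
#' @return A list with `models` and the manifest columns.
#' @export
read_pae_ensemble <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  models <- lapply(manifest$file, function(f)
    read_pae_json(file.path(dir, f)))
  list(models = models, labels = manifest$label,
       construct = manifest$construct)
}
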