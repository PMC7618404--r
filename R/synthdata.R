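#' Configuration for the RNA-seq count simulator
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' defaults mirror the study design the package models: four conditions
#' (parental cells plus wild-type, D463H and D463N over-expression) with
#' unequal replication (wild-type n = 2, all others n = 3), and a
#' gain-of-function effect structure in which D463H moves the same genes as
#' the wild-type allele, in the same direction, but with its log fold change
#' amplified by a constant multiplier (`alpha_amp`, default 2).
#'
#' Gene classes:
#' \describe{
#'   \item{null}{no effect in any condition.}
#'   \item{shared}{WT effect `beta ~ N(0, beta_sd)`; DH effect
#'     `alpha_amp * beta`; DN unaffected.}
#'   \item{dh_only}{same construction but `beta ~ N(0, beta_sd/2)`, a real
#'     WT displacement that is mostly sub-threshold at n = 2 while the
#'     amplified DH effect is detectable.}
#'   \item{dn_specific}{effect only in DN.}
#'   \item{inactive_shared}{DH and DN move together (kinase-activity
#'     independent output), WT unaffected.}
#' }
#'
#' @param n_genes Number of genes.
#' @param reps_per_condition Named integer vector of replicates for
#'   `parental`, `WT`, `DH`, `DN`; every entry must be >= 2.
#' @param baseline_logmean_mu,baseline_logmean_sd Mean and sd of per-gene
#'   baseline expression on the log2 scale.
#' @param dispersion_shape,dispersion_scale Gamma shape/scale for per-gene
#'   negative-binomial dispersions.
#' @param frac_shared,frac_dh_only,frac_dn_specific,frac_inactive_shared
#'   Fractions of genes in each effect class; must sum to at most 1.
#' @param beta_sd SD of the true wild-type log2 fold change.
#' @param alpha_amp Amplitude multiplier applied to D463H effects (> 0).
#' @param batch_sd SD of the additive per-gene log2-scale batch shift shared
#'   by replicate index across conditions.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `"rna_sim_config"`.
#' @export
rna_sim_config <- function(n_genes = 5000,
                           reps_per_condition = c(parental = 3, WT = 2,
                                                  DH = 3, DN = 3),
                           baseline_logmean_mu = 7,
                           baseline_logmean_sd = 2,
                           dispersion_shape = 2,
                           dispersion_scale = 0.025,
                           frac_shared = 0.1,
                           frac_dh_only = 0.2,
                           frac_dn_specific = 0.05,
                           frac_inactive_shared = 0.05,
                           beta_sd = 1,
                           alpha_amp = 2,
                           batch_sd = 0.2,
                           seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              reps_per_condition = reps_per_condition,
              baseline_logmean_mu = baseline_logmean_mu,
              baseline_logmean_sd = baseline_logmean_sd,
              dispersion_shape = dispersion_shape,
              dispersion_scale = dispersion_scale,
              frac_shared = frac_shared,
              frac_dh_only = frac_dh_only,
              frac_dn_specific = frac_dn_specific,
              frac_inactive_shared = frac_inactive_shared,
              beta_sd = beta_sd,
              alpha_amp = alpha_amp,
              batch_sd = batch_sd,
              seed = as.integer(seed))
  fr <- c(cfg$frac_shared, cfg$frac_dh_only, cfg$frac_dn_specific,
          cfg$frac_inactive_shared)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stopf("effect-class fractions must lie in [0,1] and sum to <= 1 (sum = %.3f)",
          sum(fr))
  if (cfg$alpha_amp <= 0) stopf("alpha_amp must be > 0")
  need <- c("parental", "WT", "DH", "DN")
  if (!all(need %in% names(cfg$reps_per_condition)))
    stopf("reps_per_condition must name all of: %s", paste(need, collapse = ", "))
  if (any(cfg$reps_per_condition < 2))
    stopf("every condition needs >= 2 replicates")
  if (cfg$n_genes < 1) stopf("n_genes must be >= 1")
  class(cfg) <- "rna_sim_config"
  cfg
}

#' Simulate gene-level RNA-seq counts with known ground truth
#'
#' Draws negative-binomial counts for the four-condition design described in
#' [rna_sim_config()]. The count mean for gene g in sample j is
#' `2^(baseline_g + lfc_{g,cond(j)} + batch_{g,rep(j)})` and counts are
#' `NB(mean, dispersion_g)`. The returned truth table records each gene's
#' effect class and true log2 fold change per non-parental condition, so
#' downstream stages can be tested by parameter recovery.
#'
#' @param cfg A [rna_sim_config()].
#' @return A list with elements `counts` (gene x sample integer matrix),
#'   `samples` (data frame: sample_id, condition, batch) and `truth`
#'   (data frame: gene_id, class, lfc_WT, lfc_DH, lfc_DN).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "rna_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(G))

  reps <- cfg$reps_per_condition[c("parental", "WT", "DH", "DN")]
  condition <- rep(names(reps), reps)
  batch <- unlist(lapply(reps, seq_len), use.names = FALSE)
  sample_id <- paste0(condition, "_", batch)
  samples <- data.frame(sample_id = sample_id, condition = condition,
                        batch = batch, stringsAsFactors = FALSE)

  baseline <- stats::rnorm(G, cfg$baseline_logmean_mu, cfg$baseline_logmean_sd)
  dispersion <- stats::rgamma(G, shape = cfg$dispersion_shape,
                              scale = cfg$dispersion_scale)
  dispersion <- pmax(dispersion, 1e-6)

  n_cls <- c(shared = round(G * cfg$frac_shared),
             dh_only = round(G * cfg$frac_dh_only),
             dn_specific = round(G * cfg$frac_dn_specific),
             inactive_shared = round(G * cfg$frac_inactive_shared))
  if (sum(n_cls) > G) n_cls["shared"] <- n_cls["shared"] - (sum(n_cls) - G)
  cls <- rep("null", G)
  idx <- sample.int(G, sum(n_cls))
  cls[idx] <- rep(names(n_cls), n_cls)

  lfc_WT <- lfc_DH <- lfc_DN <- numeric(G)
  i <- cls == "shared"
  b <- stats::rnorm(sum(i), 0, cfg$beta_sd)
  lfc_WT[i] <- b; lfc_DH[i] <- cfg$alpha_amp * b
  i <- cls == "dh_only"
  b <- stats::rnorm(sum(i), 0, cfg$beta_sd / 2)
  lfc_WT[i] <- b; lfc_DH[i] <- cfg$alpha_amp * b
  i <- cls == "dn_specific"
  lfc_DN[i] <- stats::rnorm(sum(i), 0, cfg$beta_sd)
  i <- cls == "inactive_shared"
  b <- stats::rnorm(sum(i), 0, cfg$beta_sd)
  lfc_DH[i] <- b; lfc_DN[i] <- b

  # per-gene, per-replicate-index batch shift shared across conditions
  n_batches <- max(batch)
  delta <- matrix(stats::rnorm(G * n_batches, 0, cfg$batch_sd), G, n_batches)

  lfc_by_cond <- cbind(parental = numeric(G), WT = lfc_WT,
                       DH = lfc_DH, DN = lfc_DN)
  counts <- matrix(0L, G, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- 2^(baseline + lfc_by_cond[, samples$condition[j]] +
               delta[, samples$batch[j]])
    counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / dispersion)
  }

  truth <- data.frame(gene_id = gene_id, class = cls,
                      lfc_WT = lfc_WT, lfc_DH = lfc_DH, lfc_DN = lfc_DN,
                      baseline = baseline, dispersion = dispersion,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth)
}

#' Configuration for the AP-MS label-free intensity simulator
#'
#' Parameters for [simulate_lfq()], which emulates a Myc-tag pull-down
#' experiment quantified by label-free MS: bait samples for the WT, D463H
#' and D463N constructs plus empty-vector controls, in triplicate. Protein
#' classes: `background` (bound by every bait equally), `contaminant`
#' (recovered in control pull-downs), `exclusive_dh` (detected only with the
#' D463H bait) and `preferential_dh` (bound by all baits but enriched with
#' D463H by a true log2 fold change drawn uniformly from
#' `[pref_logfc_low, pref_logfc_high]`).
#'
#' Missing values are explicit `NA`, never zero. Detection failure is
#' intensity dependent: the dropout probability
#' `plogis(dropout_slope * (dropout_midpoint - x))` is non-increasing in the
#' true log2 intensity `x`.
#'
#' @param n_background,n_contaminant,n_exclusive_dh,n_preferential_dh
#'   Protein counts per class.
#' @param bait_reps,control_reps Replicates per bait and for the control.
#' @param base_logint_mu,base_logint_sd Per-protein baseline log2 intensity
#'   distribution.
#' @param pref_logfc_low,pref_logfc_high Range of the true D463H/WT log2
#'   fold change for preferential binders.
#' @param dropout_midpoint,dropout_slope Logistic dropout parameters
#'   (log2-intensity units; slope >= 0).
#' @param dropout Logical; disable to make detection deterministic.
#' @param noise_sd Measurement noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return A validated list of class `"lfq_sim_config"`.
#' @export
lfq_sim_config <- function(n_background = 150,
                           n_contaminant = 40,
                           n_exclusive_dh = 11,
                           n_preferential_dh = 30,
                           bait_reps = 3,
                           control_reps = 3,
                           base_logint_mu = 25,
                           base_logint_sd = 2,
                           pref_logfc_low = 0.5,
                           pref_logfc_high = 2.0,
                           dropout_midpoint = 21,
                           dropout_slope = 0.8,
                           dropout = TRUE,
                           noise_sd = 0.3,
                           seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  counts <- c(n_background, n_contaminant, n_exclusive_dh, n_preferential_dh)
  if (any(counts < 0)) stopf("class counts must be >= 0")
  if (bait_reps < 1 || control_reps < 1)
    stopf("every bait and the control need >= 1 replicate")
  if (dropout_slope < 0) stopf("dropout_slope must be >= 0")
  if (pref_logfc_high < pref_logfc_low)
    stopf("pref_logfc_high must be >= pref_logfc_low")
  class(cfg) <- "lfq_sim_config"
  cfg
}

#' Simulate an AP-MS label-free log2-intensity table with known truth
#'
#' @param cfg An [lfq_sim_config()].
#' @return A list with `intensity` (protein x sample matrix, `NA` = missing),
#'   `samples` (sample_id, bait, replicate) and `truth` (protein_id, class,
#'   true_logfc, base_intensity).
#' @seealso [lfq_sim_config()] for the generative model.
#' @export
simulate_lfq <- function(cfg) {
  stopifnot(inherits(cfg, "lfq_sim_config"))
  set.seed(cfg$seed)
  classes <- rep(c("background", "contaminant", "exclusive_dh",
                   "preferential_dh"),
                 c(cfg$n_background, cfg$n_contaminant, cfg$n_exclusive_dh,
                   cfg$n_preferential_dh))
  P <- length(classes)
  if (P == 0L) stopf("at least one protein class count must be positive")
  protein_id <- sprintf("prot_%04d", seq_len(P))

  baits <- c("control", "WT", "DH", "DN")
  reps <- c(control = cfg$control_reps, WT = cfg$bait_reps,
            DH = cfg$bait_reps, DN = cfg$bait_reps)
  bait <- rep(baits, reps[baits])
  replicate <- unlist(lapply(reps[baits], seq_len), use.names = FALSE)
  sample_id <- paste0(bait, "_", replicate)
  samples <- data.frame(sample_id = sample_id, bait = bait,
                        replicate = replicate, stringsAsFactors = FALSE)

  base <- stats::rnorm(P, cfg$base_logint_mu, cfg$base_logint_sd)
  true_logfc <- rep(NA_real_, P)
  pref <- classes == "preferential_dh"
  true_logfc[pref] <- stats::runif(sum(pref), cfg$pref_logfc_low,
                                   cfg$pref_logfc_high)

  # true intensity per protein x sample; NA = structurally absent
  true_int <- matrix(NA_real_, P, nrow(samples),
                     dimnames = list(protein_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    b <- samples$bait[j]
    x <- rep(NA_real_, P)
    if (b == "control") {
      x[classes == "contaminant"] <- base[classes == "contaminant"]
    } else {
      present <- classes %in% c("background", "contaminant", "preferential_dh")
      if (b == "DH") present <- present | classes == "exclusive_dh"
      x[present] <- base[present]
      if (b == "DH") x[pref] <- base[pref] + true_logfc[pref]
    }
    true_int[, j] <- x
  }

  # contaminants must be recoverable from >= 1 control sample: exempt one
  # control replicate from dropout for them
  p_drop <- matrix(0, P, ncol(true_int))
  if (isTRUE(cfg$dropout))
    p_drop[] <- stats::plogis(cfg$dropout_slope *
                                (cfg$dropout_midpoint - true_int))
  p_drop[is.na(true_int)] <- 0
  first_ctrl <- which(samples$bait == "control")[1]
  p_drop[classes == "contaminant", first_ctrl] <- 0

  drop <- matrix(stats::runif(length(true_int)) < p_drop,
                 P, ncol(true_int))
  obs <- true_int + stats::rnorm(length(true_int), 0, cfg$noise_sd)
  obs[is.na(true_int) | drop] <- NA_real_
  dimnames(obs) <- dimnames(true_int)

  truth <- data.frame(protein_id = protein_id, class = classes,
                      true_logfc = true_logfc, base_intensity = base,
                      stringsAsFactors = FALSE)
  list(intensity = obs, samples = samples, truth = truth)
}

#' Configuration for the predicted-aligned-error ensemble simulator
#'
#' Parameters for [simulate_pae_ensemble()], which emulates the confidence
#' output of a structure-prediction ensemble for a multi-domain kinase. The
#' PAE matrix is built from blocks: the pseudosubstrate rows (X in
#' `[0, 20]`) and the C2-domain rows (X in `[200, 250]`) against the kinase
#' domain columns (Y in `[350, 650]`). In a PS-in (autoinhibited) conformer
#' the pseudosubstrate-kinase block has low error (`contact_pae`) and the
#' C2-kinase block high error (`noncontact_pae`); a PS-out (open) conformer
#' is the reverse. All other entries are `within_domain_pae`. Gaussian noise
#' is added and entries are clipped to the PAE scale `[0, 31.75]`.
#'
#' @param n_res Number of residues (>= 651 so the default regions exist).
#' @param conformer `"PS-in"` or `"PS-out"`.
#' @param within_domain_pae,contact_pae,noncontact_pae Block means in PAE
#'   units (each in `[0, 31.75]`).
#' @param noise_sd Entry-wise Gaussian noise sd.
#' @param n_models Number of models in the ensemble.
#' @param ptm_mu,ptm_sd Distribution of per-model pTM scores (clipped to
#'   `[0, 1]`).
#' @param seed Integer seed.
#' @return A validated list of class `"pae_sim_config"`.
#' @export
pae_sim_config <- function(n_res = 672,
                           conformer = c("PS-in", "PS-out"),
                           within_domain_pae = 8,
                           contact_pae = 5,
                           noncontact_pae = 25,
                           noise_sd = 2,
                           n_models = 10,
                           ptm_mu = 0.75,
                           ptm_sd = 0.05,
                           seed = 1L) {
  conformer <- match.arg(conformer)
  cfg <- list(n_res = as.integer(n_res), conformer = conformer,
              within_domain_pae = within_domain_pae,
              contact_pae = contact_pae, noncontact_pae = noncontact_pae,
              noise_sd = noise_sd, n_models = as.integer(n_models),
              ptm_mu = ptm_mu, ptm_sd = ptm_sd, seed = as.integer(seed))
  if (cfg$n_res < 651)
    stopf("n_res must be >= 651 so the default region indices exist (got %d)",
          cfg$n_res)
  blocks <- c(within_domain_pae, contact_pae, noncontact_pae)
  if (any(blocks < 0 | blocks > 31.75))
    stopf("block means must lie in [0, 31.75]")
  if (cfg$n_models < 1) stopf("n_models must be >= 1")
  class(cfg) <- "pae_sim_config"
  cfg
}

#' Simulate an ensemble of PAE models for one conformer class
#'
#' @param cfg A [pae_sim_config()].
#' @return A list with `models` (list of [pae_model()] objects) and `labels`
#'   (the true conformer of every model).
#' @export
simulate_pae_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "pae_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_res
  ps_rows <- 0:20; c2_rows <- 200:250; kin_cols <- 350:650  # 0-based
  base <- matrix(cfg$within_domain_pae, n, n)
  if (cfg$conformer == "PS-in") {
    base[ps_rows + 1, kin_cols + 1] <- cfg$contact_pae
    base[kin_cols + 1, ps_rows + 1] <- cfg$contact_pae
    base[c2_rows + 1, kin_cols + 1] <- cfg$noncontact_pae
    base[kin_cols + 1, c2_rows + 1] <- cfg$noncontact_pae
  } else {
    base[ps_rows + 1, kin_cols + 1] <- cfg$noncontact_pae
    base[kin_cols + 1, ps_rows + 1] <- cfg$noncontact_pae
    base[c2_rows + 1, kin_cols + 1] <- cfg$contact_pae
    base[kin_cols + 1, c2_rows + 1] <- cfg$contact_pae
  }
  diag(base) <- 0
  models <- vector("list", cfg$n_models)
  for (k in seq_len(cfg$n_models)) {
    pae <- base + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
    pae <- pmin(pmax(pae, 0), 31.75)
    ptm <- min(max(stats::rnorm(1, cfg$ptm_mu, cfg$ptm_sd), 0), 1)
    models[[k]] <- pae_model(pae, ptm = ptm,
                             model_id = sprintf("%s_model_%03d",
                                                cfg$conformer, k))
  }
  list(models = models, labels = rep(cfg$conformer, cfg$n_models))
}

#' Simulate gene-set collections with planted enrichment
#'
#' Random sets are uniform draws from the universe; enriched sets draw
#' `enrich_frac` of their members from genes with a positive true D463H
#' log2 fold change, so a preranked enrichment analysis on the D463H
#' contrast should flag them.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Total number of sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param n_enriched_sets Number of sets with planted signal (<= n_sets).
#' @param truth Truth table from [simulate_counts()] (needs `gene_id`,
#'   `lfc_DH`), required when `n_enriched_sets > 0`.
#' @param enrich_frac Fraction of an enriched set drawn from up-regulated
#'   genes.
#' @param seed Integer seed.
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors) and `description` (named character; `"enriched"` or
#'   `"random"`).
#' @export
simulate_genesets <- function(universe, n_sets = 20, size_range = c(10, 50),
                              n_enriched_sets = 0, truth = NULL,
                              enrich_frac = 0.8, seed = 1L) {
  if (length(universe) == 0) stopf("universe must be nonempty")
  universe <- unique(as.character(universe))
  if (max(size_range) > length(universe))
    stopf("requested set size %d exceeds universe size %d",
          max(size_range), length(universe))
  if (n_enriched_sets > n_sets) stopf("n_enriched_sets must be <= n_sets")
  if (n_enriched_sets > 0 && is.null(truth))
    stopf("truth table required to plant enriched sets")
  set.seed(as.integer(seed))
  up <- character(0)
  if (!is.null(truth))
    up <- intersect(truth$gene_id[truth$lfc_DH > 0], universe)
  sets <- list(); descr <- character(0)
  for (k in seq_len(n_sets)) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    if (k <= n_enriched_sets) {
      n_up <- min(round(enrich_frac * sz), length(up))
      members <- c(sample(up, n_up),
                   sample(setdiff(universe, up), sz - n_up))
      nm <- sprintf("enriched_%02d", k); descr[nm] <- "enriched"
    } else {
      members <- sample(universe, sz)
      nm <- sprintf("random_%02d", k - n_enriched_sets); descr[nm] <- "random"
    }
    sets[[nm]] <- unique(members)
  }
  gene_set_collection(sets, descr)
}

#' Write simulated RNA-seq outputs as TSV
#'
#' Writes `counts.tsv` (first column `gene_id`), `samples.tsv`
#' (`sample_id`, `condition`, `batch`) and `truth.tsv` under `dir`.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_counts_tsv <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a count matrix and sample metadata written by [write_counts_tsv()]
#'
#' @param counts_path,samples_path Paths to the two TSV files.
#' @return A list with `counts` and `samples` as in [simulate_counts()].
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  counts <- read_matrix_tsv(counts_path)
  storage.mode(counts) <- "integer"
  samples <- read_tsv(samples_path)
  if (!all(colnames(counts) == samples$sample_id))
    stopf("sample ids in counts and metadata disagree")
  list(counts = counts, samples = samples)
}
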