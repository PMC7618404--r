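# Default pipeline configuration. validate_config() fills these and rejects
# any key not present here.
pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "alleleaugment_out",
    alpha = 0.05,
    rnaseq = list(
      n_genes = 2000, reps_parental = 3, reps_WT = 2, reps_DH = 3,
      reps_DN = 3, baseline_logmean_mu = 7, baseline_logmean_sd = 2,
      dispersion_shape = 2, dispersion_scale = 0.025,
      frac_shared = 0.1, frac_dh_only = 0.2, frac_dn_specific = 0.05,
      frac_inactive_shared = 0.05, beta_sd = 1, alpha_amp = 2,
      batch_sd = 0.2),
    de = list(batch = TRUE),
    patterns = list(cluster = "DH_only"),
    gsea = list(enabled = TRUE, n_sets = 20, n_enriched_sets = 5,
                size_min = 10, size_max = 50, nperm = 1000,
                min_size = 5, max_size = 500),
    interactome = list(enabled = TRUE, n_background = 150,
                       n_contaminant = 40, n_exclusive_dh = 11,
                       n_preferential_dh = 30, bait_reps = 3,
                       control_reps = 3, noise_sd = 0.3,
                       min_dh_detect = 2, preferential_logfc = 0.5),
    conformer = list(enabled = TRUE, n_models = 20, noise_sd = 2,
                     frac_ps_in_WT = 0.9, frac_ps_in_DH = 0.1,
                     frac_ps_in_DN = 0.2)
  )
}

merge_block <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown configuration key '%s%s'", path, unknown[1])
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      if (!is.list(user[[nm]]))
        stopf("configuration key '%s%s' must be a block", path, nm)
      defaults[[nm]] <- merge_block(defaults[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults (alpha 0.05, preferential
#' log2 fold-change threshold 0.5, 1000 GSEA permutations, ...), and
#' rejects any key not in the documented schema, naming the offender.
#' Validation is deterministic: the same file always yields the same
#' normalized configuration.
#'
#' @param path Path to a YAML file (may be empty or contain any subset of
#'   the schema).
#' @return A normalized configuration list of class `"pipeline_config"`.
#' @export
validate_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_block(pipeline_defaults(), user, "")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(report, name, deps, fun) {
  for (d in deps) {
    st <- report$stages[[d]]$status %||% "missing"
    if (st != "ok") {
      report$stages[[name]] <- list(status = "skipped",
                                    reason = sprintf("dependency '%s' %s",
                                                     d, st))
      return(report)
    }
  }
  res <- tryCatch(fun(), error = function(e)
    structure(list(message = conditionMessage(e)), class = "stage_error"))
  if (inherits(res, "stage_error")) {
    report$stages[[name]] <- list(status = "failed", error = res$message)
  } else {
    report$stages[[name]] <- c(list(status = "ok"), res)
  }
  report
}

#' Run the full synthetic multi-omic pipeline from a configuration
#'
#' Executes, in dependency order: count simulation, differential
#' expression of the three conditions against parental (batch as a model
#' covariate), pattern assignment with the concordance/amplitude summary,
#' gene-set simulation plus preranked GSEA, the AP-MS interactome track
#' and the conformer track. All tabular outputs are written as TSV under
#' the configured output directory, and a machine-readable JSON report of
#' per-stage parameters and key results is written alongside. Every
#' stochastic stage draws its seed deterministically from the global seed
#' via [stage_seed()], so a rerun with the same configuration reproduces
#' byte-identical outputs. A failed stage is recorded in the report and
#' its dependents are skipped.
#'
#' @param cfg A `"pipeline_config"` from [validate_config()].
#' @return The run report (list of class `"run_report"`), invisibly;
#'   the same content is written to `<outdir>/report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, alpha = cfg$alpha, stages = list())
  env <- new.env(parent = emptyenv())

  report <- run_stage(report, "rnaseq", character(0), function() {
    rc <- cfg$rnaseq
    sim <- simulate_counts(rna_sim_config(
      n_genes = rc$n_genes,
      reps_per_condition = c(parental = rc$reps_parental, WT = rc$reps_WT,
                             DH = rc$reps_DH, DN = rc$reps_DN),
      baseline_logmean_mu = rc$baseline_logmean_mu,
      baseline_logmean_sd = rc$baseline_logmean_sd,
      dispersion_shape = rc$dispersion_shape,
      dispersion_scale = rc$dispersion_scale,
      frac_shared = rc$frac_shared, frac_dh_only = rc$frac_dh_only,
      frac_dn_specific = rc$frac_dn_specific,
      frac_inactive_shared = rc$frac_inactive_shared,
      beta_sd = rc$beta_sd, alpha_amp = rc$alpha_amp,
      batch_sd = rc$batch_sd,
      seed = stage_seed(cfg$seed, "rnaseq")))
    write_counts_tsv(sim, out)
    env$sim <- sim
    list(n_genes = rc$n_genes,
         n_samples = nrow(sim$samples),
         class_counts = as.list(table(sim$truth$class)))
  })

  report <- run_stage(report, "de", "rnaseq", function() {
    sim <- env$sim
    sf <- estimate_size_factors(sim$counts)
    disp <- estimate_dispersions(sim$counts, sf, sim$samples$condition)
    batch <- if (isTRUE(cfg$de$batch)) "batch" else NULL
    contrasts <- list()
    for (cond in c("WT", "DH", "DN")) {
      ct <- nb_wald_test(sim$counts, sim$samples, sf, disp,
                         condition_a = cond, condition_b = "parental",
                         batch = batch)
      write_tsv(ct, file.path(out, sprintf("de_%s.tsv", cond)))
      contrasts[[cond]] <- ct
    }
    env$contrasts <- contrasts
    env$sf <- sf
    n_sig <- vapply(contrasts, function(ct)
      sum(!is.na(ct$padj) & ct$padj < cfg$alpha), 0)
    list(batch_covariate = isTRUE(cfg$de$batch),
         n_significant = as.list(n_sig))
  })

  report <- run_stage(report, "patterns", "de", function() {
    assign <- assign_patterns(env$contrasts, alpha = cfg$alpha)
    write_tsv(assign, file.path(out, "patterns.tsv"))
    cs <- concordance_summary(assign, cfg$patterns$cluster)
    jsonlite::write_json(
      list(cluster = cs$cluster, n_genes = cs$n_genes,
           n_na_excluded = cs$n_na_excluded,
           frac_same_direction = cs$frac_same_direction,
           mean_abs_lfc = as.list(cs$mean_abs_lfc),
           amplitude_ratio = cs$amplitude_ratio),
      file.path(out, "concordance.json"), auto_unbox = TRUE, digits = NA)
    sizes <- table(assign$pattern)
    list(cluster = cs$cluster,
         cluster_sizes = as.list(sizes),
         frac_same_direction = cs$frac_same_direction,
         amplitude_ratio = cs$amplitude_ratio)
  })

  if (isTRUE(cfg$gsea$enabled))
  report <- run_stage(report, "gsea", c("rnaseq", "de"), function() {
    gc <- cfg$gsea
    coll <- simulate_genesets(env$sim$truth$gene_id, n_sets = gc$n_sets,
                              size_range = c(gc$size_min, gc$size_max),
                              n_enriched_sets = gc$n_enriched_sets,
                              truth = env$sim$truth,
                              seed = stage_seed(cfg$seed, "genesets"))
    write_gmt(coll, file.path(out, "sets.gmt"))
    ranked <- rank_genes(env$contrasts$DH)
    gr <- gsea_preranked(ranked, coll, n_perm = gc$nperm,
                         seed = stage_seed(cfg$seed, "gsea"),
                         min_size = gc$min_size, max_size = gc$max_size)
    write_tsv(gr$results, file.path(out, "gsea.tsv"))
    top <- gr$results[order(gr$results$pval), ]
    list(n_sets = nrow(gr$results),
         n_skipped = length(gr$skipped),
         top_sets = as.list(utils::head(top$set, 3)),
         top_pvals = as.list(utils::head(top$pval, 3)))
  })

  if (isTRUE(cfg$interactome$enabled))
  report <- run_stage(report, "interactome", character(0), function() {
    ic <- cfg$interactome
    sim <- simulate_lfq(lfq_sim_config(
      n_background = ic$n_background, n_contaminant = ic$n_contaminant,
      n_exclusive_dh = ic$n_exclusive_dh,
      n_preferential_dh = ic$n_preferential_dh,
      bait_reps = ic$bait_reps, control_reps = ic$control_reps,
      noise_sd = ic$noise_sd,
      seed = stage_seed(cfg$seed, "interactome")))
    write_lfq_tsv(sim$intensity, sim$samples, out)
    calls <- call_interactors(sim$intensity, sim$samples,
                              min_dh_detect = ic$min_dh_detect,
                              preferential_logfc = ic$preferential_logfc,
                              alpha = cfg$alpha)
    write_tsv(calls$table, file.path(out, "interactors.tsv"))
    writeLines(calls$string_query, file.path(out, "string_query.txt"))
    as.list(calls$summary)
  })

  if (isTRUE(cfg$conformer$enabled))
  report <- run_stage(report, "conformer", character(0), function() {
    cc <- cfg$conformer
    res <- list()
    for (construct in c("WT", "DH", "DN")) {
      frac_in <- cc[[paste0("frac_ps_in_", construct)]]
      n_in <- round(cc$n_models * frac_in)
      n_out <- cc$n_models - n_in
      models <- list(); labels <- character(0)
      if (n_in > 0) {
        e <- simulate_pae_ensemble(pae_sim_config(
          conformer = "PS-in", n_models = n_in, noise_sd = cc$noise_sd,
          seed = stage_seed(cfg$seed, paste0("conformer_in_", construct))))
        models <- c(models, e$models); labels <- c(labels, e$labels)
      }
      if (n_out > 0) {
        e <- simulate_pae_ensemble(pae_sim_config(
          conformer = "PS-out", n_models = n_out, noise_sd = cc$noise_sd,
          seed = stage_seed(cfg$seed, paste0("conformer_out_", construct))))
        models <- c(models, e$models); labels <- c(labels, e$labels)
      }
      calls <- lapply(models, classify_conformer)
      summ <- summarize_ensemble(calls, construct = construct)
      tab <- summ$calls_table
      tab$construct <- construct
      tab$true_label <- labels
      res[[construct]] <- list(summary = summ, table = tab)
    }
    all_tab <- do.call(rbind, lapply(res, `[[`, "table"))
    rownames(all_tab) <- NULL
    write_tsv(all_tab, file.path(out, "conformer_calls.tsv"))
    fr <- lapply(res, function(r)
      list(n_models = r$summary$n_models,
           frac_ps_in = r$summary$frac_ps_in,
           frac_ps_out = r$summary$frac_ps_out,
           n_ambiguous = r$summary$n_ambiguous))
    jsonlite::write_json(fr, file.path(out, "conformer_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fr
  })

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d):\n", x$seed))
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}

#' Did every executed pipeline stage succeed?
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return `TRUE` when no stage failed.
#' @export
pipeline_ok <- function(report) {
  !any(vapply(report$stages, function(s) identical(s$status, "failed"),
              logical(1)))
}
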