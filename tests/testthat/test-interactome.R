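test_that("detection counts match hand tallies and respect bounds", {
  fx <- lfq_fixture_12()
  det <- call_detection(fx$intensity, fx$samples)
  expect_equal(unname(det["P01", c("control", "WT", "DH", "DN")]),
               c(1L, 3L, 3L, 3L))
  expect_equal(unname(det["P04", c("control", "WT", "DH", "DN")]),
               c(0L, 0L, 1L, 0L))
  reps <- table(fx$samples$bait)
  for (b in colnames(det)) expect_true(all(det[, b] <= reps[[b]]))

  all_na <- matrix(NA_real_, 2, 11,
                   dimnames = list(c("a", "b"), fx$samples$sample_id))
  expect_true(all(call_detection(all_na, fx$samples) == 0))

  bad <- fx$samples; bad$bait[1] <- "mock"
  expect_error(call_detection(fx$intensity, bad), "unknown bait")
})

test_that("the 12-protein fixture partitions exactly as hand-derived", {
  fx <- lfq_fixture_12()
  calls <- call_interactors(fx$intensity, fx$samples)
  expect_setequal(calls$artefacts, fx$expected$artefacts)
  expect_setequal(calls$single_sample, fx$expected$single_sample)
  expect_setequal(calls$table$protein_id, fx$expected$retained)
  expect_setequal(calls$table$protein_id[calls$table$exclusive_dh],
                  fx$expected$exclusive)
  expect_setequal(calls$table$protein_id[calls$table$preferential_dh],
                  fx$expected$preferential)
  expect_setequal(calls$string_query, fx$expected$preferential)

  # boundary: a log fold change of exactly 0.5 is not preferential
  p10 <- calls$table[calls$table$protein_id == "P10", ]
  expect_equal(p10$logfc_dh_vs_wt, 0.5, tolerance = 1e-12)
  expect_false(p10$preferential_dh)
})

test_that("filters applied twice are idempotent", {
  fx <- lfq_fixture_12()
  f1 <- filter_artefacts(fx$intensity, fx$samples)
  f1b <- filter_artefacts(f1$intensity, fx$samples)
  expect_equal(f1b$intensity, f1$intensity)
  expect_length(f1b$removed, 0)
  f2 <- filter_single_sample(f1$intensity, fx$samples)
  f2b <- filter_single_sample(f2$intensity, fx$samples)
  expect_equal(f2b$intensity, f2$intensity)
  expect_length(f2b$removed, 0)
  expect_error(filter_artefacts(fx$intensity, data.frame(
    sample_id = fx$samples$sample_id, bait = rep("WT", 11))), "control")
})

test_that("imputation fills below the observed minimum, deterministically", {
  m <- rbind(a = c(21, NA, 25), b = c(20, 24, NA))
  imp <- impute_missing(m)
  expect_equal(unname(imp$intensity[1, 2]), 19)
  expect_equal(unname(imp$intensity[2, 3]), 19)
  expect_equal(sum(imp$mask), 2)
  expect_equal(imp$intensity[!imp$mask], m[!is.na(m)])

  # complete table: identity with empty mask
  full <- matrix(1:6 + 20, 2, 3)
  imp2 <- impute_missing(full)
  expect_equal(imp2$intensity, full)
  expect_false(any(imp2$mask))

  # imputed strictly below every observed value, over random tables
  set.seed(3)
  for (i in 1:10) {
    x <- matrix(rnorm(40, 25, 3), 8, 5)
    x[sample(40, 10)] <- NA
    im <- impute_missing(x)
    expect_lt(max(im$intensity[im$mask]), min(x, na.rm = TRUE))
  }
  expect_error(impute_missing(matrix(NA_real_, 2, 2)), "observed")
})

test_that("exclusive and preferential calls follow the decision rules", {
  det <- rbind(a = c(control = 0L, WT = 0L, DH = 3L, DN = 1L),
               b = c(0L, 0L, 1L, 0L),
               c = c(0L, 1L, 3L, 0L))
  ex <- call_exclusive(det, n_dh_reps = 3, min_dh_detect = 2)
  expect_equal(unname(ex), c(TRUE, FALSE, FALSE))
  expect_error(call_exclusive(det, n_dh_reps = 3, min_dh_detect = 4),
               "exceeds")
  # DN veto when requested
  ex2 <- call_exclusive(det, n_dh_reps = 3, ignore_dn = FALSE)
  expect_false(ex2[["a"]])

  samples <- data.frame(sample_id = paste0("s", 1:6),
                        bait = rep(c("WT", "DH"), each = 3))
  m <- rbind(p1 = c(20, 20, 20, 20.6, 20.6, 20.6),
             p2 = c(20, 20, 20, 20.5, 20.5, 20.5),
             p3 = c(20, 20, 20, 20.3, 20.3, 20.3))
  pref <- call_preferential(m, samples, c(FALSE, FALSE, TRUE))
  expect_equal(pref$preferential_dh, c(TRUE, FALSE, TRUE))
  expect_equal(pref$logfc_dh_vs_wt, c(0.6, 0.5, 0.3), tolerance = 1e-9)
  # exclusivity always implies preference
  expect_true(all(pref$preferential_dh[pref$exclusive_dh]))
})

test_that("Welch test matches closed form and is calibrated under the null", {
  a <- c(24.1, 25.3, 24.8); b <- c(23.2, 23.9, 23.5)
  m <- rbind(p = c(a, b))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        bait = rep(c("DH", "WT"), each = 3))
  res <- differential_abundance(m, samples)
  oracle <- t.test(a, b)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(oracle$parameter), tolerance = 1e-9)
  expect_equal(res$pval, oracle$p.value, tolerance = 1e-9)

  # identical replicate vectors: t = 0, p = 1
  m2 <- rbind(p = rep(c(24, 25, 26), 2))
  res2 <- differential_abundance(m2, samples)
  expect_equal(res2$t, 0)
  expect_equal(res2$pval, 1)

  # null calibration over 2000 proteins
  set.seed(17)
  null_m <- matrix(rnorm(2000 * 6, 25, 0.5), 2000, 6,
                   dimnames = list(sprintf("q%04d", 1:2000), samples$sample_id))
  res3 <- differential_abundance(null_m, samples)
  expect_gt(mean(res3$pval < 0.05), 0.03)
  expect_lt(mean(res3$pval < 0.05), 0.07)

  # fully imputed on both sides: excluded from testing
  mask <- matrix(FALSE, 1, 6)
  mask[1, ] <- TRUE
  res4 <- differential_abundance(m2, samples, mask = mask)
  expect_true(is.na(res4$pval))
  expect_equal(attr(res4, "excluded"), "p")

  expect_error(differential_abundance(m2, data.frame(
    sample_id = paste0("s", 1:6), bait = c("DH", rep("WT", 5)))), "replicates")
})

test_that("overview clusters replicate structure and counts presence", {
  set.seed(23)
  # DH close to WT, DN far away: DH/WT join before DN
  base <- rnorm(40, 25, 1)
  mk <- function(shift, n = 2) replicate(n, base + shift + rnorm(40, 0, 0.1))
  m <- cbind(mk(0), mk(0.2), mk(5))
  colnames(m) <- c("WT_1", "WT_2", "DH_1", "DH_2", "DN_1", "DN_2")
  rownames(m) <- sprintf("p%02d", 1:40)
  samples <- data.frame(sample_id = colnames(m),
                        bait = rep(c("WT", "DH", "DN"), each = 2),
                        replicate = rep(1:2, 3))
  det <- call_detection(m, samples)
  ov <- interactome_overview(m, samples, det)
  hc <- ov$sample_hclust
  # the last merge separates the DN pair from the WT/DH block
  dn_idx <- which(samples$bait == "DN")
  last <- hc$merge[nrow(hc$merge), ]
  clusters <- cutree(hc, 2)
  expect_equal(length(unique(clusters[dn_idx])), 1)
  expect_true(all(clusters[dn_idx] != clusters[samples$bait != "DN"]))

  # duplicated sample: identical PCA coordinates
  m2 <- cbind(m, DN_3 = m[, "DN_2"])
  samples2 <- rbind(samples, data.frame(sample_id = "DN_3", bait = "DN",
                                        replicate = 3))
  ov2 <- interactome_overview(m2, samples2, call_detection(m2, samples2))
  expect_equal(ov2$pca$scores["DN_2", ], ov2$pca$scores["DN_3", ],
               ignore_attr = TRUE)

  # overlap rows sum to the number of baits detecting the protein
  fx <- lfq_fixture_12()
  det_fx <- call_detection(fx$intensity, fx$samples)
  ov3 <- interactome_overview(impute_missing(fx$intensity)$intensity,
                              fx$samples, det_fx)
  nonctrl <- setdiff(colnames(det_fx), "control")
  expect_equal(rowSums(ov3$overlap)[rownames(det_fx)],
               rowSums(det_fx[, nonctrl] > 0)[rownames(det_fx)])
})

test_that("synthetic LFQ recovery: exclusive implies preferential everywhere", {
  sim <- simulate_lfq(lfq_sim_config(seed = 42))
  calls <- call_interactors(sim$intensity, sim$samples)
  tab <- calls$table
  expect_true(all(tab$preferential_dh[tab$exclusive_dh]))
  # no contaminant survives the artefact filter
  cont <- sim$truth$protein_id[sim$truth$class == "contaminant"]
  expect_length(intersect(cont, tab$protein_id), 0)
})
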