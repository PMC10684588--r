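test_that("cohort shape matches the configured design and is seed-deterministic", {
  cfg <- quick_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)

  # 14 patients x (1 primary) + 24 metastases = 38 samples
  expect_equal(nrow(a$samples), 38L)
  expect_equal(sum(a$samples$tissue_type == "primary"), 14L)
  expect_equal(sum(a$samples$tissue_type == "metastasis"), 24L)
  expect_equal(dplyr::n_distinct(a$samples$patient_id), 14L)
  per_pat <- table(a$samples$patient_id[a$samples$tissue_type == "metastasis"])
  expect_true(all(per_pat >= 1 & per_pat <= 4))

  expect_equal(nrow(a$matrix), cfg$n_proteins)
  expect_setequal(a$truth$de_proteins$protein_id, intersect(a$truth$de_proteins$protein_id, protein_ids(a$matrix)))
  expect_length(intersect(a$truth$de_proteins$protein_id, a$truth$cluster_proteins), 0)
  expect_equal(sort(unique(a$truth$cluster_labels$cluster)), seq_len(cfg$n_clusters))

  d <- simulate_cohort(quick_config(seed = 12))
  expect_false(identical(a$matrix, d$matrix))
})

test_that("invalid configurations are refused with the offending field named", {
  expect_error(sim_config(mar_rate = 1.5), "mar_rate")
  expect_error(sim_config(mnar_slope = -1), "mnar_slope")
  expect_error(sim_config(n_proteins = 10, n_de_proteins = 8, n_cluster_proteins = 8),
               "n_de_proteins")
  expect_error(sim_config(n_patients = 2, metastases_per_patient = c(1, 2),
                          total_metastases = 10), "total_metastases")
  expect_error(sim_config(metastases_per_patient = c(3, 1)), "metastases_per_patient")
})

test_that("null cohorts carry zero planted effect, empirically and in the truth", {
  cfg0 <- quick_config(de_effect = 0, sample_offset_sd = 0, seed = 1)
  co <- simulate_cohort(cfg0, with_missingness = FALSE)
  expect_true(all(co$truth$de_proteins$effect == 0))

  # Monte-Carlo: mean log2 difference of planted ids over repeated cohorts ~ 0
  diffs <- vapply(1:50, function(s) {
    co <- simulate_cohort(quick_config(de_effect = 0, sample_offset_sd = 0, seed = s),
                          with_missingness = FALSE)
    v <- log2(as.matrix(co$matrix[, -1]))
    rownames(v) <- co$matrix$protein_id
    is_met <- co$samples$tissue_type == "metastasis"
    mean(rowMeans(v[co$truth$de_proteins$protein_id, is_met, drop = FALSE]) -
           rowMeans(v[co$truth$de_proteins$protein_id, !is_met, drop = FALSE]))
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("planted log2 fold changes are recovered on complete data", {
  # per-protein mean |log2 difference| over repeated cohorts is close to the
  # planted 1.0 effect (signs vary per protein)
  effs <- unlist(lapply(1:40, function(s) {
    co <- simulate_cohort(quick_config(de_effect = 1, sample_offset_sd = 0, seed = 100 + s),
                          with_missingness = FALSE)
    v <- log2(as.matrix(co$matrix[, -1]))
    rownames(v) <- co$matrix$protein_id
    is_met <- co$samples$tissue_type == "metastasis"
    ids <- co$truth$de_proteins$protein_id
    sgn <- sign(co$truth$de_proteins$effect)
    (rowMeans(v[ids, is_met, drop = FALSE]) - rowMeans(v[ids, !is_met, drop = FALSE])) * sgn
  }))
  expect_lt(abs(mean(effs) - 1.0), 0.1)
})

test_that("missingness follows the dropout model", {
  cfg <- quick_config(seed = 5)
  full <- simulate_cohort(cfg, with_missingness = FALSE)$matrix

  # degenerate regimes
  none <- inject_missingness(full, quick_config(mar_rate = 0, mnar_slope = 0, seed = 5))
  expect_identical(as.matrix(none[, -1]), as.matrix(full[, -1]))
  all_gone <- inject_missingness(full, quick_config(mar_rate = 1, seed = 5))
  expect_true(all(is.na(all_gone[, -1])))

  # already-missing input refused
  expect_error(inject_missingness(all_gone, cfg), "already contains missing")

  # MNAR: dropout concentrates in the low-intensity decile (20 seeds)
  lowhigh <- vapply(1:20, function(s) {
    co <- simulate_cohort(quick_config(mar_rate = 0, mnar_slope = 2, seed = 200 + s,
                                       de_effect = 0, n_clusters = 0),
                          with_missingness = FALSE)
    v <- as.matrix(co$matrix[, -1])
    cfg_s <- quick_config(mar_rate = 0, mnar_slope = 2,
                          mnar_midpoint = stats::quantile(log2(v), 0.10),
                          seed = 200 + s)
    miss <- is.na(as.matrix(inject_missingness(co$matrix, cfg_s)[, -1]))
    deciles <- cut(log2(v), stats::quantile(log2(v), c(0, 0.1, 0.9, 1)),
                   include.lowest = TRUE, labels = c("low", "mid", "high"))
    c(mean(miss[deciles == "low"]), mean(miss[deciles == "high"]))
  }, numeric(2))
  expect_true(all(lowhigh[1, ] > lowhigh[2, ]))

  # marginal dropout rate matches the analytic expectation of the formula
  rates <- vapply(1:50, function(s) {
    co <- simulate_cohort(quick_config(seed = 300 + s), with_missingness = FALSE)
    v <- as.matrix(co$matrix[, -1])
    cfg_s <- quick_config(seed = 300 + s)
    p_expect <- mean(proteopipe:::dropout_probability(log2(v), cfg_s))
    p_obs <- mean(is.na(as.matrix(inject_missingness(co$matrix, cfg_s)[, -1])))
    p_obs - p_expect
  }, numeric(1))
  expect_lt(abs(mean(rates)), 0.02)
})
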