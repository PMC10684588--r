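# two well-separated sample blocks for consensus tests
blocky_matrix <- function(n_prot = 40, n_per = 5, sep = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(abs(rnorm(n_prot * 2 * n_per, 10, 0.3)), n_prot)
  v[1:(n_prot / 2), 1:n_per] <- v[1:(n_prot / 2), 1:n_per] + sep
  v[(n_prot / 2 + 1):n_prot, (n_per + 1):(2 * n_per)] <-
    v[(n_prot / 2 + 1):n_prot, (n_per + 1):(2 * n_per)] + sep
  dimnames(v) <- list(sprintf("P%03d", 1:n_prot), sprintf("S%02d", 1:(2 * n_per)))
  v
}

test_that("NMF multiplicative updates are monotone, seeded, and exact on rank-1 input", {
  set.seed(2)
  w <- runif(30, 1, 2); h <- runif(8, 1, 2)
  V <- outer(w, h)
  fit <- nmf_fit(V, 1, seed = 5, max_iter = 2000, tol = 1e-12)
  expect_lt(sqrt(fit$error) / sqrt(sum(V^2)), 1e-6)

  V2 <- matrix(runif(200), 20, 10)
  f1 <- nmf_fit(V2, 3, seed = 9)
  f2 <- nmf_fit(V2, 3, seed = 9)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
  expect_true(all(diff(f1$error_trace) <= 1e-8 * f1$error_trace[1]))

  expect_error(nmf_fit(matrix(c(-1, 1, 1, 1), 2), 1), "negative")
  expect_error(nmf_fit(V2, 10), "k must satisfy")
})

test_that("consensus matrices are symmetric, unit-diagonal, and exact on separated blocks", {
  V <- blocky_matrix()
  cr <- consensus_cluster(V, k = 2, n_runs = 10, seed = 3)
  C <- cr$consensus
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(V)))
  # perfectly separated blocks -> exact 0/1 consensus
  ideal <- outer(rep(1:2, each = 5), rep(1:2, each = 5), "==") * 1
  expect_equal(unname(C), unname(ideal))
  expect_equal(cr$dispersion, 1)
  expect_equal(cr$cophenetic, 1)
  expect_equal(dplyr::n_distinct(cr$labels$cluster), 2L)
  expect_error(consensus_cluster(V, 2, n_runs = 1), "n_runs")
})

test_that("dispersion follows its closed form", {
  expect_equal(dispersion(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(dispersion(matrix(c(1, 0.5, 0.5, 1), 2)), 0.5)
  expect_equal(dispersion(matrix(0.5, 3, 3)), 0)
  n <- 6
  ideal <- outer(rep(1:3, each = 2), rep(1:3, each = 2), "==") * 1
  expect_equal(dispersion(ideal), 1)
})

test_that("cophenetic correlation matches a brute-force UPGMA oracle", {
  ideal <- outer(rep(1:3, each = 3), rep(1:3, each = 3), "==") * 1
  expect_equal(cophenetic_correlation(ideal), 1.0)
  expect_warning(got <- cophenetic_correlation(matrix(0.5, 3, 3) + diag(0.5, 3)),
                 "zero variance")
  expect_true(is.na(got))

  set.seed(11)
  for (i in 1:5) {
    A <- matrix(runif(64), 8, 8)
    C <- (A + t(A)) / 2
    diag(C) <- 1
    expect_equal(cophenetic_correlation(C), oracle_cophenetic(C), tolerance = 1e-12)
  }
})

test_that("rank selection applies the dual-local-maximum rule with fallback", {
  tab <- tibble::tibble(k = 2:6,
                        cophenetic = c(0.80, 0.85, 0.99, 0.90, 0.88),
                        dispersion = c(0.5, 0.6, 0.9, 0.7, 0.6))
  expect_equal(select_rank(tab), 4L)
  dec <- tibble::tibble(k = 2:6, cophenetic = seq(0.9, 0.5, -0.1),
                        dispersion = seq(0.8, 0.4, -0.1))
  expect_warning(k <- select_rank(dec), "no rank")
  expect_equal(k, 2L)
  expect_warning(k2 <- select_rank(dec[1:2, ]), "fewer than 3")
  expect_equal(k2, 2L)
  # smallest qualifying k wins on multiple peaks
  two <- tibble::tibble(k = 2:8,
                        cophenetic = c(0.7, 0.9, 0.7, 0.95, 0.7, 0.9, 0.6),
                        dispersion = c(0.4, 0.8, 0.5, 0.9, 0.5, 0.8, 0.4))
  expect_equal(select_rank(two), 3L)
})

test_that("relevance scores follow the entropy formula and its invariances", {
  W <- rbind(onehot = c(8, 0), uniform = c(5, 5), skew = c(3, 1))
  rs <- relevance_scores(W, percentile = 90)
  expect_equal(rs$score[rs$protein_id == "onehot"], 1)
  expect_equal(rs$score[rs$protein_id == "uniform"], 0)
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(rs$score[rs$protein_id == "skew"], 1 - h, tolerance = 1e-10)

  # scores in [0,1]; invariant to row rescaling
  set.seed(4)
  W2 <- matrix(runif(60), 20, 3)
  r1 <- relevance_scores(W2)
  expect_true(all(r1$score >= 0 & r1$score <= 1))
  r2 <- relevance_scores(W2 * rep(runif(20, 0.1, 10), 3))
  expect_equal(r1$score, r2$score, tolerance = 1e-12)

  # strict > on the linear-interpolation percentile
  thr <- attr(r1, "threshold")
  expect_equal(thr, unname(quantile(r1$score, 0.9, type = 7)))
  expect_setequal(r1$protein_id[r1$selected], r1$protein_id[r1$score > thr])

  expect_warning(rz <- relevance_scores(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_equal(rz$score[1], 0)
  expect_error(relevance_scores(matrix(1, 3, 1)), "k >= 2")
})

test_that("PCA embedding matches an eigendecomposition oracle and handles imputation", {
  set.seed(6)
  v <- matrix(rnorm(200, 15, 2), 20, 10)
  dimnames(v) <- list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:10))
  m <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v),
                                           protein_id = rownames(v), .before = 1), "log2")
  pe <- pca_embed(m, n_components = 3)
  want <- oracle_pca_scores(t(v), 3)
  for (j in 1:3) {
    got <- pe$scores[[j + 1]]
    expect_true(max(abs(got - want$scores[, j])) < 1e-8 ||
                  max(abs(got + want$scores[, j])) < 1e-8)
  }
  expect_equal(pe$explained_variance, want$explained[1:3], tolerance = 1e-10)

  # collinear samples: one component explains everything
  line <- outer(runif(5, 1, 2), seq(0, 9))
  dimnames(line) <- list(paste0("P", 1:5), paste0("S", 1:10))
  ml <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(line),
                                            protein_id = rownames(line), .before = 1), "log2")
  pl <- pca_embed(ml, n_components = 2)
  expect_equal(pl$explained_variance[1], 1, tolerance = 1e-12)

  # unimputed embedding restricts to complete proteins
  v2 <- v; v2[1:19, 1] <- NA
  m2 <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v2),
                                            protein_id = rownames(v2), .before = 1), "log2")
  expect_error(pca_embed(m2, impute = FALSE), "fewer than 2")
  v3 <- v; v3[1:5, 1] <- NA
  m3 <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v3),
                                            protein_id = rownames(v3), .before = 1), "log2")
  expect_equal(pca_embed(m3, impute = FALSE)$n_proteins_used, 15L)
  expect_equal(pca_embed(m3, impute = TRUE)$n_proteins_used, 20L)
})

test_that("planted clusters drive rank selection, labels, and relevance enrichment", {
  n_seeds <- 6
  hits <- 0; aris <- numeric(0)
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(quick_config(n_proteins = 120, n_de_proteins = 0,
                                       n_cluster_proteins = 30, n_clusters = 3,
                                       cluster_effect = 2.0, seed = 800 + s))
    l2 <- log2_transform(filter_valid(co$matrix, 0.5))
    nm <- suppressWarnings(normalize_median(l2, select_invariant(l2, 100)))
    V <- nmf_input(impute_mean(nm$normalized))
    sw <- nmf_rank_sweep(V, k_range = 2:5, n_runs = 30, seed = 800 + s)
    k <- suppressWarnings(select_rank(sw))
    if (k == 3L) hits <- hits + 1
    cr <- sw$results[["3"]]
    truth <- co$truth$cluster_labels$cluster[
      match(cr$labels$sample_id, co$truth$cluster_labels$sample_id)]
    aris <- c(aris, mclust::adjustedRandIndex(cr$labels$cluster, truth))

    # relevance enrichment of planted cluster proteins above the 90th percentile
    rs <- relevance_scores(cr$best_W, percentile = 90)
    planted <- intersect(co$truth$cluster_proteins, rs$protein_id)
    sel <- rs$protein_id[rs$selected]
    q <- sum(planted %in% sel)
    p_hyper <- stats::phyper(q - 1, length(planted), nrow(rs) - length(planted),
                             length(sel), lower.tail = FALSE)
    expect_lt(p_hyper, 0.01)
  }
  expect_gte(hits, n_seeds - 1)
  expect_gte(mean(aris >= 0.9), (n_seeds - 1) / n_seeds)
})
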