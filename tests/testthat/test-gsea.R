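write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

two_group_matrix <- function(n_prot = 60, n1 = 6, n2 = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_prot * (n1 + n2), 14, 1), n_prot)
  dimnames(v) <- list(sprintf("G%03d", seq_len(n_prot)),
                      c(sprintf("P%02d", seq_len(n1)), sprintf("M%02d", seq_len(n2))))
  m <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v),
                                           protein_id = rownames(v), .before = 1), "log2")
  sheet <- tibble::tibble(
    sample_id = colnames(v),
    patient_id = colnames(v),
    tissue_type = rep(c("primary", "metastasis"), c(n1, n2)),
    localization = NA_character_)
  list(m = m, sheet = sheet, v = v)
}

test_that("GMT parsing handles members, duplicates, and malformed lines", {
  p <- write_tmp_gmt(c("S1\tdesc\tA\tB", "S2\tother\tB\tB\tC"))
  gs <- read_gmt(p)
  expect_equal(gs$set_name, c("S1", "S2"))
  expect_equal(gs$genes[[1]], c("A", "B"))
  expect_equal(gs$genes[[2]], c("B", "C"))  # within-set duplicate dropped

  expect_equal(nrow(read_gmt(write_tmp_gmt(character()))), 0L)
  expect_error(read_gmt(write_tmp_gmt(c("S1\tdesc"))), "line 1")
  expect_error(read_gmt(write_tmp_gmt(c("S1\td\tA", "S1\td\tB"))), "duplicate")

  # round trip
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  expect_equal(read_gmt(out), gs)
})

test_that("t ranking is deterministic, signed primary-minus-metastasis", {
  d <- two_group_matrix(n_prot = 3, n1 = 3, n2 = 3)
  v <- d$v
  v["G001", ] <- c(1, 2, 3, 4, 5, 6)        # primaries low -> negative t
  v["G002", ] <- c(4, 4.1, 3.9, 4, 4.1, 3.9)  # flat -> t ~ 0
  v["G003", ] <- c(9, 9.5, 8.5, 2, 2.5, 1.5)  # primaries high -> positive t
  m <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v),
                                           protein_id = rownames(v), .before = 1), "log2")
  rk <- rank_by_t(m, d$sheet)
  expect_equal(rk$protein_id, c("G003", "G002", "G001"))
  # pooled-variance hand value for (1,2,3) vs (4,5,6): t = -3.674...
  t_hand <- (mean(1:3) - mean(4:6)) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(rk$t[rk$protein_id == "G001"], t_hand, tolerance = 1e-12)
  expect_equal(t_hand, -3.67423461417477, tolerance = 1e-10)

  # equal means, equal variances -> t = 0
  v0 <- v; v0["G002", ] <- c(1, 2, 3, 1, 2, 3)
  m0 <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v0),
                                            protein_id = rownames(v0), .before = 1), "log2")
  expect_equal(rank_by_t(m0, d$sheet)$t[2], 0)

  # identical constant groups hit the variance floor, not infinity
  vt <- v; vt["G002", ] <- c(2, 2, 2, 0, 0, 0)
  mt <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(vt),
                                            protein_id = rownames(vt), .before = 1), "log2")
  rkt <- rank_by_t(mt, d$sheet)
  expect_equal(rkt$protein_id[1], "G002")
  expect_true(is.finite(rkt$t[1]) && rkt$t[1] > 100)
})

test_that("enrichment scores match the hand running sum and its symmetries", {
  ranked <- tibble::tibble(protein_id = c("g1", "g2", "g3"), t = c(3, 2, 1))
  # set {g3}: running sums (-0.5, -1.0, 0.0) -> ES = -1
  es3 <- enrichment_score(ranked, "g3")
  expect_equal(es3$es, -1.0)
  expect_equal(es3$running$running_sum, c(-0.5, -1.0, 0.0))
  # set {g1}: ES = +1
  expect_equal(enrichment_score(ranked, "g1")$es, 1.0)
  # set covering the whole list: no misses -> ES = 1
  expect_equal(enrichment_score(ranked, c("g1", "g2", "g3"))$es, 1.0)
  expect_error(enrichment_score(ranked, "absent"), "no members")

  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    t <- sort(runif(n, 0.1, 5), decreasing = TRUE) * sample(c(1, -1), n, TRUE)
    t <- sort(t, decreasing = TRUE)
    ids <- sprintf("g%02d", seq_len(n))
    rk <- tibble::tibble(protein_id = ids, t = t)
    set <- sample(ids, sample(2:(n - 1), 1))
    hit <- ids %in% set
    expect_equal(enrichment_score(rk, set)$es, oracle_es(t, hit), tolerance = 1e-12)
    # reversing the ranking negates the ES whenever the running-sum extremum
    # is unique (an exact +/- tie leaves the sign to the tie-break)
    w <- abs(t)^1
    inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - sum(hit)))
    runs <- sort(abs(cumsum(inc)), decreasing = TRUE)
    if (runs[1] - runs[2] > 1e-9) {
      rev_rk <- tibble::tibble(protein_id = rev(ids), t = rev(-t))
      expect_equal(enrichment_score(rev_rk, set)$es, -oracle_es(t, hit),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES reacts to set-free padding only through the miss decrement", {
  ranked <- tibble::tibble(protein_id = c("a", "b", "c"), t = c(3, 2, 1))
  padded <- tibble::tibble(protein_id = c("a", "b", "c", "z1", "z2"),
                           t = c(3, 2, 1, 0.5, 0.4))
  es1 <- enrichment_score(ranked, c("a", "b"))$es
  es2 <- enrichment_score(padded, c("a", "b"))$es
  # hits contribute identically; only 1/(N - Nh) changes
  expect_equal(es1, 1.0)
  expect_equal(es2, 1.0)
})

test_that("phenotype-permutation GSEA is seeded, calibrated, and conventional at the extreme", {
  d <- two_group_matrix(n_prot = 40, n1 = 5, n2 = 5, seed = 2)
  # plant a strongly enriched set
  v <- d$v
  planted <- sprintf("G%03d", 1:8)
  v[planted, 1:5] <- v[planted, 1:5] + 3
  m <- as_intensity_tbl(tibble::add_column(tibble::as_tibble(v),
                                           protein_id = rownames(v), .before = 1), "log2")
  gs <- tibble::tibble(set_name = c("planted", "random"),
                       description = "",
                       genes = list(planted, sprintf("G%03d", 31:38)))
  r1 <- run_gsea(m, d$sheet, gs, n_perm = 50, seed = 7)
  r2 <- run_gsea(m, d$sheet, gs, n_perm = 50, seed = 7)
  expect_equal(r1, r2)
  expect_error(run_gsea(m, d$sheet, gs, n_perm = 5), "n_perm")

  pl <- r1[r1$set_name == "planted", ]
  expect_gt(pl$es, 0)
  expect_lt(pl$p_value, 0.05)
  # ES more extreme than every same-sign permutation -> p = 1/(m+1) convention
  expect_gte(pl$p_value, 1 / 51)
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1, na.rm = TRUE))
  expect_true(all(abs(r1$es) <= 1))
  # leading edge of a positively enriched set contains planted genes
  expect_true(all(pl$leading_edge[[1]] %in% planted))

  # null calibration: random labels, random sets
  fr <- vapply(1:10, function(s) {
    d0 <- two_group_matrix(n_prot = 80, n1 = 5, n2 = 5, seed = 20 + s)
    sets <- purrr::map(1:20, ~ sample(rownames(d0$v), 10))
    gs0 <- tibble::tibble(set_name = paste0("S", 1:20), description = "", genes = sets)
    r <- run_gsea(d0$m, d0$sheet, gs0, n_perm = 100, seed = s)
    mean(r$p_value <= 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.04)
})
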