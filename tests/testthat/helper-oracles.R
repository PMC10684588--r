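# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (enumeration, closed forms, O(n^3) loops) and
# share no code with the functions they verify.

# Two-sided Mann-Whitney p by full enumeration of label assignments: U is the
# number of (x, y) pairs with x > y (+ 1/2 per tie); p is the fraction of all
# C(n1+n2, n1) relabelings whose U is at least as far from the null mean.
oracle_mw <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Cophenetic correlation by naive UPGMA agglomeration over the original
# pairwise distances: cluster distance = mean over all original cross pairs,
# cophenetic distance = height of the merge joining two leaves.
oracle_cophenetic <- function(consensus) {
  D <- 1 - consensus
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  cluster_dist <- function(a, b) mean(D[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        d <- cluster_dist(clusters[[i]], clusters[[j]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bd; coph[b, a] <- bd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  lower <- lower.tri(D)
  stats::cor(D[lower], coph[lower])
}

# Weighted running-sum enrichment score by an explicit position loop
oracle_es <- function(t_ranked, hit, weight = 1) {
  n <- length(t_ranked)
  w <- abs(t_ranked)^weight
  denom_hit <- sum(w[hit])
  miss_dec <- if (sum(hit) == n) 0 else 1 / (n - sum(hit))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / denom_hit else -miss_dec
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# PCA sample scores from an explicit eigendecomposition of the covariance of
# the column-centered samples-by-proteins matrix
oracle_pca_scores <- function(obs, n_components = 2L) {
  xc <- scale(obs, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- xc %*% eg$vectors[, seq_len(n_components), drop = FALSE]
  list(scores = scores,
       explained = eg$values / sum(eg$values))
}

# small fast sim config for tests
quick_config <- function(n_proteins = 120, n_de_proteins = 20,
                         n_cluster_proteins = 24, ...) {
  sim_config(n_proteins = n_proteins, n_de_proteins = n_de_proteins,
             n_cluster_proteins = n_cluster_proteins, ...)
}
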