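# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

# single planted gene pair under the Poisson-thinning measurement model;
# returns counts, true depths and the latent draws
sim_pair_counts <- function(n, rho, mu = c(5e-4, 5e-4), cv = 0.5,
                            depth_mean = 5000, depth_cv = 0.5, seed = 1) {
  set.seed(seed)
  shape <- 1 / cv^2
  ch <- chol(matrix(c(1, rho, rho, 1), 2))
  U <- matrix(rnorm(n * 2), n, 2) %*% ch
  Z <- vapply(1:2, function(j) {
    qgamma(pnorm(U[, j]), shape = shape, rate = shape / mu[j])
  }, numeric(n))
  sdlog <- sqrt(log(1 + depth_cv^2))
  s <- rlnorm(n, log(depth_mean) - sdlog^2 / 2, sdlog)
  s <- s * depth_mean / mean(s)
  X <- matrix(rpois(n * 2, s * Z), n, 2,
              dimnames = list(NULL, c("gA", "gB")))
  list(counts = X, depths = s, latent = Z)
}

# many independent planted pairs at a common latent rho (genes 2k-1, 2k)
sim_many_pairs <- function(n, n_pairs, rho, mu = 5e-4, cv = 0.5,
                           depth_mean = 5000, seed = 1) {
  set.seed(seed)
  G <- 2 * n_pairs
  shape <- 1 / cv^2
  U <- matrix(rnorm(n * G), n, G)
  if (rho != 0) {
    for (k in seq_len(n_pairs)) {
      a <- 2 * k - 1
      U[, 2 * k] <- rho * U[, a] + sqrt(1 - rho^2) * U[, 2 * k]
    }
  }
  Z <- qgamma(pnorm(U), shape = shape, rate = shape / mu)
  sdlog <- sqrt(log(1.25))
  s <- rlnorm(n, log(depth_mean) - sdlog^2 / 2, sdlog)
  s <- s * depth_mean / mean(s)
  X <- matrix(rpois(n * G, s * as.numeric(Z)), n, G)
  colnames(X) <- sprintf("g%03d", seq_len(G))
  list(counts = X, depths = s,
       pairs = data.frame(gene1 = sprintf("g%03d", seq(1, G, 2)),
                          gene2 = sprintf("g%03d", seq(2, G, 2))))
}

# small dense random count matrix (cells x genes)
random_counts <- function(n_cells, n_genes, lambda = 2, seed = 1) {
  set.seed(seed)
  matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes,
         dimnames = list(sprintf("cell%03d", seq_len(n_cells)),
                         sprintf("gene%03d", seq_len(n_genes))))
}

# brute-force BH step-up straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:m, function(l) {
      p[ord[l]] * m / l
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# exhaustive hypergeometric upper tail by enumerating all query draws
ora_enum <- function(universe, set, query_size, overlap) {
  draws <- combn(universe, query_size, simplify = FALSE)
  hits <- vapply(draws, function(q) length(intersect(q, set)) >= overlap,
                 logical(1))
  mean(hits)
}

# exhaustive Otsu search from the textbook definition
otsu_brute <- function(h) {
  h <- as.numeric(h)
  L <- length(h)
  n <- sum(h)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:(L - 2)) {
    idx0 <- 0:t
    idx1 <- (t + 1):(L - 1)
    w0 <- sum(h[idx0 + 1]) / n
    w1 <- sum(h[idx1 + 1]) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(idx0 * h[idx0 + 1]) / sum(h[idx0 + 1])
    mu1 <- sum(idx1 * h[idx1 + 1]) / sum(h[idx1 + 1])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}
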