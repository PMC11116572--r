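# Independent brute-force oracles. Each re-derives its quantity from the
# definition with plain loops, deliberately sharing no code with the
# package implementations.

oracle_cf <- function(measured, background) measured / background

oracle_pli <- function(cfs) {
  prod <- 1
  for (cf in cfs) prod <- prod * cf
  prod^(1 / length(cfs))
}

oracle_coverage <- function(x) {
  x <- x[x > 0]
  singletons <- 0
  for (v in x) if (v == 1) singletons <- singletons + 1
  1 - singletons / sum(x)
}

oracle_chao1 <- function(x) {
  x <- x[x > 0]
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_gini_simpson <- function(x) {
  p <- x[x > 0] / sum(x)
  total <- 0
  for (pi in p) total <- total + pi * pi
  1 - total
}

oracle_bray <- function(x, y) {
  px <- x / sum(x)
  py <- y / sum(y)
  sum(abs(px - py)) / sum(px + py)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[o[j]] / j)
    q[o[i]] <- min(1, best)
  }
  q
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Zi/Pi from the definition, looping over an adjacency matrix.
oracle_zipi <- function(adj, membership) {
  n <- nrow(adj)
  mods <- unique(membership)
  zi <- pi_ <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    kis_all <- numeric(0)
    for (j in seq_len(n)) {
      if (membership[j] == membership[i])
        kis_all <- c(kis_all, sum(adj[j, membership == membership[j]]))
    }
    own <- sum(adj[i, membership == membership[i]])
    s <- stats::sd(kis_all)
    zi[i] <- if (length(kis_all) > 1 && s > 0) (own - mean(kis_all)) / s else 0
    if (ki == 0) {
      pi_[i] <- 0
    } else {
      acc <- 0
      for (m in mods) acc <- acc + (sum(adj[i, membership == m]) / ki)^2
      pi_[i] <- 1 - acc
    }
  }
  list(zi = zi, pi = pi_)
}

oracle_modularity <- function(adj, membership) {
  two_e <- sum(adj)
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / two_e
  unname(q / two_e)
}

oracle_triangles <- function(adj, v) {
  nb <- which(adj[v, ] > 0)
  count <- 0
  if (length(nb) >= 2) {
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] > 0) count <- count + 1
    }
  }
  count
}

# double-centering PCoA oracle
oracle_pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  b <- matrix(0, n, n)
  rowm <- rowMeans(m^2)
  allm <- mean(m^2)
  for (i in seq_len(n)) for (j in seq_len(n))
    b[i, j] <- -0.5 * (m[i, j]^2 - rowm[i] - rowm[j] + allm)
  e <- eigen(b, symmetric = TRUE)
  list(values = e$values,
       points = e$vectors[, 1:k] %*% diag(sqrt(pmax(e$values[1:k], 0)), k))
}

# ANOSIM with exhaustive enumeration, independent implementation using
# explicit rank averaging over the distance list.
oracle_anosim_exact <- function(dmat, groups) {
  n <- nrow(dmat)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  dvals <- dmat[upper.tri(dmat)]
  rk <- rank(dvals)
  stat_for <- function(g) {
    within <- g[pairs[, 1]] == g[pairs[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  obs <- stat_for(groups)
  lv <- unique(groups)
  n1 <- sum(groups == lv[1])
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(ix) {
    g <- rep(lv[2], n)
    g[ix] <- lv[1]
    stat_for(g)
  })
  list(statistic = obs, p_value = sum(stats >= obs - 1e-12) / length(stats))
}

# Mantel with exhaustive permutations via recursive generation (distinct
# from the package's iterative enumerator).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  }
  out
}

oracle_mantel_exact <- function(d1, d2) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  v1 <- m1[lower.tri(m1)]
  r_for <- function(mm) stats::cor(rank(v1), rank(mm[lower.tri(mm)]))
  obs <- r_for(m2)
  rs <- vapply(oracle_perms(nrow(m1)), function(p) r_for(m2[p, p]),
               numeric(1))
  list(statistic = obs, p_value = sum(rs >= obs - 1e-12) / length(rs))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mwu_exact <- function(values, groups) {
  lv <- unique(groups)
  n1 <- sum(groups == lv[1])
  r <- rank(values)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  obs <- u_of(which(groups == lv[1]))
  combos <- utils::combn(length(values), n1)
  us <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(us <= obs + 1e-12), mean(us >= obs - 1e-12)))
}

# small random abundance fixture
random_table <- function(n_samples = 6, n_taxa = 12, domain = "bacteria",
                         lambda = 8) {
  counts <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples,
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   paste0("t", seq_len(n_taxa))))
  counts[1, ] <- counts[1, ] + 1  # guard against empty samples
  abundance_table(counts, domain)
}
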