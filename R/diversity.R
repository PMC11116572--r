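# Alpha diversity, Bray-Curtis dissimilarity, principal-coordinate
# ordination, ANOSIM and the Mann-Whitney group test.

#' Per-sample alpha diversity
#'
#' Good's coverage `1 - F1/N`, bias-corrected Chao1
#' `S_obs + F1(F1 - 1) / (2(F2 + 1))` and the Simpson index, where `F1`/`F2`
#' are singleton/doubleton counts and `N` reads per sample. Simpson defaults
#' to the Gini-Simpson form `1 - sum(p_i^2)`; `simpson = "dominance"` gives
#' `sum(p_i^2)` and `"inverse"` gives `1 / sum(p_i^2)`.
#'
#' @param tab an `abundance_table`.
#' @param simpson which Simpson variant to report.
#' @return data.frame with one row per sample: `sample_id`, `reads`,
#'   `richness`, `coverage`, `chao1`, `simpson`.
#' @export
alpha_diversity <- function(tab,
                            simpson = c("gini", "dominance", "inverse")) {
  simpson <- match.arg(simpson)
  counts <- tab$counts
  n_reads <- rowSums(counts)
  if (any(n_reads == 0))
    stop("empty sample: ", rownames(counts)[which(n_reads == 0)[1]])
  res <- t(apply(counts, 1, function(x) {
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    p <- x / sum(x)
    d <- sum(p^2)
    c(reads = sum(x), richness = s_obs,
      coverage = 1 - f1 / sum(x),
      chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
      simpson = switch(simpson, gini = 1 - d, dominance = d, inverse = 1 / d))
  }))
  data.frame(sample_id = rownames(counts), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on relative abundances, where it reduces to half the Manhattan
#' distance; 0 for identical composition, 1 for disjoint samples.
#'
#' @param tab an `abundance_table` with >= 2 samples.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(tab) {
  if (nrow(tab$counts) < 2) stop("need at least two samples")
  rel <- relative_abundance(tab)
  stats::dist(rel, method = "manhattan") / 2
}

#' Principal-coordinate ordination of a distance matrix
#'
#' Classical metric scaling (Gower double-centering of squared distances);
#' axes are ordered by eigenvalue and explained fractions are relative to
#' the sum of positive eigenvalues.
#'
#' @param d `dist` or symmetric matrix with zero diagonal.
#' @param k number of axes to return (default 2, capped at available).
#' @return list: `points` (samples x k), `eig` (all eigenvalues),
#'   `explained` (fractions for the returned axes).
#' @export
ordinate <- function(d, k = 2) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (m^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values), 1e-300)
  k <- min(k, sum(pos))
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = e$values,
       explained = e$values[seq_len(k)] / sum(e$values[pos]))
}

#' Principal component analysis of relative abundances
#'
#' Covariance PCA on the relative-abundance matrix, provided as the
#' abundance-space alternative to [ordinate()].
#'
#' @param tab an `abundance_table`.
#' @param k number of axes.
#' @return list: `points`, `explained` (variance fractions).
#' @export
ordinate_pca <- function(tab, k = 2) {
  rel <- relative_abundance(tab)
  pc <- stats::prcomp(rel, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  list(points = pc$x[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group ones: `R = (mean_between_rank - mean_within_rank) / (M/2)`
#' with `M = n(n-1)/2`. The permutation p-value uses the `(1 + b)/(1 + m)`
#' estimator; with `exact = TRUE` (two groups only) all distinct label
#' assignments are enumerated and `p = #(R_perm >= R_obs) / #assignments`.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of label permutations (ignored when exact).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all assignments (two groups, small n).
#' @return list: `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must match the distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two samples")
  ranks <- matrix(0, n, n)
  lt <- lower.tri(m)
  ranks[lt] <- rank(m[lt])
  ranks <- ranks + t(ranks)
  stat <- function(g) {
    same <- outer(g, g, "==")
    rw <- mean(ranks[lt][same[lt]])
    rb <- mean(ranks[lt][!same[lt]])
    (rb - rw) / (n * (n - 1) / 4)
  }
  r_obs <- stat(groups)
  if (exact) {
    if (length(sizes) != 2) stop("exact enumeration supports two groups")
    lab <- names(sizes)
    combos <- utils::combn(n, sizes[[1]])
    r_perm <- apply(combos, 2, function(ix) {
      g <- rep(lab[2], n); g[ix] <- lab[1]; stat(g)
    })
    return(list(statistic = r_obs,
                p_value = mean(r_perm >= r_obs - 1e-12),
                n_perm = ncol(combos)))
  }
  r_perm <- with_seed(seed, replicate(n_perm, stat(sample(groups))))
  list(statistic = r_obs,
       p_value = (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) group comparison
#'
#' Reports `U` for the first group and a two-sided p-value: permutation-exact
#' (all `choose(n, n1)` splits of the observed, possibly tied, ranks) when
#' both groups have <= 8 samples, otherwise the tie-corrected normal
#' approximation. `exact` overrides the automatic choice.
#'
#' @param values numeric vector.
#' @param groups two-level label vector.
#' @param exact logical or NULL (auto).
#' @return list: `statistic` (U of the first group level), `p_value`,
#'   `method`.
#' @export
group_compare <- function(values, groups, exact = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  n1 <- sum(groups == lev[1])
  n2 <- sum(groups == lev[2])
  if (n1 == 0 || n2 == 0) stop("empty group")
  r <- rank(values)
  u_obs <- sum(r[groups == lev[1]]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (n1 <= 8 && n2 <= 8)
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    u_perm <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_perm <= u_obs + 1e-12),
                 mean(u_perm >= u_obs - 1e-12))
    return(list(statistic = u_obs, p_value = min(1, p),
                method = "exact permutation"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = u_obs, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation (tie-corrected)")
}
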