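# Spearman correlation, Benjamini-Hochberg adjustment, environment-taxon
# heatmaps, Mantel tests and genus-level cross-domain correlation.

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of average ranks (ties averaged). The
#' default p-value uses the t approximation with n - 2 df; `exact = TRUE`
#' enumerates all rank permutations (n <= 8) and reports the two-sided
#' permutation p `#(|rho_perm| >= |rho_obs|) / n!`. A constant input gives
#' rho = 0, p = 1.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param exact use exact permutation p (n <= 8).
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = 0, p_value = 1, n = n))
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (exact) {
    perms <- enumerate_permutations(n)
    rho_perm <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
    return(list(rho = rho,
                p_value = mean(abs(rho_perm) >= abs(rho) - 1e-12), n = n))
  }
  p <- if (abs(rho) == 1) 0 else
    2 * stats::pt(-abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2)
  list(rho = rho, p_value = p, n = n)
}

# Vectorized Spearman between the columns of X (and optionally Y).
# Returns list(rho, p); constant columns give rho 0 / p 1.
spearman_matrix <- function(x, y = NULL) {
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  rx <- apply(x, 2, rank)
  const_x <- apply(rx, 2, stats::sd) == 0
  if (is.null(y)) {
    ry <- rx; const_y <- const_x
  } else {
    if (nrow(y) != n) stop("x and y must have the same samples")
    ry <- apply(y, 2, rank)
    const_y <- apply(ry, 2, stats::sd) == 0
  }
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[const_x, ] <- 0
  rho[, const_y] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  p <- 2 * stats::pt(-abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, 1e-300)),
                     n - 2)
  p[abs(rho) == 1] <- 0
  p[const_x, ] <- 1
  p[, const_y] <- 1
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, applied within one
#' family of tests.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Collapse an abundance table to a taxonomic rank (counts summed).
#' Aggregate an abundance table at a taxonomic rank
#'
#' @param tab an `abundance_table`.
#' @param rank one of the taxonomy columns (e.g. `"phylum"`, `"genus"`), or
#'   `"asv"` for no aggregation (taxon level).
#' @return An `abundance_table` whose taxa are the rank's values.
#' @export
aggregate_rank <- function(tab, rank) {
  if (identical(rank, "asv")) return(tab)
  if (!rank %in% names(tab$taxonomy))
    stop("rank '", rank, "' absent from taxonomy (have: ",
         paste(setdiff(names(tab$taxonomy), "taxon_id"), collapse = ", "), ")")
  lab <- tab$taxonomy[[rank]]
  agg <- t(rowsum(t(tab$counts), lab))
  tax <- data.frame(taxon_id = colnames(agg), stringsAsFactors = FALSE)
  tax[[rank]] <- colnames(agg)
  abundance_table(agg, tab$domain, tax)
}

sig_stars <- function(q) ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", ""))

#' Environment-taxon Spearman correlation table
#'
#' Correlates each taxon's relative abundance at `rank` with each
#' environmental variable (metals + physicochemical by default), adjusting
#' p-values with Benjamini-Hochberg over the whole taxon-by-variable family.
#' Stars mark q < 0.05 (`*`) and q < 0.01 (`**`).
#'
#' @param tab an `abundance_table`.
#' @param env a `sample_frame` covering the table's samples.
#' @param rank taxonomic rank to aggregate to (default `"phylum"`).
#' @param variables environmental columns to use.
#' @return data.frame: `taxon`, `variable`, `rho`, `p`, `q`, `n`, `sig`.
#' @export
env_taxon_correlation <- function(tab, env, rank = "phylum",
                                  variables = c(metal_vocabulary(),
                                                physchem_vocabulary())) {
  agg <- aggregate_rank(tab, rank)
  rel <- relative_abundance(agg)
  ix <- match(rownames(rel), env$sample_id)
  if (any(is.na(ix))) stop("metadata is missing samples: ",
                           paste(rownames(rel)[is.na(ix)][1], collapse = ", "))
  emat <- as.matrix(env[ix, variables, drop = FALSE])
  sm <- spearman_matrix(rel, emat)
  out <- data.frame(
    taxon = rep(colnames(rel), times = length(variables)),
    variable = rep(variables, each = ncol(rel)),
    rho = c(sm$rho), p = c(sm$p), stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$n <- sm$n
  out$sig <- sig_stars(out$q)
  attr(out, "family") <- sprintf("env_taxon:%s:%s", tab$domain, rank)
  out
}

#' Mantel test between two distance matrices
#'
#' Statistic: Spearman correlation of the strictly-lower-triangle entries.
#' Permutations jointly relabel rows and columns of `d2`; p-value is
#' `(1 + b)/(1 + m)`, or the exhaustive `#(r_perm >= r_obs)/n!` with
#' `exact = TRUE` (n <= 7).
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples.
#' @param n_perm permutations (ignored when exact).
#' @param seed RNG seed.
#' @param exact enumerate all sample permutations.
#' @return list: `statistic` (r), `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1, exact = FALSE) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in dimension")
  n <- nrow(m1)
  v1 <- rank(lower_tri_vec(m1))
  corstat <- function(mm) stats::cor(v1, rank(lower_tri_vec(mm)))
  r_obs <- corstat(m2)
  if (exact) {
    perms <- enumerate_permutations(n)
    r_perm <- apply(perms, 1, function(ix) corstat(m2[ix, ix]))
    return(list(statistic = r_obs,
                p_value = mean(r_perm >= r_obs - 1e-12),
                n_perm = nrow(perms)))
  }
  r_perm <- with_seed(seed, replicate(n_perm, {
    ix <- sample(n)
    corstat(m2[ix, ix])
  }))
  list(statistic = r_obs,
       p_value = (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Genus-level bacteria-fungus correlation matrix
#'
#' Aggregates both tables to genus, keeps genera whose mean (or per-sample
#' maximum, `mode = "max"`) relative abundance within their own domain
#' exceeds `threshold`, and tests every retained bacterial x fungal genus
#' pair with Spearman, BH-adjusted over this matrix as one family.
#'
#' @param bact,fungi `abundance_table`s sharing samples.
#' @param threshold relative-abundance retention threshold (default 0.10).
#' @param mode `"mean"` or `"max"` abundance summary.
#' @return data.frame like [env_taxon_correlation()] with columns
#'   `bacterial_genus`, `fungal_genus`; zero rows (with a warning) when no
#'   genus passes.
#' @export
genus_cross_domain <- function(bact, fungi, threshold = 0.10,
                               mode = c("mean", "max")) {
  mode <- match.arg(mode)
  keep_genera <- function(tab) {
    rel <- relative_abundance(aggregate_rank(tab, "genus"))
    score <- if (mode == "mean") colMeans(rel) else apply(rel, 2, max)
    rel[, score > threshold, drop = FALSE]
  }
  rb <- keep_genera(bact)
  rf <- keep_genera(fungi)
  shared <- intersect(rownames(rb), rownames(rf))
  empty <- data.frame(bacterial_genus = character(0),
                      fungal_genus = character(0), rho = numeric(0),
                      p = numeric(0), q = numeric(0), n = integer(0),
                      sig = character(0), stringsAsFactors = FALSE)
  if (ncol(rb) == 0 || ncol(rf) == 0) {
    warning("no genus passes the relative-abundance threshold ", threshold)
    return(empty)
  }
  rb <- rb[shared, , drop = FALSE]
  rf <- rf[shared, , drop = FALSE]
  sm <- spearman_matrix(rb, rf)
  out <- data.frame(
    bacterial_genus = rep(colnames(rb), times = ncol(rf)),
    fungal_genus = rep(colnames(rf), each = ncol(rb)),
    rho = c(sm$rho), p = c(sm$p), stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$n <- sm$n
  out$sig <- sig_stars(out$q)
  attr(out, "family") <- "genus_cross_domain"
  out
}
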