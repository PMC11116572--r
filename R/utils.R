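# Shared internal helpers and controlled vocabularies.

#' Heavy metals measured in the survey design
#'
#' The seven metals quantified per sample, in canonical order. All
#' concentrations handled by the package are in mg/kg dry soil.
#'
#' @return Character vector of metal symbols.
#' @export
metal_vocabulary <- function() {
  c("Mo", "Cd", "Sb", "Cu", "Zn", "Hg", "Pb")
}

#' Physicochemical soil variables
#'
#' The ten soil properties carried in sample metadata: microbial biomass
#' carbon/nitrogen/phosphorus (MBC, MBN, MBP), water content (WC), total and
#' available phosphorus (TP, AP), total nitrogen (TN), organic carbon (OC),
#' ammonium and nitrate nitrogen (AMN, NN).
#'
#' @return Character vector of variable names.
#' @export
physchem_vocabulary <- function() {
  c("MBC", "MBN", "MBP", "WC", "TP", "AP", "TN", "OC", "AMN", "NN")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial
  (sij - expected) / denom
}

# All permutations of 1..n as an n! x n matrix. Guarded: factorial growth.
enumerate_permutations <- function(n) {
  if (n > 8) stop("refusing to enumerate ", n, "! permutations")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- enumerate_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Strict lower-triangle of a square matrix as a vector (column-major).
lower_tri_vec <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

stop_if_not_number <- function(x, what, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad)
    stop(what, " must be ", if (strict_min) "> " else ">= ", min, call. = FALSE)
  invisible(x)
}
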