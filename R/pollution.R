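# Contamination factor, pollution load index and pollution classes.

#' Contamination factor
#'
#' CF = measured / background: how many times a metal's concentration
#' exceeds its geochemical background value.
#'
#' @param measured measured concentration(s), mg/kg, >= 0.
#' @param background background value(s), mg/kg, > 0 (recycled).
#' @return Numeric vector of contamination factors.
#' @export
contamination_factor <- function(measured, background) {
  stop_if_not_number(measured, "measured concentration", min = 0)
  stop_if_not_number(background, "background value", min = 0,
                     strict_min = TRUE)
  measured / background
}

#' Pollution load index
#'
#' Geometric mean of the contamination factors of the metals measured,
#' `(CF1 * CF2 * ... * CFn)^(1/n)`. Computed in log space; any zero CF gives
#' a PLI of exactly 0.
#'
#' @param cfs non-empty numeric vector of contamination factors, >= 0.
#' @return Numeric scalar.
#' @export
pollution_load_index <- function(cfs) {
  if (length(cfs) == 0) stop("PLI needs at least one contamination factor")
  stop_if_not_number(cfs, "contamination factors", min = 0)
  if (any(cfs == 0)) return(0)
  exp(mean(log(cfs)))
}

#' Pollution class of a CF or PLI value
#'
#' CF classes: below 1 unpolluted, 1-3 moderate, 3-6 considerable, above 6
#' highest. PLI: above 1 contaminated, otherwise uncontaminated. Values
#' exactly on a bound go to the lower class by default (the class
#' definitions use strict inequalities); `boundary = "upper"` flips this.
#'
#' @param value CF or PLI value(s), >= 0.
#' @param kind `"cf"` or `"pli"`.
#' @param boundary `"lower"` (default) or `"upper"`.
#' @return Character vector of class labels.
#' @export
classify_pollution <- function(value, kind = c("cf", "pli"),
                               boundary = c("lower", "upper")) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  stop_if_not_number(value, "value", min = 0)
  if (kind == "pli") {
    hit <- if (boundary == "lower") value > 1 else value >= 1
    return(ifelse(hit, "contaminated", "uncontaminated"))
  }
  cuts <- c(1, 3, 6)
  labels <- c("none", "moderate", "considerable", "highest")
  # "lower": a class is entered by strict '>', so a value sitting exactly on
  # a bound stays in the class below it.
  idx <- if (boundary == "lower") rowSums(outer(value, cuts, ">"))
         else rowSums(outer(value, cuts, ">="))
  labels[idx + 1]
}

#' Per-sample pollution report
#'
#' Computes each sample's per-metal contamination factors, its PLI over the
#' metals used, CF and PLI pollution classes, and arithmetic group-mean
#' PLIs.
#'
#' @param meta a `sample_frame`.
#' @param background named background values (mg/kg) covering `metals`.
#' @param metals metals to use; default all seven of [metal_vocabulary()].
#' @param boundary boundary handling for classes, see [classify_pollution()].
#' @return A `pollution_report`: list with `cf` (samples x metals matrix),
#'   `cf_class`, `pli` (named per-sample vector), `pli_class`, `group_pli`
#'   (named per-group means), `n_metals`.
#' @export
pollution_report <- function(meta, background, metals = metal_vocabulary(),
                             boundary = "lower") {
  missing <- setdiff(metals, names(background))
  if (length(missing) > 0)
    stop("no background value for: ", paste(missing, collapse = ", "))
  missing <- setdiff(metals, names(meta))
  if (length(missing) > 0)
    stop("metadata lacks metal columns: ", paste(missing, collapse = ", "))
  cf <- sapply(metals, function(m)
    contamination_factor(meta[[m]], background[[m]]))
  cf <- matrix(cf, nrow = nrow(meta),
               dimnames = list(meta$sample_id, metals))
  pli <- apply(cf, 1, pollution_load_index)
  group_pli <- tapply(pli, meta$group, mean)
  structure(list(
    cf = cf,
    cf_class = matrix(classify_pollution(c(cf), "cf", boundary),
                      nrow = nrow(cf), dimnames = dimnames(cf)),
    pli = pli,
    pli_class = classify_pollution(pli, "pli", boundary),
    group_pli = group_pli,
    n_metals = length(metals),
    group = stats::setNames(meta$group, meta$sample_id)),
    class = "pollution_report")
}

#' @export
print.pollution_report <- function(x, ...) {
  cat(sprintf("pollution_report: %d samples, %d metals\n",
              nrow(x$cf), x$n_metals))
  for (g in names(x$group_pli))
    cat(sprintf("  mean PLI [%s]: %.3f (%s)\n", g, x$group_pli[[g]],
                classify_pollution(x$group_pli[[g]], "pli")))
  invisible(x)
}

#' @export
as.data.frame.pollution_report <- function(x, ...) {
  df <- data.frame(sample_id = rownames(x$cf), group = x$group[rownames(x$cf)],
                   x$cf, pli = x$pli, pli_class = x$pli_class,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
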