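# Containers and strict TSV/GraphML input-output.
#
# Canonical on-disk dialect: tab-separated, UTF-8, '.' decimal separator,
# taxa as rows for count tables. Metal concentrations are normalized to
# mg/kg internally; a `# metal_unit:` header on metadata files declares the
# unit on disk and the conversion (ng/g -> mg/kg, factor 1e-3) is applied
# exactly once on read.

#' Construct a validated ASV abundance table
#'
#' @param counts integer matrix, samples x taxa, with unique row (sample) and
#'   column (taxon) names. Non-negative; fractional values are rejected.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param taxonomy data.frame with a `taxon_id` column plus rank columns
#'   (`phylum`, `class`, `order`, `family`, `genus`); every taxon in `counts`
#'   must appear. Unknown ranks may hold `"unclassified"`.
#' @return An `abundance_table` object.
#' @export
abundance_table <- function(counts, domain = c("bacteria", "fungi"),
                            taxonomy = NULL) {
  domain <- match.arg(domain)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or missing count at sample '", rownames(counts)[bad[1, 1]],
         "', taxon '", colnames(counts)[bad[1, 2]], "'")
  frac <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac) > 0)
    stop("non-integer count at sample '", rownames(counts)[frac[1, 1]],
         "', taxon '", colnames(counts)[frac[1, 2]], "'")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = colnames(counts),
                           phylum = "unclassified", class = "unclassified",
                           order = "unclassified", family = "unclassified",
                           genus = "unclassified", stringsAsFactors = FALSE)
  }
  if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy needs a taxon_id column")
  missing <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(missing) > 0)
    stop("taxa without taxonomy entry: ", paste(utils::head(missing, 3),
                                                collapse = ", "))
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, domain = domain, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (%s): %d samples x %d taxa, %s total reads\n",
              x$domain, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Relative abundances of an abundance table
#'
#' @param tab an `abundance_table`.
#' @return Numeric matrix, samples x taxa, rows summing to 1.
#' @export
relative_abundance <- function(tab) {
  tot <- rowSums(tab$counts)
  if (any(tot == 0))
    stop("sample with zero total count: ",
         rownames(tab$counts)[which(tot == 0)[1]])
  sweep(tab$counts, 1, tot, "/")
}

#' Construct a validated sample metadata frame
#'
#' @param df data.frame with columns `sample_id`, `group`, the seven metals
#'   ([metal_vocabulary()]) in mg/kg and the ten physicochemical variables
#'   ([physchem_vocabulary()]).
#' @return A `sample_frame` (data.frame subclass).
#' @export
sample_frame <- function(df) {
  need <- c("sample_id", "group", metal_vocabulary(), physchem_vocabulary())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1])
  for (m in metal_vocabulary()) {
    if (any(!is.finite(df[[m]]) | df[[m]] < 0))
      stop("metal ", m, " has negative or missing concentration")
  }
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_frame", "data.frame")
  df
}

# ---- count-table TSV ----

#' Write an abundance table (taxa as rows) and its taxonomy as TSV
#'
#' @param tab an `abundance_table`.
#' @param path counts TSV path; first column `taxon_id`, one column per sample.
#' @param taxonomy_path optional taxonomy TSV path.
#' @export
write_abundance <- function(tab, path, taxonomy_path = NULL) {
  out <- data.frame(taxon_id = colnames(tab$counts), t(tab$counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path))
    utils::write.table(tab$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' Orientation is auto-detected from the first header token: `taxon_id`
#' means taxa-as-rows (the canonical layout), `sample_id` samples-as-rows.
#'
#' @param path counts TSV.
#' @param taxonomy_path optional taxonomy TSV (`taxon_id` + rank columns).
#' @param domain `"bacteria"` or `"fungi"`.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path, taxonomy_path = NULL,
                           domain = c("bacteria", "fungi")) {
  domain <- match.arg(domain)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus data columns")
  key <- names(df)[1]
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count in ", path)
  if (identical(key, "taxon_id")) {
    rownames(mat) <- ids
    mat <- t(mat)
  } else if (identical(key, "sample_id")) {
    rownames(mat) <- ids
  } else {
    stop("cannot detect orientation: first header must be ",
         "'taxon_id' or 'sample_id', got '", key, "'")
  }
  taxonomy <- if (!is.null(taxonomy_path))
    utils::read.delim(taxonomy_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
  abundance_table(mat, domain, taxonomy)
}

# ---- metadata / background TSV ----

#' Write sample metadata as TSV
#'
#' A `# metal_unit: mg_kg` comment line records the on-disk unit.
#'
#' @param meta a `sample_frame`.
#' @param path output TSV.
#' @export
write_sample_frame <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# metal_unit: mg_kg", con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Honours a `# metal_unit:` header (`mg_kg` or `ng_g`); ng/g values are
#' converted to mg/kg exactly once here.
#'
#' @param path metadata TSV.
#' @return A `sample_frame` with metals in mg/kg.
#' @export
read_sample_frame <- function(path) {
  first <- readLines(path, n = 1)
  unit <- "mg_kg"
  if (grepl("^#\\s*metal_unit:", first))
    unit <- trimws(sub("^#\\s*metal_unit:", "", first))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!unit %in% c("mg_kg", "ng_g"))
    stop("unknown metal unit '", unit, "' (expected mg_kg or ng_g)")
  if (unit == "ng_g")
    for (m in intersect(metal_vocabulary(), names(df)))
      df[[m]] <- df[[m]] * 1e-3
  sample_frame(df)
}

#' Write metal background values as TSV
#' @param background named numeric vector, mg/kg.
#' @param path output TSV.
#' @export
write_background <- function(background, path) {
  utils::write.table(
    data.frame(metal = names(background), background_mg_kg = background),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read metal background values from TSV
#' @param path TSV with columns `metal`, `background_mg_kg`.
#' @return Named numeric vector.
#' @export
read_background <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metal", "background_mg_kg") %in% names(df)))
    stop("background table needs columns metal, background_mg_kg")
  bg <- stats::setNames(df$background_mg_kg, df$metal)
  stop_if_not_number(bg, "background values", min = 0, strict_min = TRUE)
  bg
}

# ---- graph export ----

#' Write a co-occurrence network to disk
#'
#' Nodes carry `domain`, `module`, `Zi`, `Pi` and `role` attributes; edges
#' carry `rho`, `q` and `sign`.
#'
#' @param net a `conet_graph` (see [build_network()]).
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"` (TSV: source, target, rho, q,
#'   sign).
#' @export
write_conet_graph <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- net$graph
  for (attr in c("module", "Zi", "Pi", "role")) {
    if (!attr %in% igraph::vertex_attr_names(g))
      g <- igraph::set_vertex_attr(g, attr,
                                   value = if (attr == "role") NA_character_
                                           else NA_real_)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rho = igraph::E(g)$rho %||% rep(NA_real_,
                                                     igraph::ecount(g)),
                     q = igraph::E(g)$q %||% rep(NA_real_, igraph::ecount(g)),
                     sign = igraph::E(g)$sign %||% rep(NA_character_,
                                                       igraph::ecount(g)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GraphML co-occurrence network back
#'
#' @param path GraphML file written by [write_conet_graph()].
#' @return A `conet_graph` (thresholds unknown, recorded as NA).
#' @export
read_conet_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g, r_threshold = NA_real_, alpha = NA_real_,
                 prevalence = NA_real_, n_samples = NA_integer_,
                 n_pairs_tested = NA_integer_),
            class = "conet_graph")
}
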