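# Synthetic paired bacterial/fungal communities with known ground truth.
#
# Latent model: a Gaussian copula over log-abundances with block (module)
# correlation driven by per-module factors; module factors share a global
# component so between-module correlation is tunable. Hubs load more
# heavily on their module's factor; connectors load on several factors at
# the maximum the covariance admits; metal responders add a slope on the
# standardized log metal concentration. Relative abundances arise by
# softmax over taxa within a domain; counts by multinomial sampling at a
# fixed depth, which is the only source of zeros.

default_backgrounds <- function() {
  c(Mo = 1.2, Cd = 0.2, Sb = 1.0, Cu = 24, Zn = 69, Hg = 0.02, Pb = 19)
}

default_cf_means <- function() {
  list(
    contaminated = c(Mo = 0.5, Cd = 30.35, Sb = 0.0125, Cu = 2.46,
                     Zn = 5.19, Hg = 11.26, Pb = 5.46),
    uncontaminated = c(Mo = 0.2, Cd = 0.6, Sb = 0.0033, Cu = 0.25,
                       Zn = 0.3, Hg = 0.04, Pb = 0.3))
}

default_physchem <- function() {
  vars <- physchem_vocabulary()
  list(
    mean = list(
      contaminated = stats::setNames(
        c(115.58, 15.85, 8.10, 14.42, 0.50, 70.73, 0.93, 13.58, 0.79, 2.11),
        vars),
      uncontaminated = stats::setNames(
        c(174.16, 20.73, 8.08, 14.94, 0.35, 45.73, 1.40, 18.93, 1.37, 4.66),
        vars)),
    sd = list(
      contaminated = stats::setNames(
        c(29.4, 3.29, 2.66, 2.71, 0.45, 56.26, 0.25, 3.63, 0.16, 0.78),
        vars),
      uncontaminated = stats::setNames(
        c(35.36, 5.68, 3.94, 1.56, 0.11, 24.43, 0.34, 4.94, 1.29, 3.33),
        vars)))
}

#' Configuration for the community simulator
#'
#' Defaults encode the study design being emulated: two groups of 9
#' (contaminated) and 7 (uncontaminated) samples, seven metals whose
#' contaminated-group mean contamination factors are Cd 30.35, Hg 11.26,
#' Pb 5.46, Zn 5.19, Cu 2.46 with Mo and Sb at trace (CF < 1) levels in
#' both groups, mutually correlated metals within a group, and planted
#' modular co-occurrence structure with hubs, connectors and metal
#' responders.
#'
#' @param n_samples named integer vector: samples per group.
#' @param n_taxa_bact,n_taxa_fungi taxa per domain.
#' @param module_sizes planted module sizes (each >= 2).
#' @param module_bact_frac fraction of each module drawn from bacteria.
#' @param rho_within latent within-module correlation, in \[0, 1).
#' @param rho_between latent between-module (taxon-level) correlation,
#'   `0 <= rho_between <= rho_within`.
#' @param rho_group_scale named per-group multiplier on planted correlations
#'   (missing groups default to 1). The default weakens interactions in the
#'   uncontaminated group, reproducing the direction in which contamination
#'   densifies the co-occurrence network.
#' @param n_hubs_per_module hubs per module (elevated loading).
#' @param hub_boost added to `rho_within` for the hub's squared loading,
#'   capped at 0.98.
#' @param n_connectors taxa outside modules loading on
#'   `connector_span` module factors at the covariance-budget maximum.
#' @param connector_span modules each connector links (capped at the
#'   module count).
#' @param n_metal_responders taxa with a planted metal slope.
#' @param effect_size_metal latent log-abundance slope per SD of log metal.
#' @param depth reads per sample per domain (multinomial size).
#' @param background_values named metal backgrounds, mg/kg.
#' @param metal_cf_means list per group: mean CF per metal (mean
#'   concentration = CF x background).
#' @param metal_group_cv named per-group coefficient of variation of metal
#'   concentrations (0 = no noise).
#' @param metal_cor correlation of log concentrations between metals within
#'   a sample group (shared lognormal factor).
#' @param physchem_mean,physchem_sd lists per group of named means/sds for
#'   the ten physicochemical variables.
#' @param baseline_struct_mean,baseline_struct_sd log-abundance baseline for
#'   structural taxa (module members, hubs, connectors, responders); kept
#'   moderately abundant so planted correlation survives counting.
#' @param baseline_bg_mean,baseline_bg_sd log-abundance baseline for
#'   background taxa; the mass-dominant background damps compositional
#'   closure effects on planted correlations.
#' @param latent_sd scale of the copula deviate in log-abundance units.
#' @param zero_inflation extra probability of zeroing a count (default 0;
#'   zeros otherwise arise only from multinomial sampling).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_samples = c(contaminated = 9, uncontaminated = 7),
    n_taxa_bact = 150, n_taxa_fungi = 50,
    module_sizes = rep(12, 8),
    module_bact_frac = 0.75,
    rho_within = 0.95, rho_between = 0.4,
    rho_group_scale = c(contaminated = 1, uncontaminated = 0.85),
    n_hubs_per_module = 1, hub_boost = 0.1,
    n_connectors = 1, connector_span = 3,
    n_metal_responders = 5, effect_size_metal = 3,
    depth = 50000,
    background_values = default_backgrounds(),
    metal_cf_means = default_cf_means(),
    metal_group_cv = c(contaminated = 0.5, uncontaminated = 0.2),
    metal_cor = 0.6,
    physchem_mean = default_physchem()$mean,
    physchem_sd = default_physchem()$sd,
    baseline_struct_mean = 0, baseline_struct_sd = 0.5,
    baseline_bg_mean = 2, baseline_bg_sd = 1.5,
    latent_sd = 1.5,
    zero_inflation = 0,
    seed = 1) {
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (is.null(names(n_samples)) || any(names(n_samples) == ""))
      stop("n_samples must be a named vector (one entry per group)")
    stop_if_not_number(n_samples, "n_samples", min = 2)
    if (any(module_sizes < 2)) stop("every module needs at least 2 taxa")
    n_struct <- sum(module_sizes) + n_connectors + n_metal_responders
    if (n_struct > n_taxa_bact + n_taxa_fungi)
      stop("module sizes plus connectors and responders exceed the ",
           "taxon count (", n_struct, " > ", n_taxa_bact + n_taxa_fungi, ")")
    if (rho_within < 0 || rho_within >= 1)
      stop("rho_within must lie in [0, 1)")
    if (rho_between < 0 || rho_between > rho_within)
      stop("implied latent covariance is not positive semi-definite: ",
           "rho_between must lie in [0, rho_within]")
    stop_if_not_number(depth, "depth", min = 0, strict_min = TRUE)
    stop_if_not_number(background_values, "background values", min = 0,
                       strict_min = TRUE)
    groups <- names(n_samples)
    for (g in groups) {
      if (is.null(metal_cf_means[[g]]))
        stop("metal_cf_means missing group '", g, "'")
      if (!all(metal_vocabulary() %in% names(metal_cf_means[[g]])))
        stop("metal_cf_means[['", g, "']] must cover all metals")
    }
    if (metal_cor < 0 || metal_cor >= 1)
      stop("metal_cor must lie in [0, 1)")
    if (any(rho_group_scale < 0 | rho_group_scale > 1))
      stop("rho_group_scale entries must lie in [0, 1]")
    if (zero_inflation < 0 || zero_inflation >= 1)
      stop("zero_inflation must lie in [0, 1)")
  })
  invisible(cfg)
}

#' Generate sample metadata (groups, metals, physicochemistry)
#'
#' Metal concentrations are log-normal around each group's configured mean
#' (mean-parameterized: `conc = mean * exp(sigma*z - sigma^2/2)` with
#' `sigma^2 = log(1 + cv^2)`), with a shared per-sample lognormal factor of
#' weight `metal_cor` making metals mutually rank-correlated within a
#' group. A CV of 0 returns the group mean exactly. Physicochemical
#' variables are truncated-normal draws around the group means.
#'
#' @param cfg a `synthetic_config`.
#' @return A `sample_frame`.
#' @export
generate_metadata <- function(cfg) {
  validate_synthetic_config(cfg)
  metals <- metal_vocabulary()
  with_seed(cfg$seed, {
    rows <- lapply(names(cfg$n_samples), function(g) {
      n <- cfg$n_samples[[g]]
      means <- cfg$metal_cf_means[[g]][metals] *
        cfg$background_values[metals]
      cv <- cfg$metal_group_cv[[g]]
      sigma <- sqrt(log(1 + cv^2))
      shared <- stats::rnorm(n)
      conc <- sapply(metals, function(m) {
        z <- sqrt(cfg$metal_cor) * shared +
          sqrt(1 - cfg$metal_cor) * stats::rnorm(n)
        means[[m]] * exp(sigma * z - sigma^2 / 2)
      })
      conc <- matrix(conc, nrow = n, dimnames = list(NULL, metals))
      pc <- sapply(physchem_vocabulary(), function(v)
        pmax(0, stats::rnorm(n, cfg$physchem_mean[[g]][[v]],
                             cfg$physchem_sd[[g]][[v]])))
      pc <- matrix(pc, nrow = n,
                   dimnames = list(NULL, physchem_vocabulary()))
      data.frame(group = g, conc, pc, check.names = FALSE,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- cbind(sample_id = sprintf("S%02d", seq_len(nrow(df))), df)
    sample_frame(df)
  })
}

# Taxonomy with domain-typical phyla and a skewed genus pool (a handful of
# dominant genera plus a long tail), so genus-level abundance filters have
# something to keep.
make_taxonomy <- function(ids, domain) {
  if (domain == "bacteria") {
    pool <- c(Proteobacteria = 0.30, Actinobacteria = 0.20,
              Acidobacteria = 0.15, Chloroflexi = 0.10,
              Gemmatimonadetes = 0.08, Planctomycetes = 0.07,
              Firmicutes = 0.04, Bacteroidetes = 0.03,
              Verrucomicrobia = 0.02, Armatimonadetes = 0.01)
    genera <- c("Arthrobacter", "Microvirga", "Sphingomonas", "Gp7",
                "Gemmatimonas", "Gp16", "Gaiella", "Bacillus",
                "Nocardioides", "Rubrobacter")
  } else {
    pool <- c(Ascomycota = 0.65, Basidiomycota = 0.15,
              Mortierellomycota = 0.10, Chytridiomycota = 0.07,
              Zoopagomycota = 0.03)
    genera <- c("Mortierella", "Pseudogymnoascus", "Solicoccozyma",
                "Bradymyces", "Fusarium", "Alternaria")
  }
  phylum <- sample(names(pool), length(ids), replace = TRUE, prob = pool)
  gprob <- 0.6^seq_along(genera)
  genus <- sample(genera, length(ids), replace = TRUE,
                  prob = gprob / sum(gprob))
  data.frame(taxon_id = ids, phylum = phylum,
             class = paste0(substr(phylum, 1, 4), "_class"),
             order = paste0(substr(phylum, 1, 4), "_order"),
             family = paste0(substr(phylum, 1, 4), "_family"),
             genus = genus, stringsAsFactors = FALSE)
}

#' Generate paired count tables with planted structure
#'
#' See the package vignette for the latent model. Counts in each domain sum
#' exactly to `cfg$depth` per sample (before optional zero-inflation).
#'
#' @param cfg a `synthetic_config`.
#' @param meta metadata from [generate_metadata()] under the same config.
#' @return list: `bacteria`, `fungi` (`abundance_table`s) and `truth`, a
#'   `synthetic_truth` list with `module_of` (named module id, NA for
#'   unstructured taxa), `hub_taxa`, `connector_taxa`,
#'   `connector_modules`, `metal_responders` (data.frame taxon/metal/slope),
#'   `group_of`, and the effective loadings.
#' @export
generate_counts <- function(cfg, meta) {
  validate_synthetic_config(cfg)
  n_s <- nrow(meta)
  n_modules <- length(cfg$module_sizes)
  span <- min(cfg$connector_span, n_modules)
  bact_ids <- sprintf("bASV%04d", seq_len(cfg$n_taxa_bact))
  fungi_ids <- sprintf("fASV%04d", seq_len(cfg$n_taxa_fungi))
  ids <- c(bact_ids, fungi_ids)
  n_taxa <- length(ids)

  # deterministic structural layout: module members (bacteria-heavy),
  # then connectors and responders from the remaining bacteria
  bact_free <- bact_ids
  fungi_free <- fungi_ids
  module_of <- stats::setNames(rep(NA_integer_, n_taxa), ids)
  hub_taxa <- character(0)
  for (m in seq_len(n_modules)) {
    nb <- min(round(cfg$module_sizes[m] * cfg$module_bact_frac),
              length(bact_free))
    nf <- cfg$module_sizes[m] - nb
    if (nf > length(fungi_free)) {
      nb <- nb + (nf - length(fungi_free))
      nf <- length(fungi_free)
    }
    members <- c(bact_free[seq_len(nb)],
                 if (nf > 0) fungi_free[seq_len(nf)])
    bact_free <- bact_free[-seq_len(nb)]
    if (nf > 0) fungi_free <- fungi_free[-seq_len(nf)]
    module_of[members] <- m
    hub_taxa <- c(hub_taxa,
                  members[seq_len(min(cfg$n_hubs_per_module,
                                      length(members)))])
  }
  connector_taxa <- bact_free[seq_len(cfg$n_connectors)]
  if (cfg$n_connectors > 0) bact_free <- bact_free[-seq_len(cfg$n_connectors)]
  responder_taxa <- bact_free[seq_len(cfg$n_metal_responders)]
  responder_metals <- rep(c("Cd", "Hg", "Pb", "Zn", "Cu"),
                          length.out = cfg$n_metal_responders)
  structural <- c(names(module_of)[!is.na(module_of)], connector_taxa,
                  responder_taxa)

  # factor loadings; hubs get a boosted squared loading (capped), connectors
  # spread a 0.98 variance budget over `span` correlated factors
  rho_f <- if (cfg$rho_within > 0) cfg$rho_between / cfg$rho_within else 0
  a_mem <- sqrt(cfg$rho_within)
  a_hub <- sqrt(min(cfg$rho_within + cfg$hub_boost, 0.98))
  b_conn <- if (span > 0) sqrt(0.98 / (span * (1 + (span - 1) * rho_f))) else 0
  loadings <- matrix(0, n_taxa, max(n_modules, 1),
                     dimnames = list(ids, NULL))
  for (m in seq_len(n_modules)) {
    members <- names(module_of)[!is.na(module_of) & module_of == m]
    loadings[members, m] <- a_mem
    loadings[intersect(members, hub_taxa), m] <- a_hub
  }
  conn_mods <- seq_len(span)
  loadings[connector_taxa, conn_mods] <- b_conn
  factor_var <- rowSums(loadings^2)
  factor_var[connector_taxa] <- b_conn^2 * span * (1 + (span - 1) * rho_f)
  if (any(factor_var > 1 + 1e-9))
    stop("implied latent covariance is not positive semi-definite")

  with_seed(cfg$seed + 1L, {
    taxonomy_b <- make_taxonomy(bact_ids, "bacteria")
    taxonomy_f <- make_taxonomy(fungi_ids, "fungi")
    mu <- ifelse(ids %in% structural,
                 stats::rnorm(n_taxa, cfg$baseline_struct_mean,
                              cfg$baseline_struct_sd),
                 stats::rnorm(n_taxa, cfg$baseline_bg_mean,
                              cfg$baseline_bg_sd))
    shared_f <- stats::rnorm(n_s)
    fac <- sqrt(rho_f) * shared_f +
      sqrt(1 - rho_f) * matrix(stats::rnorm(n_s * ncol(loadings)), n_s)
    # per-group scaling of planted correlations: corr within group g is
    # rho * scale_g, with the residual re-inflated to keep unit variance
    scale_g <- vapply(meta$group, function(g) {
      s <- cfg$rho_group_scale[g]
      if (is.na(s)) 1 else unname(s)
    }, numeric(1))
    common <- loadings %*% t(fac)
    noise <- matrix(stats::rnorm(n_taxa * n_s), n_taxa)
    z <- sweep(common, 2, sqrt(scale_g), "*") +
      noise * sqrt(pmax(0, 1 - outer(factor_var, scale_g)))
    eta <- mu + cfg$latent_sd * z
    slopes <- numeric(0)
    if (cfg$n_metal_responders > 0) {
      for (i in seq_along(responder_taxa)) {
        conc <- log(pmax(meta[[responder_metals[i]]], 1e-12))
        zscore <- if (stats::sd(conc) > 0)
          (conc - mean(conc)) / stats::sd(conc) else rep(0, n_s)
        eta[responder_taxa[i], ] <- eta[responder_taxa[i], ] +
          cfg$effect_size_metal * zscore
      }
      slopes <- rep(cfg$effect_size_metal, cfg$n_metal_responders)
    }
    draw <- function(sel_ids) {
      e <- eta[sel_ids, , drop = FALSE]
      p <- exp(sweep(e, 2, apply(e, 2, max)))  # stabilized softmax
      p <- sweep(p, 2, colSums(p), "/")
      counts <- sapply(seq_len(n_s), function(s)
        stats::rmultinom(1, cfg$depth, p[, s]))
      if (cfg$zero_inflation > 0) {
        drop <- matrix(stats::runif(length(counts)) < cfg$zero_inflation,
                       nrow(counts))
        counts[drop] <- 0
      }
      dimnames(counts) <- list(sel_ids, meta$sample_id)
      t(counts)
    }
    bact <- abundance_table(draw(bact_ids), "bacteria", taxonomy_b)
    fungi <- abundance_table(draw(fungi_ids), "fungi", taxonomy_f)
    truth <- structure(list(
      module_of = module_of,
      hub_taxa = hub_taxa,
      connector_taxa = connector_taxa,
      connector_modules = conn_mods,
      metal_responders = data.frame(taxon = responder_taxa,
                                    metal = responder_metals,
                                    slope = slopes,
                                    stringsAsFactors = FALSE),
      group_of = stats::setNames(meta$group, meta$sample_id),
      loadings = list(member = a_mem, hub = a_hub, connector = b_conn,
                      factor_cor = rho_f)),
      class = "synthetic_truth")
    list(bacteria = bact, fungi = fungi, truth = truth)
  })
}

#' Simulate a complete dataset
#'
#' @param cfg a `synthetic_config`.
#' @return list: `bacteria`, `fungi`, `meta`, `background`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  meta <- generate_metadata(cfg)
  counts <- generate_counts(cfg, meta)
  c(counts[c("bacteria", "fungi")],
    list(meta = meta, background = cfg$background_values, truth = counts$truth,
         config = cfg))
}

#' Write a simulated dataset to a directory as TSV + JSON
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  write_abundance(sim$bacteria, f("bacteria_counts.tsv"),
                  f("bacteria_taxonomy.tsv"))
  write_abundance(sim$fungi, f("fungi_counts.tsv"), f("fungi_taxonomy.tsv"))
  write_sample_frame(sim$meta, f("metadata.tsv"))
  write_background(sim$background, f("background.tsv"))
  truth <- sim$truth
  truth_df <- data.frame(
    taxon = names(truth$module_of),
    module = unname(truth$module_of),
    is_hub = names(truth$module_of) %in% truth$hub_taxa,
    is_connector = names(truth$module_of) %in% truth$connector_taxa,
    stringsAsFactors = FALSE)
  utils::write.table(truth_df, f("truth_modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$metal_responders, f("truth_responders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg_json <- lapply(unclass(cfg), function(x)
    if (is.list(x)) lapply(x, as.list) else x)
  jsonlite::write_json(cfg_json, f("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("bacteria_counts.tsv", "bacteria_taxonomy.tsv",
             "fungi_counts.tsv", "fungi_taxonomy.tsv", "metadata.tsv",
             "background.tsv", "truth_modules.tsv", "truth_responders.tsv",
             "config.json")
  invisible(stats::setNames(file.path(dir, files), files))
}
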