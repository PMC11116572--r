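# End-to-end pipeline and a small command-line front end.

default_run_config <- function() {
  list(
    r_threshold = 0.7,
    alpha = 0.05,
    prevalence = 1 / 3,
    genus_threshold = 0.10,
    n_perm = 999,
    seed = 1,
    ordination_rank = NULL,   # NULL = ASV level
    heatmap_rank = "phylum")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a paired bacterial/fungal dataset, then computes the
#' pollution report, alpha diversity with between-group Mann-Whitney tests,
#' Bray-Curtis ordination and ANOSIM per domain, the environment-taxon
#' correlation table, community-vs-metal Mantel tests, the genus-level
#' cross-domain correlation matrix, and one co-occurrence network per sample
#' group (with topology, modules, Zi/Pi and keystone taxa). All outputs are
#' written under `out_dir` together with a JSON manifest (seed, thresholds,
#' file checksums); the run is deterministic given the seed.
#'
#' @param config list of options overriding the defaults: `r_threshold`
#'   (0.7), `alpha` (0.05), `prevalence` (1/3), `genus_threshold` (0.10),
#'   `n_perm` (999), `seed` (1), `heatmap_rank` ("phylum"), plus either
#'   `input_dir` (a directory written by [write_dataset()]) or
#'   `synthetic` (arguments for [synthetic_config()]).
#' @param out_dir output directory.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with every computed object plus the manifest.
#' @export
run_all <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- utils::modifyList(default_run_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  dat <- stage("input", {
    if (!is.null(cfg$input_dir)) {
      say("loading dataset from %s", cfg$input_dir)
      d <- cfg$input_dir
      list(bacteria = read_abundance(file.path(d, "bacteria_counts.tsv"),
                                     file.path(d, "bacteria_taxonomy.tsv"),
                                     "bacteria"),
           fungi = read_abundance(file.path(d, "fungi_counts.tsv"),
                                  file.path(d, "fungi_taxonomy.tsv"),
                                  "fungi"),
           meta = read_sample_frame(file.path(d, "metadata.tsv")),
           background = read_background(file.path(d, "background.tsv")))
    } else {
      sc <- do.call(synthetic_config,
                    utils::modifyList(list(seed = cfg$seed),
                                      cfg$synthetic %||% list()))
      say("simulating dataset (seed %d)", sc$seed)
      sim <- simulate_dataset(sc)
      write_dataset(sim, f("dataset"))
      sim
    }
  })
  meta <- dat$meta
  groups <- unique(meta$group)

  say("pollution indices")
  pol <- stage("pollution", pollution_report(meta, dat$background))
  utils::write.table(as.data.frame(pol), f("pollution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pli_test <- stage("pollution", group_compare(pol$pli, meta$group))

  say("alpha diversity")
  divs <- stage("diversity", lapply(
    list(bacteria = dat$bacteria, fungi = dat$fungi), alpha_diversity))
  div_df <- do.call(rbind, lapply(names(divs), function(d)
    cbind(domain = d, divs[[d]],
          group = meta$group[match(divs[[d]]$sample_id, meta$sample_id)])))
  utils::write.table(div_df, f("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  div_tests <- stage("diversity", do.call(rbind, lapply(
    names(divs), function(d) {
      do.call(rbind, lapply(c("coverage", "chao1", "simpson"), function(ix) {
        gt <- group_compare(divs[[d]][[ix]], meta$group)
        data.frame(domain = d, index = ix, U = gt$statistic,
                   p = gt$p_value, stringsAsFactors = FALSE)
      }))
    })))
  utils::write.table(div_tests, f("diversity_group_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("ordination and ANOSIM")
  ordi <- stage("ordination", lapply(
    list(bacteria = dat$bacteria, fungi = dat$fungi), function(tab) {
      d <- bray_curtis(tab)
      list(dist = d, pcoa = ordinate(d),
           anosim = anosim(d, meta$group[match(rownames(tab$counts),
                                               meta$sample_id)],
                           n_perm = cfg$n_perm, seed = cfg$seed))
    }))
  ano_df <- do.call(rbind, lapply(names(ordi), function(d)
    data.frame(domain = d, R = ordi[[d]]$anosim$statistic,
               p = ordi[[d]]$anosim$p_value,
               n_perm = ordi[[d]]$anosim$n_perm)))
  utils::write.table(ano_df, f("anosim.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (d in names(ordi)) {
    pts <- ordi[[d]]$pcoa$points
    utils::write.table(
      data.frame(sample_id = rownames(pts), pts,
                 explained_1 = ordi[[d]]$pcoa$explained[1],
                 explained_2 = ordi[[d]]$pcoa$explained[2]),
      f(sprintf("ordination_%s.tsv", d)), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  say("environment-taxon correlation (%s level)", cfg$heatmap_rank)
  heat <- stage("association", do.call(rbind, lapply(
    list(dat$bacteria, dat$fungi), function(tab)
      cbind(domain = tab$domain,
            env_taxon_correlation(tab, meta, rank = cfg$heatmap_rank)))))
  utils::write.table(heat, f("env_taxon_correlation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("Mantel tests (community vs metals)")
  metal_mat <- scale(log(as.matrix(meta[, metal_vocabulary()]) + 1e-12))
  d_metal <- stats::dist(metal_mat)
  mantel_df <- stage("association", do.call(rbind, lapply(
    names(ordi), function(d) {
      mt <- mantel_test(ordi[[d]]$dist, d_metal, n_perm = cfg$n_perm,
                        seed = cfg$seed)
      data.frame(domain = d, r = mt$statistic, p = mt$p_value,
                 n_perm = mt$n_perm)
    })))
  utils::write.table(mantel_df, f("mantel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("genus-level cross-domain correlation")
  cross <- stage("association",
                 genus_cross_domain(dat$bacteria, dat$fungi,
                                    threshold = cfg$genus_threshold))
  utils::write.table(cross, f("genus_cross_domain.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  nets <- list()
  topo_rows <- list()
  key_rows <- list()
  for (g in groups) {
    ids <- meta$sample_id[meta$group == g]
    sub <- function(tab) abundance_table(
      tab$counts[ids, , drop = FALSE], tab$domain, tab$taxonomy)
    net <- stage(paste0("network:", g), {
      n <- build_network(sub(dat$bacteria), sub(dat$fungi),
                         r_threshold = cfg$r_threshold, alpha = cfg$alpha,
                         prevalence = cfg$prevalence)
      analyze_network(n, seed = cfg$seed)
    })
    say("network [%s]: %d nodes, %d edges", g,
        igraph::vcount(net$net$graph), igraph::ecount(net$net$graph))
    nets[[g]] <- net
    if (igraph::ecount(net$net$graph) > 0) {
      write_conet_graph(net$net, f(sprintf("network_%s.graphml", g)),
                        "graphml")
      write_conet_graph(net$net, f(sprintf("network_%s_edges.tsv", g)),
                        "edgelist")
    }
    utils::write.table(net$zipi, f(sprintf("network_%s_nodes.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    topo_rows[[g]] <- cbind(group = g, net$topology)
    keys <- net$keystone %||% character(0)
    key_rows[[g]] <- if (length(keys) == 0)
      data.frame(group = character(0), taxon = character(0))
    else data.frame(group = g, taxon = keys, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, topo_rows), f("topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, key_rows), f("keystone.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "soilconet",
    version = as.character(utils::packageVersion("soilconet")),
    seed = cfg$seed,
    thresholds = cfg[c("r_threshold", "alpha", "prevalence",
                       "genus_threshold", "n_perm")],
    outputs = lapply(stats::setNames(files, files), function(p)
      list(md5 = unname(tools::md5sum(file.path(out_dir, p))))))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote %d files to %s", length(files) + 1, out_dir)
  invisible(list(data = dat, pollution = pol, pli_test = pli_test,
                 diversity = divs, diversity_tests = div_tests,
                 ordination = ordi, heatmap = heat, mantel = mantel_df,
                 cross_domain = cross, networks = nets, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pollution`, `diversity`, `assoc`, `network`,
#' `run-all`. Shared flags: `--seed`, `--out`, `--config` (JSON file of
#' [run_all()] options). Invoked by the `inst/cli/soilconet.R` script; can
#' be called directly with an argument vector for testing.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: soilconet <simulate|pollution|diversity|assoc|network|run-all>",
    "[--config cfg.json] [--seed N] [--out DIR] [--input DIR]")
  if (length(args) == 0) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- list(seed = 1, out = ".", config = NULL, input = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown flag ", args[i], "\n", usage,
                                    call. = FALSE)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  config <- if (!is.null(opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  config$seed <- opts$seed
  if (!is.null(opts$input)) config$input_dir <- opts$input

  run_partial <- function(keep) {
    res <- run_all(config, out_dir = opts$out)
    invisible(res[keep])
  }
  switch(cmd,
    "simulate" = {
      sc <- do.call(synthetic_config,
                    utils::modifyList(list(seed = opts$seed),
                                      config$synthetic %||% list()))
      invisible(write_dataset(simulate_dataset(sc), opts$out))
    },
    "run-all" = invisible(run_all(config, out_dir = opts$out)),
    "pollution" = run_partial(c("pollution", "pli_test")),
    "diversity" = run_partial(c("diversity", "diversity_tests")),
    "assoc" = run_partial(c("heatmap", "mantel", "cross_domain")),
    "network" = run_partial("networks"),
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
}
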