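## Config-driven end-to-end runs: read inputs, infer, write outputs and a
## reproducibility manifest. The YAML config mirrors the function arguments:
##
##   datasets:
##     - expression: expr1.tsv
##       metadata: meta1.tsv      # optional; steady-state if absent
##       prior: prior1.tsv        # optional if a top-level prior is given
##       tau: 15                  # optional, default from top level
##   prior: prior.tsv             # shared prior (fallback)
##   gold_standard: gold.tsv      # optional
##   mode: mtl                    # mtl | stl
##   tfa_mode: prior_pinv         # prior_pinv | expression
##   tau: 0
##   prior_weight: 1
##   n_boot: 20
##   gamma: 1
##   seed: 42
##   num_workers: 1
##   output_dir: out/

#' Run the full inference workflow from a configuration
#'
#' Reads expression, metadata, prior and gold-standard files as declared in
#' the config, runs [multigrn()], and writes per-dataset network TSVs, a
#' combined network TSV, precision-recall TSVs and a summary JSON plus a run
#' manifest (config echo, package version, seed) to the output directory.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list.
#' @param output_dir overrides the config's output directory.
#' @return The [multigrn()] fit, invisibly.
#' @export
run_workflow <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0)
    stop_msg("config stage 'read': no datasets declared")
  out_dir <- output_dir %||% cfg$output_dir %||% "multigrn_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- if (is.character(config)) dirname(config) else "."
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }

  datasets <- list()
  priors <- list()
  taus <- numeric(0)
  for (i in seq_along(cfg$datasets)) {
    entry <- cfg$datasets[[i]]
    if (is.null(entry$expression))
      stop_msg("config stage 'read': dataset %d has no expression path", i)
    ds <- read_expression(resolve(entry$expression),
                          resolve(entry$metadata),
                          entry$id %||% sprintf("dataset_%d", i))
    prior_path <- entry$prior %||% cfg$prior
    if (is.null(prior_path))
      stop_msg("config stage 'read': dataset %d has no prior and no shared prior", i)
    datasets[[i]] <- ds
    priors[[i]] <- read_prior(resolve(prior_path))
    taus[i] <- entry$tau %||% cfg$tau %||% 0
  }
  gold <- if (!is.null(cfg$gold_standard))
    read_gold_standard(resolve(cfg$gold_standard)) else NULL

  fit <- multigrn(datasets, priors, gold = gold,
                  mode = cfg$mode %||% "mtl",
                  tfa_mode = cfg$tfa_mode %||% "prior_pinv",
                  tau = taus,
                  prior_weight = cfg$prior_weight %||% 1,
                  n_boot = cfg$n_boot %||% 20,
                  gamma = cfg$gamma %||% 1,
                  seed = cfg$seed %||% 42,
                  num_workers = cfg$num_workers %||% 1)

  for (id in fit$dataset_ids)
    write_network(fit$networks[[id]], file.path(out_dir, paste0("network_", id, ".tsv")))
  write_network(fit$combined, file.path(out_dir, "network_combined.tsv"))
  summary_json <- list(mode = fit$mode, n_boot = fit$n_boot, seed = fit$seed,
                       datasets = as.list(fit$dataset_ids))
  if (!is.null(fit$evaluation)) {
    for (nm in names(fit$evaluation$pr)) {
      curve <- fit$evaluation$pr[[nm]]
      write.table(data.frame(recall = curve$recall, precision = curve$precision),
                  file.path(out_dir, paste0("pr_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary_json$aupr <- as.list(fit$evaluation$aupr)
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = cfg, seed = fit$seed,
                   package_version = as.character(utils::packageVersion("multigrn")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}

#' Write a synthetic multi-study benchmark to disk
#'
#' Generates a ground-truth network, expression datasets, a (optionally
#' corrupted) prior and the gold standard of planted edges, in the same TSV
#' formats the readers consume, plus a truth edge list for evaluation.
#'
#' @param out_dir output directory.
#' @param genes,tfs,datasets,edges_per_gene,shared_fraction,seed passed to
#'   [generate_truth()].
#' @param samples_per_dataset,noise_sigma passed to [generate_expression()].
#' @param prior_recall,false_edge_denominator passed to [corrupt_prior()].
#' @return Invisible list of the written file paths.
#' @export
simulate_study <- function(out_dir, genes = 100, tfs = 10, datasets = 3,
                           edges_per_gene = 2, shared_fraction = 0.8,
                           samples_per_dataset = 50, noise_sigma = 1,
                           prior_recall = 0.5, false_edge_denominator = 5,
                           seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(genes, tfs, datasets, edges_per_gene,
                          shared_fraction, seed)
  expr <- generate_expression(truth, samples_per_dataset, noise_sigma)
  prior <- corrupt_prior(truth, prior_recall, false_edge_denominator)
  gold <- gold_standard_from_truth(truth)
  paths <- list()
  for (d in seq_along(expr)) {
    paths[[paste0("expression_", d)]] <-
      write_expression(expr[[d]], file.path(out_dir, sprintf("expression_%d.tsv", d)),
                       file.path(out_dir, sprintf("metadata_%d.tsv", d)))
  }
  paths$prior <- write_prior(prior, file.path(out_dir, "prior.tsv"))
  gold_path <- file.path(out_dir, "gold_standard.tsv")
  write.table(as.data.frame(gold), gold_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$gold_standard <- gold_path
  truth_path <- file.path(out_dir, "truth_edges.tsv")
  write.table(truth_edges(truth), truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$truth <- truth_path
  invisible(paths)
}
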