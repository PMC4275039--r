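# End-to-end orchestration: simulate (or load) inputs, tabulate/ingest MK
# counts, fit the selection model for both contexts, compute network
# metrics and the connectedness power law, and run the hub and betweenness
# comparisons. Every artifact is plain TSV/JSON and a run is a
# deterministic function of the configured seed.

#' Pipeline configuration
#'
#' Defaults mirror the study constants: 1000 bp upstream window, top-20%
#' hub rule, selection-class boundaries at -1 and +1, one-tailed hub
#' comparisons.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param sim a [sim_config()] for simulated inputs (its seed is overridden
#'   by `seed`).
#' @param simulate generate inputs (default); otherwise `edges_path`,
#'   `counts_coding_path` and `counts_regulatory_path` must name existing
#'   files.
#' @param edges_path,counts_coding_path,counts_regulatory_path input files
#'   when `simulate = FALSE`.
#' @param hub_fraction nominal hub fraction.
#' @param thresholds selection-class boundaries.
#' @param n_boot bootstrap replicates for the power-law goodness of fit.
#' @param display_cap upper gamma cap for the summary histogram.
#' @param out_dir directory for artifacts; `NULL` keeps results in memory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            simulate = TRUE,
                            edges_path = NULL, counts_coding_path = NULL,
                            counts_regulatory_path = NULL,
                            hub_fraction = 0.20, thresholds = c(-1, 1),
                            n_boot = 200, display_cap = 2,
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), sim = sim, simulate = simulate,
              edges_path = edges_path,
              counts_coding_path = counts_coding_path,
              counts_regulatory_path = counts_regulatory_path,
              hub_fraction = hub_fraction, thresholds = thresholds,
              n_boot = n_boot, display_cap = display_cap, out_dir = out_dir)
  if (!simulate) {
    missing <- c(edges_path, counts_coding_path, counts_regulatory_path)
    if (length(missing) < 3 || !all(file.exists(missing))) {
      stop_input("simulation disabled but input paths are missing")
    }
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  cfg$sim$seed <- cfg$seed
  cfg$sim$hub_fraction <- hub_fraction
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments; a `sim`
#' sub-map onto [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_input("reading YAML configs needs the yaml package")
  }
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the TRN and true selection coefficients (with any
#' configured hub effect), simulate or load MK count tables for both
#' contexts, fit the Poisson random-effects model and estimate per-gene
#' gamma, build the network and per-node metrics, fit the connectedness
#' power law with bootstrap goodness of fit, and run the hub-versus-non-hub
#' and betweenness-by-selection comparisons plus the gamma-distribution
#' summary. Group comparisons whose selection classes are empty at the
#' simulated scale are recorded as skipped rather than aborting the run.
#'
#' @param config a [pipeline_config()].
#' @return list of class `trn_pipeline` with elements `counts`, `fits`,
#'   `gamma`, `metrics`, `power_law`, `comparisons`, `gamma_summary`,
#'   `truth` (when simulated), `log` and `config`; artifacts are written
#'   under `config$out_dir` when set.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, sim = sim_config(n_tf = 40, n_target = 200))
#' res <- run_pipeline(cfg)
#' res$gamma_summary$fractions
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, message = msg,
                                          stringsAsFactors = FALSE)
  }
  truth <- NULL
  if (config$simulate) {
    net_sim <- simulate_trn(config$sim)
    edges <- net_sim$edges
    truth <- net_sim$truth
    node_ids <- c(names(truth$tf_degree), names(truth$target_in_degree))
    n_nodes <- length(node_ids)
    hub_flag <- setNames(rep(FALSE, n_nodes), node_ids)
    hub_flag[names(truth$hub_tf)[truth$hub_tf]] <- TRUE
    hub_flag[names(truth$hub_target)[truth$hub_target]] <- TRUE

    gam_c <- draw_gamma_profile(n_nodes, config$sim$gamma_preset_coding,
                                seed = config$seed + 11L)
    gam_r <- draw_gamma_profile(n_nodes, config$sim$gamma_preset_regulatory,
                                seed = config$seed + 12L)
    gam_c$gene_id <- node_ids
    gam_r$gene_id <- node_ids
    if (config$sim$hub_gamma_shift != 0) {
      gam_c$gamma_true <- gam_c$gamma_true +
        config$sim$hub_gamma_shift * hub_flag[gam_c$gene_id]
      gam_r$gamma_true <- gam_r$gamma_true +
        config$sim$hub_gamma_shift * hub_flag[gam_r$gene_id]
    }
    truth$gamma_coding <- gam_c
    truth$gamma_regulatory <- gam_r
    counts_c <- simulate_counts(gam_c, config$sim, "coding",
                                seed = config$seed + 21L)
    counts_r <- simulate_counts(gam_r, config$sim, "regulatory",
                                seed = config$seed + 22L)
    note("simulate", sprintf("TRN with %d TFs, %d targets, %d edges",
                             config$sim$n_tf, config$sim$n_target, nrow(edges)))
  } else {
    edges <- read.delim(config$edges_path, stringsAsFactors = FALSE)
    counts_c <- read_mk_counts(config$counts_coding_path)
    counts_r <- read_mk_counts(config$counts_regulatory_path)
    note("load", "inputs loaded from configured paths")
  }

  fit_c <- fit_mk_glmm(counts_c, context = "coding")
  fit_r <- fit_mk_glmm(counts_r, context = "regulatory")
  note("fit", sprintf("coding: %d genes (%d dropped); regulatory: %d genes (%d dropped)",
                      fit_c$n_genes, nrow(fit_c$dropped),
                      fit_r$n_genes, nrow(fit_r$dropped)))
  gamma <- rbind(estimate_gamma(fit_c, thresholds = config$thresholds),
                 estimate_gamma(fit_r, thresholds = config$thresholds))

  net <- build_network(edges)
  metrics <- node_metrics(net, hub_fraction = config$hub_fraction)
  pooled_k <- metrics$k
  pl <- fit_power_law_tail(pooled_k)
  pl <- bootstrap_gof(pl, pooled_k, n_boot = config$n_boot,
                      seed = config$seed + 31L)
  note("network", sprintf("power law: x_min=%d alpha=%.2f gof_p=%.3f",
                          pl$x_min, pl$alpha, pl$gof_p))

  comparisons <- compare_hub_vs_nonhub(gamma, metrics)
  for (ctx in c("coding", "regulatory")) {
    row <- tryCatch(
      compare_betweenness_by_selection(gamma, metrics, ctx,
                                       thresholds = config$thresholds),
      error = function(e) {
        note("compare", paste0("betweenness-", ctx, " skipped: ",
                               conditionMessage(e)))
        NULL
      })
    if (!is.null(row)) comparisons <- rbind(comparisons, row)
  }

  gamma_summary <- summarize_gamma_distribution(
    gamma[gamma$context == "regulatory", ], thresholds = config$thresholds,
    display_cap = config$display_cap)

  res <- list(counts = list(coding = counts_c, regulatory = counts_r),
              fits = list(coding = fit_c, regulatory = fit_r),
              gamma = gamma, metrics = metrics, power_law = pl,
              comparisons = comparisons, gamma_summary = gamma_summary,
              truth = truth, log = do.call(rbind, log), config = config)
  class(res) <- "trn_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res)
  res
}

module_header <- function(module) {
  sprintf("# trnsel %s | module: %s",
          as.character(utils::packageVersion("trnsel")), module)
}

write_tsv_with_header <- function(df, path, module) {
  con <- file(path, "w")
  writeLines(module_header(module), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

write_pipeline_artifacts <- function(res) {
  dir <- res$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_with_header(res$counts$coding, file.path(dir, "counts_coding.tsv"),
                        "synthetic_data")
  write_tsv_with_header(res$counts$regulatory,
                        file.path(dir, "counts_regulatory.tsv"), "synthetic_data")
  write_tsv_with_header(res$gamma, file.path(dir, "gamma_estimates.tsv"),
                        "selection_model")
  write_tsv_with_header(res$metrics, file.path(dir, "node_metrics.tsv"),
                        "network_analysis")
  write_tsv_with_header(res$comparisons, file.path(dir, "comparisons.tsv"),
                        "group_stats")
  pl <- res$power_law
  jsonlite::write_json(
    list(module = "network_analysis",
         x_min = pl$x_min, alpha = pl$alpha, ks_statistic = pl$ks_statistic,
         gof_p = pl$gof_p, n_tail = pl$n_tail, n = pl$n),
    file.path(dir, "power_law.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$gamma_summary, file.path(dir, "gamma_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  cfg$sim$gamma_preset_coding <- unclass(cfg$sim$gamma_preset_coding)
  cfg$sim$gamma_preset_regulatory <- unclass(cfg$sim$gamma_preset_regulatory)
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_tsv_with_header(res$log, file.path(dir, "run_log.tsv"), "pipeline")
  invisible(dir)
}

#' @export
print.trn_pipeline <- function(x, ...) {
  cat("TRN selection pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  genes: %d coding / %d regulatory gamma estimates\n",
              sum(x$gamma$context == "coding"),
              sum(x$gamma$context == "regulatory")))
  cat(sprintf("  power law: x_min=%d alpha=%.2f gof_p=%.3f\n",
              x$power_law$x_min, x$power_law$alpha, x$power_law$gof_p))
  cat("  regulatory gamma class fractions:\n")
  print(round(x$gamma_summary$fractions, 3))
  invisible(x)
}

#' Summarize a gamma-estimate distribution
#'
#' Selection-class fractions plus a binned histogram of the estimates.
#' Genes above `display_cap` are excluded from the histogram (for
#' readability, as large positive outliers stretch the axis) but are always
#' counted in the fractions.
#'
#' @param gamma data.frame with a `gamma_hat` column.
#' @param thresholds class boundaries.
#' @param display_cap histogram cap.
#' @param binwidth histogram bin width.
#' @return list with `fractions` (near_neutral, negative, positive), `n`,
#'   `n_above_cap` and `histogram` (data.frame mid, count).
#' @export
summarize_gamma_distribution <- function(gamma, thresholds = c(-1, 1),
                                         display_cap = 2, binwidth = 0.25) {
  if (nrow(gamma) == 0) stop_input("empty gamma table")
  cls <- classify_selection(gamma$gamma_hat, thresholds)
  fractions <- c(near_neutral = mean(cls == "near_neutral"),
                 negative = mean(cls == "negative"),
                 positive = mean(cls == "positive"))
  shown <- gamma$gamma_hat[gamma$gamma_hat <= display_cap]
  breaks <- seq(floor(min(shown) / binwidth) * binwidth,
                display_cap + binwidth, by = binwidth)
  h <- hist(shown, breaks = breaks, plot = FALSE)
  list(fractions = fractions, n = nrow(gamma),
       n_above_cap = sum(gamma$gamma_hat > display_cap),
       histogram = data.frame(mid = h$mids, count = h$counts))
}
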