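#' Configuration of the integrative miRNA-mRNA pipeline
#'
#' Collects all stage parameters with the conventional defaults: DE at
#' adjusted p < 0.05, three PLS components, 1000 bootstrap iterations,
#' association threshold |S| > 0.8, p < 0.01, FDR < 0.05, target-site
#' expectation cutoff 2.5.
#'
#' @param de_alpha adjusted-p threshold for differential expression.
#' @param pls_components latent components v for the association score.
#' @param n_boot resampling iterations for significance.
#' @param b_threshold minimum |association score| for an edge.
#' @param p_threshold maximum resampling p-value.
#' @param fdr_threshold maximum Benjamini-Hochberg FDR.
#' @param target_cutoff maximum duplex expectation for a candidate site.
#' @param sig_method `"bootstrap"` (paired case bootstrap) or
#'   `"decoupled"` (exchangeability null); see [pair_significance()].
#' @param negative_only restrict edges to negative (repression) scores.
#' @param normalize quantile-normalize both matrices before testing
#'   (FALSE by default: simulated and pre-summarized inputs are already
#'   normalized).
#' @param seed integer seed for all resampling.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(de_alpha = 0.05, pls_components = 3,
                            n_boot = 1000, b_threshold = 0.8,
                            p_threshold = 0.01, fdr_threshold = 0.05,
                            target_cutoff = 2.5,
                            sig_method = c("bootstrap", "decoupled"),
                            negative_only = FALSE, normalize = FALSE,
                            seed = 1L) {
  sig_method <- match.arg(sig_method)
  stopifnot(de_alpha >= 0, de_alpha <= 1,
            pls_components >= 1, n_boot >= 1,
            b_threshold >= 0, p_threshold >= 0, p_threshold <= 1,
            fdr_threshold >= 0, fdr_threshold <= 1, target_cutoff >= 0)
  structure(list(de_alpha = de_alpha,
                 pls_components = as.integer(pls_components),
                 n_boot = as.integer(n_boot), b_threshold = b_threshold,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 target_cutoff = target_cutoff, sig_method = sig_method,
                 negative_only = negative_only, normalize = normalize,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the integrative miRNA-mRNA analysis pipeline
#'
#' Executes the full analysis on paired expression matrices: differential
#' expression of miRNAs and mRNAs (moderated t, BH), restriction of the
#' sequence-candidate pairs to DE endpoints, PLS association scoring,
#' resampling significance with the triple threshold, bipartite network
#' construction with degree summaries/fits and coregulatory modules, and
#' per-miRNA ROC metrics for the network's miRNAs. Every intermediate
#' table is written to `out_dir` together with a JSON manifest (package
#' version, configuration, seed, config hash) and a log; reruns with the
#' same inputs and configuration are bit-identical.
#'
#' @param mirna features x samples miRNA matrix (log2 scale).
#' @param mrna features x samples mRNA matrix (log2 scale).
#' @param condition factor of length n_samples (control/treated).
#' @param candidates sequence-supported candidate pair set.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); NULL for no file output.
#' @return list of class `pipeline_run` with elements `de_mirna`,
#'   `de_mrna`, `candidates_de`, `significance`, `edges`, `network`,
#'   `degrees`, `degree_fits`, `modules`, `coregulated_fraction`, `roc`,
#'   `config`, `out_dir`.
#' @export
run_pipeline <- function(mirna, mrna, condition, candidates,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mirna <- as.matrix(mirna); mrna <- as.matrix(mrna)
  candidates <- as_candidate_pairs(candidates)
  if (isTRUE(config$normalize)) {
    mirna <- stage("normalize", quantile_normalize(mirna))
    mrna <- stage("normalize", quantile_normalize(mrna))
  }

  de_mirna <- stage("de_mirna", moderated_t_test(mirna, condition))
  de_mrna <- stage("de_mrna", moderated_t_test(mrna, condition))
  sel_mir <- select_de(de_mirna, config$de_alpha)
  sel_mrna <- select_de(de_mrna, config$de_alpha)
  say("DE: %d/%d miRNAs, %d/%d mRNAs at adj p < %g",
      length(sel_mir$all), nrow(mirna), length(sel_mrna$all), nrow(mrna),
      config$de_alpha)

  cand_de <- stage("restrict_candidates",
                   restrict_to_de(candidates, sel_mir$all, sel_mrna$all))
  say("candidate pairs among DE features: %d of %d",
      nrow(cand_de), nrow(candidates))

  empty_sig <- data.frame(mirna_id = character(), mrna_id = character(),
                          score = numeric(), b = numeric(),
                          p_value = numeric(), fdr = numeric(),
                          significant = logical())
  if (nrow(cand_de) == 0L || length(sel_mir$all) == 0L ||
      length(sel_mrna$all) == 0L) {
    sig <- empty_sig
  } else {
    X <- t(mirna[sel_mir$all, , drop = FALSE])
    Y <- t(mrna[sel_mrna$all, , drop = FALSE])
    sig <- stage("significance", pair_significance(
      X, Y, cand_de, n_boot = config$n_boot,
      ncomp = min(config$pls_components, nrow(X) - 1L),
      seed = config$seed, method = config$sig_method,
      b_threshold = config$b_threshold,
      p_threshold = config$p_threshold,
      fdr_threshold = config$fdr_threshold))
  }
  edges <- call_significant(sig, config$b_threshold, config$p_threshold,
                            config$fdr_threshold,
                            negative_only = config$negative_only)
  say("significant edges: %d of %d scored pairs", nrow(edges), nrow(sig))

  dir_map <- stats::setNames(de_mirna$direction, de_mirna$feature_id)
  if (nrow(edges) > 0L) edges$direction <- dir_map[edges$mirna_id]
  net <- stage("network", build_network(edges))
  degrees <- degree_summary(net)
  fits <- list(out_degree = NULL, in_degree = NULL)
  if (length(unique(degrees$out_degree[degrees$out_degree > 0])) >= 3L)
    fits$out_degree <- fit_degree_distribution(degrees$out_degree,
                                               "power_law")
  if (length(unique(degrees$in_degree[degrees$in_degree > 0])) >= 3L)
    fits$in_degree <- fit_degree_distribution(degrees$in_degree,
                                              "exponential")
  modules <- find_modules(net)
  coreg <- if (nrow(net$edges) > 0L) coregulated_fraction(net) else NA_real_
  say("network: %d miRNAs, %d mRNAs, %d edges; %d module(s)",
      length(net$mirnas), length(net$mrnas), nrow(net$edges),
      length(modules))

  roc_tab <- NULL
  if (length(net$mirnas) > 0L) {
    roc_tab <- do.call(rbind, lapply(net$mirnas, function(id) {
      rm_ <- roc_metrics(mirna[id, ], condition)
      data.frame(mirna = id, auc = rm_$auc,
                 sensitivity = rm_$sensitivity,
                 specificity = rm_$specificity, accuracy = rm_$accuracy,
                 cutoff = rm_$cutoff, stringsAsFactors = FALSE)
    }))
  }

  out <- structure(list(
    de_mirna = de_mirna, de_mrna = de_mrna, de_selected =
      list(mirna = sel_mir, mrna = sel_mrna),
    candidates_de = cand_de, significance = sig, edges = edges,
    network = net, degrees = degrees, degree_fits = fits,
    modules = modules, coregulated_fraction = coreg, roc = roc_tab,
    config = config, out_dir = out_dir), class = "pipeline_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(de_mirna, "de_mirna.tsv"); wt(de_mrna, "de_mrna.tsv")
    wt(cand_de, "candidates_de.tsv"); wt(sig, "significance.tsv")
    wt(edges, "edges.tsv")
    if (!is.null(roc_tab)) wt(roc_tab, "roc_mirna.tsv")
    if (nrow(net$edges) > 0L)
      write_sif(net, file.path(out_dir, "network.sif"))
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    cfg_file <- file.path(out_dir, "config.json")
    writeLines(cfg_json, cfg_file)
    manifest <- list(
      package = "plsmirnet",
      version = as.character(utils::packageVersion("plsmirnet")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = unclass(config),
      config_md5 = unname(tools::md5sum(cfg_file)),
      n_mirna = nrow(mirna), n_mrna = nrow(mrna),
      n_samples = ncol(mirna),
      n_edges = nrow(edges), n_modules = length(modules))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Integrative miRNA-mRNA pipeline run\n")
  cat("  DE miRNAs:", length(x$de_selected$mirna$all),
      " DE mRNAs:", length(x$de_selected$mrna$all), "\n")
  cat("  scored candidate pairs:", nrow(x$significance),
      " significant edges:", nrow(x$edges), "\n")
  cat("  network:", length(x$network$mirnas), "miRNAs,",
      length(x$network$mrnas), "mRNAs;",
      length(x$modules), "coregulatory module(s)\n")
  invisible(x)
}

#' Benchmark edge recovery on synthetic data
#'
#' Runs the full pipeline on a [simulate_dataset()] result and scores the
#' called edges against the planted ground truth.
#'
#' @param sim a `sim_data` object.
#' @param config a [pipeline_config()].
#' @return list with `precision`, `recall`, `n_called`, `n_planted`, and
#'   the `run` itself.
#' @export
evaluate_recovery <- function(sim, config = pipeline_config()) {
  stopifnot(inherits(sim, "sim_data"))
  run <- run_pipeline(sim$mirna, sim$mrna, sim$condition, sim$candidates,
                      config = config)
  truth_key <- paste(sim$truth$planted_edges$mirna_id,
                     sim$truth$planted_edges$mrna_id)
  called_key <- paste(run$edges$mirna_id, run$edges$mrna_id)
  tp <- sum(called_key %in% truth_key)
  list(precision = if (length(called_key)) tp / length(called_key)
       else NA_real_,
       recall = if (length(truth_key)) tp / length(truth_key)
       else NA_real_,
       n_called = length(called_key), n_planted = length(truth_key),
       run = run)
}
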