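## Configuration-driven orchestration of the three stages: protein-family
## clustering, the molecular thermometer, and gene-content reconstruction.
## All file outputs are TSV (6-decimal probabilities) or JSON and are
## byte-identical across runs with the same configuration and seeds; wall
## times go to the run log only.

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param tree path to the rooted Newick reference tree (required).
#' @param alignment path to the aligned 16S FASTA (thermometer track).
#' @param stem_annotations path to the stem-position TSV; `NULL` marks all
#'   columns as stem.
#' @param ogt_table path to the tip OGT TSV.
#' @param occurrence_matrix path to a genomes x families TSV, or `NULL` to
#'   build it from `hits` + `seq_lengths` + `seq2genome`.
#' @param hits,seq_lengths,seq2genome paths for the clustering front end.
#' @param node_label_map optional path to an ancestor-label TSV.
#' @param out_dir output directory (created if needed).
#' @param tau posterior call/presence threshold, in (0, 1).
#' @param cmax copy-number truncation cap.
#' @param replicates number R of ancestral sequence replicates.
#' @param consensus_fraction stem-mask consensus fraction.
#' @param thresholds clustering thresholds, see [filter_thresholds()].
#' @param seed integer seed used for every stochastic step.
#' @param tracks character subset of `c("thermometer", "gene_content")`.
#' @param fit_config extra options forwarded to [fit_nonhom_t92()] and
#'   [fit_rates()].
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, alignment = NULL, stem_annotations = NULL,
                            ogt_table = NULL, occurrence_matrix = NULL,
                            hits = NULL, seq_lengths = NULL,
                            seq2genome = NULL, node_label_map = NULL,
                            out_dir = "ancstate-out", tau = 0.5, cmax = 10L,
                            replicates = 100L, consensus_fraction = 1,
                            thresholds = filter_thresholds(), seed = 1L,
                            tracks = c("thermometer", "gene_content"),
                            fit_config = list()) {
  stopifnot(tau > 0, tau < 1, replicates >= 1L, cmax >= 2L)
  tracks <- match.arg(tracks, several.ok = TRUE)
  cfg <- list(tree = tree, alignment = alignment,
              stem_annotations = stem_annotations, ogt_table = ogt_table,
              occurrence_matrix = occurrence_matrix, hits = hits,
              seq_lengths = seq_lengths, seq2genome = seq2genome,
              node_label_map = node_label_map, out_dir = out_dir, tau = tau,
              cmax = as.integer(cmax), replicates = as.integer(replicates),
              consensus_fraction = consensus_fraction,
              thresholds = thresholds, seed = as.integer(seed),
              tracks = tracks, fit_config = fit_config)
  required <- c("tree")
  if ("thermometer" %in% tracks) {
    required <- c(required, "alignment", "ogt_table")
  }
  if ("gene_content" %in% tracks && is.null(cfg$occurrence_matrix)) {
    required <- c(required, "hits", "seq_lengths", "seq2genome")
  }
  missing_fields <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(missing_fields)) {
    stop("missing configuration field(s): ", paste(missing_fields, collapse = ", "))
  }
  paths <- unlist(cfg[c("tree", "alignment", "stem_annotations", "ogt_table",
                        "occurrence_matrix", "hits", "seq_lengths",
                        "seq2genome", "node_label_map")])
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("input path(s) do not exist: ", paste(absent, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the config file's directory.
#'
#' @param path config file (.yaml/.yml or .json).
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  path_keys <- c("tree", "alignment", "stem_annotations", "ogt_table",
                 "occurrence_matrix", "hits", "seq_lengths", "seq2genome",
                 "node_label_map")
  for (k in intersect(names(raw), path_keys)) {
    if (!is.null(raw[[k]]) && !file.exists(raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the molecular-thermometer track
#'
#' Reads tree, alignment, stem annotations and OGT table; prunes taxa
#' lacking either a 16S sequence or an OGT (logged); builds the consensus
#' stem mask; calibrates the thermometer; fits the nonhomogeneous T92
#' model; samples replicate ancestral sequences; and writes
#' `calibration.json`, `ancestral_ogt.tsv`, `replicate_ogt.tsv` and
#' `thermometer.log` into the output directory.
#'
#' @param config a `pipeline_config`.
#' @return report fragment (list) with stage status, parameter echo and the
#'   per-ancestor OGT summary.
#' @export
run_thermometer <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "thermometer.log"), "w")
  on.exit(close(logf))
  t0 <- Sys.time()
  tree <- read_newick(config$tree)
  mat <- read_alignment_fasta(config$alignment)
  ogt <- read_ogt_table(config$ogt_table)

  usable <- intersect(tree$tip.label, intersect(rownames(mat), names(ogt)))
  pruned <- setdiff(tree$tip.label, usable)
  if (length(pruned)) {
    log_line(logf, "pruned taxa (missing 16S or OGT): ",
             paste(pruned, collapse = ", "))
  }
  if (length(usable) < 3L) {
    stop("fewer than 3 taxa with both 16S and OGT after pruning")
  }
  tree <- prune_to_taxa(tree, usable)
  if (!is.null(config$node_label_map)) {
    tree <- label_ancestors(tree, read_node_label_map(config$node_label_map))
  }
  mat <- mat[usable, , drop = FALSE]
  mask <- if (is.null(config$stem_annotations)) rep(TRUE, ncol(mat)) else
    build_stem_mask(mat, read_stem_annotations(config$stem_annotations),
                    fraction = config$consensus_fraction)
  aln <- stem_alignment(mat, mask)
  log_line(logf, "stem mask: ", sum(mask), " of ", length(mask), " columns")

  gc <- alignment_stem_gc(aln)
  calib <- calibrate_thermometer(tree, gc, ogt[usable])
  model <- fit_nonhom_t92(tree, aln,
                          utils::modifyList(list(seed = config$seed),
                                            config$fit_config))
  if (!model$convergence) log_line(logf, "WARNING: model fit did not converge")
  reps <- sample_ancestral_replicates(tree, aln, model,
                                      R = config$replicates,
                                      seed = config$seed)
  est <- predict_ancestral_ogt(reps, calib)

  jsonlite::write_json(
    list(slope = calib$slope, intercept = calib$intercept,
         r_pearson = calib$r_pearson, r_pic = calib$r_pic,
         r2_adjusted = calib$r2_adjusted, n_taxa = calib$n_taxa,
         kappa = model$kappa, theta_root = model$theta_root,
         logLik = model$logLik, converged = model$convergence,
         seed = config$seed,
         note = "CI is the percentile interval of replicate OGT predictions; regression-coefficient uncertainty is not propagated"),
    file.path(config$out_dir, "calibration.json"),
    auto_unbox = TRUE, digits = 10)
  write_tsv6(est, file.path(config$out_dir, "ancestral_ogt.tsv"))
  rep_mat <- attr(est, "replicate_ogt")
  write_tsv6(data.frame(node = rownames(rep_mat) %||% est$node,
                        round(rep_mat, 6), check.names = FALSE),
             file.path(config$out_dir, "replicate_ogt.tsv"))
  log_line(logf, "elapsed_s: ",
           format(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  digits = 3))
  list(stage = "thermometer", status = if (model$convergence) "ok" else "warn",
       seed = config$seed, replicates = config$replicates,
       n_taxa = length(usable), pruned_taxa = pruned,
       calibration = list(slope = calib$slope, intercept = calib$intercept,
                          r_pearson = calib$r_pearson, r_pic = calib$r_pic),
       ancestral_ogt = est)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the gene-content track
#'
#' Takes an occurrence matrix (or builds one by clustering a hit table),
#' fits per-family gain-loss-duplication rates, computes node posteriors,
#' calls per-branch events and ancestral content at the configured
#' threshold, and writes `family_rates.tsv`, `node_content.tsv`,
#' `branch_events.tsv`, `gain_rates.tsv` and `gene_content_stats.json`.
#'
#' @param config a `pipeline_config`.
#' @return report fragment (list) with per-ancestor content and event
#'   summaries.
#' @export
run_gene_content <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "gene_content.log"), "w")
  on.exit(close(logf))
  tree <- read_newick(config$tree)
  if (!is.null(config$node_label_map)) {
    tree <- label_ancestors(tree, read_node_label_map(config$node_label_map))
  }
  if (!is.null(config$occurrence_matrix)) {
    mat <- read_occurrence_matrix(config$occurrence_matrix)
  } else {
    hits <- read_hits(config$hits, config$seq_lengths)
    edges <- filter_hits(hits, config$thresholds)
    universe <- unique(c(hits$query, hits$subject))
    fams <- cluster_families(universe, edges)
    write_families(fams, file.path(config$out_dir, "families.tsv"))
    mat <- build_occurrence_matrix(fams, config$seq2genome)
    write_occurrence_matrix(mat, file.path(config$out_dir,
                                           "occurrence_matrix.tsv"))
    log_line(logf, "clustered ", length(fams$families), " families from ",
             length(universe), " sequences")
  }
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing)) {
    stop("tree leaves absent from occurrence matrix: ",
         paste(missing, collapse = ", "))
  }
  mat <- mat[tree$tip.label, , drop = FALSE]
  empty <- colSums(mat) == 0
  if (any(empty)) {
    log_line(logf, "dropping ", sum(empty), " families absent from all leaves")
    mat <- mat[, !empty, drop = FALSE]
  }
  over <- mat > config$cmax
  if (any(over)) {
    log_line(logf, "truncating ", sum(over), " counts above cmax = ", config$cmax)
  }
  rates <- suppressWarnings(
    fit_rates(tree, mat, utils::modifyList(list(cmax = config$cmax),
                                           config$fit_config)))
  n_failed <- sum(!rates$converged)
  if (n_failed) log_line(logf, "WARNING: ", n_failed, " family fits not converged")
  post <- node_posteriors(tree, mat, rates)
  events <- call_events(tree, mat, rates, tau = config$tau)
  content <- ancestral_content(post, tau = config$tau)
  gr <- gain_rates(events, tree)
  cmp <- if (sum(gr$class == "ancestral") >= 2L &&
             sum(gr$class == "contemporary") >= 2L) {
    compare_gain_rates(gr$gain_rate[gr$class == "ancestral"],
                       gr$gain_rate[gr$class == "contemporary"])
  } else NULL

  write_tsv6(rates, file.path(config$out_dir, "family_rates.tsv"))
  fam_lists <- attr(content, "families")
  content_out <- content
  content_out$families <- vapply(fam_lists[content$node], function(f)
    paste(f$present, collapse = ","), character(1))
  write_tsv6(content_out, file.path(config$out_dir, "node_content.tsv"))
  write_tsv6(events, file.path(config$out_dir, "branch_events.tsv"))
  write_tsv6(gr, file.path(config$out_dir, "gain_rates.tsv"))

  by_branch <- stats::aggregate(
    cbind(call_gain, call_loss, call_expand, call_contract) ~ child,
    data = events, FUN = sum)
  internal <- content[!content$is_leaf, c("node", "n_present", "n_multicopy")]
  summary_nodes <- merge(internal, by_branch, by.x = "node", by.y = "child",
                         all.x = TRUE)
  jsonlite::write_json(
    list(tau = config$tau, cmax = config$cmax, seed = config$seed,
         n_families = ncol(mat), n_fit_failures = n_failed,
         gain_rate_comparison = cmp,
         ancestor_summaries = summary_nodes),
    file.path(config$out_dir, "gene_content_stats.json"),
    auto_unbox = TRUE, digits = 10, na = "null")
  list(stage = "gene_content", status = if (n_failed) "warn" else "ok",
       seed = config$seed, tau = config$tau, cmax = config$cmax,
       n_families = ncol(mat), n_fit_failures = n_failed,
       content = content, events_summary = by_branch,
       gain_rate_comparison = cmp)
}

#' Run every configured track
#'
#' @param config a `pipeline_config`.
#' @return full run report (list); also written as `run_report.json` in the
#'   output directory (without wall times, which go to the logs).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  report <- list(
    package_version = as.character(utils::packageVersion("ancstate")),
    seed = config$seed,
    parameters = list(tau = config$tau, cmax = config$cmax,
                      replicates = config$replicates,
                      consensus_fraction = config$consensus_fraction,
                      thresholds = config$thresholds),
    stages = list()
  )
  if ("thermometer" %in% config$tracks) {
    report$stages$thermometer <- run_thermometer(config)
  }
  if ("gene_content" %in% config$tracks) {
    report$stages$gene_content <- run_gene_content(config)
  }
  statuses <- vapply(report$stages, `[[`, character(1), "status")
  report$status <- if (all(statuses == "ok")) "ok" else "warn"
  json_report <- report
  json_report$stages <- lapply(json_report$stages, function(st) {
    st$ancestral_ogt <- if (!is.null(st$ancestral_ogt))
      as.list(st$ancestral_ogt) else NULL
    st$content <- NULL
    st
  })
  jsonlite::write_json(json_report,
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       force = TRUE)
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report
}
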