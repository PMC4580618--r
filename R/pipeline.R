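pipeline_defaults <- function() list(
  seed = 1L,
  ## synthetic experiment
  n_genes = 500L, n_pigs = 3L, deg_fraction = 0.2, noise_sd = 0.25,
  pig_sd = 0.2, dye_bias_amplitude = 0.5, fail_fraction = 0.05,
  n_terms = 100L, perturbed_term_fraction = 0.2,
  ## preprocessing
  sd_multiplier = 3, flag_threshold = 100L, flag_comparator = "strict_greater",
  span = 0.4,
  ## differential expression
  pig_mode = "random_intercept", alpha_overall = 0.05, alpha_posthoc = 0.05,
  fold_cutoff = 2,
  ## impact scoring
  min_coverage = 0.30, apply_min_genes = FALSE, sig_cap = 10,
  ## enrichment
  enrich_method = "standard", alpha_report = 0.10,
  ## clustering
  k_max = 50L, gain_threshold = 1.0, fom_runs = 50L, kmeans_iter = 100L,
  n_init = 10L,
  ## regulators
  min_downstream = 4L)

#' Build and validate a pipeline configuration
#'
#' All stage parameters with their method defaults: two 0.05 significance
#' tiers, 30\% annotation coverage, 1\% gain-of-power stopping rule with at
#' most 50 clusters, 100 k-means iterations and 50 FOM runs, optional
#' 2-fold cutoff. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  problems <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in c("alpha_overall", "alpha_posthoc", "min_coverage", "alpha_report"))
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      problems <- c(problems, sprintf("`%s` must be in [0, 1]", f))
  if (!cfg$flag_comparator %in% c("strict_greater", "greater_equal"))
    problems <- c(problems, "`flag_comparator` must be strict_greater or greater_equal")
  if (!cfg$pig_mode %in% c("random_intercept", "fixed_block"))
    problems <- c(problems, "`pig_mode` must be random_intercept or fixed_block")
  if (!cfg$enrich_method %in% c("standard", "ease"))
    problems <- c(problems, "`enrich_method` must be standard or ease")
  if (!num1(cfg$span) || cfg$span <= 0 || cfg$span > 1)
    problems <- c(problems, "`span` must be in (0, 1]")
  for (f in c("n_genes", "n_pigs", "n_terms", "k_max", "fom_runs",
              "kmeans_iter", "n_init", "min_downstream"))
    if (!num1(cfg[[f]]) || cfg[[f]] < 1)
      problems <- c(problems, sprintf("`%s` must be a count >= 1", f))
  if (length(problems) > 0L)
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- c("simulate", "preprocess", "deg", "dia", "enrich",
                     "cluster", "regulators")

## Files each stage needs from earlier stages when rerun in isolation
stage_prereqs <- list(
  simulate = character(0),
  preprocess = c("fixtures/spots.tsv", "fixtures/design.tsv"),
  deg = c("expression_matrix.tsv", "fixtures/design.tsv"),
  dia = c("deg_calls.tsv", "fixtures/annotation.gmt"),
  enrich = c("deg_calls.tsv", "fixtures/annotation.gmt"),
  cluster = "deg_calls.tsv",
  regulators = c("deg_calls.tsv", "fixtures/regulator_edges.tsv"))

#' Run the analysis pipeline
#'
#' Orchestrates the chain simulate, preprocess, deg, dia, enrich, cluster,
#' regulators. Each stage writes TSV outputs under `outdir` and the run is
#' recorded in a JSON manifest (parameters, seed, per-stage file list with
#' MD5 hashes and row counts). A stage run in isolation loads its
#' prerequisites from the output directory and fails with the missing
#' stage file named when they are absent. One global seed fans out to
#' fixed per-stage seeds, so stages rerun independently yet reproducibly.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param stages subset of the stage names (default: all, in order).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  stage_outputs <- list(
    simulate = file.path("fixtures", c("spots.tsv", "design.tsv",
                                       "regulator_edges.tsv", "annotation.gmt")),
    preprocess = "expression_matrix.tsv", deg = "deg_calls.tsv",
    dia = character(0), enrich = character(0), cluster = character(0),
    regulators = character(0))
  will_have <- list.files(outdir, recursive = TRUE)
  for (s in stages) {
    need <- setdiff(stage_prereqs[[s]], will_have)
    if (length(need) > 0L)
      stop(sprintf("stage '%s' is missing prerequisite output(s): %s (run the earlier stages first)",
                   s, paste(need, collapse = ", ")), call. = FALSE)
    will_have <- union(will_have, stage_outputs[[s]])
  }

  state <- new.env(parent = emptyenv())
  manifest <- list(package_version = as.character(utils::packageVersion("dynimpact")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = config$seed, parameters = unclass(config),
                   stages = list())
  for (s in stages) {
    message("stage: ", s)
    files <- switch(s,
      simulate = stage_simulate(config, outdir, state),
      preprocess = stage_preprocess(config, outdir, state),
      deg = stage_deg(config, outdir, state),
      dia = stage_dia(config, outdir, state),
      enrich = stage_enrich(config, outdir, state),
      cluster = stage_cluster(config, outdir, state),
      regulators = stage_regulators(config, outdir, state))
    md5 <- tools::md5sum(file.path(outdir, files))
    rows <- vapply(file.path(outdir, files), function(f)
      if (grepl("\\.(tsv|gmt)$", f)) length(readLines(f)) - 1L else NA_integer_,
      0L)
    names(md5) <- names(rows) <- files
    manifest$stages[[s]] <- list(files = files, md5 = as.list(md5),
                                 rows = as.list(rows))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, outdir, state) {
  sc <- sim_config(n_genes = config$n_genes, n_pigs = config$n_pigs,
                   deg_fraction = config$deg_fraction,
                   noise_sd = config$noise_sd, pig_sd = config$pig_sd,
                   dye_bias_amplitude = config$dye_bias_amplitude,
                   fail_fraction = config$fail_fraction,
                   n_terms = config$n_terms,
                   perturbed_term_fraction = config$perturbed_term_fraction,
                   seed = stage_seed(config$seed, "simulate"))
  state$experiment <- generate_experiment(sc)
  state$annotation <- generate_annotation(sc, state$experiment$truth)
  paths <- write_fixtures(state$experiment, file.path(outdir, "fixtures"),
                          state$annotation)
  file.path("fixtures", basename(paths))
}

stage_preprocess <- function(config, outdir, state) {
  spots <- if (!is.null(state$experiment)) state$experiment$spots else
    read_spot_table(file.path(outdir, "fixtures/spots.tsv"))
  design <- if (!is.null(state$experiment)) state$experiment$design else
    read_design(file.path(outdir, "fixtures/design.tsv"))
  em <- preprocess(spots, design, config$sd_multiplier, config$flag_threshold,
                   config$flag_comparator, config$span)
  state$em <- em
  mat <- data.frame(gene_id = em$gene_id, block_dup_index = em$block_dup_index,
                    em$values, check.names = FALSE)
  write_tsv(mat, file.path(outdir, "expression_matrix.tsv"))
  write_tsv(attr(em, "filter_report"), file.path(outdir, "filter_report.tsv"))
  c("expression_matrix.tsv", "filter_report.tsv")
}

read_expression_matrix_tsv <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(values = as.matrix(df[, -(1:2), drop = FALSE]),
                 gene_id = df$gene_id,
                 block_dup_index = df$block_dup_index, design = design),
            class = "expression_matrix")
}

stage_deg <- function(config, outdir, state) {
  if (is.null(state$em)) {
    design <- read_design(file.path(outdir, "fixtures/design.tsv"))
    state$em <- read_expression_matrix_tsv(file.path(outdir, "expression_matrix.tsv"),
                                           design)
  }
  fit <- fit_gene_model(state$em, pig_mode = config$pig_mode)
  deg <- call_deg(fit, config$alpha_overall, config$alpha_posthoc,
                  config$fold_cutoff)
  state$fit <- fit; state$deg <- deg
  write_tsv(contrast_table(fit, deg), file.path(outdir, "contrast_results.tsv"))
  write_tsv(as.data.frame(deg), file.path(outdir, "deg_calls.tsv"))
  write_tsv(attr(deg, "counts"), file.path(outdir, "deg_counts.tsv"))
  c("contrast_results.tsv", "deg_calls.tsv", "deg_counts.tsv")
}

load_deg <- function(outdir, state) {
  if (is.null(state$deg)) {
    df <- utils::read.delim(file.path(outdir, "deg_calls.tsv"),
                            stringsAsFactors = FALSE)
    df$is_deg <- as.logical(df$is_deg)
    df$passes_2fold <- as.logical(df$passes_2fold)
    state$deg <- df
  }
  state$deg
}

load_annotation <- function(outdir, state) {
  if (is.null(state$annotation))
    state$annotation <- read_gmt(file.path(outdir, "fixtures/annotation.gmt"))
  state$annotation
}

stage_dia <- function(config, outdir, state) {
  deg <- load_deg(outdir, state)
  db <- load_annotation(outdir, state)
  platform <- unique(deg$gene_id)
  filtered <- coverage_filter(db, platform, config$min_coverage,
                              apply_min_genes = config$apply_min_genes)
  impacts <- dia_impact(filtered, deg, config$sig_cap)
  state$impacts <- impacts; state$db_filtered <- filtered
  write_tsv(dia_table(impacts, filtered), file.path(outdir, "dia_results.tsv"))
  write_tsv(dia_rollup(impacts, filtered, "subcategory"),
            file.path(outdir, "dia_subcategory.tsv"))
  write_tsv(attr(filtered, "removal_log"), file.path(outdir, "dia_filter_log.tsv"))
  c("dia_results.tsv", "dia_subcategory.tsv", "dia_filter_log.tsv")
}

stage_enrich <- function(config, outdir, state) {
  deg <- load_deg(outdir, state)
  db <- load_annotation(outdir, state)
  background <- unique(deg$gene_id)
  res <- enrich_deg_lists(deg, background, db, config$enrich_method,
                          config$alpha_report)
  long <- do.call(rbind, unlist(lapply(names(res), function(cmp)
    lapply(c("up", "down"), function(d) {
      tab <- res[[cmp]][[d]]
      if (nrow(tab) == 0L) return(NULL)
      cbind(comparison_id = cmp, direction = d, tab,
            stringsAsFactors = FALSE)
    })), recursive = FALSE))
  write_tsv(long, file.path(outdir, "enrichment.tsv"))
  "enrichment.tsv"
}

stage_cluster <- function(config, outdir, state) {
  deg <- load_deg(outdir, state)
  deg_genes <- unique(deg$gene_id[deg$is_deg])
  if (length(deg_genes) < 3L)
    stop("too few differential genes to cluster", call. = FALSE)
  profiles <- deg_profile_matrix(deg, deg_genes)
  model <- cluster_profiles(profiles, k_max = config$k_max,
                            threshold_percent = config$gain_threshold,
                            n_runs = config$fom_runs,
                            n_init = config$n_init,
                            max_iter = config$kmeans_iter,
                            seed = stage_seed(config$seed, "cluster"))
  state$cluster <- model
  write_tsv(data.frame(gene_id = names(model$assignments),
                       cluster = unname(model$assignments)),
            file.path(outdir, "cluster_assignments.tsv"))
  write_tsv(data.frame(k = as.integer(names(model$fom_curve)),
                       fom = unname(model$fom_curve),
                       gain = unname(c(NA, model$gain_curve))),
            file.path(outdir, "cluster_fom.tsv"))
  write_tsv(data.frame(cluster = seq_len(model$k), model$centroids,
                       check.names = FALSE),
            file.path(outdir, "cluster_centroids.tsv"))
  c("cluster_assignments.tsv", "cluster_fom.tsv", "cluster_centroids.tsv")
}

#' Fold-change profile matrix of differential genes
#'
#' Genes x comparisons matrix of log2 fold changes for the genes called
#' differential in at least one comparison - the input to the clustering
#' stage.
#'
#' @param deg a [call_deg()] result (or equivalent long table).
#' @param genes genes to include (default: all with `is_deg` somewhere).
#' @return numeric matrix with gene rownames.
#' @export
deg_profile_matrix <- function(deg, genes = NULL) {
  genes <- genes %||% unique(deg$gene_id[deg$is_deg])
  cmps <- sort(unique(deg$comparison_id))
  m <- matrix(NA_real_, length(genes), length(cmps),
              dimnames = list(genes, cmps))
  i <- match(paste(deg$gene_id, deg$comparison_id),
             outer(genes, cmps, paste))
  keep <- !is.na(i)
  m[i[keep]] <- deg$log2fc[keep]
  m
}

stage_regulators <- function(config, outdir, state) {
  deg <- load_deg(outdir, state)
  edges <- if (!is.null(state$experiment)) state$experiment$regulator_edges else
    read_regulator_edges(file.path(outdir, "fixtures/regulator_edges.tsv"))
  background <- unique(deg$gene_id)
  dirs <- deg_gene_directions(deg)
  res <- score_regulators(edges, names(dirs), dirs, background)
  write_tsv(as.data.frame(res), file.path(outdir, "regulator_scores.tsv"))
  files <- "regulator_scores.tsv"
  cl_path <- file.path(outdir, "cluster_assignments.tsv")
  if (file.exists(cl_path)) {
    cl <- utils::read.delim(cl_path, stringsAsFactors = FALSE)
    trims <- do.call(rbind, lapply(sort(unique(cl$cluster)), function(ci)
      cbind(cluster = ci,
            trim_cluster_network(edges, cl$gene_id[cl$cluster == ci],
                                 config$min_downstream))))
    write_tsv(trims, file.path(outdir, "cluster_regulators.tsv"))
    files <- c(files, "cluster_regulators.tsv")
  }
  files
}

#' Dominant fold-change direction per differential gene
#'
#' The sign of each differential gene's log2 fold change in its most
#' significant differential comparison (smallest post-hoc p).
#'
#' @param deg a [call_deg()] result.
#' @return named numeric vector of -1/+1 signs.
#' @export
deg_gene_directions <- function(deg) {
  s <- deg[deg$is_deg & !is.na(deg$log2fc) & deg$log2fc != 0, , drop = FALSE]
  if (nrow(s) == 0L) return(stats::setNames(numeric(0), character(0)))
  s <- s[order(s$posthoc_p), ]
  s <- s[!duplicated(s$gene_id), ]
  stats::setNames(sign(s$log2fc), s$gene_id)
}

#' Summarize a completed pipeline run
#'
#' Human-readable report of a run directory: differential counts per
#' comparison with and without the fold cutoff, top terms by impact,
#' flagged enrichment terms, selected cluster number and sizes, and
#' regulator calls. Missing stage outputs are flagged as gaps rather than
#' errors.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @param top_n how many top-impact terms to show (default 10).
#' @return character vector of report lines (also printed).
#' @export
summarize_run <- function(outdir, top_n = 10L) {
  if (!dir.exists(outdir) || !file.exists(file.path(outdir, "manifest.json")))
    stop("not a pipeline run directory (no manifest.json): ", outdir,
         call. = FALSE)
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  lines <- c(sprintf("pipeline run (seed %s): stages %s",
                     manifest$seed, paste(names(manifest$stages), collapse = ", ")))
  grab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  counts <- grab("deg_counts.tsv")
  if (is.null(counts)) lines <- c(lines, "[gap] no differential-expression stage output")
  else lines <- c(lines, "DEG per comparison (up/down, with cutoff in brackets):",
                  sprintf("  %-32s %4d / %-4d  [%d / %d]", counts$comparison_id,
                          counts$n_up, counts$n_down, counts$n_up_cutoff,
                          counts$n_down_cutoff))
  dia <- grab("dia_results.tsv")
  if (is.null(dia)) lines <- c(lines, "[gap] no impact-scoring stage output")
  else lines <- c(lines, sprintf("top %d terms by total impact:", top_n),
                  sprintf("  %-8s total impact %8.3f", utils::head(dia$term_id, top_n),
                          utils::head(dia$total_impact, top_n)))
  enr <- grab("enrichment.tsv")
  if (is.null(enr)) lines <- c(lines, "[gap] no enrichment stage output")
  else lines <- c(lines, sprintf("enrichment: %d flagged term/list results of %d tested",
                                 sum(enr$flagged), nrow(enr)))
  fom <- grab("cluster_fom.tsv")
  cl <- grab("cluster_assignments.tsv")
  if (is.null(cl)) lines <- c(lines, "[gap] no clustering stage output")
  else lines <- c(lines, sprintf("clustering: selected k = %d, sizes: %s",
                                 max(cl$cluster),
                                 paste(table(cl$cluster), collapse = " ")))
  reg <- grab("regulator_scores.tsv")
  if (is.null(reg)) lines <- c(lines, "[gap] no regulator stage output")
  else {
    called <- reg[reg$predicted_state != "undetermined", , drop = FALSE]
    lines <- c(lines, sprintf("regulators: %d scored, %d called (%s)",
                              nrow(reg), nrow(called),
                              if (nrow(called) > 0)
                                paste(sprintf("%s %s z=%.2f", called$regulator_id,
                                              called$predicted_state, called$z),
                                      collapse = "; ") else ""))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
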