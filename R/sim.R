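#' Configuration for a synthetic two-color microarray experiment
#'
#' Builds and validates the full parameter set for the synthetic-experiment
#' generator. The defaults emulate a porcine mesenchymal-stem-cell
#' differentiation time course: 3 pigs, two cell types (adipose-derived and
#' bone-marrow-derived MSC), two induced differentiations (adipogenic and
#' osteogenic) sampled at 0, 2, 7 and 21 days of differentiation, with each
#' gene spotted in duplicate on every array and each sample hybridized
#' against a common reference pool.
#'
#' @param n_genes number of genes on the platform.
#' @param n_pigs number of pigs (biological replicates; random intercepts).
#' @param time_points_dd days of differentiation; must include 0.
#' @param cell_types,differentiations factor labels for the two crossed
#'   biological factors.
#' @param n_duplicate_spots technical replicate spots per gene per array.
#' @param deg_fraction fraction of genes planted as differentially expressed.
#' @param effect_patterns list of archetype log2 fold-change trajectories;
#'   each is a series-by-time matrix (rows named `CELL.DIFF`, columns named
#'   by time point, time 0 column zero). Defaults to six well-separated
#'   archetypes built by [default_effect_patterns()].
#' @param noise_sd standard deviation of spot-level log2-ratio noise.
#' @param pig_sd standard deviation of the gene-independent random pig
#'   intercept on the log2 ratio.
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent dye
#'   bias injected per array (log2 units on M).
#' @param fail_fraction fraction of spots given failing quality flags or
#'   near-background intensity.
#' @param flag100_fraction fraction of otherwise good spots flagged exactly
#'   100 (the boundary quality code).
#' @param n_terms number of annotation terms to simulate.
#' @param term_size_range integer range (min, max) of platform genes per term.
#' @param perturbed_term_fraction fraction of terms enriched for planted
#'   differential genes of a consistent direction.
#' @param genome_inflation factor (scalar, or length-2 range sampled per
#'   term) by which the genome-wide term size exceeds the platform term
#'   size; must be >= 1. The default range yields terms on both sides of a
#'   30\% platform-coverage cutoff.
#' @param n_regulators,targets_per_regulator,regulator_active_fraction size
#'   and composition of the simulated signed regulator-to-target edge list.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       n_pigs = 3L,
                       time_points_dd = c(0, 2, 7, 21),
                       cell_types = c("ASC", "BMSC"),
                       differentiations = c("adipogenic", "osteogenic"),
                       n_duplicate_spots = 2L,
                       deg_fraction = 0.2,
                       effect_patterns = NULL,
                       noise_sd = 0.25,
                       pig_sd = 0.2,
                       dye_bias_amplitude = 0.5,
                       fail_fraction = 0.05,
                       flag100_fraction = 0.01,
                       n_terms = 100L,
                       term_size_range = c(10L, 30L),
                       perturbed_term_fraction = 0.2,
                       genome_inflation = c(1.5, 5),
                       n_regulators = 12L,
                       targets_per_regulator = 20L,
                       regulator_active_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_pigs = as.integer(n_pigs),
              time_points_dd = sort(unique(as.numeric(time_points_dd))),
              cell_types = as.character(cell_types),
              differentiations = as.character(differentiations),
              n_duplicate_spots = as.integer(n_duplicate_spots),
              deg_fraction = deg_fraction,
              effect_patterns = effect_patterns,
              noise_sd = noise_sd, pig_sd = pig_sd,
              dye_bias_amplitude = dye_bias_amplitude,
              fail_fraction = fail_fraction,
              flag100_fraction = flag100_fraction,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              perturbed_term_fraction = perturbed_term_fraction,
              genome_inflation = as.numeric(genome_inflation),
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              regulator_active_fraction = regulator_active_fraction,
              seed = as.integer(seed))

  for (f in c("n_genes", "n_pigs", "n_duplicate_spots", "n_terms")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      fail_field(f, "must be a count >= 1")
  }
  for (f in c("deg_fraction", "perturbed_term_fraction", "fail_fraction",
              "flag100_fraction", "regulator_active_fraction")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] < 0 || cfg[[f]] > 1)
      fail_field(f, "must be a proportion in [0, 1]")
  }
  for (f in c("noise_sd", "pig_sd", "dye_bias_amplitude")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0)
      fail_field(f, "must be a nonnegative number")
  }
  if (!0 %in% cfg$time_points_dd)
    fail_field("time_points_dd", "must contain the baseline time point 0")
  if (length(cfg$time_points_dd) < 2L)
    fail_field("time_points_dd", "needs at least two time points")
  if (length(cfg$cell_types) < 1L || anyDuplicated(cfg$cell_types))
    fail_field("cell_types", "must be distinct labels")
  if (length(cfg$differentiations) < 1L || anyDuplicated(cfg$differentiations))
    fail_field("differentiations", "must be distinct labels")
  if (length(cfg$term_size_range) != 2L ||
      any(cfg$term_size_range < 1L) || diff(cfg$term_size_range) < 0)
    fail_field("term_size_range", "must be an increasing pair of counts >= 1")
  if (cfg$term_size_range[2] > cfg$n_genes)
    fail_field("term_size_range", "maximum term size exceeds n_genes")
  if (!length(cfg$genome_inflation) %in% c(1L, 2L) ||
      any(cfg$genome_inflation < 1))
    fail_field("genome_inflation", "must be a factor (or range) >= 1")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    fail_field("seed", "must be a single integer")

  if (is.null(cfg$effect_patterns)) {
    cfg$effect_patterns <- default_effect_patterns(cfg$cell_types,
                                                   cfg$differentiations,
                                                   cfg$time_points_dd)
  }
  series <- as.vector(outer(cfg$cell_types, cfg$differentiations, series_label))
  for (i in seq_along(cfg$effect_patterns)) {
    pat <- cfg$effect_patterns[[i]]
    if (!is.matrix(pat) || !setequal(rownames(pat), series) ||
        !setequal(colnames(pat), as.character(cfg$time_points_dd)))
      fail_field("effect_patterns",
                 sprintf("pattern %d must be a series x time matrix", i))
    if (any(pat[, "0"] != 0))
      fail_field("effect_patterns",
                 sprintf("pattern %d must be zero at time 0", i))
  }
  structure(cfg, class = "sim_config")
}

#' Default log2 fold-change archetypes
#'
#' Six cluster archetypes of planted expression trajectories, expressed as
#' log2 fold change versus each series' own time 0. Every archetype is
#' modulated by cell type as well as differentiation and time - a late
#' adipogenic induction in one cell type, an adipogenic repression in the
#' other, osteogenic induction/repression, a mid-amplitude adipogenic induction in
#' the second cell type and an early transient - so planted genes carry the
#' three-way time x cell x differentiation interaction the
#' differential-expression test is gated on. Magnitudes are 2-3 log2 units,
#' well separated relative to typical spot noise.
#'
#' @param cell_types,differentiations,time_points_dd design labels as in
#'   [sim_config()].
#' @return named list of series-by-time matrices.
#' @export
default_effect_patterns <- function(cell_types = c("ASC", "BMSC"),
                                    differentiations = c("adipogenic", "osteogenic"),
                                    time_points_dd = c(0, 2, 7, 21)) {
  tp <- sort(unique(time_points_dd))
  series <- as.vector(outer(cell_types, differentiations, series_label))
  blank <- matrix(0, nrow = length(series), ncol = length(tp),
                  dimnames = list(series, as.character(tp)))
  nlate <- length(tp) - 1L
  ramp_up <- seq(0.5, 3, length.out = nlate)
  ramp_mid <- seq(1, 2.5, length.out = nlate)
  transient <- c(2.5, seq(0.8, 0, length.out = nlate - 1L))  # early, decays back

  cellA <- cell_types[1]
  cellB <- cell_types[min(2L, length(cell_types))]
  diffA <- differentiations[1]
  diffB <- differentiations[min(2L, length(differentiations))]

  pats <- list()
  m <- blank; m[series_label(cellA, diffA), -1] <- ramp_up
  pats$adipo_up_cellA <- m
  m <- blank; m[series_label(cellB, diffA), -1] <- -ramp_up
  pats$adipo_down_cellB <- m
  m <- blank; m[series_label(cellA, diffB), -1] <- ramp_mid
  pats$osteo_up_cellA <- m
  m <- blank; m[series_label(cellB, diffB), -1] <- -ramp_mid
  pats$osteo_down_cellB <- m
  m <- blank; m[series_label(cellB, diffA), -1] <- ramp_mid
  pats$adipo_up_cellB <- m
  m <- blank; m[series_label(cellA, diffB), -1] <- transient
  pats$transient_early <- m
  pats
}

#' Generate a synthetic spot-level experiment with planted truth
#'
#' Simulates a full two-color common-reference microarray experiment: one
#' array per pig x cell type x differentiation x time point, each gene
#' spotted `n_duplicate_spots` times per array. Raw channel intensities are
#' back-computed from the planted true log2 ratios plus a gene-independent
#' random pig intercept, spot noise, a smooth intensity-dependent dye bias,
#' and additive background; a configurable fraction of spots carries failing
#' quality flags or near-background foreground intensity. Signed
#' regulator-to-target edges with planted active regulators are generated
#' alongside.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_experiment`: a list with elements
#'   `spots` (spot table), `design` (sample design), `regulator_edges`,
#'   `truth` (planted ground truth: differential genes with archetypes and
#'   true per-comparison log2 fold changes, per-array dye-bias parameters,
#'   pig effects, regulator truth) and `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, 10, 1.5)
  names(baseline) <- genes

  ## planted DEG: exact count, archetypes assigned cyclically
  n_deg <- round(cfg$deg_fraction * cfg$n_genes)
  deg_genes <- if (n_deg > 0) sort(sample(genes, n_deg)) else character(0)
  arch_ids <- if (n_deg > 0)
    rep(seq_along(cfg$effect_patterns), length.out = n_deg) else integer(0)
  names(arch_ids) <- deg_genes

  design <- expand.grid(pig = sprintf("pig%d", seq_len(cfg$n_pigs)),
                        time_dd = cfg$time_points_dd,
                        differentiation = cfg$differentiations,
                        cell_type = cfg$cell_types,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s.%s.t%g.%s", design$cell_type,
                              design$differentiation, design$time_dd,
                              design$pig)
  design$array_id <- sprintf("A%03d", seq_len(nrow(design)))
  design <- design[, c("sample_id", "array_id", "pig", "cell_type",
                       "differentiation", "time_dd")]

  ## true log2 ratio per gene x sample (0 for non-DEG)
  mu <- matrix(0, nrow = cfg$n_genes, ncol = nrow(design),
               dimnames = list(genes, design$sample_id))
  ser <- series_label(design$cell_type, design$differentiation)
  tchr <- as.character(design$time_dd)
  for (g in deg_genes) {
    pat <- cfg$effect_patterns[[arch_ids[[g]]]]
    mu[g, ] <- pat[cbind(ser, tchr)]
  }

  pig_eff <- stats::rnorm(cfg$n_pigs, 0, cfg$pig_sd)
  names(pig_eff) <- sprintf("pig%d", seq_len(cfg$n_pigs))

  dye_bias <- data.frame(array_id = design$array_id,
                         amplitude = cfg$dye_bias_amplitude,
                         phase = stats::runif(nrow(design), 0, 2 * pi),
                         stringsAsFactors = FALSE)

  n_arrays <- nrow(design)
  per_array <- cfg$n_genes * cfg$n_duplicate_spots
  idx_gene <- rep(rep(seq_len(cfg$n_genes), each = cfg$n_duplicate_spots),
                  times = n_arrays)
  idx_array <- rep(seq_len(n_arrays), each = per_array)
  n_spots <- length(idx_gene)

  m_true <- mu[cbind(idx_gene, idx_array)] + pig_eff[design$pig[idx_array]]
  e1 <- stats::rnorm(n_spots, 0, cfg$noise_sd / sqrt(2))
  e2 <- stats::rnorm(n_spots, 0, cfg$noise_sd / sqrt(2))
  l2_ch2 <- baseline[idx_gene] + e2
  l2_ch1 <- baseline[idx_gene] + m_true + e1
  a_true <- (l2_ch1 + l2_ch2) / 2
  delta <- dye_bias$amplitude[idx_array] *
    sin(2 * pi * (a_true - 8) / 6 + dye_bias$phase[idx_array])
  l2_ch1 <- l2_ch1 + delta / 2
  l2_ch2 <- l2_ch2 - delta / 2

  bg1 <- 2 ^ stats::rnorm(n_spots, 6, 0.3)
  bg2 <- 2 ^ stats::rnorm(n_spots, 6, 0.3)
  bg_sd <- 0.15 * (bg1 + bg2) / 2
  ch1_fg <- 2 ^ l2_ch1 + bg1
  ch2_fg <- 2 ^ l2_ch2 + bg2

  flag <- rep(200L, n_spots)
  flag[stats::runif(n_spots) < cfg$flag100_fraction] <- 100L
  n_fail <- round(cfg$fail_fraction * n_spots)
  fail_idx <- sample.int(n_spots, n_fail)
  half <- length(fail_idx) %/% 2L
  bad_flag <- fail_idx[seq_len(half)]
  low_int <- fail_idx[setdiff(seq_along(fail_idx), seq_len(half))]
  flag[bad_flag] <- sample(c(-100L, -50L, 0L), length(bad_flag), replace = TRUE)
  ch1_fg[low_int] <- bg1[low_int] + stats::runif(length(low_int), 0, 2) * bg_sd[low_int]

  spots <- data.frame(
    spot_id = sprintf("S%05d", rep(seq_len(per_array), times = n_arrays)),
    gene_id = genes[idx_gene],
    array_id = design$array_id[idx_array],
    block_dup_index = rep(rep(seq_len(cfg$n_duplicate_spots),
                              times = cfg$n_genes), times = n_arrays),
    ch1_fg_median = ch1_fg, ch1_bg_median = bg1,
    ch2_fg_median = ch2_fg, ch2_bg_median = bg2,
    bg_sd = bg_sd, flag = flag, stringsAsFactors = FALSE)

  ## true log2FC per comparison for planted DEG
  cmp <- comparison_table(cfg$cell_types, cfg$differentiations, cfg$time_points_dd)
  true_l2fc <- matrix(0, nrow = n_deg, ncol = nrow(cmp),
                      dimnames = list(deg_genes, cmp$comparison_id))
  for (g in deg_genes) {
    pat <- cfg$effect_patterns[[arch_ids[[g]]]]
    s <- series_label(cmp$cell_type, cmp$differentiation)
    true_l2fc[g, ] <- pat[cbind(s, as.character(cmp$time_num))] -
      pat[cbind(s, as.character(cmp$time_den))]
  }

  regs <- simulate_regulators(cfg, genes, deg_genes, arch_ids)

  truth <- list(genes = genes,
                deg_genes = data.frame(
                  gene_id = deg_genes,
                  archetype = unname(arch_ids),
                  overall_sign = if (n_deg > 0) vapply(deg_genes, function(g)
                    sign(sum(cfg$effect_patterns[[arch_ids[[g]]]])), 0)
                  else numeric(0),
                  stringsAsFactors = FALSE, row.names = NULL),
                true_log2fc = true_l2fc,
                comparisons = cmp,
                pig_effects = pig_eff,
                dye_bias_params = dye_bias,
                regulator_truth = regs$truth,
                baseline = baseline)

  structure(list(spots = spots, design = design,
                 regulator_edges = regs$edges, truth = truth, config = cfg),
            class = "sim_experiment")
}

## Planted regulator edges: active regulators have sign-consistent edges to
## planted differential genes; null regulators get random targets and signs.
simulate_regulators <- function(cfg, genes, deg_genes, arch_ids) {
  if (cfg$n_regulators < 1L)
    return(list(edges = data.frame(regulator_id = character(0),
                                   target_gene_id = character(0),
                                   sign = integer(0)),
                truth = data.frame(regulator_id = character(0),
                                   mode = character(0))))
  reg_ids <- sprintf("REG%02d", seq_len(cfg$n_regulators))
  n_active <- round(cfg$regulator_active_fraction * cfg$n_regulators)
  modes <- c(rep(c("activating", "inhibiting"), length.out = n_active),
             rep("null", cfg$n_regulators - n_active))
  deg_sign <- vapply(deg_genes, function(g)
    sign(sum(cfg$effect_patterns[[arch_ids[[g]]]])), 0)
  usable <- deg_genes[deg_sign != 0]
  edges <- vector("list", cfg$n_regulators)
  for (i in seq_len(cfg$n_regulators)) {
    k <- min(cfg$targets_per_regulator, length(genes))
    if (modes[i] == "null" || length(usable) == 0L) {
      tg <- sample(genes, k)
      sg <- sample(c(-1L, 1L), k, replace = TRUE)
    } else {
      n_deg_t <- min(length(usable), ceiling(0.7 * k))
      tg <- c(sample(usable, n_deg_t), sample(setdiff(genes, usable),
                                              k - n_deg_t))
      sg <- integer(k)
      ds <- deg_sign[tg]; ds[is.na(ds)] <- 0
      ## consistency: active regulator, edge sign * target direction = +1
      sg <- ifelse(ds != 0, as.integer(ds),
                   sample(c(-1L, 1L), k, replace = TRUE))
      if (modes[i] == "inhibiting") sg <- -sg
    }
    edges[[i]] <- data.frame(regulator_id = reg_ids[i], target_gene_id = tg,
                             sign = as.integer(sg), stringsAsFactors = FALSE)
  }
  list(edges = do.call(rbind, edges),
       truth = data.frame(regulator_id = reg_ids, mode = modes,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic term-to-gene annotation database
#'
#' Produces an annotation database over the simulated platform. Terms drawn
#' as perturbed are enriched in planted differential genes of a consistent
#' direction; null terms sample platform genes uniformly. Each term's
#' genome-wide size is its platform size times a (possibly per-term) genome
#' inflation factor, so platform coverage `platform_size / genome_size`
#' spans both sides of a typical 30\% cutoff under the default
#' configuration. One null term is forced to a single platform gene to
#' exercise the single-gene term filter.
#'
#' @param config the [sim_config()] used for the experiment.
#' @param truth the `truth` element of the matching [generate_experiment()]
#'   run (or the `sim_experiment` itself).
#' @return an [annotation_db] with a `perturbed` attribute recording each
#'   planted term's true direction and its overlap with planted
#'   differential genes; the same table is appended to `truth` by callers.
#' @export
generate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(truth, "sim_experiment")) truth <- truth$truth
  genes <- truth$genes
  if (config$term_size_range[2] > length(genes))
    fail_field("term_size_range", "maximum term size exceeds the number of genes")
  set.seed(stage_seed(config$seed, "annotation"))

  n_terms <- config$n_terms
  n_pert <- round(config$perturbed_term_fraction * n_terms)
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  status <- c(rep(c("up", "down"), length.out = n_pert),
              rep("null", n_terms - n_pert))
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  n_terms, replace = TRUE)
  ## at least one single-gene term among the nulls
  if (n_pert < n_terms) sizes[n_terms] <- 1L

  deg_up <- truth$deg_genes$gene_id[truth$deg_genes$overall_sign > 0]
  deg_dn <- truth$deg_genes$gene_id[truth$deg_genes$overall_sign < 0]

  infl <- if (length(config$genome_inflation) == 1L)
    rep(config$genome_inflation, n_terms)
  else stats::runif(n_terms, config$genome_inflation[1], config$genome_inflation[2])

  gene_sets <- vector("list", n_terms)
  overlap <- integer(n_terms)
  for (i in seq_len(n_terms)) {
    sz <- sizes[i]
    pool <- switch(status[i], up = deg_up, down = deg_dn, null = character(0))
    if (status[i] != "null" && length(pool) > 0L) {
      n_bias <- min(length(pool), ceiling(0.6 * sz))
      gs <- c(sample(pool, n_bias), sample(setdiff(genes, pool), sz - n_bias))
    } else {
      gs <- sample(genes, sz)
    }
    gene_sets[[i]] <- sort(gs)
    overlap[i] <- length(intersect(gs, truth$deg_genes$gene_id))
  }

  terms <- data.frame(term_id = term_ids, name = term_ids,
                      category = sprintf("CAT%d", ((seq_len(n_terms) - 1L) %% 3L) + 1L),
                      subcategory = sprintf("SUB%d", ((seq_len(n_terms) - 1L) %% 6L) + 1L),
                      genome_gene_count = as.integer(ceiling(sizes * infl)),
                      stringsAsFactors = FALSE)
  names(gene_sets) <- term_ids
  db <- annotation_db(terms, gene_sets)
  attr(db, "perturbed") <- data.frame(
    term_id = term_ids, status = status, platform_size = sizes,
    deg_overlap = overlap, stringsAsFactors = FALSE)
  db
}

#' Generate a normalized expression matrix directly from the planted model
#'
#' Skips the spot-level machinery (raw intensities, background, dye bias,
#' quality flags) and simulates the normalized log2 ratios the
#' preprocessing stage would produce: planted true log2 fold change plus
#' the random pig intercept plus spot noise, with duplicate spots as
#' separate rows. Useful for studying the statistical stages in isolation
#' at the exact noise and effect levels of the model.
#'
#' @param config a [sim_config()].
#' @return list with `em` (an `expression_matrix`) and `truth` (as in
#'   [generate_experiment()], without spot-level fields).
#' @export
generate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(stage_seed(cfg$seed, "expression"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_deg <- round(cfg$deg_fraction * cfg$n_genes)
  deg_genes <- if (n_deg > 0) sort(sample(genes, n_deg)) else character(0)
  arch_ids <- if (n_deg > 0)
    rep(seq_along(cfg$effect_patterns), length.out = n_deg) else integer(0)
  names(arch_ids) <- deg_genes

  design <- expand.grid(pig = sprintf("pig%d", seq_len(cfg$n_pigs)),
                        time_dd = cfg$time_points_dd,
                        differentiation = cfg$differentiations,
                        cell_type = cfg$cell_types,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s.%s.t%g.%s", design$cell_type,
                              design$differentiation, design$time_dd,
                              design$pig)
  design$array_id <- sprintf("A%03d", seq_len(nrow(design)))
  design <- design[, c("sample_id", "array_id", "pig", "cell_type",
                       "differentiation", "time_dd")]

  mu <- matrix(0, nrow = cfg$n_genes, ncol = nrow(design),
               dimnames = list(genes, design$sample_id))
  ser <- series_label(design$cell_type, design$differentiation)
  tchr <- as.character(design$time_dd)
  for (g in deg_genes) {
    pat <- cfg$effect_patterns[[arch_ids[[g]]]]
    mu[g, ] <- pat[cbind(ser, tchr)]
  }
  pig_eff <- stats::rnorm(cfg$n_pigs, 0, cfg$pig_sd)
  names(pig_eff) <- sprintf("pig%d", seq_len(cfg$n_pigs))

  nd <- cfg$n_duplicate_spots
  ridx <- rep(seq_len(cfg$n_genes), each = nd)
  values <- mu[ridx, , drop = FALSE] +
    rep(pig_eff[design$pig], each = length(ridx)) +
    stats::rnorm(length(ridx) * nrow(design), 0, cfg$noise_sd)
  dim(values) <- c(length(ridx), nrow(design))
  colnames(values) <- design$sample_id

  cmp <- comparison_table(cfg$cell_types, cfg$differentiations,
                          cfg$time_points_dd)
  true_l2fc <- matrix(0, nrow = n_deg, ncol = nrow(cmp),
                      dimnames = list(deg_genes, cmp$comparison_id))
  for (g in deg_genes) {
    pat <- cfg$effect_patterns[[arch_ids[[g]]]]
    s <- series_label(cmp$cell_type, cmp$differentiation)
    true_l2fc[g, ] <- pat[cbind(s, as.character(cmp$time_num))] -
      pat[cbind(s, as.character(cmp$time_den))]
  }
  em <- structure(list(values = values, gene_id = genes[ridx],
                       block_dup_index = rep(seq_len(nd), cfg$n_genes),
                       design = design),
                  class = "expression_matrix")
  list(em = em,
       truth = list(genes = genes,
                    deg_genes = data.frame(gene_id = deg_genes,
                                           archetype = unname(arch_ids),
                                           stringsAsFactors = FALSE,
                                           row.names = NULL),
                    true_log2fc = true_l2fc, comparisons = cmp,
                    pig_effects = pig_eff))
}
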