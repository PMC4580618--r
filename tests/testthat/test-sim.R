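test_that("identical seed and configuration give byte-identical outputs", {
  cfg <- sim_config(n_genes = 60, n_terms = 12, seed = 5)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$spots, b$spots)
  expect_identical(a$design, b$design)
  expect_identical(a$regulator_edges, b$regulator_edges)
  expect_identical(generate_annotation(cfg, a$truth),
                   generate_annotation(cfg, b$truth))
})

test_that("truth bookkeeping matches the configured proportions exactly", {
  cfg <- sim_config(n_genes = 500, deg_fraction = 0.2, n_terms = 50,
                    perturbed_term_fraction = 0.2, seed = 9)
  exp <- generate_experiment(cfg)
  expect_equal(nrow(exp$truth$deg_genes), 100)
  expect_true(all(exp$truth$deg_genes$gene_id %in% exp$truth$genes))
  ann <- generate_annotation(cfg, exp$truth)
  pert <- attr(ann, "perturbed")
  expect_equal(sum(pert$status != "null"), 10)
  ## recorded overlap counts are correct
  for (i in sample(nrow(pert), 10)) {
    expect_equal(pert$deg_overlap[i],
                 length(intersect(ann$gene_sets[[pert$term_id[i]]],
                                  exp$truth$deg_genes$gene_id)))
  }
  ## zero-DEG case
  cfg0 <- sim_config(n_genes = 60, deg_fraction = 0, n_terms = 10, seed = 5)
  expect_equal(nrow(generate_experiment(cfg0)$truth$deg_genes), 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(deg_fraction = 1.5), "deg_fraction")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(time_points_dd = c(2, 7, 21)), "time_points_dd")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(genome_inflation = 0.5), "genome_inflation")
  expect_error(sim_config(n_genes = 20, term_size_range = c(10, 30)),
               "term_size_range")
})

test_that("one sample per design cell and duplicate spots per gene per array", {
  sx <- small_experiment()
  d <- sx$exp$design
  cells <- table(d$pig, d$cell_type, d$differentiation, d$time_dd)
  expect_true(all(cells == 1))
  per <- table(sx$exp$spots$gene_id, sx$exp$spots$array_id)
  expect_true(all(per == sx$cfg$n_duplicate_spots))
})

test_that("back-computed intensities recover the planted log2 ratios", {
  sx <- small_experiment()
  sp <- sx$exp$spots
  truth <- sx$exp$truth
  cfg <- sx$cfg
  ok <- sp$flag > 100 &
    sp$ch1_fg_median >= sp$ch1_bg_median + 3 * sp$bg_sd &
    sp$ch2_fg_median >= sp$ch2_bg_median + 3 * sp$bg_sd
  sp <- sp[ok, ]
  m_obs <- log2((sp$ch1_fg_median - sp$ch1_bg_median) /
                  (sp$ch2_fg_median - sp$ch2_bg_median))
  a_obs <- 0.5 * log2((sp$ch1_fg_median - sp$ch1_bg_median) *
                        (sp$ch2_fg_median - sp$ch2_bg_median))
  db <- truth$dye_bias_params
  i <- match(sp$array_id, db$array_id)
  m_debias <- m_obs - db$amplitude[i] * sin(2 * pi * (a_obs - 8) / 6 + db$phase[i])
  design <- sx$exp$design
  mu_true <- matrix(0, length(truth$genes), nrow(design),
                    dimnames = list(truth$genes, design$array_id))
  for (j in seq_len(nrow(truth$deg_genes))) {
    g <- truth$deg_genes$gene_id[j]
    pat <- cfg$effect_patterns[[truth$deg_genes$archetype[j]]]
    mu_true[g, ] <- pat[cbind(series_label(design$cell_type, design$differentiation),
                              as.character(design$time_dd))]
  }
  expected <- mu_true[cbind(sp$gene_id, sp$array_id)] +
    truth$pig_effects[design$pig[match(sp$array_id, design$array_id)]]
  err_by_gene <- tapply(m_debias - expected, sp$gene_id, mean)
  n_by_gene <- tapply(m_debias, sp$gene_id, length)
  bound <- 3 * cfg$noise_sd / sqrt(n_by_gene[names(err_by_gene)])
  expect_gt(mean(abs(err_by_gene) < bound), 0.99)
})

test_that("genome inflation controls the coverage filter outcome", {
  truth <- small_experiment()$exp$truth
  cfg1 <- sim_config(n_genes = 150, n_terms = 20, genome_inflation = 1, seed = 3)
  db1 <- generate_annotation(cfg1, truth)
  f1 <- coverage_filter(db1, truth$genes)
  expect_equal(nrow(f1$terms), 20)
  cfg4 <- sim_config(n_genes = 150, n_terms = 20, genome_inflation = 4, seed = 3)
  db4 <- generate_annotation(cfg4, truth)
  f4 <- coverage_filter(db4, truth$genes)
  expect_equal(nrow(f4$terms), 0)
})

test_that("annotation includes a single-gene term and unbiased null terms", {
  sx <- small_experiment()
  expect_true(any(lengths(sx$ann$gene_sets) == 1L))
  cfg0 <- sim_config(n_genes = 150, n_terms = 30, perturbed_term_fraction = 0,
                     seed = 4)
  db0 <- generate_annotation(cfg0, small_experiment()$exp$truth)
  expect_true(all(attr(db0, "perturbed")$status == "null"))
})

test_that("fixtures round-trip losslessly through the readers", {
  sx <- small_experiment()
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sx$exp, dir, sx$ann)
  sp <- read_spot_table(paths[["spots"]])
  expect_equal(sp, sx$exp$spots, tolerance = 1e-8)
  expect_equal(read_design(paths[["design"]]), sx$exp$design)
  expect_equal(read_regulator_edges(paths[["regulator_edges"]]),
               sx$exp$regulator_edges)
  db <- read_gmt(paths[["annotation"]])
  expect_equal(db$terms, sx$ann$terms)
  expect_equal(db$gene_sets, sx$ann$gene_sets)
  expect_equal(length(readLines(paths[["annotation"]])), nrow(sx$ann$terms))
})

test_that("an empty regulator set still writes a valid header-only file", {
  cfg <- sim_config(n_genes = 30, n_terms = 5, n_regulators = 0, seed = 2,
                    term_size_range = c(3, 8))
  exp <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(exp, dir)
  edges <- read_regulator_edges(paths[["regulator_edges"]])
  expect_equal(nrow(edges), 0)
})

test_that("the matrix-level generator plants the same truth structure", {
  cfg <- sim_config(n_genes = 80, seed = 6)
  r1 <- generate_expression_matrix(cfg)
  r2 <- generate_expression_matrix(cfg)
  expect_identical(r1$em$values, r2$em$values)
  expect_equal(nrow(r1$truth$deg_genes), round(0.2 * 80))
  expect_equal(ncol(r1$em$values), 48)
  ## planted effect visible: mean value at perturbed cells tracks the truth
  g <- r1$truth$deg_genes$gene_id[1]
  tl <- r1$truth$true_log2fc[g, ]
  big <- names(tl)[which.max(abs(tl))]
  cmp <- r1$truth$comparisons
  row <- cmp[cmp$comparison_id == big, ]
  des <- r1$em$design
  sel <- function(t) des$sample_id[des$cell_type == row$cell_type &
                                     des$differentiation == row$differentiation &
                                     des$time_dd == t]
  i <- which(r1$em$gene_id == g)
  obs <- mean(r1$em$values[i, sel(row$time_num)]) -
    mean(r1$em$values[i, sel(row$time_den)])
  expect_lt(abs(obs - tl[[big]]), 0.5)
})
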