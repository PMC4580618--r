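test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "index 2")
  expect_error(bh_adjust(c(-0.1)), "index 1")
})

test_that("fold-change / percent conversion follows the signed convention", {
  expect_equal(fold_change_percent(2), 100)
  expect_equal(fold_change_percent(-2), -100)
  expect_equal(fold_change_percent(1), 0)
  expect_equal(fold_change_percent(c(1.5, -4)), c(50, -300))
  expect_error(fold_change_percent(0.5), "index 1")
  expect_equal(log2fc_to_fold(c(1, -1, 0, 2)), c(2, -2, 1, 4))
  expect_equal(fold_change_percent(log2fc_to_fold(1)), 100)
})

test_that("the two-tier rule gates on both the overall FDR and the post-hoc p", {
  res <- structure(list(
    genes = data.frame(gene_id = c("g1", "g2", "g3"),
                       overall_p = c(0.001, 0.01, 0.8),
                       overall_fdr = c(0.004, 0.04, 0.9),
                       degenerate = FALSE, note = "",
                       stringsAsFactors = FALSE),
    log2fc = matrix(c(2, 0.5, 1, 1.2, 0.4, 0.1), nrow = 3,
                    dimnames = list(c("g1", "g2", "g3"), c("c1", "c2"))),
    posthoc_p = matrix(c(0.01, 0.2, 0.01, 0.01, 0.01, 0.9), nrow = 3,
                       dimnames = list(c("g1", "g2", "g3"), c("c1", "c2"))),
    comparisons = data.frame(comparison_id = c("c1", "c2")),
    pig_mode = "fixed_block"), class = "contrast_results")
  deg <- call_deg(res)
  get <- function(g, cmp) deg[deg$gene_id == g & deg$comparison_id == cmp, ]
  expect_true(get("g1", "c1")$is_deg)            # both tiers pass
  expect_true(get("g1", "c1")$passes_2fold)      # |log2fc| = 2
  expect_false(get("g2", "c1")$is_deg)           # posthoc 0.2 fails
  expect_true(get("g2", "c2")$is_deg)            # fdr 0.04, posthoc 0.01
  expect_false(get("g2", "c2")$passes_2fold)     # log2fc 0.4
  expect_false(get("g3", "c1")$is_deg)           # overall fdr fails
  counts <- attr(deg, "counts")
  expect_equal(counts$n_up[counts$comparison_id == "c1"], 1)
  expect_equal(counts$n_up_cutoff[counts$comparison_id == "c2"], 1)
})

test_that("a constant gene is flagged degenerate and never called", {
  cfg <- sim_config(n_genes = 5, deg_fraction = 0, noise_sd = 0.25,
                    term_size_range = c(2L, 5L), seed = 2)
  r <- generate_expression_matrix(cfg)
  r$em$values[r$em$gene_id == "G0001", ] <- 3.14
  fit <- fit_gene_model(r$em, pig_mode = "fixed_block")
  g <- fit$genes[fit$genes$gene_id == "G0001", ]
  expect_true(g$degenerate)
  expect_equal(g$overall_p, 1)
  expect_true(all(fit$log2fc["G0001", ] == 0))
})

test_that("a planted single-series effect is recovered with its magnitude", {
  ## one gene with true log2FC = 2 from 7 dd in ASC/adipogenic only
  pat0 <- default_effect_patterns()[[1]] * 0
  pat <- pat0; pat["ASC.adipogenic", c("7", "21")] <- 2
  hits <- 0; in_band <- 0; n_sim <- 20
  for (s in seq_len(n_sim)) {
    cfg <- sim_config(n_genes = 10, deg_fraction = 0.1, noise_sd = 0.25,
                      term_size_range = c(2L, 8L),
                      effect_patterns = list(pat), seed = 100 + s)
    r <- generate_expression_matrix(cfg)
    fit <- fit_gene_model(r$em)
    g <- r$truth$deg_genes$gene_id[1]
    est <- fit$log2fc[g, "ASC.adipogenic.t7_vs_t0"]
    p <- fit$posthoc_p[g, "ASC.adipogenic.t7_vs_t0"]
    if (abs(est - 2) <= 0.5) in_band <- in_band + 1
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.9)
  expect_gte(in_band / n_sim, 0.9)
})

test_that("random-intercept and fixed-block fits agree on the DEG set", {
  cfg <- sim_config(n_genes = 100, seed = 21)
  r <- generate_expression_matrix(cfg)
  f_mixed <- fit_gene_model(r$em, pig_mode = "random_intercept")
  f_block <- fit_gene_model(r$em, pig_mode = "fixed_block")
  d_mixed <- call_deg(f_mixed)
  d_block <- call_deg(f_block)
  agree <- mean(vapply(unique(d_mixed$gene_id), function(g)
    any(d_mixed$is_deg[d_mixed$gene_id == g]) ==
      any(d_block$is_deg[d_block$gene_id == g]), TRUE))
  expect_gte(agree, 0.95)
  ## interaction F-tests are near-identical in the balanced design
  expect_lt(max(abs(f_mixed$genes$overall_p - f_block$genes$overall_p)),
            0.02)
})

test_that("planted positive effects never come out significantly negative", {
  sx <- small_experiment()
  fit <- small_deg()$fit
  truth <- sx$exp$truth
  tl <- truth$true_log2fc
  est <- fit$log2fc[rownames(tl), colnames(tl)]
  pp <- fit$posthoc_p[rownames(tl), colnames(tl)]
  strong <- abs(tl) >= 1 & !is.na(est) & !is.na(pp) & pp < 0.05
  expect_equal(sum(sign(est[strong]) != sign(tl[strong])), 0)
})

test_that("missing samples are tolerated by the per-gene fit", {
  cfg <- sim_config(n_genes = 20, term_size_range = c(2L, 10L), seed = 8)
  r <- generate_expression_matrix(cfg)
  drop <- sample(ncol(r$em$values), 6)
  r$em$values[, drop] <- NA
  r$em$values <- r$em$values[, -drop]
  r$em$design <- r$em$design[-drop, ]
  fit <- fit_gene_model(r$em, pig_mode = "fixed_block")
  expect_equal(nrow(fit$genes), 20)
  expect_true(all(is.finite(fit$genes$overall_p)))
})

test_that("the REML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lmerTest")
  cfg <- sim_config(n_genes = 6, deg_fraction = 0.5, seed = 33,
                    term_size_range = c(2L, 5L))
  r <- generate_expression_matrix(cfg)
  fit <- fit_gene_model(r$em)
  des <- r$em$design
  for (g in c("G0001", "G0004")) {
    i <- which(r$em$gene_id == g)
    d <- data.frame(y = as.vector(r$em$values[i, , drop = FALSE]),
                    time = factor(rep(des$time_dd, each = length(i))),
                    cell = factor(rep(des$cell_type, each = length(i))),
                    diff = factor(rep(des$differentiation, each = length(i))),
                    pig = factor(rep(des$pig, each = length(i))))
    ref <- lmerTest::lmer(y ~ time * cell * diff + (1 | pig), data = d)
    an <- stats::anova(ref)   # Satterthwaite df
    p_ref <- an["time:cell:diff", "Pr(>F)"]
    expect_equal(fit$genes$overall_p[fit$genes$gene_id == g], p_ref,
                 tolerance = 1e-4)
    ## cell-mean contrast from the reference fit
    em_ref <- predict(ref, newdata = data.frame(
      time = factor(c(7, 0), levels = levels(d$time)),
      cell = factor("ASC", levels = levels(d$cell)),
      diff = factor("adipogenic", levels = levels(d$diff))), re.form = NA)
    expect_equal(fit$log2fc[g, "ASC.adipogenic.t7_vs_t0"],
                 unname(em_ref[1] - em_ref[2]), tolerance = 1e-6)
  }
})
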