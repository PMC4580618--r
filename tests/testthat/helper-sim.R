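## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

## A small but complete simulated experiment used across test files
small_experiment <- function() {
  cached("small_experiment", function() {
    cfg <- sim_config(n_genes = 150, n_terms = 40, seed = 3)
    exp <- generate_experiment(cfg)
    ann <- generate_annotation(cfg, exp$truth)
    list(cfg = cfg, exp = exp, ann = ann)
  })
}

## The same experiment pushed through preprocessing and the fixed-block fit
small_deg <- function() {
  cached("small_deg", function() {
    sx <- small_experiment()
    em <- preprocess(sx$exp$spots, sx$exp$design)
    fit <- fit_gene_model(em, pig_mode = "fixed_block")
    deg <- call_deg(fit)
    list(em = em, fit = fit, deg = deg)
  })
}

## True archetype log2FC profiles (one row per gene, cycling archetypes)
archetype_profiles <- function(n_genes = 120, noise_sd = 0.25, seed = 1) {
  cmp <- comparison_table(c("ASC", "BMSC"), c("adipogenic", "osteogenic"),
                          c(0, 2, 7, 21))
  pats <- default_effect_patterns()
  prof <- t(vapply(rep(seq_along(pats), length.out = n_genes), function(a) {
    p <- pats[[a]]
    s <- series_label(cmp$cell_type, cmp$differentiation)
    p[cbind(s, as.character(cmp$time_num))] -
      p[cbind(s, as.character(cmp$time_den))]
  }, numeric(nrow(cmp))))
  colnames(prof) <- cmp$comparison_id
  rownames(prof) <- sprintf("g%03d", seq_len(n_genes))
  set.seed(seed)
  prof + stats::rnorm(length(prof), 0, noise_sd)
}

## Minimal hand-built spot table rows
spot_row <- function(ch1_fg, ch1_bg, ch2_fg, ch2_bg, bg_sd, flag,
                     gene = "G1", array = "A1", spot = "S1", dup = 1L) {
  data.frame(spot_id = spot, gene_id = gene, array_id = array,
             block_dup_index = dup, ch1_fg_median = ch1_fg,
             ch1_bg_median = ch1_bg, ch2_fg_median = ch2_fg,
             ch2_bg_median = ch2_bg, bg_sd = bg_sd, flag = flag,
             stringsAsFactors = FALSE)
}

## Hand-built long DEG-call table (as produced by call_deg)
fake_deg <- function(gene_id, comparison_id, log2fc, posthoc_p, is_deg,
                     passes_2fold = TRUE) {
  structure(data.frame(gene_id = gene_id, comparison_id = comparison_id,
                       log2fc = log2fc, posthoc_p = posthoc_p,
                       overall_fdr = ifelse(is_deg, 0.01, 0.5),
                       is_deg = is_deg, passes_2fold = passes_2fold,
                       stringsAsFactors = FALSE),
            class = c("deg_calls", "data.frame"))
}

## Rank-based AUROC of score separating positives from negatives
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Independent step-up FDR oracle, written directly from the formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), 0)
  q <- numeric(m)
  q[o] <- adj
  q
}
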