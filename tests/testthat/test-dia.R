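test_that("GMT parsing enforces the dialect and reports the faulty line", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.gmt")
  writeLines(c("T1\tKEGG|Metabolism|10\tG1\tG2\tG3",
               "T2\tGO|BP|4\tG2"), good)
  db <- read_gmt(good)
  expect_equal(nrow(db$terms), 2)
  expect_equal(db$terms$genome_gene_count, c(10L, 4L))
  expect_equal(db$gene_sets$T1, c("G1", "G2", "G3"))

  bad1 <- file.path(dir, "bad1.gmt")
  writeLines(c("T1\tKEGG|Metabolism|10\tG1", "T2\tKEGG|Metabolism\tG1"), bad1)
  expect_error(read_gmt(bad1), "line 2")
  bad2 <- file.path(dir, "bad2.gmt")
  writeLines(c("T1\tA|B|5\tG1", "T1\tA|B|5\tG2"), bad2)
  expect_error(read_gmt(bad2), "duplicate")
})

test_that("coverage filtering keeps the 30% boundary and drops single-gene terms in GO mode", {
  terms <- data.frame(term_id = c("T1", "T2", "T3"), name = c("T1", "T2", "T3"),
                      category = "GO", subcategory = "BP",
                      genome_gene_count = c(10L, 10L, 3L),
                      stringsAsFactors = FALSE)
  sets <- list(T1 = c("G1", "G2", "G3"),   # coverage 0.30: boundary kept
               T2 = c("G1", "G2"),         # coverage 0.20: dropped
               T3 = "G1")                  # coverage 0.33 but 1 platform gene
  db <- annotation_db(terms, sets)
  platform <- sprintf("G%d", 1:50)
  kept <- coverage_filter(db, platform)
  expect_setequal(kept$terms$term_id, c("T1", "T3"))
  go <- coverage_filter(db, platform, apply_min_genes = TRUE)
  expect_equal(go$terms$term_id, "T1")
  log <- attr(go, "removal_log")
  expect_equal(log$reason[log$term_id == "T3"], "fewer platform genes than minimum")
})

test_that("impact and direction follow the proportion x magnitude x significance form", {
  ## 4 genes, all up-regulated DEG, |log2fc| = 1, p = 0.01
  deg <- fake_deg(sprintf("G%d", 1:4), "c1", rep(1, 4), rep(0.01, 4), TRUE)
  r <- term_impact(sprintf("G%d", 1:4), deg, "c1")
  expect_equal(r$impact, 2)       # 1 * 1 * 2
  expect_equal(r$direction, 2)
  ## 2 up, 2 down with identical magnitude and significance
  deg2 <- fake_deg(sprintf("G%d", 1:4), "c1", c(1, 1, -1, -1), rep(0.01, 4), TRUE)
  r2 <- term_impact(sprintf("G%d", 1:4), deg2, "c1")
  expect_equal(r2$impact, 2)
  expect_equal(r2$direction, 0)
  ## no DEG at all
  deg0 <- fake_deg(sprintf("G%d", 1:4), "c1", rep(0.2, 4), rep(0.5, 4), FALSE)
  r0 <- term_impact(sprintf("G%d", 1:4), deg0, "c1")
  expect_equal(r0$impact, 0)
  expect_equal(r0$direction, 0)
  ## significance cap bounds underflowing p-values
  degc <- fake_deg("G1", "c1", 1, 1e-300, TRUE)
  expect_equal(term_impact("G1", degc, "c1")$impact, 10)
})

test_that("impact bounds direction, scales linearly and grows with conversions", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    deg <- fake_deg(sprintf("G%d", 1:n), "c1",
                    rnorm(n), runif(n, 1e-6, 1), runif(n) < 0.5)
    r <- term_impact(sprintf("G%d", 1:n), deg, "c1")
    expect_gte(r$impact, abs(r$direction) - 1e-12)
    expect_equal(r$impact == 0, r$n_deg == 0)
    ## linearity in fold-change magnitude
    deg_scaled <- deg; deg_scaled$log2fc <- deg$log2fc * 3
    r3 <- term_impact(sprintf("G%d", 1:n), deg_scaled, "c1")
    expect_equal(r3$impact, 3 * r$impact, tolerance = 1e-12)
    ## converting a non-DEG gene to an up-DEG never decreases impact
    if (any(!deg$is_deg)) {
      j <- which(!deg$is_deg)[1]
      deg_up <- deg
      deg_up$is_deg[j] <- TRUE
      deg_up$log2fc[j] <- abs(deg_up$log2fc[j]) + 0.5
      r_up <- term_impact(sprintf("G%d", 1:n), deg_up, "c1")
      expect_gte(r_up$impact, r$impact - 1e-12)
    }
  }
})

test_that("category roll-up is the unweighted mean of member terms", {
  terms <- data.frame(term_id = c("T1", "T2", "T3"), name = c("T1", "T2", "T3"),
                      category = c("C1", "C1", "C2"),
                      subcategory = c("S1", "S1", "S2"),
                      genome_gene_count = 5L, stringsAsFactors = FALSE)
  db <- annotation_db(terms, list(T1 = "G1", T2 = "G2", T3 = "G3"))
  imp <- structure(data.frame(term_id = c("T1", "T2", "T3"),
                              comparison_id = "c1",
                              impact = c(2, 4, 7), direction = c(2, -4, 7),
                              stringsAsFactors = FALSE),
                   class = c("term_impacts", "data.frame"))
  sub <- dia_rollup(imp, db, "subcategory")
  expect_equal(sub$impact[sub$group == "S1"], 3)
  expect_equal(sub$direction[sub$group == "S1"], -1)
  expect_equal(sub$impact[sub$group == "S2"], 7)   # single member = member
})

test_that("direction-of-impact summaries sum over time and subtract matched series", {
  cmp <- comparison_table(c("ASC", "BMSC"), c("adipogenic", "osteogenic"),
                          c(0, 2, 7, 21))
  vs0 <- cmp[cmp$time_den == 0, ]
  ## term perturbed in adipogenesis only: DoI +2 at each time point in both cells
  imp <- structure(data.frame(
    term_id = "T1", comparison_id = cmp$comparison_id,
    impact = ifelse(cmp$differentiation == "adipogenic", 2, 0),
    direction = ifelse(cmp$differentiation == "adipogenic", 2, 0),
    stringsAsFactors = FALSE), class = c("term_impacts", "data.frame"))
  s <- dia_doi_summaries(imp, cmp)
  expect_equal(s$doi_sum.ASC.adipogenic, 6)
  expect_equal(s$doi_adipogenic_minus_osteogenic.ASC, 6)
  expect_equal(s$doi_adipogenic_minus_osteogenic.BMSC, 6)
  expect_equal(s$doi_ASC_minus_BMSC.adipogenic, 0)
  ## identical series difference to zero
  imp2 <- imp; imp2$direction <- 1; imp2$impact <- 1
  s2 <- dia_doi_summaries(imp2, cmp)
  expect_equal(s2$doi_adipogenic_minus_osteogenic.ASC, 0)
  ## missing comparisons are an error naming the gap
  imp3 <- imp[-1, ]
  expect_error(dia_doi_summaries(imp3, cmp), "unmatched")
})

test_that("planted perturbed terms rank above null terms and with the right sign", {
  sx <- small_experiment()
  deg <- small_deg()$deg
  filtered <- coverage_filter(sx$ann, sx$exp$truth$genes)
  impacts <- dia_impact(filtered, deg)
  summ <- dia_doi_summaries(impacts)
  pert <- attr(sx$ann, "perturbed")
  status <- pert$status[match(summ$term_id, pert$term_id)]
  expect_gte(auroc(summ$total_impact, status != "null"), 0.9)
  doi_total <- rowSums(summ[, grep("^doi_sum\\.", names(summ)), drop = FALSE])
  idx <- which(status != "null")
  expect_true(all(sign(doi_total[idx]) ==
                    ifelse(status[idx] == "up", 1, -1)))
})
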