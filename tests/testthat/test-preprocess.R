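test_that("spot filtering applies the intensity and flag rules literally", {
  sp <- rbind(
    spot_row(1000, 100, 1000, 100, 50, 200, spot = "S1"),  # passes both
    spot_row(1000, 100, 1000, 100, 50, 100, spot = "S2"),  # flag boundary
    spot_row(240, 100, 1000, 100, 50, 200, spot = "S3"))   # 240 < 250
  strict <- filter_spots(sp)
  expect_equal(strict$spot_id, "S1")
  inclusive <- filter_spots(sp, flag_comparator = "greater_equal")
  expect_setequal(inclusive$spot_id, c("S1", "S2"))
  rep <- attr(strict, "filter_report")
  expect_equal(rep$n_input, 3)
  expect_equal(rep$n_retained, 1)
  expect_error(filter_spots(sp[, -5]), "ch1_fg_median")
})

test_that("raising the intensity multiplier never enlarges the retained set", {
  sp <- small_experiment()$exp$spots
  kept_prev <- NULL
  for (m in c(1, 2, 3, 5, 8)) {
    kept <- paste(filter_spots(sp, sd_multiplier = m)$array_id,
                  filter_spots(sp, sd_multiplier = m)$spot_id)
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("M and A match a direct recomputation", {
  set.seed(42)
  n <- 50
  sp <- spot_row(0, 0, 0, 0, 0, 200)[rep(1, n), ]
  sp$spot_id <- sprintf("S%d", 1:n)
  sp$ch1_bg_median <- runif(n, 50, 80)
  sp$ch2_bg_median <- runif(n, 50, 80)
  sp$ch1_fg_median <- sp$ch1_bg_median + 2 ^ runif(n, 8, 12)
  sp$ch2_fg_median <- sp$ch2_bg_median + 2 ^ runif(n, 8, 12)
  ma <- compute_ma(sp)
  c1 <- sp$ch1_fg_median - sp$ch1_bg_median
  c2 <- sp$ch2_fg_median - sp$ch2_bg_median
  expect_equal(ma$M, log2(c1) - log2(c2), tolerance = 1e-12)
  expect_equal(ma$A, (log2(c1) + log2(c2)) / 2, tolerance = 1e-12)
  ## symmetry and simple ratios
  eq <- spot_row(1100, 100, 1100, 100, 10, 200)
  expect_equal(compute_ma(eq)$M, 0)
  quad <- spot_row(4100, 100, 1100, 100, 10, 200)
  expect_equal(compute_ma(quad)$M, 2)
  ## nonpositive background subtraction drops the spot, with a count
  neg <- spot_row(90, 100, 1100, 100, 10, 200)
  out <- compute_ma(rbind(eq, neg))
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_nonpositive"), 1)
})

test_that("loess leaves a trend-free array almost unchanged and removes a linear bias", {
  set.seed(1)
  n <- 200
  base <- data.frame(spot_id = sprintf("S%d", 1:n), gene_id = sprintf("G%d", 1:n),
                     array_id = "A1", block_dup_index = 1L,
                     A = runif(n, 8, 14), stringsAsFactors = FALSE)
  ## constant M: the local fit is that constant, so M' = M - mean(M) exactly
  flat <- base; flat$M <- rep(0.7, n)
  out <- loess_normalize(flat)
  expect_lt(max(abs(out$M - (flat$M - mean(flat$M)))), 1e-10)
  ## exact linear bias is removed to negligible residual slope
  lin <- base; lin$M <- 0.3 * lin$A
  outl <- loess_normalize(lin)
  expect_lt(abs(coef(lm(outl$M ~ outl$A))[2]), 0.01)
  expect_error(loess_normalize(lin, span = 0), "span")
  expect_error(loess_normalize(lin, span = 1.5), "span")
  expect_warning(loess_normalize(base[1:5, c(1:4, 5)] |>
                                   transform(M = 0.1), span = 0.4),
                 "loess skipped")
})

test_that("planted sinusoidal dye bias is removed by loess plus centering", {
  sx <- small_experiment()
  filtered <- filter_spots(sx$exp$spots)
  ma <- loess_normalize(compute_ma(filtered))
  med <- tapply(ma$M, ma$array_id, median)
  expect_lt(max(abs(med)), 0.1)   # amplitude 0.5 cut by better than 5x
  em <- center_arrays(ma, sx$exp$design)
  col_med <- apply(em$values, 2, median, na.rm = TRUE)
  expect_lt(max(abs(col_med)), 1e-12)
})

test_that("array centering is idempotent, location-free and keeps duplicates", {
  sx <- small_experiment()
  ma <- loess_normalize(compute_ma(filter_spots(sx$exp$spots)))
  em1 <- center_arrays(ma, sx$exp$design)
  ## adding a constant per array changes nothing after centering
  shifted <- ma; shifted$M <- shifted$M + 5
  em2 <- center_arrays(shifted, sx$exp$design)
  expect_equal(em1$values, em2$values, tolerance = 1e-12)
  ## centering twice equals centering once
  ma_centered <- ma
  med <- tapply(ma$M, ma$array_id, median)
  ma_centered$M <- ma$M - med[ma$array_id]
  em3 <- center_arrays(ma_centered, sx$exp$design)
  expect_equal(em1$values, em3$values, tolerance = 1e-12)
  ## duplicate spots remain separate rows
  expect_true(any(duplicated(em1$gene_id)))
  expect_equal(sort(unique(em1$block_dup_index)), 1:2)
})
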