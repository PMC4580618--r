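#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values, with
#' input validation. NA entries are carried through.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad) > 0L)
    stop(sprintf("p-value out of [0, 1] at index %d (value %g)",
                 bad[1], p[bad[1]]), call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Convert signed fold change to percent change
#'
#' Fold changes use the signed convention (sign carries direction, so a
#' halving is -2, never 0.5): a 2-fold change is a +/-100 percent change.
#'
#' @param fc signed fold change(s); `|fc| >= 1` required.
#' @return percent change, `sign(fc) * (|fc| - 1) * 100`.
#' @export
fold_change_percent <- function(fc) {
  bad <- which(!is.na(fc) & abs(fc) < 1)
  if (length(bad) > 0L)
    stop(sprintf("|fold change| < 1 at index %d (value %g); convert ratios to signed fold change first",
                 bad[1], fc[bad[1]]), call. = FALSE)
  sign(fc) * (abs(fc) - 1) * 100
}

#' Convert a log2 fold change to a signed fold change
#' @param log2fc log2 fold change(s).
#' @return signed fold change: `2^log2fc` for increases, `-2^(-log2fc)`
#'   for decreases (and +1 at zero).
#' @export
log2fc_to_fold <- function(log2fc) {
  ifelse(log2fc >= 0, 2 ^ log2fc, -(2 ^ (-log2fc)))
}

## Fixed-effect design machinery shared by both pig modes: a cell-mean
## contrast matrix mapping model coefficients to the reported pairwise
## differences (every time vs the series' own 0, plus consecutive times).
build_contrast_info <- function(design, pig_mode) {
  tp <- sort(unique(design$time_dd))
  lev <- list(time = as.character(tp),
              cell = sort(unique(design$cell_type)),
              diff = sort(unique(design$differentiation)),
              pig = sort(unique(design$pig)))
  cmp <- comparison_table(lev$cell, lev$diff, tp)
  grid <- expand.grid(time = factor(lev$time, levels = lev$time),
                      cell = factor(lev$cell, levels = lev$cell),
                      diff = factor(lev$diff, levels = lev$diff),
                      stringsAsFactors = FALSE)
  grid$pig <- factor(lev$pig[1], levels = lev$pig)
  form <- if (pig_mode == "fixed_block")
    ~ pig + time * cell * diff else ~ time * cell * diff
  X <- stats::model.matrix(form, grid)
  key <- paste(grid$time, grid$cell, grid$diff)
  D <- X[match(paste(cmp$time_num, cmp$cell_type, cmp$differentiation), key), ,
         drop = FALSE] -
    X[match(paste(cmp$time_den, cmp$cell_type, cmp$differentiation), key), ,
      drop = FALSE]
  rownames(D) <- cmp$comparison_id
  list(levels = lev, comparisons = cmp, D = D,
       cmp_key_num = paste(cmp$time_num, cmp$cell_type, cmp$differentiation),
       cmp_key_den = paste(cmp$time_den, cmp$cell_type, cmp$differentiation))
}

#' Fit the per-gene factorial model and extract contrasts
#'
#' For every gene, fits normalized log2 ratios to the factorial model with
#' fixed effects of time, cell type, differentiation and all their
#' interactions, and pig as a random intercept (the default) or a fixed
#' block. Duplicate-spot rows of a gene enter as repeated observations of
#' the same sample; they are never averaged. The overall p-value is the
#' F-test of the time x cell type x differentiation interaction, adjusted
#' across genes by Benjamini-Hochberg; post-hoc p-values and log2 fold
#' changes come from pairwise contrasts of estimated cell means, within
#' each (cell type, differentiation) series: each time point against that
#' series' own time 0 and between consecutive time points.
#'
#' @param em an `expression_matrix` from [preprocess()]/[center_arrays()],
#'   or a plain numeric matrix (rows may repeat per gene) with `design`
#'   supplied.
#' @param design sample design table; defaults to the one embedded in `em`.
#' @param pig_mode `"random_intercept"` (REML mixed model) or
#'   `"fixed_block"` (ordinary least squares with pig as a block factor).
#'   In the balanced crossed design the two give near-identical interaction
#'   tests; the fixed-block fit is also the fallback when a mixed fit fails.
#' @param gene_id,block_dup_index row annotations when `em` is a plain
#'   matrix (default: rownames, all dup index 1).
#' @return object of class `contrast_results`: `genes` (gene_id, overall_p,
#'   overall_fdr, degenerate flag, note), `comparisons` (long table of
#'   gene_id, comparison_id, log2fc, posthoc_p) and the comparison
#'   definitions.
#' @export
fit_gene_model <- function(em, design = NULL,
                           pig_mode = c("random_intercept", "fixed_block"),
                           gene_id = NULL, block_dup_index = NULL) {
  pig_mode <- match.arg(pig_mode)
  if (inherits(em, "expression_matrix")) {
    values <- em$values
    gene_id <- em$gene_id
    design <- design %||% em$design
  } else {
    values <- as.matrix(em)
    gene_id <- gene_id %||% rownames(values)
    if (is.null(gene_id)) stop("gene_id required for a plain matrix input")
  }
  check_columns(design, c("sample_id", "pig", "cell_type", "differentiation",
                          "time_dd"), "design table")
  if (length(unique(design$pig)) < 2L)
    stop("need >= 2 pigs to fit the model", call. = FALSE)
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("every matrix column must map to one design row", call. = FALSE)

  info <- build_contrast_info(design, pig_mode)
  lev <- info$levels
  n_s <- nrow(design)
  base_factors <- data.frame(
    time = factor(as.character(design$time_dd), levels = lev$time),
    cell = factor(design$cell_type, levels = lev$cell),
    diff = factor(design$differentiation, levels = lev$diff),
    pig = factor(design$pig, levels = lev$pig))

  gene_rows <- split(seq_along(gene_id), gene_id)
  genes <- names(gene_rows)
  n_cmp <- nrow(info$comparisons)

  res_overall <- rep(NA_real_, length(genes))
  res_note <- character(length(genes))
  res_degen <- logical(length(genes))
  l2fc <- matrix(NA_real_, length(genes), n_cmp,
                 dimnames = list(genes, info$comparisons$comparison_id))
  pp <- l2fc

  for (gi in seq_along(genes)) {
    idx <- gene_rows[[gi]]
    k <- length(idx)
    y <- as.vector(values[idx, , drop = FALSE])  # dup rows vary fastest
    fac <- base_factors[rep(seq_len(n_s), each = k), , drop = FALSE]
    ok <- !is.na(y)
    if (sum(ok) < 2L || stats::sd(y[ok]) < 1e-10) {
      res_overall[gi] <- 1; l2fc[gi, ] <- 0; pp[gi, ] <- 1
      res_degen[gi] <- TRUE; res_note[gi] <- "degenerate: constant or empty"
      next
    }
    d <- cbind(fac[ok, , drop = FALSE], y = y[ok])
    fit <- fit_one_gene(d, pig_mode)
    if (is.null(fit)) {
      res_note[gi] <- "fit failed"
      next
    }
    res_overall[gi] <- fit$overall_p
    res_note[gi] <- fit$note
    est <- contrast_estimates(fit, info$D)
    ## a contrast is estimable only if both of its design cells have data
    pres <- unique(paste(d$time, d$cell, d$diff))
    estimable <- info$cmp_key_num %in% pres & info$cmp_key_den %in% pres
    est$log2fc[!estimable] <- NA_real_
    est$p[!estimable] <- NA_real_
    l2fc[gi, ] <- est$log2fc
    pp[gi, ] <- est$p
  }

  structure(list(
    genes = data.frame(gene_id = genes, overall_p = res_overall,
                       overall_fdr = bh_adjust(res_overall),
                       degenerate = res_degen, note = res_note,
                       stringsAsFactors = FALSE),
    log2fc = l2fc, posthoc_p = pp,
    comparisons = info$comparisons, pig_mode = pig_mode),
    class = "contrast_results")
}

## Fit one gene; returns NULL on unrecoverable failure. A failed mixed fit
## falls back to the fixed-block model (noted).
fit_one_gene <- function(d, pig_mode) {
  three_way <- "time:cell:diff"
  if (pig_mode == "random_intercept") {
    fit <- tryCatch(
      nlme::lme(y ~ time * cell * diff, random = ~ 1 | pig, data = d,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      an <- tryCatch(stats::anova(fit), error = function(e) NULL)
      if (!is.null(an) && three_way %in% rownames(an)) {
        return(list(beta = nlme::fixef(fit), V = stats::vcov(fit),
                    df = an[three_way, "denDF"],
                    overall_p = an[three_way, "p-value"], note = ""))
      }
    }
    note <- "mixed fit failed; fixed-block fallback"
  } else note <- ""
  fit <- tryCatch(stats::lm(y ~ pig + time * cell * diff, data = d),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  an <- stats::anova(fit)
  row <- match(three_way, rownames(an))
  op <- if (is.na(row)) NA_real_ else an[row, "Pr(>F)"]
  beta <- stats::coef(fit)
  V <- matrix(0, length(beta), length(beta),
              dimnames = list(names(beta), names(beta)))
  est <- !is.na(beta)
  V[est, est] <- stats::vcov(fit)[names(beta)[est], names(beta)[est], drop = FALSE]
  list(beta = beta, V = V, df = stats::df.residual(fit),
       overall_p = op, note = note)
}

contrast_estimates <- function(fit, D) {
  beta <- fit$beta
  absent <- setdiff(colnames(D), names(beta))
  present <- intersect(colnames(D), names(beta))
  usable_coef <- !is.na(beta[present])
  V <- fit$V[present, present, drop = FALSE]
  est <- p <- rep(NA_real_, nrow(D))
  for (j in seq_len(nrow(D))) {
    if (length(absent) > 0L && any(D[j, absent] != 0)) next  # unestimable
    load <- D[j, present]
    if (any(load != 0 & !usable_coef)) next  # unestimable contrast
    b <- beta[present]; b[!usable_coef] <- 0
    e <- sum(load * b)
    se <- sqrt(drop(load %*% V %*% load))
    est[j] <- e
    p[j] <- if (se > 0 && is.finite(fit$df) && fit$df > 0)
      2 * stats::pt(-abs(e / se), fit$df) else NA_real_
  }
  list(log2fc = est, p = p)
}

#' @export
print.contrast_results <- function(x, ...) {
  cat(sprintf("contrast_results: %d genes, %d comparisons (pig: %s)\n",
              nrow(x$genes), nrow(x$comparisons), x$pig_mode))
  cat(sprintf("  genes with overall FDR <= 0.05: %d\n",
              sum(x$genes$overall_fdr <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Two-tier differential-expression calls
#'
#' A gene is differentially expressed in a comparison when its overall
#' interaction FDR passes `alpha_overall` and the comparison's post-hoc
#' p-value passes `alpha_posthoc`. The fold-change cutoff is reported
#' separately (`passes_2fold`), so counts with and without the cutoff can
#' both be tabulated.
#'
#' @param results a `contrast_results` from [fit_gene_model()].
#' @param alpha_overall FDR threshold for the three-way interaction.
#' @param alpha_posthoc pairwise post-hoc p threshold.
#' @param fold_cutoff fold-change magnitude cutoff (default 2, i.e. a
#'   +/-100 percent change); NULL to skip.
#' @return data frame of class `deg_calls`: gene_id, comparison_id, log2fc,
#'   posthoc_p, overall_fdr, is_deg, passes_2fold; per-comparison up/down
#'   counts with and without the cutoff in the `counts` attribute.
#' @export
call_deg <- function(results, alpha_overall = 0.05, alpha_posthoc = 0.05,
                     fold_cutoff = 2) {
  stopifnot(inherits(results, "contrast_results"))
  g <- results$genes
  long <- data.frame(
    gene_id = rep(g$gene_id, times = nrow(results$comparisons)),
    comparison_id = rep(results$comparisons$comparison_id, each = nrow(g)),
    log2fc = as.vector(results$log2fc),
    posthoc_p = as.vector(results$posthoc_p),
    overall_fdr = rep(g$overall_fdr, times = nrow(results$comparisons)),
    stringsAsFactors = FALSE)
  long$is_deg <- !is.na(long$overall_fdr) & long$overall_fdr <= alpha_overall &
    !is.na(long$posthoc_p) & long$posthoc_p <= alpha_posthoc
  long$passes_2fold <- if (is.null(fold_cutoff)) TRUE else
    !is.na(long$log2fc) & abs(long$log2fc) >= log2(fold_cutoff)

  counts <- do.call(rbind, lapply(split(long, long$comparison_id), function(s) {
    data.frame(comparison_id = s$comparison_id[1],
               n_up = sum(s$is_deg & s$log2fc > 0, na.rm = TRUE),
               n_down = sum(s$is_deg & s$log2fc < 0, na.rm = TRUE),
               n_up_cutoff = sum(s$is_deg & s$passes_2fold & s$log2fc > 0, na.rm = TRUE),
               n_down_cutoff = sum(s$is_deg & s$passes_2fold & s$log2fc < 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  structure(long, counts = counts, class = c("deg_calls", "data.frame"))
}

#' Wide per-gene results table
#'
#' Flattens a `contrast_results` (and optional DEG calls) into the wide
#' layout used by the pipeline's TSV output: gene_id, overall_p,
#' overall_fdr, then log2fc / posthoc_p (/ is_deg) columns per comparison.
#'
#' @param results a `contrast_results`.
#' @param deg optional matching [call_deg()] result.
#' @return data frame.
#' @export
contrast_table <- function(results, deg = NULL) {
  out <- results$genes[, c("gene_id", "overall_p", "overall_fdr")]
  for (cmp in results$comparisons$comparison_id) {
    out[[paste0(cmp, ".log2fc")]] <- results$log2fc[, cmp]
    out[[paste0(cmp, ".posthoc_p")]] <- results$posthoc_p[, cmp]
    if (!is.null(deg)) {
      s <- deg[deg$comparison_id == cmp, ]
      out[[paste0(cmp, ".is_deg")]] <-
        s$is_deg[match(out$gene_id, s$gene_id)]
    }
  }
  out
}
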