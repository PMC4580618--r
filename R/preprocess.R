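#' Filter spots on background-relative intensity and quality flag
#'
#' A spot is retained only if both channel foreground medians are at least
#' `sd_multiplier` background standard deviations above the channel's
#' background median, and its quality flag passes the comparator against
#' `flag_threshold`. The scanner convention flags good spots at exactly 100,
#' so both a strict (`> 100`, the default) and an inclusive (`>= 100`)
#' comparator are provided.
#'
#' @param spots spot table (see [read_spot_table()] for the schema).
#' @param sd_multiplier background standard deviations required above the
#'   background median (default 3).
#' @param flag_threshold quality-flag cutoff (default 100).
#' @param flag_comparator `"strict_greater"` (default) or `"greater_equal"`.
#' @return the retained subset of `spots`, with a `filter_report` attribute:
#'   per-array counts of input, retained, intensity-dropped and
#'   flag-dropped spots.
#' @export
filter_spots <- function(spots, sd_multiplier = 3, flag_threshold = 100L,
                         flag_comparator = c("strict_greater", "greater_equal")) {
  check_columns(spots, spot_columns, "spot table")
  flag_comparator <- match.arg(flag_comparator)
  ok_int <- spots$ch1_fg_median >= spots$ch1_bg_median + sd_multiplier * spots$bg_sd &
    spots$ch2_fg_median >= spots$ch2_bg_median + sd_multiplier * spots$bg_sd
  ok_flag <- if (flag_comparator == "strict_greater")
    spots$flag > flag_threshold else spots$flag >= flag_threshold
  keep <- ok_int & ok_flag

  report <- do.call(rbind, lapply(split(seq_len(nrow(spots)), spots$array_id),
    function(i) data.frame(array_id = spots$array_id[i[1]],
                           n_input = length(i),
                           n_retained = sum(keep[i]),
                           n_dropped_intensity = sum(!ok_int[i]),
                           n_dropped_flag = sum(!ok_flag[i]),
                           stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' Compute per-spot M and A values
#'
#' Background-subtracts both channels and forms the log-ratio
#' `M = log2(ch1 / ch2)` and mean log-intensity `A = log2(ch1 * ch2) / 2`.
#' Spots where background subtraction leaves a nonpositive value in either
#' channel cannot form a ratio and are dropped (counted in the
#' `n_nonpositive` attribute).
#'
#' @param spots a (typically filtered) spot table.
#' @return data frame with spot identifiers and columns `M`, `A`.
#' @export
compute_ma <- function(spots) {
  check_columns(spots, spot_columns, "spot table")
  ch1 <- spots$ch1_fg_median - spots$ch1_bg_median
  ch2 <- spots$ch2_fg_median - spots$ch2_bg_median
  ok <- ch1 > 0 & ch2 > 0
  out <- data.frame(spot_id = spots$spot_id[ok], gene_id = spots$gene_id[ok],
                    array_id = spots$array_id[ok],
                    block_dup_index = spots$block_dup_index[ok],
                    M = log2(ch1[ok] / ch2[ok]),
                    A = 0.5 * log2(ch1[ok] * ch2[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "n_nonpositive") <- sum(!ok)
  out
}

#' Within-array loess normalization of M on A
#'
#' Removes the intensity-dependent dye bias per array by subtracting a
#' robust local-linear (tricube-weighted, 3 robustness iterations) fit of M
#' on A: `M' = M - fit(A)`. Arrays with fewer than 20 spots are passed
#' through unchanged with a warning.
#'
#' @param ma per-spot M/A table from [compute_ma()].
#' @param span loess span in (0, 1] (default 0.4).
#' @return `ma` with `M` replaced by the corrected values (the raw values
#'   are kept in `M_raw`).
#' @export
loess_normalize <- function(ma, span = 0.4) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must be a number in (0, 1]", call. = FALSE)
  check_columns(ma, c("array_id", "M", "A"), "MA table")
  ma$M_raw <- ma$M
  for (a in unique(ma$array_id)) {
    i <- which(ma$array_id == a)
    if (length(i) < 20L) {
      warning(sprintf("array %s has %d spots (< 20); loess skipped", a, length(i)))
      next
    }
    fit <- stats::lowess(ma$A[i], ma$M[i], f = span, iter = 3)
    ma$M[i] <- ma$M[i] - stats::approx(fit$x, fit$y, xout = ma$A[i],
                                       rule = 2, ties = mean)$y
  }
  ma
}

#' Median-center each array and assemble the expression matrix
#'
#' Subtracts the per-array median of the normalized log ratios ("array
#' centering") and arranges the result as a genes-x-samples matrix of
#' normalized log2(sample/reference) ratios. Duplicate spots are retained
#' as separate rows (keyed by `gene_id` plus `block_dup_index`), never
#' averaged; spots missing on an array leave NA cells.
#'
#' @param ma normalized M/A table from [loess_normalize()].
#' @param design sample design table mapping `array_id` to `sample_id`.
#' @return an `expression_matrix`: list with `values` (numeric matrix),
#'   `gene_id`, `block_dup_index`, and the `design`.
#' @export
center_arrays <- function(ma, design) {
  check_columns(ma, c("gene_id", "array_id", "block_dup_index", "M"), "MA table")
  check_columns(design, c("sample_id", "array_id"), "design table")
  med <- tapply(ma$M, ma$array_id, stats::median)
  ma$M <- ma$M - med[ma$array_id]

  key <- paste(ma$gene_id, ma$block_dup_index, sep = "\r")
  rows <- unique(key)
  sample_of <- stats::setNames(design$sample_id, design$array_id)
  cols <- design$sample_id
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                   dimnames = list(NULL, cols))
  values[cbind(match(key, rows), match(sample_of[ma$array_id], cols))] <- ma$M

  parts <- do.call(rbind, strsplit(rows, "\r", fixed = TRUE))
  structure(list(values = values, gene_id = parts[, 1],
                 block_dup_index = as.integer(parts[, 2]), design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d spot rows (%d genes) x %d samples, %.1f%% missing\n",
              nrow(x$values), length(unique(x$gene_id)), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Fixed order: quality filtering, M/A computation, within-array loess
#' normalization, array median centering. The order is part of the method
#' and cannot be rearranged.
#'
#' @inheritParams filter_spots
#' @inheritParams loess_normalize
#' @param design sample design table.
#' @return an `expression_matrix` with the spot `filter_report` attached as
#'   an attribute.
#' @export
preprocess <- function(spots, design, sd_multiplier = 3, flag_threshold = 100L,
                       flag_comparator = c("strict_greater", "greater_equal"),
                       span = 0.4) {
  filtered <- filter_spots(spots, sd_multiplier, flag_threshold, flag_comparator)
  ma <- compute_ma(filtered)
  ma <- loess_normalize(ma, span)
  em <- center_arrays(ma, design)
  attr(em, "filter_report") <- attr(filtered, "filter_report")
  em
}
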