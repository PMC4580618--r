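#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with a message identifying the offending field/column
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## Derive a per-stage seed from a global seed so stages can be rerun
## independently yet reproducibly. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 1009L)
}

## Series label used throughout: one (cell type, differentiation) pair
series_label <- function(cell, diff) paste(cell, diff, sep = ".")

## Canonical comparison id, e.g. "ASC.adipogenic.t7_vs_t0"
comparison_id <- function(cell, diff, t_num, t_den) {
  sprintf("%s.%s.t%s_vs_t%s", cell, diff, t_num, t_den)
}

## All pairwise comparisons reported per series: every time point vs the
## series' own time 0, plus consecutive time points.
comparison_pairs <- function(time_points) {
  tp <- sort(unique(time_points))
  pairs <- lapply(tp[-1], function(t) c(t, tp[1]))
  if (length(tp) > 2L) {
    for (i in 2:(length(tp) - 1L)) pairs <- c(pairs, list(c(tp[i + 1L], tp[i])))
  }
  unique(pairs)
}

#' Enumerate the reported pairwise comparisons of a factorial time course
#'
#' For every (cell type, differentiation) series: each later time point
#' against the series' own baseline, plus consecutive time points. The
#' canonical comparison naming is `CELL.DIFF.t<num>_vs_t<den>`.
#'
#' @param cell_types,differentiations factor labels.
#' @param time_points numeric time points (the smallest is the baseline).
#' @return data frame: comparison_id, cell_type, differentiation,
#'   time_num, time_den.
#' @export
comparison_table <- function(cell_types, differentiations, time_points) {
  pairs <- comparison_pairs(time_points)
  grid <- expand.grid(cell = cell_types, diff = differentiations,
                      pair = seq_along(pairs), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    p <- pairs[[grid$pair[i]]]
    data.frame(comparison_id = comparison_id(grid$cell[i], grid$diff[i], p[1], p[2]),
               cell_type = grid$cell[i], differentiation = grid$diff[i],
               time_num = p[1], time_den = p[2], stringsAsFactors = FALSE)
  }))
  out[order(out$cell_type, out$differentiation, out$time_num, out$time_den), ,
      drop = FALSE]
}
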