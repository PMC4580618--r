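#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ hypergeometric: drawing `n` genes from a background of
#' `N` of which `K` belong to the term. Computed in log space via the
#' stable distribution-function routine.
#'
#' @param k observed overlap.
#' @param n gene-list size.
#' @param K term size in the background.
#' @param N background size.
#' @return upper-tail probability.
#' @export
hypergeom_upper <- function(k, n, K, N) {
  bad <- k > pmin(n, K) | n > N | K > N | k < 0 | n < 0 | K < 0 | N < 1
  if (any(bad))
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N",
         call. = FALSE)
  ifelse(k <= 0, 1,
         exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                           log.p = TRUE)))
}

#' EASE score
#'
#' Conservative (jackknifed) variant of the one-sided Fisher/hypergeometric
#' test: one gene is removed from the overlap before testing, so
#' `ease_score(k, ...) = hypergeom_upper(k - 1, ...)` and a single-gene
#' overlap is never significant.
#'
#' @inheritParams hypergeom_upper
#' @return upper-tail probability of the jackknifed overlap.
#' @export
ease_score <- function(k, n, K, N) {
  hypergeom_upper(pmax(k - 1, 0), n, K, N)
}

#' Over-representation analysis of a gene list
#'
#' Tests each annotation term for over-representation in `gene_list`
#' against the annotated-platform background, with BH correction across
#' the tested terms. Both the standard hypergeometric p and the
#' conservative EASE score are reported; `method` selects which feeds the
#' FDR column and the report flag.
#'
#' @param gene_list character vector of genes (must lie in `background`).
#' @param background character vector: the annotated platform.
#' @param db an [annotation_db].
#' @param method `"standard"` or `"ease"`.
#' @param alpha_report threshold on the FDR for the `flagged` column
#'   (default 0.10).
#' @return data frame of class `enrichment_result`: term_id, name,
#'   category, k, n, K, N, p_raw, p_ease, fdr, flagged.
#' @export
enrich <- function(gene_list, background, db,
                   method = c("standard", "ease"), alpha_report = 0.10) {
  method <- match.arg(method)
  stopifnot(inherits(db, "annotation_db"))
  gene_list <- unique(gene_list)
  background <- unique(background)
  stray <- setdiff(gene_list, background)
  if (length(stray) > 0L)
    stop("gene list contains genes absent from the background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  ## background = annotated platform: restrict to genes carrying annotation
  annotated <- intersect(background, unique(unlist(db$gene_sets)))
  gene_list <- intersect(gene_list, annotated)
  N <- length(annotated)
  n <- length(gene_list)
  if (n == 0L) warning("empty gene list after restriction to the annotated background")

  sets <- lapply(db$gene_sets, intersect, annotated)
  K <- lengths(sets)
  keep <- K > 0L
  k <- vapply(sets[keep], function(g) length(intersect(g, gene_list)), 0L)
  p_raw <- hypergeom_upper(k, n, K[keep], N)
  p_ease <- ease_score(k, n, K[keep], N)
  p_sel <- if (method == "ease") p_ease else p_raw
  out <- data.frame(term_id = db$terms$term_id[keep],
                    name = db$terms$name[keep],
                    category = db$terms$category[keep],
                    k = k, n = n, K = K[keep], N = N,
                    p_raw = p_raw, p_ease = p_ease,
                    fdr = bh_adjust(p_sel), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$flagged <- out$fdr <= alpha_report
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment of up- and down-regulated lists per comparison
#'
#' Splits differential-expression calls into up- and down-regulated gene
#' lists per comparison and runs [enrich()] on each, mirroring chart-style
#' over-representation of separate direction lists.
#'
#' @param deg a [call_deg()] result.
#' @param background annotated-platform gene set.
#' @param db an [annotation_db].
#' @inheritParams enrich
#' @return named list (comparison) of lists with `up` and `down`
#'   enrichment tables.
#' @export
enrich_deg_lists <- function(deg, background, db,
                             method = c("standard", "ease"),
                             alpha_report = 0.10) {
  method <- match.arg(method)
  lapply(split(as.data.frame(deg), deg$comparison_id), function(s) {
    up <- intersect(s$gene_id[s$is_deg & s$log2fc > 0], background)
    dn <- intersect(s$gene_id[s$is_deg & s$log2fc < 0], background)
    list(up = enrich(up, background, db, method, alpha_report),
         down = enrich(dn, background, db, method, alpha_report))
  })
}
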