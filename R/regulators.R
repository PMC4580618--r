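#' Significance of regulator-target overlap with a gene list
#'
#' Hypergeometric upper-tail probability that at least the observed number
#' of a regulator's targets fall in the differential (or cluster) gene
#' list, given the background. Delegates to [hypergeom_upper()], the single
#' source of truth for over-representation probabilities in this package.
#'
#' @param targets the regulator's target genes.
#' @param deg_set the differential / cluster gene list (subset of
#'   `background`).
#' @param background the annotated platform background.
#' @return the overlap p-value.
#' @export
overlap_pvalue <- function(targets, deg_set, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  targets <- intersect(unique(targets), background)
  deg_set <- intersect(unique(deg_set), background)
  hypergeom_upper(length(intersect(targets, deg_set)),
                  length(deg_set), length(targets), length(background))
}

#' Activation z-score for one regulator
#'
#' Scores the directional consistency between a regulator's signed edges
#' and the observed direction of its differential targets under the
#' activation hypothesis: an edge is consistent when
#' `edge sign x target direction = +1`. The z-score is
#' `(n_consistent - n_inconsistent) / sqrt(n_consistent + n_inconsistent)`;
#' `z >= 2` predicts an activated regulator, `z <= -2` an inhibited one.
#' Sign-unknown edges are excluded from the score but counted.
#'
#' @param edges data frame of the regulator's edges (`target_gene_id`,
#'   `sign`).
#' @param deg_directions named numeric vector: sign of log2 fold change for
#'   each differential gene.
#' @return list with `z`, `n_consistent`, `n_inconsistent`, `n_unknown`,
#'   `predicted_state` (`"activated"`, `"inhibited"` or `"undetermined"`).
#' @export
activation_zscore <- function(edges, deg_directions) {
  check_columns(edges, c("target_gene_id", "sign"), "edge table")
  hit <- edges$target_gene_id %in% names(deg_directions)
  e <- edges[hit, , drop = FALSE]
  dirs <- sign(deg_directions[e$target_gene_id])
  usable <- e$sign != 0 & dirs != 0
  n_unknown <- sum(!usable)
  prod <- e$sign[usable] * dirs[usable]
  n_con <- sum(prod > 0)
  n_inc <- sum(prod < 0)
  if (n_con + n_inc == 0L)
    return(list(z = NA_real_, n_consistent = 0L, n_inconsistent = 0L,
                n_unknown = n_unknown, predicted_state = "undetermined"))
  z <- (n_con - n_inc) / sqrt(n_con + n_inc)
  state <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else "undetermined"
  list(z = z, n_consistent = n_con, n_inconsistent = n_inc,
       n_unknown = n_unknown, predicted_state = state)
}

#' Score all upstream regulators against a differential gene set
#'
#' For every regulator in the edge list: overlap p-value of its targets
#' with the differential genes, and the activation z-score from the signed
#' edges and observed fold-change directions. Regulators with no targets
#' in the background are skipped (logged in an attribute).
#'
#' @param edges regulator edge list (`regulator_id`, `target_gene_id`,
#'   `sign`).
#' @param deg_set differential gene ids.
#' @param deg_directions named vector of fold-change signs for `deg_set`
#'   (e.g. `sign(log2fc)` of the comparison of interest).
#' @param background annotated platform background.
#' @return data frame of class `regulator_result`: regulator_id,
#'   n_targets_in_background, n_targets_deg, overlap_p, n_consistent,
#'   n_inconsistent, z, predicted_state.
#' @export
score_regulators <- function(edges, deg_set, deg_directions, background) {
  check_columns(edges, c("regulator_id", "target_gene_id", "sign"),
                "regulator edge list")
  background <- unique(background)
  deg_set <- intersect(unique(deg_set), background)
  deg_directions <- deg_directions[intersect(names(deg_directions), deg_set)]
  skipped <- character(0)
  rows <- lapply(split(edges, edges$regulator_id), function(e) {
    reg <- e$regulator_id[1]
    in_bg <- e[e$target_gene_id %in% background, , drop = FALSE]
    if (nrow(in_bg) == 0L) { skipped <<- c(skipped, reg); return(NULL) }
    zz <- activation_zscore(in_bg, deg_directions)
    data.frame(regulator_id = reg,
               n_targets_in_background = nrow(in_bg),
               n_targets_deg = length(intersect(in_bg$target_gene_id, deg_set)),
               overlap_p = overlap_pvalue(in_bg$target_gene_id, deg_set,
                                          background),
               n_consistent = zz$n_consistent,
               n_inconsistent = zz$n_inconsistent,
               z = zz$z, predicted_state = zz$predicted_state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("regulator_result", "data.frame"))
}

#' Trim a cluster network to well-connected regulators
#'
#' Keeps only the regulators with at least `min_downstream` targets among
#' the genes of the cluster, the rule used when growing upstream
#' transcription factors onto a cluster network.
#'
#' @param edges regulator edge list.
#' @param cluster_genes genes in the cluster.
#' @param min_downstream minimum in-cluster targets (default 4; a
#'   configurable threshold also supports summaries at other cutoffs).
#' @return data frame: regulator_id, n_downstream, retained; the kept
#'   regulators' in-cluster targets in the `downstream` attribute.
#' @export
trim_cluster_network <- function(edges, cluster_genes, min_downstream = 4L) {
  check_columns(edges, c("regulator_id", "target_gene_id"), "regulator edge list")
  if (length(cluster_genes) == 0L) stop("cluster_genes is empty", call. = FALSE)
  by_reg <- split(edges$target_gene_id, edges$regulator_id)
  downstream <- lapply(by_reg, intersect, cluster_genes)
  out <- data.frame(regulator_id = names(by_reg),
                    n_downstream = lengths(downstream),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$retained <- out$n_downstream >= min_downstream
  out <- out[order(-out$n_downstream), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "downstream") <- downstream[out$regulator_id[out$retained]]
  out
}
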