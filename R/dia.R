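#' Filter annotation terms by platform coverage
#'
#' Keeps terms whose platform coverage (platform genes / genome-wide genes
#' annotated to the term) reaches `min_coverage`; the 30\% default boundary
#' is inclusive. In GO mode (`apply_min_genes = TRUE`) terms represented by
#' a single platform gene are additionally removed.
#'
#' @param db an [annotation_db].
#' @param platform character vector of gene ids present on the array.
#' @param min_coverage minimum platform/genome coverage (default 0.30).
#' @param min_platform_genes minimum platform genes when `apply_min_genes`
#'   (default 2, i.e. single-gene terms are dropped).
#' @param apply_min_genes apply the single-gene term filter (GO mode).
#' @return the filtered [annotation_db], gene sets intersected with the
#'   platform; dropped terms with reasons in the `removal_log` attribute.
#' @export
coverage_filter <- function(db, platform, min_coverage = 0.30,
                            min_platform_genes = 2L, apply_min_genes = FALSE) {
  stopifnot(inherits(db, "annotation_db"))
  if (length(platform) == 0L) stop("platform gene set is empty", call. = FALSE)
  on_platform <- lapply(db$gene_sets, intersect, platform)
  n_platform <- lengths(on_platform)
  coverage <- pmin(1, n_platform / db$terms$genome_gene_count)
  keep <- coverage >= min_coverage & n_platform > 0L
  reason <- ifelse(n_platform == 0L, "no platform genes",
                   ifelse(coverage < min_coverage, "coverage below cutoff", ""))
  if (apply_min_genes) {
    few <- n_platform < min_platform_genes
    reason[keep & few] <- "fewer platform genes than minimum"
    keep <- keep & !few
  }
  log <- data.frame(term_id = db$terms$term_id, n_platform = n_platform,
                    coverage = coverage, kept = keep, reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- annotation_db(db$terms[keep, , drop = FALSE], on_platform[keep])
  attr(out, "removal_log") <- log
  attr(out, "perturbed") <- attr(db, "perturbed")
  out
}

#' Impact and direction of impact for one term in one comparison
#'
#' Combines, separately for up- and down-regulated differential genes of
#' the term, the proportion of differential genes, their mean absolute log2
#' fold change and their mean significance:
#' `impact_dir = (|D_dir| / |G|) * mean(|log2fc|) * mean(min(-log10 p, sig_cap))`,
#' with `G` the term's platform genes having results and `D_dir` its
#' up/down differential genes in the comparison. The impact is the sum of
#' the two directional components and the signed direction of impact their
#' difference, so a term's impact always bounds the magnitude of its
#' direction.
#'
#' @param term_genes character vector of the term's platform genes.
#' @param deg a [call_deg()] result (the fold-change cutoff is not used for
#'   impact scoring).
#' @param comparison_id which comparison to score.
#' @param sig_cap cap on -log10 post-hoc p (default 10), bounding the
#'   influence of underflowing p-values.
#' @return one-row data frame with impact, direction and component counts;
#'   NULL when no term gene has a result in the comparison.
#' @export
term_impact <- function(term_genes, deg, comparison_id, sig_cap = 10) {
  s <- deg[deg$comparison_id == comparison_id &
             deg$gene_id %in% term_genes &
             !is.na(deg$log2fc) & !is.na(deg$posthoc_p), , drop = FALSE]
  if (nrow(s) == 0L) return(NULL)
  n_g <- nrow(s)
  up <- s$is_deg & s$log2fc > 0
  dn <- s$is_deg & s$log2fc < 0
  comp <- function(sel) {
    if (!any(sel)) return(c(0, 0, 0, 0))
    mfc <- mean(abs(s$log2fc[sel]))
    msig <- mean(pmin(-log10(s$posthoc_p[sel]), sig_cap))
    c((sum(sel) / n_g) * mfc * msig, sum(sel), mfc, msig)
  }
  u <- comp(up); d <- comp(dn)
  data.frame(comparison_id = comparison_id,
             impact = u[1] + d[1], direction = u[1] - d[1],
             n_genes = n_g, n_deg = sum(up | dn),
             n_up = u[2], n_down = d[2],
             mean_absfc_up = u[3], mean_absfc_down = d[3],
             mean_sig_up = u[4], mean_sig_down = d[4],
             stringsAsFactors = FALSE)
}

#' Score every term in every comparison
#'
#' Applies [term_impact()] across an annotation database and all
#' comparisons present in the differential-expression calls. Terms with no
#' scored genes in a comparison are skipped and logged.
#'
#' @param db a (coverage-filtered) [annotation_db].
#' @param deg a [call_deg()] result.
#' @param sig_cap see [term_impact()].
#' @return object of class `term_impacts`: long data frame (term_id,
#'   comparison_id, impact, direction, components) with the term metadata
#'   and comparison definitions attached as attributes.
#' @export
dia_impact <- function(db, deg, sig_cap = 10) {
  stopifnot(inherits(db, "annotation_db"))
  comparisons <- unique(deg$comparison_id)
  deg_by_cmp <- split(as.data.frame(deg), deg$comparison_id)
  skipped <- character(0)
  rows <- vector("list", nrow(db$terms) * length(comparisons))
  n <- 0L
  for (t in db$terms$term_id) {
    genes <- db$gene_sets[[t]]
    for (cmp in comparisons) {
      r <- term_impact(genes, deg_by_cmp[[cmp]], cmp, sig_cap)
      if (is.null(r)) { skipped <- c(skipped, paste(t, cmp)); next }
      n <- n + 1L
      rows[[n]] <- cbind(term_id = t, r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(n)])
  structure(out, terms = db$terms, skipped = skipped,
            class = c("term_impacts", "data.frame"))
}

#' Roll impact scores up to subcategory or category level
#'
#' Group value per comparison is the unweighted mean of member-term impacts
#' and directions, so a single-member group equals its member.
#'
#' @param impacts a `term_impacts` from [dia_impact()].
#' @param db the matching [annotation_db].
#' @param level `"subcategory"` or `"category"`.
#' @return data frame: group, comparison_id, n_terms, impact, direction.
#' @export
dia_rollup <- function(impacts, db, level = c("subcategory", "category")) {
  level <- match.arg(level)
  grp <- db$terms[[level]][match(impacts$term_id, db$terms$term_id)]
  if (anyNA(grp))
    stop("impacts contain terms absent from the annotation", call. = FALSE)
  key <- interaction(grp, impacts$comparison_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(impacts)), key), function(i) {
    data.frame(group = grp[i[1]], comparison_id = impacts$comparison_id[i[1]],
               n_terms = length(i), impact = mean(impacts$impact[i]),
               direction = mean(impacts$direction[i]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$comparison_id), , drop = FALSE]
}

#' Time-summed impact and direction-of-impact contrasts
#'
#' For each term, sums impact and direction of impact (DoI) over the
#' time-course of each (cell type, differentiation) series, using the
#' comparisons of each time point against the series' own time 0. The
#' contrast columns subtract, per cell type, the osteogenic from the
#' adipogenic summed DoI (second differentiation from the first), and, per
#' differentiation, the BMSC from the ASC summed DoI (second cell type from
#' the first), flagging the terms most different between differentiations
#' or between cell types.
#'
#' @param impacts a `term_impacts` from [dia_impact()].
#' @param comparisons comparison definition table (as in a
#'   `contrast_results`); reconstructed from the comparison ids if omitted.
#' @return data frame, one row per term: per-series `impact_sum.*` and
#'   `doi_sum.*`, per-cell differentiation contrasts, per-differentiation
#'   cell contrasts, and `total_impact` (sum over all series).
#' @export
dia_doi_summaries <- function(impacts, comparisons = NULL) {
  if (is.null(comparisons)) comparisons <- parse_comparisons(impacts$comparison_id)
  cmp <- comparisons
  tp0 <- min(cmp$time_den)
  vs0 <- cmp[cmp$time_den == tp0, , drop = FALSE]
  cells <- sort(unique(cmp$cell_type))
  diffs <- sort(unique(cmp$differentiation))
  terms <- unique(impacts$term_id)

  ## every term must have all vs-0 comparisons scored
  have <- split(impacts$comparison_id, impacts$term_id)
  missing <- unlist(lapply(terms, function(t) {
    m <- setdiff(vs0$comparison_id, have[[t]])
    if (length(m)) paste(t, m) else character(0)
  }))
  if (length(missing) > 0L)
    stop("unmatched comparisons for DoI summaries: ",
         paste(utils::head(missing, 10), collapse = "; "), call. = FALSE)

  sum_of <- function(t, cl, df, what) {
    ids <- vs0$comparison_id[vs0$cell_type == cl & vs0$differentiation == df]
    sum(impacts[[what]][impacts$term_id == t & impacts$comparison_id %in% ids])
  }
  out <- data.frame(term_id = terms, stringsAsFactors = FALSE)
  for (cl in cells) for (df in diffs) {
    s <- series_label(cl, df)
    out[[paste0("impact_sum.", s)]] <-
      vapply(terms, sum_of, 0, cl = cl, df = df, what = "impact")
    out[[paste0("doi_sum.", s)]] <-
      vapply(terms, sum_of, 0, cl = cl, df = df, what = "direction")
  }
  if (length(diffs) >= 2L) for (cl in cells) {
    out[[sprintf("doi_%s_minus_%s.%s", diffs[1], diffs[2], cl)]] <-
      out[[paste0("doi_sum.", series_label(cl, diffs[1]))]] -
      out[[paste0("doi_sum.", series_label(cl, diffs[2]))]]
  }
  if (length(cells) >= 2L) for (df in diffs) {
    out[[sprintf("doi_%s_minus_%s.%s", cells[1], cells[2], df)]] <-
      out[[paste0("doi_sum.", series_label(cells[1], df))]] -
      out[[paste0("doi_sum.", series_label(cells[2], df))]]
  }
  out$total_impact <- rowSums(out[, grep("^impact_sum\\.", names(out)),
                                  drop = FALSE])
  out[order(-out$total_impact), , drop = FALSE]
}

## Recover (cell, differentiation, time pair) from canonical comparison ids
parse_comparisons <- function(ids) {
  ids <- unique(ids)
  m <- regmatches(ids, regexec("^([^.]+)\\.([^.]+)\\.t([0-9.]+)_vs_t([0-9.]+)$", ids))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("cannot parse comparison id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  data.frame(comparison_id = ids,
             cell_type = vapply(m, `[`, "", 2),
             differentiation = vapply(m, `[`, "", 3),
             time_num = as.numeric(vapply(m, `[`, "", 4)),
             time_den = as.numeric(vapply(m, `[`, "", 5)),
             stringsAsFactors = FALSE)
}

#' Full per-term DIA output table
#'
#' Wide layout mirroring the package's TSV export: term metadata, per
#' comparison impact and direction, then the time-summed series and
#' contrast columns, sorted descending by total impact.
#'
#' @param impacts a `term_impacts`.
#' @param db the matching [annotation_db].
#' @return data frame.
#' @export
dia_table <- function(impacts, db) {
  summaries <- dia_doi_summaries(impacts)
  meta <- db$terms[match(summaries$term_id, db$terms$term_id),
                   c("term_id", "name", "category", "subcategory")]
  wide <- meta
  for (cmp in sort(unique(impacts$comparison_id))) {
    s <- impacts[impacts$comparison_id == cmp, ]
    i <- match(wide$term_id, s$term_id)
    wide[[paste0(cmp, ".impact")]] <- s$impact[i]
    wide[[paste0(cmp, ".direction")]] <- s$direction[i]
  }
  cbind(wide, summaries[, -1, drop = FALSE], row.names = NULL)
}
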