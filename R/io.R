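#' Term-to-gene annotation database
#'
#' Container for gene-set annotation with category metadata and genome-wide
#' term sizes, as used by the impact-scoring and enrichment stages.
#'
#' @param terms data frame with columns `term_id`, `name`, `category`,
#'   `subcategory`, `genome_gene_count`.
#' @param gene_sets named list (by `term_id`) of character vectors of gene
#'   ids present on the platform.
#' @return object of class `annotation_db`.
#' @export
annotation_db <- function(terms, gene_sets) {
  check_columns(terms, c("term_id", "name", "category", "subcategory",
                         "genome_gene_count"), "annotation terms")
  if (anyDuplicated(terms$term_id))
    stop("duplicate term_id in annotation: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "),
         call. = FALSE)
  if (!setequal(names(gene_sets), terms$term_id))
    stop("gene_sets names must match terms$term_id", call. = FALSE)
  if (any(terms$genome_gene_count < 1))
    stop("genome_gene_count must be >= 1 for every term", call. = FALSE)
  structure(list(terms = terms, gene_sets = gene_sets[terms$term_id]),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  sizes <- lengths(x$gene_sets)
  cat(sprintf("annotation_db: %d terms, %d categories, platform term sizes %d-%d\n",
              nrow(x$terms), length(unique(x$terms$category)),
              min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.annotation_db <- function(x) nrow(x$terms)

#' Read a GMT annotation file
#'
#' Parses the GMT dialect used throughout the package: one term per line,
#' `term_id <TAB> category|subcategory|genome_gene_count <TAB> gene ids...`.
#'
#' @param path GMT file path.
#' @return an [annotation_db].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(annotation_db(data.frame(term_id = character(0), name = character(0),
                                    category = character(0), subcategory = character(0),
                                    genome_gene_count = integer(0)),
                         stats::setNames(list(), character(0))))
  parse_line <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i), call. = FALSE)
    meta <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    if (length(meta) != 3L || is.na(suppressWarnings(as.integer(meta[3]))))
      stop(sprintf("malformed GMT line %d: description must be 'category|subcategory|genome_gene_count'", i),
           call. = FALSE)
    list(term_id = f[1], category = meta[1], subcategory = meta[2],
         genome_gene_count = as.integer(meta[3]), genes = f[-(1:2)])
  }
  parsed <- lapply(seq_along(lines), parse_line)
  terms <- data.frame(term_id = vapply(parsed, `[[`, "", "term_id"),
                      name = vapply(parsed, `[[`, "", "term_id"),
                      category = vapply(parsed, `[[`, "", "category"),
                      subcategory = vapply(parsed, `[[`, "", "subcategory"),
                      genome_gene_count = vapply(parsed, `[[`, 0L, "genome_gene_count"),
                      stringsAsFactors = FALSE)
  gene_sets <- lapply(parsed, `[[`, "genes")
  names(gene_sets) <- terms$term_id
  annotation_db(terms, gene_sets)
}

#' Write an annotation database as GMT
#' @param db an [annotation_db].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  lines <- vapply(seq_len(nrow(db$terms)), function(i) {
    t <- db$terms[i, ]
    paste(c(t$term_id,
            paste(t$category, t$subcategory, t$genome_gene_count, sep = "|"),
            db$gene_sets[[t$term_id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

spot_columns <- c("spot_id", "gene_id", "array_id", "block_dup_index",
                  "ch1_fg_median", "ch1_bg_median", "ch2_fg_median",
                  "ch2_bg_median", "bg_sd", "flag")

#' Read a spot-level measurement table (TSV)
#' @param path TSV path with the exact spot-table header.
#' @return data frame of spot measurements.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, spot_columns, "spot table")
  df
}

#' Read a sample design table (TSV)
#' @param path TSV path with columns sample_id, array_id, pig, cell_type,
#'   differentiation, time_dd.
#' @return data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("sample_id", "array_id", "pig", "cell_type",
                      "differentiation", "time_dd"), "design table")
  df
}

#' Read a signed regulator-to-target edge list (TSV)
#' @param path TSV path with columns regulator_id, target_gene_id, sign.
#' @return data frame; `sign` is +1 (activating expression), -1
#'   (repressing) or 0 (unknown).
#' @export
read_regulator_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("regulator_id", "target_gene_id", "sign"),
                "regulator edge list")
  if (!all(df$sign %in% c(-1L, 0L, 1L)))
    stop("regulator edge sign must be -1, 0 or +1", call. = FALSE)
  if (anyDuplicated(df[, c("regulator_id", "target_gene_id")]))
    stop("duplicate (regulator, target) pairs in edge list", call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write synthetic-experiment fixtures to disk
#'
#' Writes the spot table, sample design and regulator edge list as TSV and
#' the annotation as GMT, in the dialects the package readers consume; the
#' files round-trip losslessly through [read_spot_table()], [read_design()],
#' [read_regulator_edges()] and [read_gmt()].
#'
#' @param experiment a [generate_experiment()] result.
#' @param directory output directory (created if absent).
#' @param annotation optional [annotation_db] to write alongside.
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(experiment, directory, annotation = NULL) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- c(spots = file.path(directory, "spots.tsv"),
             design = file.path(directory, "design.tsv"),
             regulator_edges = file.path(directory, "regulator_edges.tsv"))
  write_tsv(experiment$spots, paths[["spots"]])
  write_tsv(experiment$design, paths[["design"]])
  write_tsv(experiment$regulator_edges, paths[["regulator_edges"]])
  if (!is.null(annotation)) {
    paths <- c(paths, annotation = file.path(directory, "annotation.gmt"))
    write_gmt(annotation, paths[["annotation"]])
  }
  paths
}
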