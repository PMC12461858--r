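#' Staged expression matrix
#'
#' Container for a genes-by-samples matrix of log2-scale expression values
#' together with an ordered temporal-stage label per sample. Stages are
#' 1-based contiguous integers `1..T`; all downstream "stage t" indexing uses
#' this convention. Rows are sorted by gene symbol and columns by
#' (stage, sample id) so loading is insensitive to input order.
#'
#' @param values numeric matrix, genes x samples, with unique rownames (gene
#'   symbols) and colnames (sample ids).
#' @param stage_of named integer vector mapping every sample id to its stage.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the reordered matrix), `gene_ids`, `sample_ids`, `stage_of` (named
#'   integer vector aligned with columns) and `n_stages`.
#' @export
expr_matrix <- function(values, stage_of) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs gene rownames and sample colnames")
  }
  rownames(values) <- normalize_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids in `values`")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids in `values`")
  if (anyNA(values)) abort("missing values in expression matrix")
  missing_stage <- setdiff(colnames(values), names(stage_of))
  if (length(missing_stage) > 0) {
    abort(paste0("missing stage for sample(s): ",
                 paste(head(missing_stage, 5), collapse = ", ")))
  }
  stage_of <- stage_of[colnames(values)]
  st <- as.integer(stage_of)
  if (anyNA(st)) abort("non-integer stage labels")
  stages <- sort(unique(st))
  if (!identical(stages, seq_len(max(st))) || max(st) < 2) {
    abort(sprintf("non-contiguous stages: observed {%s}; need contiguous 1..T with T >= 2",
                  paste(stages, collapse = ",")))
  }
  # canonical order: genes sorted; samples by (stage, sample id)
  values <- values[order(rownames(values)), , drop = FALSE]
  ord <- order(st, colnames(values))
  values <- values[, ord, drop = FALSE]
  st <- st[ord]
  names(st) <- colnames(values)
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), stage_of = st,
         n_stages = max(st)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %d stages (%s)\n",
              length(x$gene_ids), length(x$sample_ids), x$n_stages,
              paste(tabulate(x$stage_of), collapse = "/")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Samples belonging to one temporal stage
#'
#' @param expr an [expr_matrix].
#' @param stage stage ordinal in `1..T`.
#' @return The genes x samples submatrix for that stage.
#' @export
stage_values <- function(expr, stage) {
  stopifnot(inherits(expr, "expr_matrix"))
  stage <- as.integer(stage)
  if (stage < 1 || stage > expr$n_stages) abort("stage out of range")
  expr$values[, expr$stage_of == stage, drop = FALSE]
}

#' Read a staged expression table
#'
#' Reads a delimited genes-by-samples table (first column gene symbols,
#' header row of sample ids) plus a two-column sample-to-stage map, validates
#' both, and returns an [expr_matrix]. Gene symbols are uppercased and
#' whitespace-stripped. Duplicate gene rows are collapsed according to
#' `dup_policy`; the number collapsed is reported.
#'
#' @param path_values path to the TSV expression table (log2-scale values).
#' @param path_stage_map path to a two-column TSV (`sample_id`, `stage`),
#'   with or without a header.
#' @param dup_policy how to collapse duplicated gene rows: `"variance"`
#'   (default; keep the highest-variance row), `"first"`, or `"mean"`.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path_values, path_stage_map,
                            dup_policy = c("variance", "first", "mean")) {
  dup_policy <- match.arg(dup_policy)
  raw <- readr::read_tsv(path_values, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort("expression table needs a gene column plus >= 1 sample")
  genes <- normalize_symbols(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(NULL, colnames(mat))))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell at gene row %d ('%s'), sample column '%s'",
                  bad[1, 1], genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf("missing value at gene row %d ('%s'), sample column '%s'",
                  bad[1, 1], genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    keep <- switch(dup_policy,
      first = !duplicated(genes),
      variance = {
        v <- apply(num, 1, var)
        # within each duplicated symbol keep the highest-variance row
        ord <- order(genes, -v)
        keep_sorted <- !duplicated(genes[ord])
        keep <- logical(length(genes)); keep[ord] <- keep_sorted; keep
      },
      mean = NULL
    )
    if (dup_policy == "mean") {
      num <- rowsum(num, group = genes) / as.vector(table(genes)[sort(unique(genes))])
      genes <- rownames(num)
    } else {
      num <- num[keep, , drop = FALSE]
      genes <- genes[keep]
    }
    dnb_log("collapsed %d duplicate gene row(s) by policy '%s'", n_dup, dup_policy)
  }
  rownames(num) <- genes

  sm <- readr::read_tsv(path_stage_map, col_types = readr::cols(.default = "c"),
                        col_names = FALSE, progress = FALSE, show_col_types = FALSE)
  if (ncol(sm) < 2) abort("stage map needs two columns: sample_id, stage")
  # tolerate a header line
  if (suppressWarnings(is.na(as.integer(sm[[2]][1]))) && nrow(sm) > 1) {
    sm <- sm[-1, , drop = FALSE]
  }
  st <- suppressWarnings(as.integer(sm[[2]]))
  if (anyNA(st)) abort(sprintf("non-integer stage label at stage-map line %d",
                               which(is.na(st))[1]))
  stage_of <- setNames(st, sm[[1]])
  expr_matrix(num, stage_of)
}

#' Write an expression matrix and its stage map as TSV
#'
#' Inverse of [read_expression()]; used by the simulator and the pipeline to
#' serialize intermediate artifacts.
#'
#' @param expr an [expr_matrix].
#' @param path_values,path_stage_map output paths.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, path_values, path_stage_map) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- tibble(gene = expr$gene_ids)
  df <- dplyr::bind_cols(df, as_tibble(expr$values, .name_repair = "minimal"))
  readr::write_tsv(df, path_values, progress = FALSE)
  readr::write_tsv(tibble(sample_id = expr$sample_ids,
                          stage = unname(expr$stage_of)),
                   path_stage_map, progress = FALSE)
  invisible(expr)
}
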