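#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a biomarker result
#'
#' @param x a `dnb_result`.
#' @param ... unused.
#' @return Tibble with one row per gene: `gene`, `role`, `degree` (in the
#'   result subnetwork).
#' @export
tidy.dnb_result <- function(x, ...) {
  deg <- igraph::degree(x$subnetwork)
  tibble(gene = x$genes, role = unname(x$roles[x$genes]),
         degree = unname(deg[x$genes]))
}

#' @rdname tidy.dnb_result
#' @return For `glance()`: a one-row tibble of result-level counts.
#' @export
glance.dnb_result <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_edges = nrow(x$edges),
         n_dominators = length(x$dominators),
         n_connectors = length(x$connectors),
         connected = x$connected, n_components = x$n_components)
}

#' Tidy a DNI curve
#'
#' @param x a `dnb_dni`.
#' @param ... unused.
#' @return The per-stage tibble (`stage`, `g_alpha`, `d_alpha`, `d_union`,
#'   `ce`, `dni`).
#' @export
tidy.dnb_dni <- function(x, ...) as_tibble(x)

#' @rdname tidy.dnb_dni
#' @export
glance.dnb_dni <- function(x, ...) {
  tibble(peak_stage = peak_stage(x), peak_dni = max(x$dni),
         n_stages = nrow(x), module_size = length(attr(x, "module")))
}

#' Tidy a temporal classification report
#'
#' @param x a `dnb_classification`.
#' @param ... unused.
#' @return Per-split metric tibble.
#' @export
tidy.dnb_classification <- function(x, ...) x$per_split

#' @rdname tidy.dnb_classification
#' @return For `glance()`: one row with `<metric>_mean` / `<metric>_sd`
#'   columns.
#' @export
glance.dnb_classification <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_longer(c("mean", "sd"), names_to = "stat") |>
    dplyr::mutate(name = paste0(.data$metric, "_", .data$stat)) |>
    dplyr::select("name", "value") |>
    tidyr::pivot_wider()
  dplyr::bind_cols(tibble(n_splits = nrow(x$per_split),
                          n_features = length(x$features)), wide)
}

#' Tidy an anomaly gene set
#'
#' @param x a `dnb_anomalies`.
#' @param ... unused.
#' @return Tibble `gene`, `stage`, `score`, `hit` (whether the gene is in
#'   that stage's top fraction).
#' @export
tidy.dnb_anomalies <- function(x, ...) {
  hits <- dplyr::bind_rows(lapply(names(x$per_stage), function(s) {
    tibble(gene = x$per_stage[[s]], stage = as.integer(s), hit = TRUE)
  }))
  x$scores |>
    dplyr::left_join(hits, by = c("gene", "stage")) |>
    dplyr::mutate(hit = !is.na(.data$hit)) |>
    dplyr::arrange(.data$stage, dplyr::desc(.data$score))
}
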