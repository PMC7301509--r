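#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a MeSH dataset into one row per term
#'
#' @param x A [mesh_dataset].
#' @param ... Unused.
#' @return The [mesh_terms()] tibble with multi-valued columns flattened to
#'   `"|"`-joined strings.
#' @export
tidy.mesh_dataset <- function(x, ...) {
  tt <- mesh_terms(x)
  for (col in c("tree_numbers", "categories", "semantic_types", "cuis")) {
    tt[[col]] <- join_multi(tt[[col]])
  }
  tt
}

#' @rdname tidy.mesh_dataset
#' @return `glance()`: a one-row tibble with table sizes and `n_total`.
#' @export
glance.mesh_dataset <- function(x, ...) {
  tibble::tibble(
    n_main_headings = nrow(x$main_headings),
    n_scrs = nrow(x$scrs),
    n_concepts = length(x$concept_map),
    n_parent_child = nrow(x$parent_child),
    n_categories = length(unique(substr(names(x$tn_owner), 1, 1))),
    n_total = x$manifest$n_total %||% NA_real_
  )
}

#' Tidy an information-content table
#'
#' @param x A `mesh_ic_table` from [build_ic_table()].
#' @param ... Unused.
#' @return A plain tibble with columns `ui`, `rollup`, `ic`, `p` (the
#'   occurrence probability `10^-ic`).
#' @export
tidy.mesh_ic_table <- function(x, ...) {
  tibble::tibble(ui = x$ui, rollup = x$rollup, ic = x$ic, p = 10^(-x$ic))
}

#' @rdname tidy.mesh_ic_table
#' @return `glance()`: one row with `n_terms`, `n_total`, `log_base` and
#'   the IC range.
#' @export
glance.mesh_ic_table <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x), n_total = attr(x, "n_total"),
                 log_base = attr(x, "log_base"),
                 inclusive = attr(x, "inclusive"),
                 min_ic = min(x$ic), max_ic = max(x$ic))
}
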