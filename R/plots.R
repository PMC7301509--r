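#' Plot the information-content distribution by hierarchy depth
#'
#' Each main heading is placed at the depth of its shallowest tree number;
#' IC should trend upward with depth (deeper terms are rarer, hence more
#' informative).
#'
#' @param object A `mesh_ic_table` from [build_ic_table()].
#' @param ds The [mesh_dataset] the table was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mesh_ic_table <- function(object, ds, ...) {
  depth <- vapply(object$ui, function(u) {
    min(tn_depth(term_tree_numbers(ds, u)))
  }, numeric(1))
  df <- tibble::tibble(ic = object$ic, depth = factor(depth))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$ic)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Hierarchy depth (components of shallowest tree number)",
                  y = "Information content (-log10 P)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of pairwise semantic similarities
#'
#' @param ds A [mesh_dataset].
#' @param uis Character vector of term ids to compare (all pairs).
#' @param method,ic_table,omega Passed to [mesh_similarity()].
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(ds, uis,
                                    method = c("lin", "res", "jc", "rel", "wang"),
                                    ic_table = NULL, omega = 0.6) {
  method <- match.arg(method)
  pairs <- tidyr::expand_grid(ui1 = uis, ui2 = uis)
  sims <- mesh_similarity_pairs(pairs, ds, methods = method,
                                ic_table = ic_table, omega = omega)
  ggplot2::ggplot(sims, ggplot2::aes(x = .data$ui1, y = .data$ui2,
                                     fill = .data[[method]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (method == "res") NULL else c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = method) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
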