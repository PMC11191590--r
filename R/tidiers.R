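#' Tidy a clustering solution
#'
#' @param x A `cluster_solution` from [grid_search_clustering()].
#' @param ... Unused.
#' @return One row per chemical: `cas`, `cluster`, and the embedding
#'   coordinates `dim1`, `dim2`, ...
#' @export
tidy.cluster_solution <- function(x, ...) {
  emb <- as_tibble(x$embedding, .name_repair = ~ paste0("dim", seq_along(.x)))
  bind_cols(tibble(cas = names(x$labels), cluster = unname(x$labels)), emb)
}

#' @describeIn tidy.cluster_solution One-row summary: winning parameters,
#'   `k`, `silhouette`, acceptance flag and grid size.
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(
    k = x$k, silhouette = x$silhouette, accepted = x$accepted,
    n_neighbors = x$params$n_neighbors, min_dist = x$params$min_dist,
    n_components = x$params$n_components, umap_seed = x$params$umap_seed,
    kmeans_seed = x$params$kmeans_seed,
    n_chemicals = length(x$labels), n_grid_points = nrow(x$history)
  )
}

#' Plot the embedding of a clustering solution
#'
#' Scatter of the UMAP embedding, colored by cluster.
#'
#' @param object A `cluster_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      color = "cluster",
      title = sprintf("k = %d, silhouette = %.2f%s", object$k, object$silhouette,
                      if (object$accepted) "" else " (below threshold)"),
      x = "UMAP 1", y = "UMAP 2"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of database coverage
#'
#' @param coverage Output of [coverage_summary()].
#' @return A ggplot of per-level percentages of the registry, faceted by
#'   database.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage,
                  ggplot2::aes(.data$level, .data$pct_registry)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~database, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of registry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a cluster profile
#'
#' Tile heatmap of the column-standardized ER submatrix with rows and
#' columns in dendrogram leaf order.
#'
#' @param profile One element of the [cluster_profile()] result.
#' @return A ggplot, or `NULL` (with a message) for an empty profile.
#' @export
plot_profile_heatmap <- function(profile) {
  m <- profile$scaled_matrix
  if (is.null(m) || nrow(m) == 0) {
    message("empty profile; nothing to plot")
    return(invisible(NULL))
  }
  m <- m[profile$additive_order, profile$pathway_order, drop = FALSE]
  df <- as_tibble(m, rownames = "cas") |>
    tidyr::pivot_longer(-"cas", names_to = "set_id", values_to = "z") |>
    mutate(cas = factor(.data$cas, levels = rownames(m)),
           set_id = factor(.data$set_id, levels = colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$set_id, .data$cas, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled ER",
                  title = sprintf("Cluster %s profile", profile$cluster_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1, size = 6))
}
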