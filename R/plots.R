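## Figures: per-cluster trajectory panels, MDS embeddings and the
## tree-cut sweep trace. All plots use the fourth-root age axis and the
## per-gene standardization of the analysis modules.

#' Per-cluster developmental trajectory panels
#'
#' One panel per retained cluster: the cluster-mean standardized
#' expression of every sample (points) with 3-df spline curves fitted
#' per group (lines), on the fourth-root age axis.
#'
#' @param object A `cluster_solution`.
#' @param study The [expression_study()] the clustering was computed on
#'   (control + autism samples).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_solution <- function(object, study, ...) {
  members <- cluster_members(object)
  if (!length(members)) rlang::abort("no retained clusters to plot.")
  z <- standardize_rows(study$rpkm[unlist(members), , drop = FALSE])
  x <- age_transform(study$samples$age_days)
  pts <- purrr::imap_dfr(members, function(cl, id) {
    tibble::tibble(
      cluster = sprintf("cluster %s (n = %d)", id, length(cl)),
      sample_id = study$samples$sample_id,
      group = study$samples$group,
      age_t = x,
      mean_expr = colMeans(z[cl, , drop = FALSE])
    )
  })
  curves <- pts |>
    dplyr::group_by(.data$cluster, .data$group) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_spline3df(d$mean_expr, d$age_t, transform = FALSE)
      grid <- seq(min(d$age_t), max(d$age_t), length.out = 50)
      tibble::tibble(age_t = grid, mean_expr = predict_trajectory(fit, grid))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(pts, ggplot2::aes(.data$age_t, .data$mean_expr, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curves, linewidth = 0.8) +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(
      x = expression((age + 1)^{1 / 4}),
      y = "standardized expression (cluster mean)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' MDS plot of samples on expression-correlation distance
#'
#' @param study An [expression_study()].
#' @param gene_subset Genes used for the embedding (default all).
#' @return A ggplot object; point size tracks age, colour the group.
#' @export
plot_mds <- function(study, gene_subset = NULL) {
  emb <- mds_embedding(study, gene_subset)
  ggplot2::ggplot(
    emb,
    ggplot2::aes(.data$dim1, .data$dim2,
      colour = .data$group, size = .data$age_days
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2") +
    ggplot2::theme_minimal()
}

#' Tree-cut sweep trace plot
#'
#' Cluster counts and significant-term counts across cut heights, with
#' the chosen (rank-1) height marked.
#'
#' @param trace The sweep trace tibble from
#'   [select_height_by_enrichment()] (or the `trace` attribute of a
#'   swept `cluster_solution`).
#' @return A ggplot object.
#' @export
plot_sweep_trace <- function(trace) {
  long <- tidyr::pivot_longer(
    trace[, c("height", "n_clusters", "n_significant_terms")],
    cols = -"height", names_to = "measure", values_to = "value"
  )
  chosen <- max(trace$height[trace$rank == 1])
  ggplot2::ggplot(long, ggplot2::aes(.data$height, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "tree-cut height", y = NULL) +
    ggplot2::theme_minimal()
}
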