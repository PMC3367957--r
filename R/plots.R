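#' @describeIn selectivity_profile Electivity plot: mean +/- SE per prey,
#'   faceted by predator stage (the standard presentation of multiple-choice
#'   selectivity results).
#' @param object The object to plot.
#' @method autoplot selectivity_profile
#' @export
autoplot.selectivity_profile <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$prey_id, y = .data$mean_electivity)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_electivity - .data$se_electivity,
                   ymax = .data$mean_electivity + .data$se_electivity),
      width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~predator_stage_id) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "Electivity index") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @describeIn diet_overlap Heatmap of the overlap matrix.
#' @param object The object to plot.
#' @method autoplot overlap_matrix
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  labs <- rownames(object)
  df <- tibble(
    label_i = factor(rep(labs, times = ncol(object)), levels = labs),
    label_j = factor(rep(labs, each = nrow(object)), levels = rev(labs)),
    overlap = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$label_i, .data$label_j,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("overlap\n(", attr(object, "kind"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @describeIn nmds_ordination Scatter of the first two ordination axes.
#' @param object The object to plot.
#' @method autoplot nmds_ordination
#' @export
autoplot.nmds_ordination <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::labs(x = "NMDS axis 1", y = "NMDS axis 2",
                  subtitle = paste0("stress = ", round(object$stress, 2))) +
    ggplot2::theme_bw()
}

#' @describeIn mortality_table Dot plot of per-predator mortality by prey,
#'   with the per-prey grand mean as a dashed line.
#' @param object The object to plot.
#' @method autoplot mortality_table
#' @export
autoplot.mortality_table <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$mean_mortality,
                               y = .data$predator_stage_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$mean_mortality - .data$se_mortality, 0),
                   xmax = pmin(.data$mean_mortality + .data$se_mortality, 1)),
      height = 0.2) +
    ggplot2::geom_vline(data = object$grand,
                        ggplot2::aes(xintercept = .data$grand_mean_mortality),
                        linetype = 2) +
    ggplot2::facet_wrap(~prey_id) +
    ggplot2::labs(x = "Proportion consumed", y = NULL) +
    ggplot2::theme_bw()
}

#' @describeIn find_modules Tile plot of the web with rows and columns
#'   ordered by module.
#' @param object The object to plot.
#' @param web The `bipartite_web` the partition was fitted to.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, web = NULL, ...) {
  if (is.null(web)) abort("supply the web the partition was fitted to")
  A <- unclass(web)
  ro <- names(sort(object$rows))
  co <- names(sort(object$cols))
  df <- tibble(
    predator = factor(rep(rownames(A), times = ncol(A)), levels = ro),
    prey = factor(rep(colnames(A), each = nrow(A)), levels = co),
    weight = as.vector(A),
    same_module = as.vector(outer(object$rows[rownames(A)],
                                  object$cols[colnames(A)], `==`)))
  ggplot2::ggplot(df, ggplot2::aes(.data$prey, .data$predator)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     colour = .data$same_module)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = NULL, size = "weight",
                  colour = "within module") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
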