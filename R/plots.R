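#' Heat-map figures for density maps, t-maps and significance masks
#'
#' ggplot2 rasters of a template-space matrix, with y flipped so the
#' forehead is at the top. `plot_t_map()` overlays nothing but uses a
#' diverging scale centred at zero; `plot_cluster_map()` draws the
#' significant-cluster mask (+1 / -1 / 0).
#'
#' @param map a `density_map` or plain matrix in template space.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_density_map <- function(map, title = NULL) {
  df <- template_df(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "template x (px)", y = "template y (px)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_density_map
#' @param t_map a t-statistic matrix.
#' @param t_crit optional threshold; sub-threshold pixels are blanked.
#' @export
plot_t_map <- function(t_map, t_crit = NULL, title = NULL) {
  df <- template_df(t_map)
  if (!is.null(t_crit)) df$value[abs(df$value) < t_crit] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "t", low = "blue", mid = "white",
                                  high = "red", na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "template x (px)", y = "template y (px)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_density_map
#' @param result a [permutation_test()] result.
#' @export
plot_cluster_map <- function(result, title = NULL) {
  plot_t_map(result$t_map * (significance_mask(result) != 0),
             t_crit = NULL, title = title)
}

template_df <- function(map) {
  m <- unclass(map)
  data.frame(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), ncol(m)),
    value = as.vector(m)
  )
}
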