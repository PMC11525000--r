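#' Plot aggregated indicators against curiosity intensity
#'
#' One panel per indicator and strategy, one series per map size,
#' mirroring the layout of the study's result figures. Requires ggplot2.
#'
#' @param agg Aggregated table from [aggregate_indicators()].
#' @param indicator One of `"up_time_ratio"`, `"n_rounds"`, `"entropy"`,
#'   `"goal_rate"`, `"n_new_productions"`.
#' @return A ggplot object.
#' @export
plot_indicator <- function(agg, indicator = "up_time_ratio") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_indicator() requires the ggplot2 package")
  mcol <- paste0("mean_", indicator)
  scol <- paste0("sd_", indicator)
  stopifnot(mcol %in% names(agg))
  agg$mean_val <- agg[[mcol]]
  agg$sd_val <- agg[[scol]]
  agg$size_f <- factor(paste0(agg$size, "x", agg$size))
  ggplot2::ggplot(agg, ggplot2::aes(
    x = reward, y = mean_val,
    colour = size_f, group = size_f)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = mean_val - sd_val / 10,
      ymax = mean_val + sd_val / 10)) +
    ggplot2::facet_wrap(~strategy, nrow = 1) +
    ggplot2::labs(x = "curiosity reward", y = indicator,
                  colour = "map size") +
    ggplot2::theme_minimal()
}

#' Plot a run trajectory as a heat map over the maze
#'
#' Visit frequencies colour the corner points; traversed segments are drawn
#' with width proportional to traversal count, dashed where a compiled jump
#' connects non-adjacent corner points. Requires ggplot2.
#'
#' @param record A traced `cm_run_record`.
#' @param maze The maze of the run.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(record, maze) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory() requires the ggplot2 package")
  tr <- render_trajectory(record, maze)
  segs <- tr$segments
  co <- tr$nodes
  segs <- merge(segs, stats::setNames(co[c("node", "row", "col")],
                                      c("from", "row0", "col0")), by = "from")
  segs <- merge(segs, stats::setNames(co[c("node", "row", "col")],
                                      c("to", "row1", "col1")), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs, ggplot2::aes(
      x = col0, y = -row0, xend = col1, yend = -row1,
      linewidth = count, linetype = !adjacent),
      colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_point(data = co, ggplot2::aes(
      x = col, y = -row, size = visits,
      colour = visits)) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::annotate("text", x = 0, y = 0, label = "S", vjust = -1) +
    ggplot2::annotate("text",
                      x = node_coords(maze$goal)[["col"]],
                      y = -node_coords(maze$goal)[["row"]],
                      label = "G", vjust = -1) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "visits", size = "visits")
}
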