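#' Plot a trajectory
#'
#' Density of every compartment against time (ggplot2 if installed,
#' otherwise base graphics). Plotting is a convenience; no analysis depends
#' on it.
#'
#' @param x A `dormprey_trajectory`.
#' @param log_y Log-scale the density axis (clipped at 1e-6 mg/L).
#' @param ... Unused.
#' @return A ggplot object, or `NULL` (base graphics), invisibly.
#' @export
plot.dormprey_trajectory <- function(x, log_y = FALSE, ...) {
  sp <- setdiff(names(x), "time")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    long <- do.call(rbind, lapply(sp, function(s)
      data.frame(time = x$time, species = s, density = x[[s]])))
    long$species <- factor(long$species, levels = sp)
    g <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$density,
                                            colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (days)", y = "density (mg/L)")
    if (log_y) g <- g + ggplot2::scale_y_log10(limits = c(1e-6, NA))
    return(g)
  }
  cols <- seq_along(sp) + 1
  ymax <- max(as.matrix(x[sp]))
  graphics::plot(NULL, xlim = range(x$time),
                 ylim = if (log_y) c(1e-6, ymax) else c(0, ymax),
                 log = if (log_y) "y" else "",
                 xlab = "time (days)", ylab = "density (mg/L)")
  for (k in seq_along(sp))
    graphics::lines(x$time, if (log_y) pmax(x[[sp[k]]], 1e-6) else x[[sp[k]]],
                    col = cols[k])
  graphics::legend("topright", legend = sp, col = cols, lty = 1, bty = "n")
  invisible(NULL)
}

#' Heatmap of a sweep grid
#'
#' Winner map over the two swept parameters; infeasible cells are blank.
#' Requires ggplot2.
#'
#' @param x A `sweep_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.sweep_grid <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting a sweep_grid requires ggplot2", call. = FALSE)
  df <- as.data.frame(x)
  df$winner[!df$feasible] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$axis2_value, .data$axis1_value,
                                   fill = .data$winner)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(PA = "#1b7837", dormitive = "#762a83", none = "grey70"),
      na.value = "white") +
    ggplot2::labs(x = x$axis2$label, y = x$axis1$label, fill = "winner")
}
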