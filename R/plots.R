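#' Plot a configuration frame
#'
#' Draws cells as thick polylines (capsule chains) in the periodic box,
#' coloured by a per-segment scalar: segment speed (needs a trajectory),
#' collision strain energy, or cell id. The layout is deterministic for a
#' given input.
#'
#' @param x a `myxo_state`, or a `myxo_sim` together with `time_s`.
#' @param color `"cell"`, `"speed"` or `"strain"`.
#' @param sim the `myxo_sim` a state was taken from; required for
#'   `color = "speed"` so speeds can be measured around the frame.
#' @param time_s frame time when `x` is a `myxo_sim`.
#' @param window_min speed measurement window, min.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_frame <- function(x, color = c("cell", "speed", "strain"), sim = NULL,
                       time_s = NULL, window_min = 1) {
  color <- match.arg(color)
  if (inherits(x, "myxo_sim")) {
    sim <- x
    if (is.null(time_s)) time_s <- max(x$frames$time_s)
    x <- frame_state(x, time_s)
  }
  stopifnot(inherits(x, "myxo_state"))
  params <- x$params
  df <- tidy(x)
  # unwrap each cell about its first particle so wrapped cells draw whole
  np <- params$n_particles
  df <- dplyr::group_by(df, .data$cell_id)
  df <- dplyr::mutate(
    df,
    x_um = .data$x_um[1] + mi_vec(.data$x_um - .data$x_um[1],
                                  params$domain[1]),
    y_um = .data$y_um[1] + mi_vec(.data$y_um - .data$y_um[1],
                                  params$domain[2])
  )
  df <- dplyr::ungroup(df)
  scalar_lab <- "cell"
  if (color == "strain") {
    se <- strain_energies(x, params)
    seg <- dplyr::mutate(se, scalar = .data$energy_J)
    scalar_lab <- "strain energy (J)"
  } else if (color == "speed") {
    if (is.null(sim)) stop("color = 'speed' needs the myxo_sim (sim = ...)")
    sp <- segment_speeds(sim, window_min = window_min)
    near <- unique(sp$time_s)
    t0 <- near[which.min(abs(near - x$time_s))]
    seg <- dplyr::filter(sp, .data$time_s == t0)
    seg <- dplyr::mutate(seg, scalar = .data$speed_um_min)
    scalar_lab <- "speed (um/min)"
  } else {
    nseg <- np - 1L
    seg <- tibble::tibble(
      cell_id = rep(unique(df$cell_id), each = nseg),
      segment_index = rep(seq_len(nseg) - 1L, dplyr::n_distinct(df$cell_id)),
      scalar = rep(unique(df$cell_id), each = nseg)
    )
  }
  ends <- dplyr::mutate(df, segment_index = .data$particle_index)
  segdf <- dplyr::inner_join(
    dplyr::rename(ends, x0 = "x_um", y0 = "y_um"),
    dplyr::mutate(dplyr::rename(ends, x1 = "x_um", y1 = "y_um"),
                  segment_index = .data$segment_index - 1L),
    by = c("cell_id", "segment_index"),
    suffix = c("", ".y")
  )
  segdf <- dplyr::inner_join(segdf, seg, by = c("cell_id", "segment_index"))
  ggplot2::ggplot(segdf) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1,
                   colour = .data$scalar),
      linewidth = 2, lineend = "round") +
    ggplot2::scale_colour_viridis_c(name = scalar_lab) +
    ggplot2::coord_equal(xlim = c(0, params$domain[1]),
                         ylim = c(0, params$domain[2])) +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_frame
#' @param object a `myxo_state`.
autoplot.myxo_state <- function(object, color = "cell", ...) {
  plot_frame(object, color = color, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
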