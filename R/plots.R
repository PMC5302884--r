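# ggplot2 displays for the main result types.  Plots are presentation-only
# side effects; no computation consumes them.

#' Plot a densitometry trace
#'
#' @param object A `bnp_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bnp_trace <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$position, y = .data$intensity))
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$intensity - .data$sd, 0),
                   ymax = .data$intensity + .data$sd),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(
      x = if (is_aligned(object)) "aligned gel axis (4x = 0, 720 kDa = 1)"
          else "gel axis",
      y = "intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an oligomer size distribution
#'
#' @param object A `bak_sizedist`.
#' @param mass Plot dimer-unit mass (as on a blot) instead of complex counts.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bak_sizedist <- function(object, mass = FALSE, ...) {
  df <- if (mass) {
    m <- mass_weight(object)
    tibble::tibble(size = m$size, y = m$mass)
  } else {
    tibble::tibble(size = object$size, y = object$count)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$y)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = "oligomer size (dimer units)",
                  y = if (mass) "mass fraction" else "complexes") +
    ggplot2::theme_minimal()
}

#' Overlay replicate traces
#'
#' Overlay of per-replicate predicted densitometry curves, optionally with
#' their mean.
#'
#' @param traces List of `bnp_trace` objects.
#' @param mean_trace Optional mean trace drawn on top.
#' @return A ggplot.
#' @export
plot_trace_overlay <- function(traces, mean_trace = NULL) {
  df <- purrr::map_dfr(seq_along(traces), function(i) {
    tibble::tibble(replicate = i,
                   position = traces[[i]]$position,
                   intensity = traces[[i]]$intensity)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$intensity,
                                        group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue4")
  if (!is.null(mean_trace)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(position = mean_trace$position,
                            intensity = mean_trace$intensity,
                            replicate = 0),
      colour = "black", linewidth = 0.8
    )
  }
  p + ggplot2::labs(x = "gel axis", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Map of linked components on the lattice
#'
#' Draws each cell at its lattice position, coloured by connected component
#' (singletons in grey), the visual output style of the simulation.
#'
#' @param result A `bak_linkage` from a lattice run.
#' @param lattice The `bak_lattice` used.
#' @return A ggplot.
#' @export
plot_lattice_components <- function(result, lattice) {
  stopifnot(inherits(result, "bak_linkage"), inherits(lattice, "bak_lattice"))
  n <- lattice$n_cells
  q <- (seq_len(n) - 1L) %% lattice$cols
  r <- (seq_len(n) - 1L) %/% lattice$cols
  if (lattice$geometry == "hexagonal") {
    x <- q + r / 2
    y <- r * sqrt(3) / 2
  } else {
    x <- q
    y <- r
  }
  size_of_cell <- result$component_sizes[result$component]
  df <- tibble::tibble(
    x = x, y = y,
    component = factor(ifelse(size_of_cell > 1L, result$component, NA))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$component)) +
    ggplot2::geom_point(size = 1.2, show.legend = FALSE) +
    ggplot2::scale_colour_discrete(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
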