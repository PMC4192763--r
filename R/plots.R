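#' Plot the per-breath stiffness history of a session
#'
#' Per-breath stiffness (points), the rolling smoothed stiffness (line) and
#' the detected PEEP (lower trace) against breath index — the standard
#' monitoring view of a ventilation session.
#'
#' @param object,x A `vm_mechanics` tibble from [analyze_breaths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vm_mechanics <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$status == "accepted", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$breath_index)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$stiffness, colour = "stiffness"),
      alpha = 0.45, size = 0.9, na.rm = TRUE
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$stiffness_smooth, colour = "smoothed stiffness"),
      linewidth = 0.8, na.rm = TRUE
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$peep, colour = "detected PEEP"),
      linewidth = 0.6, na.rm = TRUE
    ) +
    ggplot2::scale_colour_manual(
      values = c(
        "stiffness" = "#4477AA",
        "smoothed stiffness" = "#222222",
        "detected PEEP" = "#CC3311"
      ),
      name = NULL
    ) +
    ggplot2::labs(
      x = "breath index",
      y = expression(paste("stiffness (", cmH[2], "O/L)  /  PEEP (", cmH[2], "O)"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vm_mechanics
#' @export
plot.vm_mechanics <- function(x, ...) print(autoplot(x, ...))

#' Plot a recruitment-manoeuvre stiffness-vs-PEEP ladder
#'
#' Stiffness against PEEP with the ascending arm dashed and the descending
#' arm solid (the usual manoeuvre-plot convention), the minimal-stiffness
#' descending level marked, and the recommended PEEP as a vertical line.
#'
#' @param object,x An `rm_result` from [recommend_peep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_result <- function(object, ...) {
  lad <- tidy(object)
  ggplot2::ggplot(
    lad,
    ggplot2::aes(x = .data$peep, y = .data$stiffness, linetype = .data$arm)
  ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = object$recommended_peep, colour = "#CC3311",
      linewidth = 0.7
    ) +
    ggplot2::annotate(
      "point",
      x = object$minimal_stiffness_peep,
      y = lad$stiffness[lad$arm == "descending" &
                          lad$peep == object$minimal_stiffness_peep][1],
      shape = 1, size = 4, stroke = 1.2, colour = "#CC3311"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(ascending = "dashed", descending = "solid"), name = "arm"
    ) +
    ggplot2::labs(
      x = expression(paste("PEEP (", cmH[2], "O)")),
      y = expression(paste("stiffness (", cmH[2], "O/L)")),
      caption = sprintf("recommended PEEP: %.3g cmH2O", object$recommended_peep)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rm_result
#' @export
plot.rm_result <- function(x, ...) print(autoplot(x, ...))

#' Plot per-breath time-varying elastance curves
#'
#' Edrs against normalised inspiration time for the selected breaths; a flat
#' trace indicates constant elastance over the breath, while dips below zero
#' are the signature of superimposed spontaneous effort.
#'
#' @param results A `vm_mechanics` tibble from [analyze_breaths()].
#' @param breaths Optional breath indices to include (default: all accepted).
#' @return A ggplot object.
#' @export
plot_edrs <- function(results, breaths = NULL) {
  d <- tibble::as_tibble(results)
  if (!is.null(breaths)) d <- d[d$breath_index %in% breaths, , drop = FALSE]
  curves <- tidyr::unnest(
    dplyr::select(d, "breath_index", "edrs"), "edrs"
  )
  if (nrow(curves) == 0) abort("No Edrs curves to plot for the selected breaths.")
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$tau, y = .data$edrs, group = .data$breath_index)
  ) +
    ggplot2::geom_line(alpha = 0.5, colour = "#4477AA") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "normalised inspiration time",
      y = expression(paste(E[drs], " (", cmH[2], "O/L)"))
    ) +
    ggplot2::theme_minimal()
}
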