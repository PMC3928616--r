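#' Plot focality profiles
#'
#' Normalized potential magnitude along the sampling line for each electrode
#' configuration, annotated with the full width at half maximum.
#'
#' @param x a `focality_result` from [run_focality()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_focality <- function(x, ...) {
  need_ggplot()
  df <- x$profiles
  df$x_um <- df$x * 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = x_um, y = v_norm,
                                   color = config)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along profile line (µm)",
                  y = "|V| / max |V|",
                  color = "configuration",
                  title = "Field focality 50 µm above the stimulation electrode") +
    ggplot2::theme_minimal()
}

#' Plot a mirror report
#'
#' The extracellular potential at the compartment centers and the end-of-pulse
#' membrane polarization, overlaid with the mirror image of the field.
#'
#' @param x a `mirror_report` from [run_mirror_fiber()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_mirror <- function(x, ...) {
  need_ggplot()
  df <- rbind(
    data.frame(y_um = x$y * 1e6, mV = x$Ve * 1e3,
               what = "extracellular potential"),
    data.frame(y_um = x$y * 1e6, mV = (x$vm - mean(x$vm)) * 1e3,
               what = "membrane polarization (end of pulse, mean-centered)"),
    data.frame(y_um = x$y * 1e6, mV = -(x$Ve - mean(x$Ve)) * 1e3,
               what = "mirror image of the field")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = y_um, y = mV,
                                   linetype = what,
                                   color = what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along fiber (µm)", y = "mV",
                  title = "Mirror response of a passive fiber") +
    ggplot2::theme_minimal()
}

#' Plot a hybrid vs whole-FEM comparison
#'
#' End-of-pulse membrane potential along the neuron for the cable (hybrid)
#' solution and the whole-FEM bottom/top membrane sides.
#'
#' @param x a `comparison_report` from [run_comparison()].
#' @param geometry which geometry to plot (name in the report).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_comparison <- function(x, geometry = names(x)[1], ...) {
  need_ggplot()
  r <- x[[geometry]]
  df <- rbind(
    data.frame(y_um = r$hybrid$y * 1e6, mV = r$hybrid$vm * 1e3,
               curve = "cable (hybrid)"),
    data.frame(y_um = r$bottom$y * 1e6, mV = r$bottom$vm * 1e3,
               curve = "whole-FEM, bottom side"),
    data.frame(y_um = r$top$y * 1e6, mV = r$top$vm * 1e3,
               curve = "whole-FEM, top side")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = y_um, y = mV,
                                   color = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along neuron (µm)",
                  y = "membrane potential (mV)",
                  title = paste0("Hybrid vs whole-FEM (", geometry, ")")) +
    ggplot2::theme_minimal()
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package")
  }
}
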