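# ggplot2 displays for time courses, band tables and fits.

#' Plot a cleavage time course as native-gel species kinetics
#'
#' @param object An `mk_tc` time course.
#' @param species `"native"` for the five gel classes, `"states"` for raw
#'   state occupancies.
#' @param mech Mechanism if the time course lacks the attribute.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mk_tc <- function(object, species = c("native", "states"),
                           mech = NULL, ...) {
  species <- match.arg(species)
  if (species == "native") {
    d <- native_fractions(object, mech %||% attr(object, "mechanism"))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$fraction,
                                    colour = .data$species)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::scale_x_sqrt() +
      ggplot2::labs(x = "time (s)", y = "molar fraction", colour = "species") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$fraction,
                                         colour = .data$state)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_sqrt() +
      ggplot2::labs(x = "time (s)", y = "occupancy", colour = "state") +
      ggplot2::theme_minimal()
  }
}

#' Plot a band table as a virtual gel lane
#'
#' Migration is drawn as decreasing log-length (cosmetic only); band
#' darkness is proportional to intensity.
#'
#' @param object An `mk_bands` table (or a named list of them, one per lane).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mk_bands <- function(object, ...) {
  lanes <- if (inherits(object, "mk_bands")) list(lane = object) else object
  d <- bind_rows(lapply(names(lanes), function(nm) {
    mutate(as_tibble(lanes[[nm]]), lane = nm)
  }))
  d <- d[d$intensity > 1e-12, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lane, y = .data$length,
                                  alpha = .data$intensity)) +
    ggplot2::geom_tile(height = 0.012, width = 0.6, fill = "black") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_alpha(range = c(0.25, 1)) +
    ggplot2::labs(x = NULL, y = "fragment length (nt)", alpha = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic dataset against its generating truth
#'
#' @param object An `mk_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mk_dataset <- function(object, ...) {
  truth <- attr(object, "truth")$truth_tbl
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$value,
                                    colour = .data$observable)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "time (s)", y = "observed fraction") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(data = truth, linewidth = 0.4)
  }
  p
}

#' Plot observed vs fitted observables of a rate fit
#'
#' @param object An `mk_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mk_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_s, y = .data$value,
                               colour = .data$observable)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = object$fitted, linewidth = 0.4) +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "time (s)", y = "fraction",
                  title = sprintf("%s mechanism, AIC %.1f",
                                  object$mechanism$kind, object$AIC)) +
    ggplot2::theme_minimal()
}
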