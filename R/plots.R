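# ggplot2 views of the main result types.

#' Plot an editing profile
#'
#' Per-position substrate-to-product conversion frequency along the
#' protospacer, in the style of per-site editing-signature panels.
#'
#' @param object An `editing_profile` from [window_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.editing_profile <- function(object, ...) {
  lab <- sprintf("%s>%s frequency", attr(object, "edit_from") %||% "edit",
                 attr(object, "edit_to") %||% "")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$frequency)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = object$position) +
    ggplot2::labs(x = "protospacer position", y = lab,
                  title = attr(object, "editor")) +
    ggplot2::theme_minimal()
}

#' Plot a substitution matrix
#'
#' Heatmap of off-reference call frequency per position and called
#' base.
#'
#' @param object A `substitution_matrix` from
#'   [tabulate_substitutions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.substitution_matrix <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(cols = all_of(DNA_BASES), names_to = "base",
                        values_to = "count") |>
    mutate(frequency = ifelse(.data$depth > 0,
                              .data$count / .data$depth, NA_real_),
           frequency = ifelse(.data$base == .data$ref, NA_real_,
                              .data$frequency))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$base,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey95") +
    ggplot2::labs(x = "reference position", y = "called base",
                  fill = "off-ref\nfrequency") +
    ggplot2::theme_minimal()
}

#' Plot cohort targetability fractions
#'
#' Bar chart of correctable and precisely-correctable fractions per
#' editor and variant transition class.
#'
#' @param fractions Output of [cohort_fractions()].
#' @return A ggplot.
#' @export
plot_cohort_fractions <- function(fractions) {
  long <- fractions |>
    tidyr::pivot_longer(cols = c("frac_correctable", "frac_precise"),
                        names_to = "verdict", values_to = "fraction") |>
    mutate(verdict = ifelse(.data$verdict == "frac_correctable",
                            "correctable", "precise"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$fraction,
                                     fill = .data$verdict)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~editor) +
    ggplot2::labs(x = "variant class (ref>alt)", y = "fraction of class") +
    ggplot2::theme_minimal()
}
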