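#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point scale_x_log10
#'   scale_y_log10 labs theme_minimal
NULL

#' Plot a sequestration curve
#'
#' Flux versus residence-time threshold per organic pool, log-log axes
#' (the t = 0 intercept is dropped from the log axis).
#'
#' @param object a `seq_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.seq_curve <- function(object, ...) {
  el <- attr(object, "element")
  df <- filter(as_tibble(object), .data$t_years > 0, .data$flux_Pg_y > 0)
  ggplot(df, aes(x = .data$t_years, y = .data$flux_Pg_y,
                 colour = .data$pool)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "residence-time threshold t (y)",
         y = bquote(Phi[tau >= t] ~ "(Pg" ~ .(el) ~ y^-1 * ")"),
         colour = "pool") +
    theme_minimal()
}

#' Plot a C:P sequestration-stoichiometry curve
#'
#' @param cp a [cp_curve()] table, optionally with a `fraction` column
#'   (as from [run_labile_dop_sensitivity()]`$cp_curves`).
#' @return a ggplot (molar C:P vs log threshold).
#' @export
plot_cp_curve <- function(cp) {
  df <- filter(as_tibble(cp), .data$t_years > 0, !is.na(.data$cp_ratio))
  p <- if ("fraction" %in% names(df)) {
    ggplot(df, aes(x = .data$t_years, y = .data$cp_ratio,
                   colour = factor(.data$fraction))) +
      labs(colour = "labile DOP fraction")
  } else {
    ggplot(df, aes(x = .data$t_years, y = .data$cp_ratio))
  }
  p + geom_line() + scale_x_log10() +
    labs(x = "residence-time threshold t (y)",
         y = "C:P of sequestration flux (mol:mol)") +
    theme_minimal()
}

#' @export
autoplot.labile_dop_sensitivity <- function(object, ...) {
  plot_cp_curve(object$cp_curves)
}
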