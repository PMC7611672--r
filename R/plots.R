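#' Plot the drug-by-CNR moderation
#'
#' Outcome against locus coeruleus CNR with one fitted line per drug
#' condition; a non-parallel pair of lines is the moderation signature.
#'
#' @param object a [fit_moderation_lmm()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.moderation_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cnr, y = .data$y,
                                  colour = .data$drug)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "locus coeruleus CNR (z)",
                  y = paste0(object$outcome, " (z)"),
                  colour = NULL,
                  title = "Drug x CNR moderation")
}

#' Plot group-level posterior SSRT distributions
#'
#' Density of the group-level SSRT posterior for one or more fits.
#'
#' @param ... named [fit_race_model()] objects (names label the groups).
#' @return a ggplot object.
#' @export
plot_ssrt_posteriors <- function(...) {
  fits <- list(...)
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  df <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(derive_ssrt(f), group = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "SSRT (s)", y = "posterior density", fill = NULL)
}

#' Plot an SSD staircase trace
#'
#' Stop-signal delay over successive stop trials, showing the adaptive
#' tracking toward 50% stop accuracy.
#'
#' @param trials a simulated or observed trial table.
#' @return a ggplot object.
#' @export
plot_staircase <- function(trials) {
  st <- trials[trials$kind == "stop", , drop = FALSE]
  st$stop_index <- seq_len(nrow(st))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$stop_index, y = .data$ssd)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = is.na(.data$response)),
                        size = 0.8) +
    ggplot2::labs(x = "stop trial", y = "SSD (s)",
                  colour = "inhibited")
}
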