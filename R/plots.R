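# Base-graphics plot methods for the main result objects.

#' @export
plot.delta_contact_profile <- function(x, ...) {
  n <- length(x$delta)
  graphics::plot(seq_len(n), x$delta, type = "h",
                 col = ifelse(x$delta < 0, "steelblue", "firebrick"),
                 xlab = "residue", ylab = expression(Delta * "contact"),
                 main = sprintf("%.0f K vs %.0f K", x$t_hi, x$t_lo), ...)
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  graphics::image(seq_len(n), seq_len(n), x$matrix,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue", ylab = "residue",
                  main = sprintf("contact frequency, %.0f K (%s)",
                                 x$temperature, x$scope), ...)
  invisible(x)
}

#' @export
plot.trend_report <- function(x, ...) {
  graphics::plot(x$temperatures, x$means, type = "b", pch = 19,
                 xlab = "temperature (K)", ylab = "ensemble mean",
                 main = sprintf("trend: %s", x$classification), ...)
  invisible(x)
}

#' @export
plot.fret_prediction <- function(x, ...) {
  graphics::plot(x$temperature, x$lifetime, type = "b", pch = 19,
                 ylim = range(c(x$ci_lo, x$ci_hi)),
                 xlab = "temperature (K)",
                 ylab = "predicted donor lifetime (ns)", ...)
  graphics::arrows(x$temperature, x$ci_lo, x$temperature, x$ci_hi,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
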