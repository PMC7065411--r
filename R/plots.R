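#' Diagnostic plots for a validated prediction equation
#'
#' `plot_centered_residuals()` draws the centered-residual diagnostic:
#' residuals (observed minus predicted weight) against the predicted
#' values centered around their mean, with the per-period regression
#' line whose intercept and slope are the systematic error components
#' (mean bias and slope departure). `plot_observed_predicted()` draws
#' observed against predicted weight with the 45-degree identity line
#' and the per-period least-squares line; with no systematic error the
#' two coincide. Both draw on the active graphics device.
#'
#' @param coeffs a [coefficient_set()].
#' @param records records with observed `bw` (see [validate_model()]).
#' @param main plot title.
#' @return invisibly, the data.frame of period, observed and predicted
#'   values that was plotted.
#' @export
plot_centered_residuals <- function(coeffs, records,
                                    main = "Centered-residual diagnostic") {
  d <- .validation_frame(coeffs, records)
  cols <- c(lactation = "#1b7837", dry = "#762a83")
  graphics::plot(d$pred - stats::ave(d$pred, d$period), d$obs - d$pred,
                 col = cols[d$period], pch = 16, cex = 0.5,
                 xlab = "predicted body weight, centered within period (kg)",
                 ylab = "observed - predicted body weight (kg)",
                 main = main)
  graphics::abline(h = 0, lty = 3)
  for (per in unique(d$period)) {
    sub <- d[d$period == per, ]
    if (nrow(sub) < 3 || stats::var(sub$pred) == 0) next
    st <- stpierre_regression(sub$obs, sub$pred)
    graphics::abline(st$intercept, st$slope, col = cols[per], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = 16, bty = "n")
  invisible(d)
}

#' @rdname plot_centered_residuals
#' @export
plot_observed_predicted <- function(coeffs, records,
                                    main = "Observed vs. predicted body weight") {
  d <- .validation_frame(coeffs, records)
  cols <- c(lactation = "#1b7837", dry = "#762a83")
  graphics::plot(d$pred, d$obs, col = cols[d$period], pch = 16, cex = 0.5,
                 xlab = "predicted body weight (kg)",
                 ylab = "observed body weight (kg)", main = main)
  graphics::abline(0, 1, lty = 2)
  for (per in unique(d$period)) {
    sub <- d[d$period == per, ]
    if (nrow(sub) < 3 || stats::var(sub$pred) == 0) next
    f <- stats::lm(obs ~ pred, data = sub)
    graphics::abline(f, col = cols[per], lwd = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = 16, bty = "n")
  invisible(d)
}

.validation_frame <- function(coeffs, records) {
  records <- as.data.frame(records)
  if (!"bw" %in% names(records))
    stop("records need observed body weight in column bw")
  data.frame(period = ifelse(as.numeric(records$day) > 0,
                             "lactation", "dry"),
             obs = as.numeric(records$bw),
             pred = predict_bw(records, coeffs),
             stringsAsFactors = FALSE)
}
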