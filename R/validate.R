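#' Deterministic every-fifth-record hold-out split
#'
#' Reproduces the study's 80/20 split: records are sorted by the cows'
#' identification numbers (and, within cow, by day relative to calving,
#' then input order, to make the order total), and every fifth record
#' (positions 5, 10, 15, ...) goes to the validation subset. Sorting
#' first makes the split a pure function of the record set, so a permuted
#' input yields the identical partition.
#'
#' @param records data.frame with columns `cow_id` and `day`.
#' @return list with elements `estimation` (80 %) and `validation`
#'   (20 %).
#' @export
split_every_fifth <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("cannot split an empty record set")
  if (!all(c("cow_id", "day") %in% names(records)))
    stop("records need cow_id and day columns")
  ord <- order(as.character(records$cow_id), as.numeric(records$day),
               seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  val <- seq_len(nrow(sorted)) %% 5 == 0
  list(estimation = sorted[!val, , drop = FALSE],
       validation = sorted[val, , drop = FALSE])
}

#' Decompose the mean square prediction error
#'
#' Splits the MSPE between observed and predicted values into the error
#' of central tendency (squared mean bias), the error due to regression
#' (departure of the observed-on-predicted slope from 1) and the error
#' due to disturbance (random scatter):
#' \deqn{MSPE = (\bar O - \bar P)^2 + (s_P - r\,s_O)^2 + (1 - r^2)\,s_O^2}
#' with population (divide-by-n) standard deviations and the Pearson
#' correlation r, so the three terms sum to the MSPE exactly. ECT and ER
#' are systematic and removable by linear correction of the predictions;
#' ED is not.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2), kg.
#' @return named numeric vector `c(mspe, ect, er, ed)`, kg^2.
#' @examples
#' mspe_decompose(c(1, 2, 3, 6), c(1, 2, 3, 4))
#' @export
mspe_decompose <- function(observed, predicted) {
  o <- as.numeric(observed); p <- as.numeric(predicted)
  if (length(o) != length(p)) stop("observed and predicted differ in length")
  if (length(o) < 2) stop("need at least 2 observations")
  if (any(is.na(o)) || any(is.na(p))) stop("missing values not allowed")
  mspe <- mean((o - p)^2)
  ect <- (mean(o) - mean(p))^2
  s_o <- sqrt(mean((o - mean(o))^2))
  s_p <- sqrt(mean((p - mean(p))^2))
  if (s_p == 0)
    stop("predicted values are constant; ER and ED are undefined")
  r <- if (s_o == 0) 0 else stats::cor(o, p)
  er <- (s_p - r * s_o)^2
  ed <- (1 - r^2) * s_o^2
  c(mspe = mspe, ect = ect, er = er, ed = ed)
}

#' Centered-residual regression
#'
#' Ordinary least squares of the residuals (observed minus predicted) on
#' the predicted values centered around their mean. By construction the
#' intercept equals the mean bias (the ECT component before squaring) and
#' the slope equals `cov(O, P)/var(P) - 1`, i.e. 0 exactly when the
#' observed-on-predicted regression slope is 1 (no error due to
#' regression).
#'
#' @inheritParams mspe_decompose
#' @return list with `intercept` (kg), `slope` (kg/kg) and their standard
#'   errors `intercept_se`, `slope_se`.
#' @export
stpierre_regression <- function(observed, predicted) {
  o <- as.numeric(observed); p <- as.numeric(predicted)
  if (length(o) != length(p)) stop("observed and predicted differ in length")
  if (stats::var(p) == 0) stop("predicted values are constant")
  x <- p - mean(p)
  f <- stats::lm((o - p) ~ x)
  # a perfect fit (zero residual variance) is legitimate here, e.g. when
  # validating on noise-free data; silence summary.lm's reliability note
  se <- suppressWarnings(sqrt(diag(stats::vcov(f))))
  list(intercept = unname(stats::coef(f)[1]),
       slope = unname(stats::coef(f)[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]))
}

#' Validate a prediction equation on held-out records
#'
#' Predicts body weight for every record via [predict_bw()] and evaluates
#' the predictions separately for the lactation and dry periods (a
#' record's own period assignment is used, never re-derived from the
#' prediction): RMSPE, the squared Pearson correlation between observed
#' and predicted (R^2), the MSPE decomposition into ECT/ER/ED (absolute,
#' kg^2, and as percentages of the MSPE) and the centered-residual
#' intercept and slope. A period with fewer than 3 records is flagged
#' insufficient rather than failing the whole validation.
#'
#' @param coeffs a [coefficient_set()].
#' @param records data.frame of records with observed `bw` and the
#'   columns [predict_bw()] requires.
#' @return data.frame of class `bw_validation`, one row per period, with
#'   columns `period`, `n`, `insufficient`, `mspe`, `rmspe`, `r2`, `ect`,
#'   `er`, `ed`, `ect_pct`, `er_pct`, `ed_pct`, `stpierre_intercept`,
#'   `stpierre_slope` (+ standard errors).
#' @export
validate_model <- function(coeffs, records) {
  records <- as.data.frame(records)
  if (!"bw" %in% names(records))
    stop("records need observed body weight in column bw")
  pred <- predict_bw(records, coeffs)
  period <- ifelse(as.numeric(records$day) > 0, "lactation", "dry")
  rows <- lapply(c("lactation", "dry"), function(per) {
    idx <- period == per
    n <- sum(idx)
    base <- data.frame(period = per, n = n, insufficient = n < 3,
                       mspe = NA_real_, rmspe = NA_real_, r2 = NA_real_,
                       ect = NA_real_, er = NA_real_, ed = NA_real_,
                       ect_pct = NA_real_, er_pct = NA_real_,
                       ed_pct = NA_real_,
                       stpierre_intercept = NA_real_,
                       stpierre_slope = NA_real_,
                       stpierre_intercept_se = NA_real_,
                       stpierre_slope_se = NA_real_,
                       stringsAsFactors = FALSE)
    if (n < 3) return(base)
    o <- as.numeric(records$bw[idx]); p <- pred[idx]
    dec <- mspe_decompose(o, p)
    stp <- stpierre_regression(o, p)
    base$mspe <- dec[["mspe"]]
    base$rmspe <- sqrt(dec[["mspe"]])
    base$r2 <- stats::cor(o, p)^2
    base$ect <- dec[["ect"]]; base$er <- dec[["er"]]; base$ed <- dec[["ed"]]
    if (dec[["mspe"]] > 0) {
      base$ect_pct <- 100 * dec[["ect"]] / dec[["mspe"]]
      base$er_pct <- 100 * dec[["er"]] / dec[["mspe"]]
      base$ed_pct <- 100 * dec[["ed"]] / dec[["mspe"]]
    } else {
      base$ect_pct <- 0; base$er_pct <- 0; base$ed_pct <- 0
    }
    base$stpierre_intercept <- stp$intercept
    base$stpierre_slope <- stp$slope
    base$stpierre_intercept_se <- stp$intercept_se
    base$stpierre_slope_se <- stp$slope_se
    base
  })
  structure(do.call(rbind, rows),
            class = c("bw_validation", "data.frame"))
}

#' @export
print.bw_validation <- function(x, ...) {
  cat("Validation of body-weight predictions\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (isTRUE(r$insufficient)) {
      cat(sprintf("  %-9s n=%d: insufficient records\n", r$period, r$n))
      next
    }
    cat(sprintf(
      "  %-9s n=%5d  RMSPE %.1f kg  R2 %.1f %%  ECT/ER/ED %% %.3f/%.3f/%.3f\n",
      r$period, r$n, r$rmspe, 100 * r$r2, r$ect_pct, r$er_pct, r$ed_pct))
    cat(sprintf(
      "            centered-residual intercept %.3f kg (SE %.3f), slope %.4f (SE %.4f)\n",
      r$stpierre_intercept, r$stpierre_intercept_se,
      r$stpierre_slope, r$stpierre_slope_se))
  }
  invisible(x)
}
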