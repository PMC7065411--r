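#' Physiological-stage effect (fitted stage curve)
#'
#' Evaluates the fitted stage curve of a prediction equation: a
#' fourth-degree polynomial in days in milk during lactation, a linear
#' function of the (negative) day relative to calving during the dry
#' period. The curves are polynomial fits to the stage-class least-squares
#' means and are only valid inside the class domains -- their curvature
#' changes outside, so out-of-domain days are an error, never
#' extrapolated.
#'
#' @param day numeric vector of days; lactation `[1, 364]`, dry
#'   `[-56, -1]`.
#' @param period `"lactation"` or `"dry"` (scalar, applies to all days).
#' @param coeffs a [coefficient_set()].
#' @return numeric vector of stage effects, kg.
#' @examples
#' m <- bw_model("hgbghw")
#' stage_effect(c(-56, -1), "dry", m) # 4.60, 17.03
#' @export
stage_effect <- function(day, period = c("lactation", "dry"), coeffs) {
  period <- match.arg(period)
  validate_coefficient_set(coeffs)
  day <- as.numeric(day)
  check_stage_day(day, period)
  cf <- if (period == "lactation") coeffs$lactation_curve else coeffs$dry_curve
  drop(outer(day, seq_along(cf) - 1, `^`) %*% cf)
}

#' Predict body weight for cow records
#'
#' Applies a prediction equation to weighing records:
#' intercept + genotype effect + parity effect +
#' sum over measurements of (pooled + genotype-specific slope) x value +
#' stage curve at the record's day. The random farm effect is set to 0,
#' i.e. predictions are at population level, matching how the equations
#' are validated against observations.
#'
#' @param records data.frame of cow records with columns `genotype` (class
#'   labels, see [genotype_levels()]), `parity_class` (or `parity`, which
#'   is classified on the fly), `day` (day relative to calving; positive =
#'   lactation, negative = dry), and one column per measurement required
#'   by `coeffs$model_spec` (cm or score points).
#' @param coeffs a [coefficient_set()].
#' @return numeric vector of predicted body weights, kg.
#' @examples
#' rec <- data.frame(genotype = "BS", parity_class = "P5plus",
#'                   day = 100, HG = 210, BG = 256, HW = 57)
#' predict_bw(rec, bw_model("hgbghw"))
#' @export
predict_bw <- function(records, coeffs) {
  validate_coefficient_set(coeffs)
  records <- as.data.frame(records)
  missing_tr <- setdiff(coeffs$model_spec, names(records))
  if (length(missing_tr) > 0) {
    stop("records lack measurement(s) required by the model: ",
         paste(missing_tr, collapse = ", "))
  }
  for (tr in coeffs$model_spec) {
    if (any(is.na(records[[tr]]))) {
      stop("missing values in required measurement ", tr)
    }
  }
  if (!"genotype" %in% names(records)) {
    stop("records need a 'genotype' column (see classify_genotype)")
  }
  geno <- as.character(records$genotype)
  if (any(!geno %in% genotype_levels())) {
    stop("unknown genotype class label(s): ",
         paste(unique(setdiff(geno, genotype_levels())), collapse = ", "))
  }
  if ("parity_class" %in% names(records)) {
    pc <- as.character(records$parity_class)
    if (any(!pc %in% parity_levels())) {
      stop("unknown parity class label(s): ",
           paste(unique(setdiff(pc, parity_levels())), collapse = ", "))
    }
  } else if ("parity" %in% names(records)) {
    pc <- classify_parity(records$parity)
  } else {
    stop("records need a 'parity_class' or 'parity' column")
  }
  day <- as.numeric(records$day)
  check_stage_day(day)

  pred <- coeffs$intercept +
    coeffs$genotype_effect[geno] +
    coeffs$parity_effect[pc]
  for (tr in coeffs$model_spec) {
    slope <- coeffs$pooled_slope[[tr]] + coeffs$genotype_slope[tr, geno]
    pred <- pred + slope * as.numeric(records[[tr]])
  }
  is_lact <- day > 0
  stage <- numeric(length(day))
  if (any(is_lact))
    stage[is_lact] <- stage_effect(day[is_lact], "lactation", coeffs)
  if (any(!is_lact))
    stage[!is_lact] <- stage_effect(day[!is_lact], "dry", coeffs)
  unname(pred + stage)
}
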