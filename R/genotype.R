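#' Genotype, parity and physiological-stage classes
#'
#' The prediction equations distinguish five genotype classes: Fleckvieh
#' with at most 10 % Red Holstein (RH) ancestry (`FV`), Fleckvieh with a
#' medium (`FV_RH_m`, >10 to <=44.5 %) or high (`FV_RH_h`, >44.5 %) RH gene
#' proportion, purebred Holstein-Friesian (`HF`) and Brown Swiss (`BS`).
#' `BS` is the reference class: its class effect and all its slope
#' deviations are 0. Parity is grouped into 1, 2, 3+4 and >=5 calvings,
#' with the oldest class (`P5plus`) as reference.
#'
#' @return `genotype_levels()` and `parity_levels()` return character
#'   vectors of the class labels, reference class first (the ordering used
#'   for treatment-coded model matrices).
#' @export
genotype_levels <- function() c("BS", "FV", "FV_RH_m", "FV_RH_h", "HF")

#' @rdname genotype_levels
#' @export
parity_levels <- function() c("P5plus", "P1", "P2", "P3_4")

#' Assign a cow to a genotype class
#'
#' Holstein-Friesian and Brown Swiss cows map directly to `HF` and `BS`.
#' Fleckvieh cows are subclassed by their Red Holstein gene proportion:
#' <=10 % `FV`, >10 to <=44.5 % `FV_RH_m`, >44.5 % `FV_RH_h`.
#'
#' @param breed character vector with entries `"FV"`, `"HF"` or `"BS"`.
#' @param rh_fraction numeric vector of RH gene proportions in `[0, 1]`;
#'   only consulted for `breed == "FV"` (may be `NA` otherwise).
#' @return character vector of genotype class labels
#'   (see [genotype_levels()]).
#' @examples
#' classify_genotype("FV", 0.0625) # "FV"
#' classify_genotype(c("FV", "HF"), c(0.25, NA))
#' @export
classify_genotype <- function(breed, rh_fraction = NA_real_) {
  breed <- as.character(breed)
  bad <- !breed %in% c("FV", "HF", "BS")
  if (any(bad)) {
    stop("unknown breed label(s): ", paste(unique(breed[bad]), collapse = ", "),
         " (expected FV, HF or BS)")
  }
  rh_fraction <- rep_len(as.numeric(rh_fraction), length(breed))
  is_fv <- breed == "FV"
  if (any(is_fv & (is.na(rh_fraction) | rh_fraction < 0 | rh_fraction > 1))) {
    stop("rh_fraction must be given and within [0, 1] for FV cows")
  }
  out <- breed
  out[is_fv & rh_fraction <= 0.10] <- "FV"
  out[is_fv & rh_fraction > 0.10 & rh_fraction <= 0.445] <- "FV_RH_m"
  out[is_fv & rh_fraction > 0.445] <- "FV_RH_h"
  out
}

#' Assign a parity number to a parity class
#'
#' @param parity integer vector of calving numbers (>= 1).
#' @return character vector with entries `"P1"`, `"P2"`, `"P3_4"` or
#'   `"P5plus"`.
#' @examples
#' classify_parity(c(1, 4, 13))
#' @export
classify_parity <- function(parity) {
  parity <- as.numeric(parity)
  if (any(is.na(parity) | parity < 1 | parity != round(parity))) {
    stop("parity must be an integer >= 1")
  }
  out <- rep("P5plus", length(parity))
  out[parity == 1] <- "P1"
  out[parity == 2] <- "P2"
  out[parity %in% c(3, 4)] <- "P3_4"
  out
}

#' Physiological-stage classes
#'
#' The fixed effect of physiological stage combines 13 lactation months
#' (days in milk 1--364, 28 days each) with four 2-week dry stages (days
#' -56 to -1 relative to the next calving). A record's day relative to
#' calving determines its class uniquely: positive days are lactation,
#' negative days the dry period.
#'
#' @param day numeric vector of days relative to calving; lactation days in
#'   `[1, 364]`, dry days in `[-56, -1]`.
#' @return `stage_class()`: a data.frame with columns `day`, `period`
#'   (`"lactation"`/`"dry"`), `class_index` (1--13 or 1--4) and `label`
#'   (`"L01"`...`"L13"`, `"D1"`...`"D4"`).
#' @examples
#' stage_class(c(1, 28, 29, -56, -1))
#' @export
stage_class <- function(day) {
  day <- as.numeric(day)
  check_stage_day(day)
  period <- ifelse(day > 0, "lactation", "dry")
  idx <- ifelse(day > 0, ceiling(day / 28), floor((day + 56) / 14) + 1)
  label <- ifelse(day > 0, sprintf("L%02d", idx), paste0("D", idx))
  data.frame(day = day, period = period, class_index = as.integer(idx),
             label = label, stringsAsFactors = FALSE)
}

# domain guard shared by classification and curve evaluation
check_stage_day <- function(day, period = NULL) {
  if (any(is.na(day))) stop("day relative to calving must not be missing")
  if (is.null(period)) {
    ok <- (day >= 1 & day <= 364) | (day >= -56 & day <= -1)
  } else if (period == "lactation") {
    ok <- day >= 1 & day <= 364
  } else {
    ok <- day >= -56 & day <= -1
  }
  if (!all(ok)) {
    stop("day relative to calving out of domain (", paste(day[!ok][1]),
         "): lactation days must lie in [1, 364], dry days in [-56, -1]; ",
         "the fitted stage curves are not valid outside these limits")
  }
  invisible(TRUE)
}

#' @rdname stage_class
#' @details `stage_labels()` returns the 17 class labels in model order;
#'   `stage_midpoints()` returns the representative (midpoint) day of each
#'   class in one period, the abscissae used when fitting stage curves.
#' @param period `"lactation"` or `"dry"`.
#' @export
stage_labels <- function() c(sprintf("L%02d", 1:13), paste0("D", 1:4))

#' @rdname stage_class
#' @export
stage_midpoints <- function(period = c("lactation", "dry")) {
  period <- match.arg(period)
  if (period == "lactation") seq(14.5, by = 28, length.out = 13)
  else seq(-49.5, by = 14, length.out = 4)
}
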