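#' Measurement traits handled by the package
#'
#' Nine stick/tape body measurements plus the two subjective scores, with
#' the abbreviations used in record files: heart girth (HG), belly girth
#' (BG), stature (ST), body length (BL), pelvis length (PL), body depth
#' (BD), hip width (HW), pin width (PW), knee width (KW) -- all in cm --
#' body condition score (BCS, points 1--5) and muscle score (MUSC, points
#' 1--10).
#'
#' @return character vector of trait abbreviations.
#' @export
trait_names <- function() {
  c("HG", "BG", "ST", "BL", "PL", "BD", "HW", "PW", "KW", "BCS", "MUSC")
}

#' Default measurement profile of the study population
#'
#' Period-specific means, standard deviations and observed ranges of the
#' eleven traits among Austrian Fleckvieh, Holstein and Brown Swiss cows:
#' dry cows are on average heavier with wider heart and belly girths,
#' while skeletal measurements barely change between periods. These
#' profiles are the generator defaults in [sim_config()].
#'
#' @param period `"lactation"` or `"dry"`.
#' @return a list with named numeric vectors `mean`, `sd`, `lower`,
#'   `upper` (one entry per trait) and the trait correlation matrix
#'   `corr` (see [trait_correlations()]).
#' @export
measurement_profile <- function(period = c("lactation", "dry")) {
  period <- match.arg(period)
  tr <- trait_names()
  if (period == "lactation") {
    mean <- c(210, 256, 146, 90, 56, 84, 57, 39, 53, 3.15, 5.1)
    sd    <- c(10.3, 13.6, 4.5, 5.6, 3.0, 4.5, 3.4, 4.7, 5.5, 0.58, 1.5)
    lower <- c(173, 204, 128, 73, 46, 67, 45, 27, 36, 1.00, 1.0)
    upper <- c(253, 312, 163, 111, 68, 99, 68, 59, 69, 5.00, 9.0)
  } else {
    mean <- c(217, 271, 146, 91, 56, 86, 58, 40, 55, 3.57, 5.9)
    sd    <- c(11.2, 13.5, 4.6, 5.8, 3.1, 4.2, 3.4, 4.8, 6.2, 0.56, 1.6)
    lower <- c(185, 235, 130, 75, 45, 71, 47, 27, 36, 2.00, 1.0)
    upper <- c(264, 307, 163, 109, 66, 99, 67, 57, 71, 5.00, 9.0)
  }
  list(mean = stats::setNames(mean, tr), sd = stats::setNames(sd, tr),
       lower = stats::setNames(lower, tr), upper = stats::setNames(upper, tr),
       corr = trait_correlations(period))
}

#' Default between-trait Pearson correlations
#'
#' Pairwise correlations among the eleven traits, recorded separately for
#' the lactation and dry periods; girth measurements correlate strongly
#' with each other (r = 0.72) and with width and depth measurements, while
#' stature and body length are nearly uncorrelated with condition.
#'
#' @inheritParams measurement_profile
#' @return an 11 x 11 correlation matrix with trait names as dimnames.
#' @export
trait_correlations <- function(period = c("lactation", "dry")) {
  period <- match.arg(period)
  tr <- trait_names()
  # upper triangles, row-wise: HG vs (BG..MUSC), BG vs (ST..MUSC), ...
  if (period == "lactation") {
    ut <- c(
      0.72, 0.25, 0.16, 0.44, 0.55, 0.57, 0.34, 0.21, 0.35, 0.34,  # HG
            0.16, 0.25, 0.32, 0.62, 0.54, 0.34, 0.24, 0.30, 0.34,  # BG
                  0.40, 0.50, 0.41, 0.36, 0.04, 0.14, 0.00, -0.12, # ST
                        0.24, 0.33, 0.32, 0.00, 0.05, 0.00, 0.01,  # BL
                              0.48, 0.56, 0.23, 0.20, 0.13, 0.02,  # PL
                                    0.60, 0.22, 0.24, 0.06, 0.03,  # BD
                                          0.36, 0.32, 0.16, 0.11,  # HW
                                                0.21, 0.11, 0.22,  # PW
                                                      0.22, 0.13,  # KW
                                                            0.58)  # BCS
  } else {
    ut <- c(
      0.72, 0.25, 0.08, 0.40, 0.53, 0.53, 0.29, 0.15, 0.45, 0.37,  # HG
            0.20, 0.19, 0.33, 0.60, 0.51, 0.26, 0.22, 0.39, 0.35,  # BG
                  0.43, 0.48, 0.41, 0.34, 0.04, 0.19, 0.04, -0.08, # ST
                        0.23, 0.28, 0.25, -0.06, 0.13, 0.05, 0.10, # BL
                              0.46, 0.53, 0.22, 0.18, 0.21, 0.10,  # PL
                                    0.54, 0.19, 0.27, 0.21, 0.16,  # BD
                                          0.36, 0.34, 0.27, 0.20,  # HW
                                                0.18, 0.16, 0.17,  # PW
                                                      0.23, 0.14,  # KW
                                                            0.49)  # BCS
  }
  m <- diag(length(tr))
  m[upper.tri(m)] <- 0 # placeholder, fill row-wise below
  k <- 1
  for (i in seq_len(length(tr) - 1)) {
    for (j in seq(i + 1, length(tr))) {
      m[i, j] <- ut[k]
      m[j, i] <- ut[k]
      k <- k + 1
    }
  }
  dimnames(m) <- list(tr, tr)
  m
}
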