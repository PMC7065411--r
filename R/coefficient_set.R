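#' Prediction-equation coefficient sets
#'
#' A `coefficient_set` holds one complete body-weight prediction equation:
#' the intercept (kg), genotype and parity class effects (kg), pooled and
#' genotype-specific regression slopes for the body measurements (kg/cm,
#' or kg/point for scores), and the physiological-stage curves -- a
#' fourth-degree polynomial in days in milk for lactation and a linear
#' function of the day relative to calving for the dry period. Predicted
#' weight for a record is
#' \deqn{\hat Y = \mu + G_i + P_j + \sum_l (b_l + b_l(G_i))\,X_l + f_{per}(day),}
#' with the Brown Swiss genotype and the oldest parity class as reference
#' (zero) classes and the random farm effect set to 0.
#'
#' @param intercept model intercept, kg.
#' @param genotype_effect named numeric, one entry per genotype class
#'   (see [genotype_levels()]); `BS` must be 0.
#' @param parity_effect named numeric, one entry per parity class;
#'   `P5plus` must be 0.
#' @param pooled_slope named numeric of regression slopes, one entry per
#'   measurement in `model_spec`.
#' @param genotype_slope numeric matrix of slope deviations, rows =
#'   measurements of `model_spec`, columns = genotype classes; the `BS`
#'   column must be 0.
#' @param lactation_curve numeric length 5: polynomial coefficients
#'   (constant first) in days in milk, valid for days 1--364.
#' @param dry_curve numeric length 2: intercept and slope in the (negative)
#'   day relative to calving, valid for days -56 to -1.
#' @param model_spec character vector naming the measurements the equation
#'   requires, in order.
#' @param name optional short label (e.g. `"hgbghw"`).
#' @return an object of class `coefficient_set`.
#' @seealso [bw_model()] for the packaged published equations,
#'   [predict_bw()], [stage_effect()].
#' @export
coefficient_set <- function(intercept, genotype_effect, parity_effect,
                            pooled_slope, genotype_slope,
                            lactation_curve, dry_curve,
                            model_spec, name = NULL) {
  obj <- structure(
    list(name = name,
         model_spec = as.character(model_spec),
         intercept = as.numeric(intercept),
         genotype_effect = unlist(genotype_effect)[genotype_levels()],
         parity_effect = unlist(parity_effect)[parity_levels()],
         pooled_slope = unlist(pooled_slope)[as.character(model_spec)],
         genotype_slope = as.matrix(genotype_slope)[as.character(model_spec),
                                                    genotype_levels(),
                                                    drop = FALSE],
         lactation_curve = as.numeric(lactation_curve),
         dry_curve = as.numeric(dry_curve)),
    class = "coefficient_set")
  validate_coefficient_set(obj)
  obj
}

validate_coefficient_set <- function(x) {
  stopifnot(inherits(x, "coefficient_set"))
  if (length(x$model_spec) < 1 || anyDuplicated(x$model_spec))
    stop("model_spec must be a non-empty list of distinct measurements")
  if (length(x$intercept) != 1 || is.na(x$intercept))
    stop("intercept must be a single number")
  if (any(is.na(x$genotype_effect)) ||
      !identical(names(x$genotype_effect), genotype_levels()))
    stop("genotype_effect must name all genotype classes")
  if (x$genotype_effect[["BS"]] != 0)
    stop("reference class violation: genotype_effect[BS] must be 0")
  if (any(is.na(x$parity_effect)) ||
      !identical(names(x$parity_effect), parity_levels()))
    stop("parity_effect must name all parity classes")
  if (x$parity_effect[["P5plus"]] != 0)
    stop("reference class violation: parity_effect[P5plus] must be 0")
  if (any(is.na(x$pooled_slope)))
    stop("every measurement in model_spec needs a pooled slope")
  if (any(is.na(x$genotype_slope)))
    stop("genotype_slope must be complete over model_spec x genotype classes")
  if (any(x$genotype_slope[, "BS"] != 0))
    stop("reference class violation: genotype_slope[, BS] must be 0")
  if (length(x$lactation_curve) != 5)
    stop("lactation_curve must have 5 polynomial coefficients")
  if (length(x$dry_curve) != 2)
    stop("dry_curve must have 2 coefficients")
  invisible(x)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Body-weight prediction equation",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  measurements:", paste(x$model_spec, collapse = ", "), "\n")
  cat("  intercept:", format(x$intercept), "kg\n")
  cat("  genotype effects (kg):\n")
  print(round(x$genotype_effect, 4))
  cat("  parity effects (kg):\n")
  print(round(x$parity_effect, 4))
  cat("  pooled slopes (kg/cm):\n")
  print(round(x$pooled_slope, 4))
  cat("  genotype-specific slope deviations (kg/cm):\n")
  print(round(x$genotype_slope, 4))
  cat("  lactation stage curve (DIM 1-364):",
      paste(format(x$lactation_curve, digits = 6), collapse = ", "), "\n")
  cat("  dry stage curve (day -56..-1):",
      paste(format(x$dry_curve, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a coefficient set as structured text
#'
#' Coefficient sets are serialized as YAML with nested maps, preserving
#' full double precision so a write/read round trip is bit-exact.
#'
#' @param x a [coefficient_set()].
#' @param path file path.
#' @return `read_coefficient_set()` returns a `coefficient_set`;
#'   `write_coefficient_set()` returns `path` invisibly.
#' @export
write_coefficient_set <- function(x, path) {
  validate_coefficient_set(x)
  # 15 significant digits round-trip all packaged constants bit-exactly
  # while keeping the text file readable
  writeLines(yaml::as.yaml(cs_to_list(x), precision = 15), path)
  invisible(path)
}

cs_to_list <- function(x) {
  out <- list(
    name = x$name,
    model_spec = as.list(x$model_spec),
    intercept = x$intercept,
    genotype_effect = as.list(x$genotype_effect),
    parity_effect = as.list(x$parity_effect),
    pooled_slope = as.list(x$pooled_slope),
    genotype_slope = lapply(seq_along(x$model_spec), function(i)
      as.list(stats::setNames(x$genotype_slope[i, ], colnames(x$genotype_slope)))),
    lactation_curve = as.list(x$lactation_curve),
    dry_curve = as.list(x$dry_curve))
  names(out$genotype_slope) <- x$model_spec
  out
}

cs_from_list <- function(raw) {
  ms <- unlist(raw$model_spec)
  gs <- do.call(rbind, lapply(raw$genotype_slope, function(r) unlist(r)))
  rownames(gs) <- ms
  coefficient_set(
    intercept = raw$intercept,
    genotype_effect = unlist(raw$genotype_effect),
    parity_effect = unlist(raw$parity_effect),
    pooled_slope = unlist(raw$pooled_slope),
    genotype_slope = gs,
    lactation_curve = unlist(raw$lactation_curve),
    dry_curve = unlist(raw$dry_curve),
    model_spec = ms,
    name = raw$name)
}

#' @rdname write_coefficient_set
#' @export
read_coefficient_set <- function(path) {
  cs_from_list(yaml::read_yaml(path))
}

#' Packaged published prediction equations
#'
#' Loads one of the two published coefficient sets shipped with the
#' package: `"hgbg"` (heart girth + belly girth) or `"hgbghw"` (heart
#' girth + belly girth + hip width). Both include genotype-specific
#' slopes, parity effects and the fitted lactation/dry stage curves, in
#' the original units (kg, cm).
#'
#' @param name `"hgbg"` or `"hgbghw"`.
#' @return a [coefficient_set()].
#' @examples
#' m <- bw_model("hgbghw")
#' stage_effect(-56, "dry", m)
#' @export
bw_model <- function(name = c("hgbghw", "hgbg")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("model_", name, ".yml"),
                      package = "cowbw", mustWork = TRUE)
  read_coefficient_set(path)
}
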