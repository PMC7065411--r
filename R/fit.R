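#' Specification of a candidate prediction model
#'
#' @param measurements character vector of trait abbreviations (subset of
#'   [trait_names()]), in order.
#' @param genotype_specific add genotype-specific slope deviations for
#'   every measurement (the advanced model) or pooled slopes only (the
#'   basic model).
#' @param quadratic also include squared measurement terms. Supported for
#'   exploration; quadratic effects did not improve prediction in the
#'   study population and are excluded from the packaged equations.
#' @return a list of class `bw_model_spec`.
#' @export
model_spec <- function(measurements, genotype_specific = TRUE,
                       quadratic = FALSE) {
  measurements <- as.character(measurements)
  if (length(measurements) < 1 || anyDuplicated(measurements))
    stop("measurements must be a non-empty list without duplicates")
  unknown <- setdiff(measurements, trait_names())
  if (length(unknown) > 0)
    stop("unknown measurement(s): ", paste(unknown, collapse = ", "))
  structure(list(measurements = measurements,
                 genotype_specific = isTRUE(genotype_specific),
                 quadratic = isTRUE(quadratic)),
            class = "bw_model_spec")
}

# factor-coded model frame shared by fit and LSM computation
fit_frame <- function(records, spec) {
  records <- as.data.frame(records)
  need <- c("farm_id", "genotype", "day", "bw", spec$measurements)
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  if (!"parity_class" %in% names(records)) {
    if (!"parity" %in% names(records))
      stop("records lack required column(s): parity_class")
    records$parity_class <- classify_parity(records$parity)
  }
  d <- data.frame(
    bw = as.numeric(records$bw),
    farm_id = factor(records$farm_id),
    genotype = factor(records$genotype, levels = genotype_levels()),
    parity_class = factor(records$parity_class, levels = parity_levels()),
    stage = factor(stage_class(records$day)$label, levels = stage_labels()))
  for (tr in spec$measurements) d[[tr]] <- as.numeric(records[[tr]])
  if (nlevels(droplevels(d$farm_id)) < 2)
    stop("cannot fit: need records from at least 2 farms")
  for (fx in c("genotype", "parity_class", "stage")) {
    empty <- setdiff(levels(d[[fx]]), unique(as.character(d[[fx]])))
    if (length(empty) > 0)
      stop("cannot fit: no records in ", fx, " class(es) ",
           paste(empty, collapse = ", "))
  }
  if (any(is.na(d))) stop("records contain missing values in model columns")
  d
}

fit_formula <- function(spec) {
  terms <- c("genotype", "parity_class", "stage", spec$measurements)
  if (spec$quadratic)
    terms <- c(terms, sprintf("I(%s^2)", spec$measurements))
  if (spec$genotype_specific)
    terms <- c(terms, sprintf("genotype:%s", spec$measurements))
  stats::as.formula(paste("bw ~", paste(terms, collapse = " + "),
                          "+ (1 | farm_id)"))
}

#' Fit a body-weight prediction model by REML
#'
#' Estimates the mixed model
#' \deqn{Y = \mu + G_i + P_j + PS_k + \sum_l b_l X_l
#'   [+ \sum_l b_l(G_i) X_l] + F_m + \varepsilon}
#' with fixed genotype, parity and physiological-stage classes, linear
#' regressions on the chosen body measurements (optionally with
#' genotype-specific slope deviations), and a random farm effect, using
#' REML via [lme4::lmer()]. Reference coding puts Brown Swiss, the oldest
#' parity class and the first lactation month at 0. The fit is completed
#' into a full prediction equation by extracting stage least-squares
#' means, fitting the stage curves and assembling a [coefficient_set()]
#' (see [stage_lsm()], [fit_stage_curves()],
#' [assemble_prediction_model()]).
#'
#' @param records data.frame of weighing records (e.g. a herd from
#'   [simulate_herd()] or [read_records()]): needs `farm_id`, `genotype`,
#'   `parity_class` (or `parity`), `day`, `bw` and the measurements in
#'   `spec`.
#' @param spec a [model_spec()].
#' @return an object of class `bw_fit`: a list with the fitted
#'   `coefficients` ([coefficient_set()]), `fixef`, `farm_variance`,
#'   `residual_variance`, `rmse`, `aic` (REML-based, as the original
#'   mixed-model software reports it), `stage_lsm`, `curve_rmse`,
#'   `n_records`, the `spec`, and the underlying `lmerMod` as `model`.
#' @export
fit_mixed <- function(records, spec) {
  stopifnot(inherits(spec, "bw_model_spec"))
  d <- fit_frame(records, spec)
  fit <- tryCatch(
    lme4::lmer(fit_formula(spec), data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e)))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop("mixed-model fit did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4), collapse = "; "))
  vc <- as.data.frame(lme4::VarCorr(fit))
  farm_var <- vc$vcov[vc$grp == "farm_id"]
  resid_var <- stats::sigma(fit)^2

  lsm <- stage_lsm(fit)
  curves <- fit_stage_curves(lsm)

  out <- structure(list(
    spec = spec,
    model = fit,
    fixef = lme4::fixef(fit),
    farm_variance = farm_var,
    residual_variance = resid_var,
    rmse = sqrt(resid_var),
    aic = stats::AIC(fit),
    stage_lsm = lsm,
    curve_rmse = curves$curve_rmse,
    curves = curves,
    covariate_means = vapply(spec$measurements, function(tr) mean(d[[tr]]),
                             numeric(1)),
    n_records = nrow(d)), class = "bw_fit")
  out$coefficients <- assemble_prediction_model(out)
  out
}

#' @export
print.bw_fit <- function(x, ...) {
  cat("Body-weight mixed-model fit (", x$n_records, " records)\n", sep = "")
  cat("  measurements:", paste(x$spec$measurements, collapse = ", "),
      if (x$spec$genotype_specific) "(genotype-specific slopes)", "\n")
  cat(sprintf("  RMSE: %.2f kg   farm SD: %.2f kg   AIC (REML): %.1f\n",
              x$rmse, sqrt(x$farm_variance), x$aic))
  cat(sprintf("  stage-curve RMSE: lactation %.2f kg, dry %.2f kg\n",
              x$curve_rmse[["lactation"]], x$curve_rmse[["dry"]]))
  invisible(x)
}

#' Least-squares means of the physiological-stage classes
#'
#' Model-adjusted mean body weight of each of the 17 stage classes:
#' genotype and parity classes averaged with equal weight, measurements
#' held at their grand means, farm effect 0 -- the convention of the
#' LSMEANS statement in the mixed-model software the equations originate
#' from (implemented via [emmeans::emmeans()] with asymptotic degrees of
#' freedom; only the means themselves are used downstream).
#'
#' @param fit a `bw_fit` or the underlying `lmerMod`.
#' @return named numeric vector of 17 LSMs (kg), in [stage_labels()]
#'   order.
#' @export
stage_lsm <- function(fit) {
  model <- if (inherits(fit, "bw_fit")) fit$model else fit
  em <- emmeans::emmeans(model, "stage", lmer.df = "asymptotic")
  s <- summary(em)
  stats::setNames(s$emmean, as.character(s$stage))[stage_labels()]
}

#' Fit continuous stage curves to the stage-class least-squares means
#'
#' Ordinary least squares of the 13 lactation LSMs on a fourth-degree
#' polynomial in days in milk and of the 4 dry-period LSMs on a straight
#' line in the day relative to calving, each evaluated at the class
#' midpoint days. A fourth-degree lactation polynomial is needed: degree
#' 2 fits poorly and degree 3 changes curvature prematurely within the
#' lactation window.
#'
#' @param lsm named numeric vector of 17 stage LSMs ([stage_labels()]
#'   order), kg.
#' @param lactation_days,dry_days abscissae of the 13 + 4 classes;
#'   defaults are the class midpoints (see [stage_midpoints()]).
#' @return list with `lactation_curve` (5 coefficients, constant first),
#'   `dry_curve` (2 coefficients), `curve_rmse` (named, kg: root mean
#'   squared residual of each fit) and the `fitted` values.
#' @export
fit_stage_curves <- function(lsm,
                             lactation_days = stage_midpoints("lactation"),
                             dry_days = stage_midpoints("dry")) {
  lsm <- lsm[stage_labels()]
  if (any(is.na(lsm))) stop("need all 17 stage LSMs (13 lactation + 4 dry)")
  yl <- unname(lsm[1:13]); yd <- unname(lsm[14:17])
  if (length(lactation_days) != 13 || length(dry_days) != 4)
    stop("need 13 lactation and 4 dry abscissae")
  d <- lactation_days
  fl <- stats::lm(yl ~ d + I(d^2) + I(d^3) + I(d^4))
  fd <- stats::lm(yd ~ dry_days)
  rmse <- c(lactation = sqrt(mean(stats::resid(fl)^2)),
            dry = sqrt(mean(stats::resid(fd)^2)))
  list(lactation_curve = unname(stats::coef(fl)),
       dry_curve = unname(stats::coef(fd)),
       curve_rmse = rmse,
       fitted = c(stats::setNames(stats::fitted(fl), stage_labels()[1:13]),
                  stats::setNames(stats::fitted(fd), stage_labels()[14:17])))
}

#' Assemble a continuous prediction equation from a mixed-model fit
#'
#' Replaces the categorical stage effect of a fitted model by the
#' continuous stage curves, producing a [coefficient_set()] usable at any
#' day of the lactation or dry window. Because the two curves and the
#' intercept share one additive constant that the data cannot separate,
#' a fixed convention resolves it: the stage values are centered to mean
#' 0 over the 17 class-midpoint days and the remainder is absorbed into
#' the intercept. Predictions at a class's midpoint day agree with the
#' categorical model's predictions to within the curve-fit RMSE.
#'
#' @param fit a `bw_fit` from [fit_mixed()].
#' @return a [coefficient_set()].
#' @export
assemble_prediction_model <- function(fit) {
  stopifnot(inherits(fit, "bw_fit"))
  fe <- fit$fixef
  spec <- fit$spec
  gl <- genotype_levels(); pl <- parity_levels()

  pick <- function(prefix, levels) {
    out <- stats::setNames(numeric(length(levels)), levels)
    for (lv in levels[-1]) {
      nm <- paste0(prefix, lv)
      if (nm %in% names(fe)) out[lv] <- fe[[nm]]
    }
    out
  }
  geno_eff <- pick("genotype", gl)
  par_eff <- pick("parity_class", pl)
  pooled <- stats::setNames(fe[spec$measurements], spec$measurements)
  gs <- matrix(0, length(spec$measurements), length(gl),
               dimnames = list(spec$measurements, gl))
  if (spec$genotype_specific) {
    for (tr in spec$measurements) {
      for (lv in gl[-1]) {
        nm <- paste0("genotype", lv, ":", tr)
        if (nm %in% names(fe)) gs[tr, lv] <- fe[[nm]]
      }
    }
  }

  # constant absorbed by the stage LSMs: equal-weight class effects plus
  # slopes at the covariate grand means
  xbar <- fit$covariate_means[spec$measurements]
  d_bar <- mean(geno_eff + colSums(gs * xbar)) + mean(par_eff) +
    sum(pooled * xbar)
  reps <- c(stage_midpoints("lactation"), stage_midpoints("dry"))
  cv <- fit$curves
  vals <- c(drop(outer(reps[1:13], 0:4, `^`) %*% cv$lactation_curve),
            cv$dry_curve[1] + cv$dry_curve[2] * reps[14:17])
  m <- mean(vals)
  lac <- cv$lactation_curve; lac[1] <- lac[1] - m
  dry <- cv$dry_curve; dry[1] <- dry[1] - m

  coefficient_set(
    intercept = m - d_bar,
    genotype_effect = geno_eff,
    parity_effect = par_eff,
    pooled_slope = pooled,
    genotype_slope = gs,
    lactation_curve = lac,
    dry_curve = dry,
    model_spec = spec$measurements,
    name = paste0("fit_", paste(tolower(spec$measurements), collapse = "")))
}

#' Rank candidate model specifications
#'
#' Fits each candidate on the same records and orders them by fitted
#' RMSE (ties broken by fewer measurements); the REML-based AIC is
#' reported alongside. Candidates whose fit fails are kept in the table
#' with the error message instead of being fatal.
#'
#' @param records weighing records, as for [fit_mixed()].
#' @param candidates list of [model_spec()]s.
#' @return data.frame with one row per candidate (`measurements`,
#'   `n_measurements`, `rmse`, `aic`, `error`), ordered best first, with
#'   the successful fits in attribute `fits`.
#' @export
stepwise_evaluate <- function(records, candidates) {
  if (inherits(candidates, "bw_model_spec")) candidates <- list(candidates)
  rows <- lapply(candidates, function(sp) {
    f <- tryCatch(fit_mixed(records, sp), error = function(e) e)
    if (inherits(f, "error")) {
      list(tab = data.frame(
        measurements = paste(sp$measurements, collapse = "+"),
        n_measurements = length(sp$measurements),
        rmse = NA_real_, aic = NA_real_,
        error = conditionMessage(f), stringsAsFactors = FALSE), fit = NULL)
    } else {
      list(tab = data.frame(
        measurements = paste(sp$measurements, collapse = "+"),
        n_measurements = length(sp$measurements),
        rmse = f$rmse, aic = f$aic, error = NA_character_,
        stringsAsFactors = FALSE), fit = f)
    }
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "tab"))
  ord <- order(is.na(tab$rmse), tab$rmse, tab$n_measurements)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- lapply(rows, `[[`, "fit")[ord]
  tab
}
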