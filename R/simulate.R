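#' Nearest positive semi-definite correlation matrix
#'
#' Correlation targets assembled from separately reported triangles (one
#' per period) need not be positive semi-definite. `repair_correlation()`
#' checks the smallest eigenvalue and, when needed, projects to the
#' nearest PSD correlation matrix (unit diagonal preserved); an already
#' PSD input is returned unchanged.
#'
#' @param m square symmetric matrix with unit diagonal and entries in
#'   `[-1, 1]`.
#' @param tol eigenvalue tolerance below which the matrix counts as
#'   indefinite.
#' @return a valid correlation matrix with the same dimnames.
#' @export
repair_correlation <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-12))
    stop("correlation matrix must be square and symmetric")
  if (any(abs(m) > 1 + 1e-12) || any(abs(diag(m) - 1) > 1e-12))
    stop("correlation matrix entries must lie in [-1, 1] with unit diagonal")
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -tol)
    return(m)
  out <- as.matrix(Matrix::nearPD(m, corr = TRUE, keepDiag = TRUE)$mat)
  dimnames(out) <- dimnames(m)
  out
}

#' Configuration of the synthetic-herd generator
#'
#' Collects every parameter of the generator. The defaults emulate the
#' study population: 167 farms with about 38 cows each and about 7
#' weighings per cow; a genotype mixture of 2604 low-RH Fleckvieh, 773
#' medium-RH and 373 high-RH crosses, 1056 Holstein and 1500 Brown Swiss
#' cows; 10 % of records in the dry period; period-specific trait means,
#' SDs, ranges and correlations (see [measurement_profile()]); and body
#' weight generated from the packaged `hgbghw` equation plus a random
#' farm effect and residual noise whose SD equals that equation's
#' reported model RMSE (30.4 kg; 32.5 kg when `truth` is the `hgbg`
#' equation).
#'
#' @param n_farms number of farms.
#' @param cows_per_farm cows per farm; a single integer, or a length-2
#'   range sampled uniformly per farm.
#' @param records_per_cow weighing records per cow.
#' @param genotype_mixture named proportions over the genotype classes
#'   (must sum to 1).
#' @param dry_fraction probability that a record falls in the dry period.
#' @param parity_mean target mean parity of the truncated-geometric parity
#'   distribution over `1:parity_max`.
#' @param parity_max largest parity.
#' @param lactation_profile,dry_profile measurement profiles, as returned
#'   by [measurement_profile()].
#' @param farm_sd standard deviation of the random farm effect, kg.
#' @param residual_sd residual SD, kg; default depends on `truth` (see
#'   above).
#' @param truth the generating [coefficient_set()].
#' @param stage_days `"uniform"` draws integer days uniformly over each
#'   period's domain; `"midpoint"` places every record at its stage
#'   class's midpoint day (useful for noiseless exactness studies, where
#'   the categorical stage model must hold without within-class
#'   variation).
#' @param max_rejects cap on redraw rounds for the truncated multivariate
#'   normal; exceeded caps signal an infeasible truncation configuration.
#' @param seed integer seed; the whole herd is a deterministic function of
#'   the config including this seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_farms = 167,
                       cows_per_farm = 38,
                       records_per_cow = 7,
                       genotype_mixture = c(FV = 2604, FV_RH_m = 773,
                                            FV_RH_h = 373, HF = 1056,
                                            BS = 1500) / 6306,
                       dry_fraction = 0.10,
                       parity_mean = 3.0,
                       parity_max = 13,
                       lactation_profile = measurement_profile("lactation"),
                       dry_profile = measurement_profile("dry"),
                       farm_sd = 20,
                       residual_sd = NULL,
                       truth = bw_model("hgbghw"),
                       stage_days = c("uniform", "midpoint"),
                       max_rejects = 1000,
                       seed = 1) {
  stage_days <- match.arg(stage_days)
  if (is.null(residual_sd)) {
    residual_sd <- if (identical(truth$name, "hgbg")) 32.5 else 30.4
  }
  if (abs(sum(genotype_mixture) - 1) > 1e-8)
    stop("genotype_mixture must sum to 1")
  if (!all(genotype_levels() %in% names(genotype_mixture)))
    stop("genotype_mixture must name all genotype classes")
  if (farm_sd < 0) stop("farm_sd must be >= 0")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  for (p in list(lactation_profile, dry_profile)) {
    if (any(p$sd <= 0)) stop("all measurement SDs must be > 0")
    if (any(p$upper <= p$lower)) stop("infeasible truncation bounds")
  }
  structure(list(
    n_farms = n_farms, cows_per_farm = cows_per_farm,
    records_per_cow = records_per_cow,
    genotype_mixture = genotype_mixture[genotype_levels()],
    dry_fraction = dry_fraction,
    parity_mean = parity_mean, parity_max = parity_max,
    lactation_profile = lactation_profile, dry_profile = dry_profile,
    farm_sd = farm_sd, residual_sd = residual_sd, truth = truth,
    stage_days = stage_days, max_rejects = max_rejects,
    seed = as.integer(seed)), class = "sim_config")
}

# truncated-geometric parity probabilities with a given mean
parity_probs <- function(mean_target, kmax) {
  mean_k <- function(p) {
    k <- seq_len(kmax)
    w <- p * (1 - p)^(k - 1)
    sum(k * w) / sum(w)
  }
  p <- stats::uniroot(function(p) mean_k(p) - mean_target,
                      c(1e-4, 0.9999), tol = 1e-12)$root
  k <- seq_len(kmax)
  w <- p * (1 - p)^(k - 1)
  w / sum(w)
}

# draw n rows from a truncated MVN by vectorized rejection
rtmvnorm_reject <- function(n, profile, max_rejects) {
  sigma <- diag(profile$sd) %*% repair_correlation(profile$corr) %*%
    diag(profile$sd)
  draw <- function(k) MASS::mvrnorm(k, mu = profile$mean, Sigma = sigma)
  x <- draw(n)
  if (n == 1) x <- matrix(x, nrow = 1)
  bad <- which(rowSums(sweep(x, 2, profile$lower, `<`) |
                       sweep(x, 2, profile$upper, `>`)) > 0)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_rejects)
      stop("truncation bounds rejected all redraws (", max_rejects,
           " rounds); the truncation configuration looks infeasible")
    y <- draw(length(bad))
    if (length(bad) == 1) y <- matrix(y, nrow = 1)
    x[bad, ] <- y
    bad <- bad[rowSums(sweep(y, 2, profile$lower, `<`) |
                       sweep(y, 2, profile$upper, `>`)) > 0]
  }
  colnames(x) <- names(profile$mean)
  x
}

#' Read or write a generator configuration as structured text
#'
#' The whole [sim_config()] -- including the measurement profiles, their
#' correlation matrices and the generating coefficient set -- is
#' serialized as YAML, so a simulation is fully reproducible from the
#' file alone.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  prof_to_list <- function(p) {
    list(mean = as.list(p$mean), sd = as.list(p$sd),
         lower = as.list(p$lower), upper = as.list(p$upper),
         corr = apply(p$corr, 1, as.list, simplify = FALSE))
  }
  out <- list(
    n_farms = config$n_farms,
    cows_per_farm = config$cows_per_farm,
    records_per_cow = config$records_per_cow,
    genotype_mixture = as.list(config$genotype_mixture),
    dry_fraction = config$dry_fraction,
    parity_mean = config$parity_mean,
    parity_max = config$parity_max,
    farm_sd = config$farm_sd,
    residual_sd = config$residual_sd,
    stage_days = config$stage_days,
    max_rejects = config$max_rejects,
    seed = config$seed,
    lactation_profile = prof_to_list(config$lactation_profile),
    dry_profile = prof_to_list(config$dry_profile),
    truth = cs_to_list(config$truth))
  # unlike the packaged constants, derived proportions need all 17
  # significant digits to reload bit-exactly
  writeLines(yaml::as.yaml(out, precision = 17), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  prof_from_list <- function(p) {
    tr <- names(p$mean)
    corr <- do.call(rbind, lapply(p$corr, unlist))
    dimnames(corr) <- list(tr, tr)
    list(mean = unlist(p$mean), sd = unlist(p$sd),
         lower = unlist(p$lower), upper = unlist(p$upper), corr = corr)
  }
  sim_config(
    n_farms = raw$n_farms,
    cows_per_farm = unlist(raw$cows_per_farm),
    records_per_cow = raw$records_per_cow,
    genotype_mixture = unlist(raw$genotype_mixture),
    dry_fraction = raw$dry_fraction,
    parity_mean = raw$parity_mean,
    parity_max = raw$parity_max,
    lactation_profile = prof_from_list(raw$lactation_profile),
    dry_profile = prof_from_list(raw$dry_profile),
    farm_sd = raw$farm_sd,
    residual_sd = raw$residual_sd,
    truth = cs_from_list(raw$truth),
    stage_days = raw$stage_days,
    max_rejects = raw$max_rejects,
    seed = raw$seed)
}

#' Simulate a synthetic herd
#'
#' Draws farms, cows and weighing records with the statistical structure
#' the estimation pipeline assumes: genotype labels from the configured
#' mixture (RH gene fractions uniform within each Fleckvieh subclass's
#' interval), parities from a truncated-geometric distribution, stage days
#' per period, measurements from the period's truncated multivariate
#' normal, and observed body weight as
#' `predict_bw(record, truth) + farm effect + residual`.
#' The realized farm effect and residual of every record are stored in the
#' provenance columns `.farm_effect` and `.residual`, so the generating
#' identity can be reconstructed exactly.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class `cow_herd` (one row per weighing record)
#'   with the identity, class, day, measurement and `bw` columns plus the
#'   provenance columns; the config is attached as attribute `config`.
#' @examples
#' herd <- simulate_herd(sim_config(n_farms = 5, cows_per_farm = 4,
#'                                  records_per_cow = 2, seed = 7))
#' nrow(herd)
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_cows_farm <- if (length(config$cows_per_farm) == 2) {
    sample(config$cows_per_farm[1]:config$cows_per_farm[2],
           config$n_farms, replace = TRUE)
  } else rep(config$cows_per_farm, config$n_farms)
  farm_id <- sprintf("F%03d", seq_len(config$n_farms))
  farm_eff <- stats::rnorm(config$n_farms, 0, config$farm_sd)
  names(farm_eff) <- farm_id

  n_cows <- sum(n_cows_farm)
  cow_farm <- rep(farm_id, n_cows_farm)
  cow_id <- sprintf("AT%06d", seq_len(n_cows))
  geno <- sample(names(config$genotype_mixture), n_cows, replace = TRUE,
                 prob = config$genotype_mixture)
  rh <- rep(NA_real_, n_cows)
  rh[geno == "FV"] <- stats::runif(sum(geno == "FV"), 0, 0.10)
  rh[geno == "FV_RH_m"] <- stats::runif(sum(geno == "FV_RH_m"), 0.10, 0.445)
  rh[geno == "FV_RH_h"] <- stats::runif(sum(geno == "FV_RH_h"), 0.445, 1)
  breed <- ifelse(startsWith(geno, "FV"), "FV", geno)
  parity <- sample(seq_len(config$parity_max), n_cows, replace = TRUE,
                   prob = parity_probs(config$parity_mean, config$parity_max))

  n <- n_cows * config$records_per_cow
  ri <- rep(seq_len(n_cows), each = config$records_per_cow)
  period <- ifelse(stats::runif(n) < config$dry_fraction, "dry", "lactation")
  day <- numeric(n)
  is_l <- period == "lactation"
  if (config$stage_days == "uniform") {
    day[is_l] <- sample(1:364, sum(is_l), replace = TRUE)
    day[!is_l] <- sample(-56:-1, sum(!is_l), replace = TRUE)
  } else {
    day[is_l] <- sample(stage_midpoints("lactation"), sum(is_l), replace = TRUE)
    day[!is_l] <- sample(stage_midpoints("dry"), sum(!is_l), replace = TRUE)
  }
  meas <- matrix(NA_real_, n, length(trait_names()),
                 dimnames = list(NULL, trait_names()))
  if (any(is_l))
    meas[is_l, ] <- rtmvnorm_reject(sum(is_l), config$lactation_profile,
                                    config$max_rejects)
  if (any(!is_l))
    meas[!is_l, ] <- rtmvnorm_reject(sum(!is_l), config$dry_profile,
                                     config$max_rejects)

  herd <- data.frame(
    cow_id = cow_id[ri], farm_id = cow_farm[ri],
    breed = breed[ri], rh_fraction = rh[ri], genotype = geno[ri],
    parity = parity[ri], parity_class = classify_parity(parity[ri]),
    period = period, day = day,
    stage_label = stage_class(day)$label,
    meas,
    stringsAsFactors = FALSE)
  resid <- stats::rnorm(n, 0, config$residual_sd)
  herd$.farm_effect <- unname(farm_eff[herd$farm_id])
  herd$.residual <- resid
  herd$bw <- predict_bw(herd, config$truth) + herd$.farm_effect + resid
  structure(herd, config = config, class = c("cow_herd", "data.frame"))
}

#' Split a herd by cow, not by record
#'
#' Alternative hold-out splitter for simulation studies: partitions the
#' records so that no cow contributes to both subsets.
#'
#' @param records data.frame with a `cow_id` column.
#' @param fraction proportion of cows assigned to the second (validation)
#'   subset, in `(0, 1)`.
#' @param seed optional integer; given the same seed and records the split
#'   is identical on repeated calls.
#' @return list with elements `estimation` and `validation`.
#' @export
split_cow_level <- function(records, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  cows <- sort(unique(as.character(records$cow_id)))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n_val <- max(1, round(fraction * length(cows)))
  val_cows <- sample(cows, n_val)
  list(estimation = records[!records$cow_id %in% val_cows, , drop = FALSE],
       validation = records[records$cow_id %in% val_cows, , drop = FALSE])
}
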