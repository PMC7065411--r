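# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small config for quick structural tests
tiny_config <- function(seed = 42, ...) {
  sim_config(n_farms = 6, cows_per_farm = 5, records_per_cow = 3,
             seed = seed, ...)
}

# noiseless limit: residual SD driven to (almost) zero, no farm effect,
# records at stage-class midpoint days so the categorical stage model is
# exact in the generator
noiseless_config <- function(residual_sd = 1e-8) {
  sim_config(n_farms = 20, cows_per_farm = 15, records_per_cow = 4,
             farm_sd = 0, residual_sd = residual_sd,
             stage_days = "midpoint", seed = 11)
}

noiseless_fit <- function() {
  cached("noiseless_fit", {
    herd <- simulate_herd(noiseless_config())
    suppressWarnings(fit_mixed(herd, model_spec(c("HG", "BG", "HW"))))
  })
}

# moderate realistic herd for fitting behaviour (about 6000 records)
midsize_herd <- function() {
  cached("midsize_herd",
         simulate_herd(sim_config(n_farms = 100, cows_per_farm = 15,
                                  records_per_cow = 4, seed = 7)))
}

# study-scale herd used by the acceptance checks (about 20000 records)
acceptance_herd <- function() {
  cached("acceptance_herd",
         simulate_herd(sim_config(cows_per_farm = 17, records_per_cow = 7,
                                  seed = 1)))
}

acceptance_fit <- function() {
  cached("acceptance_fit",
         fit_mixed(acceptance_herd(), model_spec(c("HG", "BG", "HW"))))
}

# the generating truth shifted to the assembly's centering convention:
# stage values mean 0 over the 17 class-midpoint days, remainder in the
# intercept (the split between intercept and curve constants is not
# separately identifiable from data)
normalize_truth <- function(truth) {
  reps <- c(stage_midpoints("lactation"), stage_midpoints("dry"))
  vals <- c(drop(outer(reps[1:13], 0:4, `^`) %*% truth$lactation_curve),
            truth$dry_curve[1] + truth$dry_curve[2] * reps[14:17])
  m <- mean(vals)
  truth$lactation_curve[1] <- truth$lactation_curve[1] - m
  truth$dry_curve[1] <- truth$dry_curve[1] - m
  truth$intercept <- truth$intercept + m
  truth
}
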