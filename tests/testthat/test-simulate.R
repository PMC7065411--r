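test_that("correlation repair leaves PSD matrices untouched", {
  expect_identical(repair_correlation(diag(4)), diag(4))
  m2 <- matrix(c(1, 0.82, 0.82, 1), 2)
  expect_identical(repair_correlation(m2), m2)
  expect_error(repair_correlation(matrix(c(1, 0.3, 0.5, 1), 2)), "symmetric")
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(repair_correlation(bad), "\\[-1, 1\\]")
})

test_that("indefinite matrices are projected to a nearby correlation matrix", {
  m <- matrix(c(1, 0.9, 0.9,
                0.9, 1, -0.9,
                0.9, -0.9, 1), 3, byrow = TRUE)
  expect_lt(min(eigen(m, only.values = TRUE)$values), 0)
  r <- repair_correlation(m)
  expect_gte(min(eigen(r, only.values = TRUE)$values), -1e-8)
  expect_equal(diag(r), rep(1, 3))
  expect_true(isSymmetric(r))
})

test_that("default trait correlation targets are already valid", {
  # both period matrices are assembled from printed triangles; verify by
  # eigendecomposition that no repair (hence no entry change) is needed
  for (per in c("lactation", "dry")) {
    m <- trait_correlations(per)
    expect_equal(dim(m), c(11, 11))
    expect_true(isSymmetric(m))
    expect_gte(min(eigen(m, only.values = TRUE)$values), 0)
    expect_identical(repair_correlation(m), m)
  }
})

test_that("simulation is a deterministic function of the config", {
  cfg <- tiny_config()
  h1 <- simulate_herd(cfg)
  h2 <- simulate_herd(cfg)
  expect_identical(h1, h2)
  h3 <- simulate_herd(tiny_config(seed = 43))
  expect_false(identical(h1$bw, h3$bw))
  # simulation restores the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_herd(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("observed weight decomposes exactly into signal, farm and residual", {
  h <- simulate_herd(tiny_config())
  truth <- attr(h, "config")$truth
  recon <- predict_bw(h, truth) + h$.farm_effect + h$.residual
  expect_equal(h$bw, recon, tolerance = 1e-12)
  # farm effects are shared within farm
  expect_true(all(tapply(h$.farm_effect, h$farm_id,
                         function(x) length(unique(x))) == 1))
})

test_that("noise-free limit reproduces the generating equation", {
  cfg <- tiny_config(farm_sd = 0, residual_sd = 1e-9)
  h <- simulate_herd(cfg)
  expect_equal(h$bw, predict_bw(h, cfg$truth), tolerance = 1e-6)
})

test_that("measurements respect the configured truncation bounds", {
  h <- simulate_herd(sim_config(n_farms = 30, cows_per_farm = 10,
                                records_per_cow = 3, seed = 5))
  for (per in c("lactation", "dry")) {
    prof <- measurement_profile(per)
    sub <- h[h$period == per, ]
    for (tr in trait_names()) {
      expect_true(all(sub[[tr]] >= prof$lower[[tr]] &
                        sub[[tr]] <= prof$upper[[tr]]),
                  label = paste(per, tr, "within bounds"))
    }
  }
  expect_true(all(h$BCS >= 1 & h$BCS <= 5))
  expect_true(all(h$MUSC >= 1 & h$MUSC <= 10))
})

test_that("simulated moments recover the configured profile", {
  h <- cached("moment_herd",
              simulate_herd(sim_config(n_farms = 80, cows_per_farm = 14,
                                       records_per_cow = 10, seed = 8)))
  lact <- h[h$period == "lactation", ]
  n <- nrow(lact)
  expect_gt(n, 9000)
  prof <- measurement_profile("lactation")
  # headline trait: heart girth mean 210 cm (SD 10.3)
  expect_equal(mean(lact$HG), 210, tolerance = 1 / 210)
  expect_equal(sd(lact$HG), 10.3, tolerance = 1 / 10.3)
  expect_equal(cor(lact$HG, lact$BG), 0.72, tolerance = 0.03 / 0.72)
  for (tr in trait_names()) {
    mu <- prof$mean[[tr]]; s <- prof$sd[[tr]]
    # 4 standard errors, plus a small allowance where the truncation
    # bounds sit close enough to the mean to shift/shrink the moments
    expect_lt(abs(mean(lact[[tr]]) - mu), 4 * s / sqrt(n) + 0.03 * s)
    expect_lt(abs(sd(lact[[tr]]) - s), 4 * s / sqrt(2 * n) + 0.035 * s)
  }
  cm <- cor(as.matrix(lact[, trait_names()]))
  expect_lt(max(abs(cm - prof$corr)), 0.05)
})

test_that("genotype mixture and parity distribution match the configuration", {
  h <- cached("moment_herd",
              simulate_herd(sim_config(n_farms = 80, cows_per_farm = 14,
                                       records_per_cow = 10, seed = 8)))
  cows <- h[!duplicated(h$cow_id), ]
  mix <- table(cows$genotype)[genotype_levels()] / nrow(cows)
  target <- attr(h, "config")$genotype_mixture
  expect_lt(max(abs(mix - target)), 0.03)
  # sampling tolerance: 4 standard errors of the cow-level mean
  expect_lt(abs(mean(cows$parity) - 3.0),
            4 * sd(cows$parity) / sqrt(nrow(cows)))
  expect_true(all(cows$parity >= 1 & cows$parity <= 13))
  # RH fractions stay inside their subclass intervals
  expect_true(all(cows$rh_fraction[cows$genotype == "FV"] <= 0.10))
  with_m <- cows$rh_fraction[cows$genotype == "FV_RH_m"]
  expect_true(all(with_m > 0.10 & with_m <= 0.445))
  expect_true(all(cows$rh_fraction[cows$genotype == "FV_RH_h"] > 0.445))
})

test_that("cow-level split keeps every cow on one side only", {
  h <- simulate_herd(tiny_config())
  sp <- split_cow_level(h, 0.2, seed = 3)
  expect_length(intersect(sp$estimation$cow_id, sp$validation$cow_id), 0)
  expect_equal(nrow(sp$estimation) + nrow(sp$validation), nrow(h))
  sp2 <- split_cow_level(h, 0.2, seed = 3)
  expect_identical(sp$validation$cow_id, sp2$validation$cow_id)
  # 10 single-record cows at 20 % -> 8 + 2
  ten <- data.frame(cow_id = sprintf("C%02d", 1:10), x = 1:10)
  sp3 <- split_cow_level(ten, 0.2, seed = 1)
  expect_equal(nrow(sp3$estimation), 8)
  expect_equal(nrow(sp3$validation), 2)
  expect_error(split_cow_level(ten, 1.2), "fraction")
})

test_that("infeasible truncation bounds fail fast", {
  prof <- measurement_profile("lactation")
  prof$lower["HG"] <- 300 # far above the configured mean of 210
  expect_error(sim_config(lactation_profile = prof), "infeasible|bounds")
  prof2 <- measurement_profile("lactation")
  prof2$lower["HG"] <- 251; prof2$upper["HG"] <- 253
  cfg <- sim_config(n_farms = 2, cows_per_farm = 2, records_per_cow = 2,
                    lactation_profile = prof2, max_rejects = 3)
  expect_error(simulate_herd(cfg), "infeasible")
})

test_that("mixture and noise configuration is validated", {
  expect_error(sim_config(genotype_mixture = c(FV = 1)), "sum to 1|classes")
  expect_error(sim_config(farm_sd = -1), "farm_sd")
  expect_error(sim_config(residual_sd = 0), "residual_sd")
})
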