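test_that("noiseless herds return every identifiable coefficient exactly", {
  f <- noiseless_fit()
  truth <- normalize_truth(bw_model("hgbghw"))
  a <- f$coefficients
  tol <- 1e-6
  expect_lt(max(abs(a$pooled_slope - truth$pooled_slope)), tol)
  expect_lt(max(abs(a$genotype_slope - truth$genotype_slope)), tol)
  expect_lt(max(abs(a$genotype_effect - truth$genotype_effect)), tol)
  expect_lt(max(abs(a$parity_effect - truth$parity_effect)), tol)
  expect_lt(max(abs(a$lactation_curve - truth$lactation_curve)), tol)
  expect_lt(max(abs(a$dry_curve - truth$dry_curve)), tol)
  expect_lt(abs(a$intercept - truth$intercept), tol)
  expect_lt(f$rmse, 1e-6)
  expect_lt(max(f$curve_rmse), 1e-6)
  # and the refit predicts identically to the raw published truth
  fresh <- simulate_herd(tiny_config(seed = 12))
  expect_lt(max(abs(predict_bw(fresh, a) -
                      predict_bw(fresh, bw_model("hgbghw")))), 1e-6)
})

test_that("assembled equation satisfies coefficient-set invariants", {
  a <- noiseless_fit()$coefficients
  expect_identical(a$genotype_effect[["BS"]], 0)
  expect_identical(a$parity_effect[["P5plus"]], 0)
  expect_true(all(a$genotype_slope[, "BS"] == 0))
  expect_s3_class(a, "coefficient_set")
})

test_that("assembled curves agree with the categorical stage model", {
  f <- noiseless_fit()
  herd <- simulate_herd(noiseless_config())
  d <- cowbw:::fit_frame(herd, f$spec)
  categorical <- predict(f$model, newdata = d, re.form = NA)
  continuous <- predict_bw(herd, f$coefficients)
  # records sit at class midpoint days, so the only discrepancy is the
  # curve-fit residual
  expect_lte(mean(abs(continuous - categorical)), max(f$curve_rmse) + 1e-9)
})

test_that("stage curve fitting recovers exact polynomials and closed forms", {
  lab <- stage_labels()
  # degree-4 lactation truth evaluated at the 13 midpoints: exact recovery
  p4 <- c(2.7426, -0.324907, 0.00231406, -0.00000567999, 4.74719e-9)
  dl <- stage_midpoints("lactation")
  yl <- drop(outer(dl, 0:4, `^`) %*% p4)
  # dry: values (4, 8, 12, 16) at days (-49, -35, -21, -7): simple linear
  # regression has slope (4 per 14 days) = 2/7 and intercept
  # mean(y) - slope * mean(day) = 10 + (2/7) * 28 = 18
  lsm <- setNames(c(yl, c(4, 8, 12, 16)), lab)
  cv <- fit_stage_curves(lsm, dry_days = c(-49, -35, -21, -7))
  expect_equal(cv$lactation_curve, p4, tolerance = 1e-8)
  expect_lt(cv$curve_rmse[["lactation"]], 1e-8)
  expect_equal(cv$dry_curve, c(18, 2 / 7), tolerance = 1e-10)
  expect_lt(cv$curve_rmse[["dry"]], 1e-10)
})

test_that("constant stage means yield a flat curve", {
  lsm <- setNames(rep(7.5, 17), stage_labels())
  cv <- fit_stage_curves(lsm)
  expect_equal(cv$lactation_curve, c(7.5, 0, 0, 0, 0), tolerance = 1e-8)
  expect_equal(cv$dry_curve, c(7.5, 0), tolerance = 1e-10)
  expect_error(fit_stage_curves(lsm[1:10]), "17")
})

test_that("stage LSMs shift by exactly c when all weights shift by c", {
  herd <- simulate_herd(sim_config(n_farms = 15, cows_per_farm = 8,
                                   records_per_cow = 3, seed = 21))
  sp <- model_spec("HG", genotype_specific = FALSE)
  f1 <- fit_mixed(herd, sp)
  shifted <- herd
  shifted$bw <- shifted$bw + 50
  f2 <- fit_mixed(shifted, sp)
  expect_equal(unname(f2$stage_lsm - f1$stage_lsm), rep(50, 17),
               tolerance = 1e-8)
})

test_that("stage LSMs match a manual fixed-effect computation", {
  f <- cached("lsm_fit", {
    herd <- midsize_herd()
    fit_mixed(herd, model_spec(c("HG", "BG", "HW")))
  })
  fe <- f$fixef
  gl <- genotype_levels(); pl <- parity_levels()
  g_eff <- c(0, fe[paste0("genotype", gl[-1])])
  p_eff <- c(0, fe[paste0("parity_class", pl[-1])])
  xbar <- f$covariate_means
  slope_terms <- sum(fe[names(xbar)] * xbar)
  inter_by_geno <- vapply(gl, function(g) {
    if (g == gl[1]) return(0)
    sum(fe[paste0("genotype", g, ":", names(xbar))] * xbar)
  }, numeric(1))
  base <- unname(fe["(Intercept)"] + mean(g_eff + inter_by_geno) +
                   mean(p_eff) + slope_terms)
  ps <- c(0, fe[paste0("stage", stage_labels()[-1])])
  expect_equal(unname(f$stage_lsm), unname(base + ps), tolerance = 1e-8)
})

test_that("estimated stage profile tracks the generating curve", {
  f <- cached("lsm_fit", {
    herd <- midsize_herd()
    fit_mixed(herd, model_spec(c("HG", "BG", "HW")))
  })
  truth <- bw_model("hgbghw")
  # class means of the generating polynomial by direct averaging over the
  # integer days of each class (the LSM carries an arbitrary constant, so
  # compare centered profiles)
  cls <- stage_class(c(1:364, -56:-1))
  val <- c(stage_effect(1:364, "lactation", truth),
           stage_effect(-56:-1, "dry", truth))
  target <- tapply(val, cls$label, mean)[stage_labels()]
  est <- f$stage_lsm
  expect_lt(max(abs((est - mean(est)) - (target - mean(target)))), 5)
})

test_that("slope recovery from a realistic herd is unbiased at herd scale", {
  f <- cached("lsm_fit", {
    herd <- midsize_herd()
    fit_mixed(herd, model_spec(c("HG", "BG", "HW")))
  })
  truth <- bw_model("hgbghw")
  expect_lt(max(abs(f$coefficients$pooled_slope - truth$pooled_slope)), 0.4)
  expect_equal(f$rmse, 30.4, tolerance = 1.5 / 30.4)
  expect_gte(f$farm_variance, 0)
})

test_that("configured farm spread is reflected in the variance component", {
  fits <- lapply(c(5, 40), function(fs) {
    herd <- simulate_herd(sim_config(n_farms = 40, cows_per_farm = 10,
                                     records_per_cow = 3, farm_sd = fs,
                                     seed = 31))
    fit_mixed(herd, model_spec("HG", genotype_specific = FALSE))
  })
  expect_lt(fits[[1]]$farm_variance, fits[[2]]$farm_variance)
})

test_that("stepwise ranking mirrors the predictive ordering of the girths", {
  herd <- midsize_herd()
  cands <- list(model_spec("ST"), model_spec("HG"),
                model_spec(c("HG", "BG")), model_spec(c("HG", "BG", "HW")))
  tab <- cached("stepwise_tab", stepwise_evaluate(herd, cands))
  expect_equal(nrow(tab), 4)
  # heart girth beats stature as a single predictor
  expect_lt(tab$rmse[tab$measurements == "HG"],
            tab$rmse[tab$measurements == "ST"])
  # adding belly girth, then hip width, strictly reduces RMSE
  r1 <- tab$rmse[tab$measurements == "HG"]
  r2 <- tab$rmse[tab$measurements == "HG+BG"]
  r3 <- tab$rmse[tab$measurements == "HG+BG+HW"]
  expect_true(r3 < r2 && r2 < r1)
  expect_equal(tab$measurements[1], "HG+BG+HW")
  # single candidate -> ranking of length 1
  one <- stepwise_evaluate(herd, list(model_spec("HG")))
  expect_equal(nrow(one), 1)
})

test_that("failed candidates are recorded, not fatal", {
  herd <- midsize_herd()
  broken <- herd
  broken$PW <- NULL
  tab <- stepwise_evaluate(broken, list(model_spec("HG"), model_spec("PW")))
  expect_equal(sum(is.na(tab$rmse)), 1)
  expect_match(tab$error[is.na(tab$rmse)], "PW")
  expect_false(is.na(tab$rmse[1]))
})

test_that("degenerate designs fail with a named cause", {
  herd <- simulate_herd(tiny_config())
  no_bs <- herd[herd$genotype != "BS", ]
  expect_error(fit_mixed(no_bs, model_spec("HG")), "BS")
  one_farm <- herd[herd$farm_id == herd$farm_id[1], ]
  expect_error(fit_mixed(one_farm, model_spec("HG")), "2 farms")
  expect_error(fit_mixed(herd[, setdiff(names(herd), "bw")],
                         model_spec("HG")), "bw")
})
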