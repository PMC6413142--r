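test_that("the one-call fit reproduces the generating model end to end", {
  lfl <- synthetic_pure_lfl()
  desc <- builtin_components()
  desc$pure_lfl <- unname(lfl[desc$component_id])
  desc$recip_lfl <- 1 / desc$pure_lfl
  d <- generate_dataset(lfl, deviation_amplitude = 0,
                        noise_sd = 0, n = 181, seed = 3)

  # the generating law is recovered exactly on the reciprocal scale:
  # 1/LFL of a Le Chatelier mixture is the molar blend of the pure 1/LFLs
  mm <- build_mixture_matrix(d, desc, rule = "fmol_sum")
  mm$y <- 1 / mm$y
  exact <- fit_mlr(mm, "recip_lfl")
  expect_equal(exact$stats$r2, 1, tolerance = 1e-10)
  expect_equal(unname(exact$coefficients), 1, tolerance = 1e-6)
  expect_equal(exact$intercept, 0, tolerance = 1e-6)

  # a linear norm_cont model approximates the same curves well but not
  # perfectly: the backbone is intrinsically nonlinear in these features
  fit <- qspr_lfl(d, desc, rule = "norm_cont",
                  subset = c(model_descriptor_names(), "pure_lfl"),
                  split = 0.8, split_seed = 2)
  expect_s3_class(fit, "qspr_lfl")
  expect_gt(fit$validation$q2_ext, 0.85)
  expect_gt(fit$stats$r2, 0.95)
})

test_that("with experimental-scale noise the test error tracks the noise", {
  desc <- builtin_components()
  desc$pure_lfl <- unname(synthetic_pure_lfl()[desc$component_id])
  aaes <- vapply(1:3, function(seed) {
    d <- generate_dataset(synthetic_pure_lfl(), noise_sd = 0.1,
                          n = 181, seed = seed)
    fit <- qspr_lfl(d, desc, subset = c(model_descriptor_names(), "pure_lfl"),
                    split = 0.8, split_seed = seed)
    fit$validation$aae_test
  }, numeric(1))
  expect_true(all(aaes < 0.2))   # within a factor 2 of the 0.1 vol% noise
  expect_true(all(aaes > 0.05))
})

test_that("deviation rules are modelled against the deviation target", {
  lfl <- synthetic_pure_lfl()
  d <- generate_dataset(lfl, n = 150, seed = 9)
  mm <- build_mixture_matrix(d, builtin_components(), rule = "mol_dev",
                             pure_lfl = lfl)
  expect_equal(mm$target, "deviation")
  expect_equal(mm$y,
               unname(deviation_target(d$lfl_exp, lfl[d$comp1],
                                       lfl[d$comp2], d$x1)),
               tolerance = 1e-12)
  expect_error(build_mixture_matrix(d, builtin_components(),
                                    rule = "mol_dev"), "pure_lfl")
  # direct rules keep the raw LFL
  mm2 <- build_mixture_matrix(d, builtin_components(), rule = "norm_cont")
  expect_equal(mm2$target, "lfl")
  expect_equal(mm2$y, d$lfl_exp)
})

test_that("fit methods: coef, predict, residuals, summary, simulate", {
  planted <- planted_norm_cont_data(n_desc = 8, n_true = 3, seed = 15,
                                    noise_sd = 0.1, n_records = 140)
  rec <- planted$mm$records
  shift <- 1 - min(planted$mm$y)   # keep LFL positive; shift is absorbed
  rec$lfl_exp <- planted$mm$y + shift
  fit <- qspr_lfl(rec, planted$descriptors, subset = planted$truth,
                  split = 0.8)
  expect_named(coef(fit)[-1], planted$truth)
  expect_length(fitted(fit), 112L)          # round(0.8 * 140)
  expect_equal(fitted(fit) + residuals(fit),
               planted$mm$y[fit$split$train] + shift)
  # predict on new records equals the linear form
  pred <- predict(fit, rec[1:7, ], descriptors = planted$descriptors)
  mmn <- build_mixture_matrix(rec[1:7, ], planted$descriptors, "norm_cont")
  expect_equal(unname(pred),
               unname(drop(cbind(1, mmn$X[, planted$truth]) %*% coef(fit))))

  s <- summary(fit)
  expect_s3_class(s, "summary.qspr_lfl")
  expect_equal(sum(abs(s$mean_effects)), 100, tolerance = 1e-9)
  expect_output(print(s), "Q2_LOO")
  expect_output(print(fit), "Mixing rule")

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(112L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))

  ad <- plot(fit)   # Williams plot returns the AD report invisibly
  expect_s3_class(ad, "ad_report")
  expect_equal(nrow(ad$table), 140L)
})

test_that("GA selection inside the wrapper finds the planted subset", {
  planted <- planted_norm_cont_data(n_desc = 10, n_true = 3, seed = 33,
                                    n_records = 130)
  rec <- planted$mm$records
  rec$lfl_exp <- planted$mm$y - min(planted$mm$y) + 1
  fit <- qspr_lfl(rec, planted$descriptors, subset = NULL,
                  ga = ga_control(population_size = 24, generations = 20,
                                  subset_size = 3, seed = 8))
  expect_setequal(fit$subset, planted$truth)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-9)
  expect_true(all(diff(fit$trace) >= 0))
})
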