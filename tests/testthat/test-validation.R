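test_that("error metrics match hand arithmetic", {
  y <- c(1, 2, 3); yhat <- y - c(0.1, -0.2, 0.3)
  expect_equal(aae(y, yhat), 0.2)
  expect_equal(rmse(y, yhat), sqrt(0.14 / 3))
  expect_equal(aae(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(aae(2.0, 2.5), 0.5)
  expect_equal(rmse(c(1, 2), c(1.3, 2.3)), 0.3)
  expect_error(aae(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
  # AAE <= RMSE with equality iff all absolute residuals agree
  withr::with_seed(4, {
    for (i in 1:50) {
      r <- rnorm(10)
      expect_lte(aae(r, numeric(10)), rmse(r, numeric(10)) + 1e-12)
    }
  })
})

test_that("Q2_LOO: exact fits, shortcut/refit identity and noise behaviour", {
  mm <- rand_mm(40, 3, seed = 2, beta = c(D1 = 1, D2 = 2))
  expect_equal(q2_loo(mm), 1, tolerance = 1e-10)

  for (seed in 1:10) {
    mm <- rand_mm(50, 6, seed = seed,
                  beta = setNames(runif(3), paste0("D", 1:3)),
                  noise_sd = 0.5)
    expect_equal(q2_loo(mm, method = "shortcut"),
                 q2_loo(mm, method = "refit"), tolerance = 1e-10)
    # PRESS >= SSres, so Q2_LOO never exceeds R2
    expect_lte(q2_loo(mm), fit_mlr(mm)$stats$r2)
  }

  # pure-noise responses cross-validate at or below zero in expectation
  q2 <- vapply(1:100, function(seed) {
    q2_loo(rand_mm(30, 3, seed = 1000 + seed))
  }, numeric(1))
  expect_lt(mean(q2), 0)
})

test_that("points-out split has the stated arithmetic and determinism", {
  s <- points_out_split(181, seed = 3)
  expect_length(s$train, 145L)
  expect_length(s$test, 36L)
  expect_setequal(c(s$train, s$test), 1:181)

  s10 <- points_out_split(10, seed = 1)
  expect_length(s10$train, 8L)
  expect_length(s10$test, 2L)

  expect_identical(points_out_split(100, seed = 9),
                   points_out_split(100, seed = 9))
  expect_false(identical(points_out_split(100, seed = 9)$train,
                         points_out_split(100, seed = 10)$train))
  expect_error(points_out_split(4), "at least 5")
})

test_that("external Q2 uses the training mean in its denominator", {
  expect_equal(q2_ext(c(2, 3), c(2.1, 2.9), 2.5), 1 - 0.02 / 0.5)
  expect_equal(q2_ext(c(2, 3), c(2, 3), 2.5), 1)
  expect_equal(q2_ext(c(2, 3), c(2.5, 2.5), 2.5), 0)
  # invariant to test-set ordering
  withr::with_seed(11, {
    y <- rnorm(20, 3); yh <- y + rnorm(20, sd = 0.2)
    o <- sample(20)
  })
  expect_equal(q2_ext(y, yh, 2.8), q2_ext(y[o], yh[o], 2.8))
  expect_error(q2_ext(c(2, 2), c(1, 3), 2), "degenerate")
})

test_that("rm2 rewards identity and penalizes systematic offset", {
  withr::with_seed(5, y <- rnorm(15, 3))
  expect_equal(rm2(y, y), 1)
  shifted <- rm2(y, y + 0.8)
  r2 <- cor(y, y + 0.8)^2   # correlation untouched by the shift
  expect_lt(shifted, r2)
  # uncorrelated predictions give near-zero rm2 in expectation
  vals <- vapply(1:200, function(s) {
    withr::with_seed(3000 + s, rm2(rnorm(25), rnorm(25)))
  }, numeric(1))
  expect_lt(mean(vals), 0.15)
  expect_error(rm2(1:2, 1:2), "at least 3")
})

test_that("Y-randomization separates real signal from shuffled responses", {
  planted <- planted_norm_cont_data(n_desc = 8, n_true = 3, seed = 17,
                                    noise_sd = 0.1, n_records = 120)
  fit <- fit_mlr(planted$mm, planted$truth)
  yr <- y_randomization(planted$mm, subset = planted$truth,
                        runs = 60, seed = 5)
  expect_length(yr$r2_random, 60L)
  expect_true(all(yr$r2_random < yr$r2_original))
  expect_gt(yr$distance, 3)
  expect_gte(yr$distance, yr$distance_max)
  expect_equal(yr$mean, mean(yr$r2_random))
  expect_output(print(yr), "distance")

  # a response that is already noise shows no significant distance
  noise_mm <- rand_mm(100, 5, seed = 23)
  yr0 <- y_randomization(noise_mm, subset = paste0("D", 1:3),
                         runs = 60, seed = 6)
  expect_lt(abs(yr0$distance), 3)

  expect_error(y_randomization(noise_mm, subset = "D1", runs = 10),
               "at least 50")
})

test_that("Y-randomization can rerun subset selection per shuffle", {
  planted <- planted_norm_cont_data(n_desc = 6, n_true = 2, seed = 29,
                                    noise_sd = 0.15, n_records = 90)
  yr <- y_randomization(planted$mm, subset = NULL,
                        ga = ga_control(population_size = 8,
                                        generations = 4, subset_size = 2,
                                        seed = 1),
                        runs = 50, seed = 2)
  expect_gt(yr$distance, 3)
  # selection bias: reselected random models fit better than a fixed subset
  yr_fixed <- y_randomization(planted$mm, subset = planted$truth,
                              runs = 50, seed = 2)
  expect_gte(yr$mean, yr_fixed$mean)
})
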