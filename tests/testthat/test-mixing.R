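test_that("the rule catalogue has the 6/3/3 class structure", {
  rules <- mixing_rules()
  expect_equal(nrow(rules), 12L)
  expect_equal(sum(rules$class == "direct"), 6L)
  expect_equal(sum(rules$class == "deviation"), 3L)
  expect_equal(sum(rules$class == "other"), 3L)
  expect_equal(rule_class("norm_cont"), "direct")
  expect_equal(rule_class("mol_dev"), "deviation")
  expect_equal(rule_class("cent"), "other")
})

test_that("mixing formulas match hand arithmetic", {
  d1 <- c(D = 2); d2 <- c(D = 4)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "fmol_sum")[1]), 3.4)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "norm_cont")[1]),
               sqrt(0.36 + 7.84))
  expect_equal(unname(mix_descriptors(d1, d2, 0.5, "cent")[1]), 3)
  expect_equal(unname(mix_descriptors(d1, d2, 0.5, "sqr_diff")[1]), 4)
  expect_equal(unname(mix_descriptors(d1, d2, 0.5, "abs_diff")[1]), 2)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "fmol_diff")[1]),
               abs(0.3 * 2 - 0.7 * 4))
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "sqr_fmol")[1]),
               0.09 * 2 + 0.49 * 4)
  expect_equal(unname(mix_descriptors(d1, d2, 0.25, "root_fmol")[1]),
               0.5 * 2 + sqrt(0.75) * 4)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "sqr_fmol_sum")[1]), 3.4^2)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "mol_dev")[1]),
               (1 - 0.4) * 2)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "sqr_mol_dev")[1]),
               (1 - 0.16) * 2)
  expect_equal(unname(mix_descriptors(d1, d2, 0.3, "mol_dev_sqr")[1]),
               0.36 * 2)
})

test_that("identical components are fixed points of averaging rules", {
  d <- c(A = 1.7, B = -0.4)
  expect_equal(unclass(mix_descriptors(d, d, 0.5, "fmol_sum"))[1:2], d)
  expect_equal(unclass(mix_descriptors(d, d, 0.5, "cent"))[1:2], d)
  expect_equal(unname(mix_descriptors(d, d, 0.5, "abs_diff")[1:2]), c(0, 0))
})

test_that("all twelve rules are component-swap symmetric (random cases)", {
  rules <- mixing_rules()$rule
  withr::with_seed(42, {
    for (case in 1:200) {
      d1 <- c(D = runif(1, -5, 5)); d2 <- c(D = runif(1, -5, 5))
      x1 <- runif(1)
      for (r in rules) {
        expect_equal(unname(mix_descriptors(d1, d2, x1, r)[1]),
                     unname(mix_descriptors(d2, d1, 1 - x1, r)[1]),
                     tolerance = 1e-12, label = r)
      }
    }
  })
})

test_that("pure limits behave as the formulas dictate", {
  d1 <- c(D = 2.5); d2 <- c(D = 0.7)
  expect_equal(unname(mix_descriptors(d1, d2, 1, "mol_dev")[1]), 0)
  expect_equal(unname(mix_descriptors(d1, d2, 0, "mol_dev_sqr")[1]), 0)
  expect_equal(unname(mix_descriptors(d1, d2, 1, "fmol_sum")[1]), 2.5)
  expect_equal(unname(mix_descriptors(d1, d2, 0, "fmol_sum")[1]), 0.7)
  # equimolar molar contribution coincides with the centroid
  expect_equal(unname(mix_descriptors(d1, d2, 0.5, "fmol_sum")[1]),
               unname(mix_descriptors(d1, d2, 0.5, "cent")[1]))
})

test_that("vectorised mixing equals a naive scalar loop", {
  withr::with_seed(7, {
    nm <- paste0("d", 1:10)
    d1 <- setNames(runif(10, -3, 3), nm)
    d2 <- setNames(runif(10, -3, 3), nm)
    x1 <- 0.37
  })
  for (r in mixing_rules()$rule) {
    got <- mix_descriptors(d1, d2, x1, r)
    ref <- vapply(nm, function(k) {
      unname(mix_descriptors(d1[k], d2[k], x1, r)[1])
    }, numeric(1))
    expect_equal(unclass(got)[nm], ref, tolerance = 1e-12, label = r)
  }
})

test_that("schema and range errors are raised", {
  expect_error(mix_descriptors(c(A = 1), c(B = 1), 0.5), "same descriptors")
  expect_error(mix_descriptors(c(A = 1), c(A = 1), 1.2), "mole fraction")
})

test_that("deviation target subtracts the linear blend", {
  expect_equal(deviation_target(3.0, 2.0, 4.0, 0.5), 0)
  expect_equal(deviation_target(2.8, 2.0, 4.0, 0.5), -0.2)
  expect_equal(deviation_target(2.0 * 0.3 + 4.0 * 0.7, 2.0, 4.0, 0.3), 0)
  expect_error(deviation_target(3, -1, 4, 0.5), "positive")
})

test_that("Le Chatelier rule interpolates between the pure limits", {
  expect_equal(le_chatelier(2, 4, 0.5), 1 / (0.25 + 0.125))
  expect_equal(le_chatelier(2, 4, 1), 2)
  expect_equal(le_chatelier(2, 4, 0), 4)
  expect_equal(le_chatelier(3, 3, 0.31), 3)
  withr::with_seed(13, {
    for (i in 1:100) {
      l1 <- runif(1, 1, 5); l2 <- runif(1, 1, 5); x <- runif(1)
      v <- le_chatelier(l1, l2, x)
      expect_gte(v, min(l1, l2) - 1e-12)
      expect_lte(v, max(l1, l2) + 1e-12)
    }
  })
  expect_error(le_chatelier(-1, 2, 0.5), "positive")
  expect_error(le_chatelier(1, 2, 1.5), "\\[0, 1\\]")
})
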