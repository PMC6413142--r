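# brute-force topological distances used as the in-test oracle
floyd_dist <- function(graph) {
  n <- n_atoms(graph)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (b in seq_len(nrow(graph$bonds))) {
    D[graph$bonds$i[b], graph$bonds$j[b]] <- 1
    D[graph$bonds$j[b], graph$bonds$i[b]] <- 1
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  }
  D
}

test_that("intrinsic states match hand evaluation of the Kier-Hall formula", {
  expect_equal(intrinsic_states(parse_smiles("CC")), c(2, 2))
  expect_equal(intrinsic_states(parse_smiles("C=C")), c(3, 3))
  expect_equal(intrinsic_states(parse_smiles("CCCC")), c(2, 1.5, 1.5, 2))
  # methane: isolated heavy atom, delta -> max(delta, 1) convention
  expect_equal(intrinsic_states(parse_smiles("C")), 1)
})

test_that("rotatable bond count follows the nonterminal single-bond rule", {
  expect_equal(rbn(parse_smiles("C")), 0L)
  expect_equal(rbn(parse_smiles("CCCC")), 1L)
  expect_equal(rbn(parse_smiles("CC(C)C")), 0L)
  expect_equal(rbn(parse_smiles("C=CC=C")), 1L)   # conjugated but rotatable
  expect_equal(rbn(parse_smiles("C#C")), 0L)
  expect_equal(rbn(parse_smiles("CCCCCC")), 3L)
  expect_equal(rbn(parse_smiles("C1CCCCC1")), 0L) # ring bonds excluded
})

test_that("MAXDP equals the brute-force pairwise perturbation maximum", {
  expect_equal(maxdp(parse_smiles("CC")), 0)
  expect_equal(maxdp(parse_smiles("C=C")), 0)

  for (s in c("CCC", "CCCC", "CC(C)C", "CC=C", "C=CC=C", "CCC=C")) {
    g <- parse_smiles(s)
    I <- intrinsic_states(g)
    D <- floyd_dist(g)
    dI <- sapply(seq_along(I), function(i) {
      sum((I[i] - I[-i]) / (D[i, -i] + 1)^2)
    })
    expect_equal(maxdp(g), max(c(dI[dI > 0], 0)), label = s)
  }
  expect_equal(maxdp(parse_smiles("C")), 0)
})

test_that("Psi_i_0 is the inverse-sqrt intrinsic-state sum", {
  expect_equal(psi_i_0(parse_smiles("CC")), 2 / sqrt(2))
  expect_equal(psi_i_0(parse_smiles("C=C")), 2 / sqrt(3))
  # all atoms at I = 1 sum to the atom count (methane convention)
  expect_equal(psi_i_0(parse_smiles("C")), 1)
})

test_that("Burden eigenvalues follow the stated matrix convention", {
  expect_equal(spmax_bh(parse_smiles("CC"), k = 1), 1.1)
  expect_equal(spmax_bh(parse_smiles("C"), k = 4), 0)     # padding
  expect_equal(spmax_bh(parse_smiles("CCC"), k = 4), 0)   # padding
  # independent eigen computation for butane
  g <- parse_smiles("CCCC")
  B <- matrix(0.001, 4, 4); diag(B) <- 1
  B[1, 2] <- B[2, 1] <- B[2, 3] <- B[3, 2] <- B[3, 4] <- B[4, 3] <- 0.1
  ev <- sort(eigen(B, symmetric = TRUE)$values, decreasing = TRUE)
  for (k in 1:4) expect_equal(spmax_bh(g, k), ev[k])
  # eigenvalues real and non-increasing in k
  vals <- sapply(1:4, spmax_bh, graph = g)
  expect_true(all(diff(vals) <= 0))
  expect_error(spmax_bh(g, k = 0), "positive")
})

test_that("3D-MoRSE matches its closed form and invariances", {
  expect_equal(morse(embed_molecule(parse_smiles("C")), 24), 0)

  g <- embed_molecule(parse_smiles("C#C"), seed = 2)
  r <- dist(g$coords)[1]
  expect_equal(morse(g, 24, "u"), sin(23 * r) / (23 * r))
  expect_equal(morse(g, 1, "u"), 1)   # s = 0 term is w_i w_j

  g4 <- embed_molecule(parse_smiles("CCCC"), seed = 2)
  for (sig in c(1, 16, 24, 32)) {
    expect_lte(abs(morse(g4, sig, "u")), choose(4, 2))
  }
  # rigid rotation + translation leave the descriptor unchanged
  theta <- 0.71
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  g4rot <- g4
  g4rot$coords <- g4$coords %*% R + matrix(c(1, -2, 0.5), 4, 3, byrow = TRUE)
  expect_equal(morse(g4rot, 24, "u"), morse(g4, 24, "u"))
  expect_equal(morse(g4rot, 16, "m"), morse(g4, 16, "m"))

  # all-carbon molecules: relative mass weighting collapses to unweighted
  expect_equal(morse(g4, 16, "m"), morse(g4, 16, "u"))

  expect_error(morse(parse_smiles("CC"), 24), "coordinates")
  expect_error(morse(g4, 0), "1..32")
})

test_that("topological descriptors are invariant to SMILES atom order", {
  variants <- list(
    c("CCCC", "C(C)CC"),
    c("CC(C)C", "C(C)(C)C"),
    c("C=CC=C", "C(=C)C=C"),
    c("CCC=C", "C=CCC")
  )
  for (v in variants) {
    g1 <- parse_smiles(v[1]); g2 <- parse_smiles(v[2])
    expect_equal(rbn(g1), rbn(g2), label = v[2])
    expect_equal(maxdp(g1), maxdp(g2), label = v[2])
    expect_equal(psi_i_0(g1), psi_i_0(g2), label = v[2])
    expect_equal(spmax_bh(g1, 4), spmax_bh(g2, 4), label = v[2])
  }
})

test_that("the six-descriptor vector is deterministic and complete", {
  v1 <- compute_model_descriptors("CCC=C", seed = 9)
  v2 <- compute_model_descriptors("CCC=C", seed = 9)
  expect_identical(v1, v2)
  expect_named(v1, model_descriptor_names())
  expect_true(all(is.finite(v1)))

  m <- compute_model_descriptors("C")
  expect_equal(unname(m[c("RBN", "Mor24u", "Mor16m")]), c(0, 0, 0))
  expect_equal(unname(compute_model_descriptors("CCCC")[["RBN"]]), 1)
})

test_that("descriptor_table builds one labelled row per molecule", {
  tab <- descriptor_table(c("C", "CC"), c("methane", "ethane"))
  expect_equal(tab$component_id, c("methane", "ethane"))
  expect_true(all(model_descriptor_names() %in% names(tab)))
  expect_error(descriptor_table(c("C", "C"), c("a", "a")), "anyDuplicated")
})
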