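test_that("stoichiometric matrix has net coefficients and flagged fixed rows", {
  m <- two_species_model()
  S <- stoich_matrix(m)
  expect_equal(unname(S[, "R"]), c(-1, 1))
  m2 <- mass_model(list(species("A", x0 = 2), species("B")),
                   list(reaction("R", c(A = 2), c(B = 1), reversible = FALSE)))
  expect_equal(unname(stoich_matrix(m2)[, "R"]), c(-2, 1))
  m3 <- mass_model(list(species("A", fixed = TRUE), species("B")),
                   list(reaction("R", c(A = 1), c(B = 1), Keq = 1)))
  expect_equal(unname(attr(stoich_matrix(m3), "fixed")), c(TRUE, FALSE))
  empty <- mass_model(list(), list())
  expect_equal(dim(stoich_matrix(empty)), c(0L, 0L))
})

test_that("species on both sides of a reaction are net-cancelled", {
  r <- reaction("R", c(A = 1, B = 2), c(B = 3, C = 1), reversible = FALSE)
  expect_equal(r$reactants, c(A = 1))
  expect_equal(sort(names(r$products)), c("B", "C"))
  expect_equal(r$products[["B"]], 1)
  expect_error(reaction("R", c(A = 1.5), c(B = 1)), "positive integers")
})

test_that("mass-action rate law matches hand evaluations and vanishes at equilibrium", {
  # A <-> B at Gamma = Keq
  r <- reaction("R", c(A = 1), c(B = 1), kf = 1, Keq = 2)
  expect_identical(mass_action_rate(r, c(A = 1, B = 2)), 0)
  # irreversible first order
  r2 <- reaction("R", c(A = 1), c(B = 1), kf = 2, reversible = FALSE)
  expect_equal(mass_action_rate(r2, c(A = 3, B = 99)), 6)
  # 2A <-> B hand evaluation: 1 * (4 - 4/4) = 3
  r3 <- reaction("R", c(A = 2), c(B = 1), kf = 1, Keq = 4)
  expect_equal(mass_action_rate(r3, c(A = 2, B = 4)), 3)
  expect_error(mass_action_rate(r3, c(A = -1, B = 1)), "negative")
  expect_error(mass_action_rate(r3, c(B = 1)), "missing")
})

test_that("mass-action ratio matches hand evaluations and rejects zero reactants", {
  r <- reaction("R", c(A = 1), c(B = 1), Keq = 1)
  expect_equal(mass_action_ratio(r, c(A = 1, B = 2)), 2)
  expect_equal(mass_action_ratio(r, c(A = 0.7, B = 0.7)), 1)
  r2 <- reaction("R", c(A = 2), c(B = 1), Keq = 1)
  expect_equal(mass_action_ratio(r2, c(A = 2, B = 8)), 2)
  expect_error(mass_action_ratio(r, c(A = 0, B = 1)), "zero reactant")
})

test_that("rate is a monotone function of the driving force (sign law)", {
  r <- reaction("R", c(A = 1), c(B = 2), kf = 0.8, Keq = 3)
  set.seed(4)
  for (i in 1:50) {
    x <- c(A = runif(1, 0.01, 5), B = runif(1, 0.01, 5))
    v <- mass_action_rate(r, x)
    drive <- log(r$Keq) - log(mass_action_ratio(r, x))
    expect_equal(sign(v), sign(drive))
  }
})

test_that("ODE assembly combines participating reactions and zeroes fixed species", {
  # chain A -> B -> C: dB/dt = v1 - v2, checked structurally and numerically
  m <- mass_model(
    list(species("A", x0 = 2, fixed = TRUE), species("B", x0 = 1),
         species("C", x0 = 0.5)),
    list(reaction("v1", c(A = 1), c(B = 1), kf = 2, reversible = FALSE),
         reaction("v2", c(B = 1), c(C = 1), kf = 0.5, Keq = 4))
  )
  odes <- build_odes(m)
  expect_identical(odes$A, 0)
  set.seed(7)
  S <- unclass(stoich_matrix(m))
  for (i in 1:20) {
    x <- c(A = 2, B = runif(1, 0.1, 3), C = runif(1, 0.1, 3))
    v <- c(2 * x[["A"]], 0.5 * (x[["B"]] - x[["C"]] / 4))
    num <- vapply(odes, function(e) eval(e, as.list(x)), numeric(1))
    dxdt <- as.vector(S %*% v)
    dxdt[fixed_species(m)] <- 0
    expect_equal(unname(num), dxdt)
  }
})

test_that("custom rate laws replace mass action and must close over known symbols", {
  m <- mass_model(
    list(species("A", x0 = 1), species("B", x0 = 1)),
    list(reaction("R", c(A = 1), c(B = 1), kf = 3, Keq = 2)),
    custom_rates = list(R = quote(kf * A / (1 + A)))
  )
  odes <- build_odes(m)
  expect_equal(eval(odes$A, list(A = 1, B = 5)), -1.5)
  expect_error(
    mass_model(list(species("A")),
               list(reaction("R", c(A = 1), c(A = 2), reversible = FALSE)) |>
                 (\(x) x)(),
               custom_rates = list(R = quote(k_mystery * A))),
    "unresolved symbols")
})

test_that("conserved pools span the left nullspace with minimal integer entries", {
  # closed A <-> B: total mass pool
  expect_equal(unname(conserved_pools(two_species_model())),
               matrix(c(1, 1), 1))
  # open chain with exchange: no pools
  fx <- make_linear_chain(3, seed = 2)
  expect_equal(nrow(conserved_pools(fx$model)), 0L)
  # enzyme cycle with fixed ligands: enzyme pool over {E, ES}
  pools <- conserved_pools(enzyme_cycle_model())
  expect_equal(pools, matrix(c(1, 1), 1, dimnames = list(NULL, c("E", "ES"))))
  # every pool annihilates S (property over fixtures)
  fg <- make_toy_glycolysis(seed = 3)
  P <- conserved_pools(fg$model)
  S_nf <- unclass(stoich_matrix(fg$model))[colnames(P), ]
  expect_equal(max(abs(P %*% S_nf)), 0)
  expect_true(all(P == round(P)))
})
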