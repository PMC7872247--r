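test_that("integration matches closed-form solutions of linear systems", {
  # irreversible decay: A(t) = exp(-t)
  traj <- integrate_model(decay_model(kf = 1, A0 = 1), t_span = c(0, 5))
  expect_lt(max(abs(traj$states[, "A"] - exp(-traj$times))), 1e-7)
  # mass conservation along the trajectory
  expect_lt(max(abs(rowSums(traj$states) - 1)), 1e-8)
  # reversible relaxation A <-> B, kf = 1, Keq = 1, x0 = (2, 0):
  # A(t) = 1 + exp(-2t)
  m <- two_species_model(kf = 1, Keq = 1, xA = 2, xB = 0)
  tr2 <- integrate_model(m, t_span = c(0, 4))
  expect_lt(max(abs(tr2$states[, "A"] - (1 + exp(-2 * tr2$times)))), 1e-7)
  # fluxes are recomputed from states: v = kf (A - B)
  expect_equal(unname(tr2$fluxes[, "R"]),
               unname(tr2$states[, "A"] - tr2$states[, "B"]),
               tolerance = 1e-10)
})

test_that("fixed species stay clamped during integration", {
  m <- mass_model(
    list(species("A", x0 = 3, fixed = TRUE), species("B", x0 = 0)),
    list(reaction("R", c(A = 1), c(B = 1), kf = 1, reversible = FALSE)))
  traj <- integrate_model(m, t_span = c(0, 2))
  expect_true(all(traj$states[, "A"] == 3))
  # with constant influx 3, B grows linearly
  expect_lt(max(abs(traj$states[, "B"] - 3 * traj$times)), 1e-6)
})

test_that("perturbations retarget kf or concentrations at the stated instant", {
  m <- decay_model(kf = 1, A0 = 1)
  # doubling kf at t = 1: A(t) = e^-1 * exp(-2 (t - 1)) afterwards
  traj <- integrate_model(m, t_span = c(0, 3),
                          pert = perturbation(c(R = 2), time = 1))
  post <- traj$times >= 1
  expect_lt(max(abs(traj$states[post, "A"] -
                      exp(-1) * exp(-2 * (traj$times[post] - 1)))), 1e-6)
  # state continuity at the perturbation instant for parameter targets
  i <- which(traj$times == 1)
  expect_equal(unname(traj$states[i, "A"]), exp(-1), tolerance = 1e-6)
  # absolute species perturbation resets the concentration
  tr2 <- integrate_model(m, t_span = c(0, 2),
                         pert = perturbation(c(A = 0.5), time = 1,
                                             absolute = TRUE))
  j <- which(tr2$times == 1)
  expect_equal(unname(tr2$states[j, "A"]), 0.5, tolerance = 1e-8)
  expect_error(integrate_model(m, t_span = c(0, 1),
                               pert = perturbation(c(nope = 2))),
               "neither a reaction nor a species")
})

test_that("jacobian matches the analytic linearization and finite differences", {
  # A <-> B, kf = 1, Keq = 1: J = [[-1, 1], [1, -1]]
  m <- two_species_model(kf = 1, Keq = 1)
  J <- jacobian(m, c(A = 1, B = 1))
  expect_equal(unname(J), matrix(c(-1, 1, 1, -1), 2))
  # finite-difference cross-check on a nonlinear fixture
  fx <- make_toy_glycolysis(seed = 8)
  x <- reference_state(fx$model)
  Ja <- jacobian(fx$model, x)
  f <- function(xx) {
    S <- unclass(stoich_matrix(fx$model))
    d <- as.vector(S %*% make_rate_fn(fx$model)(xx))
    d[fixed_species(fx$model)] <- 0
    d
  }
  h <- 1e-7
  for (sid in c("atp", "fdp")) {
    xp <- x; xm <- x
    xp[sid] <- x[sid] * (1 + h); xm[sid] <- x[sid] * (1 - h)
    fd <- (f(xp) - f(xm)) / (2 * x[sid] * h)
    expect_lt(max(abs(Ja[, sid] - fd)), 1e-4 * max(1, max(abs(Ja[, sid]))))
  }
})

test_that("reduced Jacobian eigenvalues drop conserved zero modes", {
  m <- two_species_model(kf = 1, Keq = 1)
  # full Jacobian has eigenvalues {0, -2}; the reduced one keeps only -2
  ev_full <- eigen(jacobian(m, c(A = 1, B = 1)), only.values = TRUE)$values
  expect_equal(sort(Re(ev_full)), c(-2, 0))
  evr <- eigen(reduced_jacobian(m, c(A = 1, B = 1)), only.values = TRUE)$values
  expect_equal(as.numeric(Re(evr)), -2)
  expect_equal(timescales(m, c(A = 1, B = 1)), 0.5)
})

test_that("steady states found by every strategy agree with closed forms", {
  # closed A <-> B with total T = 3, Keq = 2: A* = T/(1+Keq) = 1, B* = 2
  m <- two_species_model(kf = 1, Keq = 2, xA = 3, xB = 0)
  for (strat in c("integrate", "hybrid")) {
    xs <- find_steady_state(m, strategy = strat)
    expect_equal(unname(xs[["A"]]), 1, tolerance = 1e-6)
    expect_equal(unname(xs[["B"]]), 2, tolerance = 1e-6)
    expect_lt(attr(xs, "residual"), 1e-9)
  }
  # the log-space Newton solver needs a strictly interior start (same pool)
  m_int <- two_species_model(kf = 1, Keq = 2, xA = 2.9, xB = 0.1)
  xs_n <- find_steady_state(m_int, strategy = "newton")
  expect_equal(unname(xs_n[["A"]]), 1, tolerance = 1e-6)
  expect_equal(unname(xs_n[["B"]]), 2, tolerance = 1e-6)
  expect_equal(sum(xs_n), 3, tolerance = 1e-8)
  # open fixture: reference state is already at steady state
  fx <- make_toy_glycolysis(seed = 4)
  xs2 <- find_steady_state(fx$model)
  expect_lt(max(abs(xs2 - reference_state(fx$model)) /
                  reference_state(fx$model)), 1e-6)
})

test_that("stability classification agrees between eigenvalues and simulation", {
  fx <- make_linear_chain(3, seed = 6)
  xs <- find_steady_state(fx$model)
  expect_true(is_stable(fx$model, xs, method = "eigen"))
  expect_true(is_stable(fx$model, xs, method = "simulate"))
  # an autocatalytic runaway is unstable (mass action net-cancels A -> 2A,
  # so the exponential feedback enters as a custom rate law)
  m_un <- mass_model(
    list(species("A", x0 = 1e-6), species("src", x0 = 1, fixed = TRUE)),
    list(reaction("grow", c(src = 1), c(A = 1), kf = 1, reversible = FALSE)),
    custom_rates = list(grow = quote(kf * A)))
  # dA/dt = A: x = 0 is a steady state but repelling
  x0 <- c(A = 0, src = 1)
  expect_false(is_stable(m_un, x0, method = "eigen"))
  expect_false(is_stable(m_un, x0, method = "simulate",
                         pert = perturbation(c(A = 1e-3), absolute = TRUE),
                         horizon = 100))
})

test_that("trajectory interpolation is exact at knots and refuses extrapolation", {
  m <- two_species_model(kf = 1, Keq = 1, xA = 2, xB = 0)
  traj <- integrate_model(m, t_span = c(0, 4), n_out = 81L)
  fine <- interpolate_trajectory(traj, seq(0, 4, length.out = 37))
  expect_equal(fine$states[1, ], traj$states[1, ])
  expect_equal(fine$states[37, ], traj$states[nrow(traj$states), ])
  # interpolant stays near the true solution between knots
  expect_lt(max(abs(fine$states[, "A"] - (1 + exp(-2 * fine$times)))), 1e-4)
  expect_error(interpolate_trajectory(traj, c(2, 5)), "outside")
})
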