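test_that("assembly yields the full Cartesian product with exact steady states", {
  fx <- make_toy_glycolysis(seed = 17)
  rids <- reaction_ids(fx$model)
  v_ref <- fx$ss$fluxes
  lb <- stats::setNames(rep(0, length(rids)), rids)
  ub <- pmax(3 * v_ref, 0)[rids]
  lb["HEX"] <- ub["HEX"] <- v_ref[["HEX"]]
  lb["ADK"] <- ub["ADK"] <- 0
  fs <- sample_fluxes(fx$model, lb, ub, n = 4, thin = 10, seed = 17)
  pol <- build_concentration_polytope(fx$model, directions = v_ref, d = 0.8)
  cs <- hit_and_run(pol, n = 3, thin = 10, seed = 18)
  cands <- assemble_ensemble(fx$model, fs, cs)
  expect_length(cands, 12L)
  # each parameterized candidate sits exactly on its sampled steady state
  S_nf <- unclass(stoich_matrix(fx$model))[!fixed_species(fx$model), ]
  for (cand in cands) {
    if (cand$status == "infeasible") next
    expect_equal(cand$status, "untested")
    x <- reference_state(cand$model)
    v <- make_rate_fn(cand$model)(x)
    expect_lt(max(abs(S_nf %*% v)), 1e-9)
    expect_equal(unname(v[["HEX"]]), unname(v_ref[["HEX"]]), tolerance = 1e-9)
  }
  ids <- t(vapply(cands, function(cc)
    c(cc$flux_state_id, cc$conc_state_id), numeric(2)))
  expect_equal(nrow(unique(ids)), 12L)
})

test_that("stability filtering classifies candidates and logs discards", {
  fx <- make_toy_glycolysis(seed = 17)
  rids <- reaction_ids(fx$model)
  v_ref <- fx$ss$fluxes
  lb <- stats::setNames(rep(0, length(rids)), rids)
  ub <- pmax(3 * v_ref, 0)[rids]
  lb["HEX"] <- ub["HEX"] <- v_ref[["HEX"]]
  lb["ADK"] <- ub["ADK"] <- 0
  fs <- sample_fluxes(fx$model, lb, ub, n = 2, thin = 10, seed = 17)
  pol <- build_concentration_polytope(fx$model, directions = v_ref, d = 0.8)
  cs <- hit_and_run(pol, n = 2, thin = 10, seed = 18)
  cands <- assemble_ensemble(fx$model, fs, cs)
  ens <- filter_stable(cands, perturbation(c(ATPM = 1.5)))
  st <- ensemble_status(ens)
  expect_equal(sum(st), 4L)
  expect_equal(unname(st[["untested"]]), 0L)
  expect_equal(nrow(ens$discard_log),
               unname(st[["unstable"]] + st[["infeasible"]]))
  expect_gte(unname(st[["stable"]]), 1L)
  for (cand in ens$candidates)
    if (cand$status == "stable")
      expect_lt(attr(cand$x_star, "residual"), 1e-6)
})

test_that("ensemble simulation and aggregation produce coherent statistics", {
  res <- run_ensemble_workflow(seed = 2, n_states = 3, thin = 10,
                               t_span = c(0, 20), grid_n = 15)
  ens <- res$ensemble
  n_stable <- ensemble_status(ens)[["stable"]]
  expect_gte(unname(n_stable), 2L)
  # shared grid spans the window exactly
  expect_equal(ens$times[1], 0)
  expect_equal(ens$times[length(ens$times)], 20)
  agg <- res$summary
  expect_equal(unique(agg$n_candidates), unname(n_stable))
  expect_true(all(agg$ci95_lo <= agg$mean + 1e-12))
  expect_true(all(agg$mean <= agg$ci95_hi + 1e-12))
  expect_true(all(agg$q25 <= agg$median + 1e-12))
  expect_true(all(agg$median <= agg$q75 + 1e-12))
  # energy charge stays in [0, 1] and drops under the extra ATP load
  expect_true(all(agg$mean >= 0 & agg$mean <= 1))
  expect_lt(agg$mean[nrow(agg)], agg$mean[1])
  # aggregation against a hand-stacked oracle for the mean
  trajs <- Filter(Negate(is.null), ens$trajectories)
  M <- vapply(trajs, function(tr)
    energy_charge(tr$states[, "atp"], tr$states[, "adp"], tr$states[, "amp"]),
    numeric(length(ens$times)))
  expect_equal(agg$mean, rowMeans(M))
  med <- apply(M, 1, stats::median)
  expect_equal(agg$median, med)
})

test_that("energy charge matches its defining formula and edge cases", {
  expect_equal(energy_charge(1, 1, 1), 0.5)
  expect_equal(energy_charge(1, 0, 0), 1)
  expect_equal(energy_charge(0, 0, 1), 0)
  expect_equal(energy_charge(c(2, 1), c(1, 2), c(1, 1)),
               c((2 + 0.5) / 4, (1 + 1) / 4))
  expect_error(energy_charge(0, 0, 0), "undefined")
})

test_that("quantities resolve to species, fluxes, or custom functions", {
  fx <- make_linear_chain(2, seed = 3)
  traj <- integrate_model(fx$model, t_span = c(0, 1), n_out = 5L)
  expect_equal(eval_quantity(traj, "X1"), traj$states[, "X1"])
  expect_equal(eval_quantity(traj, "R_in"), traj$fluxes[, "R_in"])
  f <- function(states, fluxes) states[, "X1"] + states[, "X2"]
  expect_equal(eval_quantity(traj, f),
               traj$states[, "X1"] + traj$states[, "X2"])
  expect_error(eval_quantity(traj, "nothere"), "neither")
})
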