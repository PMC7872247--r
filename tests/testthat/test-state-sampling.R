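test_that("interior point of a box-and-halfspace polytope is feasible and deep", {
  # unit square cut by x + y <= 1: Chebyshev radius is 1/(2 + sqrt(2))
  p <- polytope(matrix(c(1, 1), 1), 1, c(0, 0), c(1, 1), c("x", "y"),
                space = "flux")
  ip <- find_interior_point(p)
  expect_true(min(polytope_slack(p, ip)) > 0)
  expect_equal(attr(ip, "radius"), 1 / (2 + sqrt(2)), tolerance = 1e-8)
  # slab polytope: the determined coordinate is the slab midpoint
  p2 <- polytope(NULL, numeric(0), c(0, 0), c(1, 0.2), c("x", "y"),
                 space = "flux")
  ip2 <- find_interior_point(p2)
  expect_equal(unname(ip2[["y"]]), 0.1, tolerance = 1e-8)
  expect_equal(attr(ip2, "radius"), 0.1, tolerance = 1e-8)
  # empty polytope errors
  p_empty <- polytope(matrix(c(1, 1), 1), -1, c(0, 0), c(1, 1), c("x", "y"),
                      space = "flux")
  expect_error(find_interior_point(p_empty), "empty")
})

test_that("hit-and-run samples stay feasible, are deterministic, and fill the box", {
  p <- polytope(NULL, numeric(0), c(0, -1, 2), c(1, 1, 5),
                c("a", "b", "c"), space = "flux")
  s1 <- hit_and_run(p, n = 500, thin = 5, seed = 42)
  s2 <- hit_and_run(p, n = 500, thin = 5, seed = 42)
  expect_identical(s1$samples, s2$samples)
  s3 <- hit_and_run(p, n = 500, thin = 5, seed = 43)
  expect_false(identical(s1$samples, s3$samples))
  for (i in seq_len(nrow(s1$samples)))
    expect_gte(min(polytope_slack(p, s1$samples[i, ])), 0)
  # samples approach the box extremes (coverage, not just feasibility)
  expect_lt(min(s1$samples[, "a"]), 0.1)
  expect_gt(max(s1$samples[, "a"]), 0.9)
  # sampler does not disturb the global RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(hit_and_run(p, n = 10, thin = 2, seed = 7))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("log-concentration polytopes enforce thermodynamic and bound limits", {
  fx <- make_toy_glycolysis(seed = 9)
  v_ref <- fx$ss$fluxes
  pol <- build_concentration_polytope(fx$model, directions = v_ref,
                                      bound_mode = "deviation", d = 0.8)
  ss <- hit_and_run(pol, n = 200, thin = 10, seed = 3)
  x_ref <- reference_state(fx$model)[colnames(ss$samples)]
  ratios <- sweep(ss$samples, 2, x_ref, "/")
  expect_gte(min(ratios), 0.2 - 1e-9)
  expect_lte(max(ratios), 1.8 + 1e-9)
  # every sampled state keeps all reference flux directions feasible
  full <- reference_state(fx$model)
  for (i in seq_len(nrow(ss$samples))) {
    x <- full
    x[colnames(ss$samples)] <- ss$samples[i, ]
    sd_ <- steady_state_data(v_ref, x)
    expect_equal(nrow(check_direction_consistency(fx$model, sd_)), 0L)
  }
  # magnitude mode: one order of magnitude each way
  pol_m <- build_concentration_polytope(fx$model, directions = v_ref,
                                        bound_mode = "magnitude", d = 1)
  sm <- hit_and_run(pol_m, n = 100, thin = 10, seed = 3)
  rat_m <- sweep(sm$samples, 2, x_ref, "/")
  expect_gte(min(rat_m), 0.1 - 1e-9)
  expect_lte(max(rat_m), 10 + 1e-6)
})

test_that("flux sampling satisfies the balance exactly and honours pins", {
  fx <- make_toy_glycolysis(seed = 10)
  rids <- reaction_ids(fx$model)
  v_ref <- fx$ss$fluxes
  lb <- stats::setNames(rep(0, length(rids)), rids)
  ub <- pmax(3 * v_ref, 0)[rids]
  lb["HEX"] <- ub["HEX"] <- v_ref[["HEX"]]
  lb["ADK"] <- ub["ADK"] <- 0
  vs <- sample_fluxes(fx$model, lb, ub, n = 100, thin = 10, seed = 5)
  S_nf <- unclass(stoich_matrix(fx$model))[!fixed_species(fx$model), ]
  expect_lt(max(abs(S_nf %*% t(vs$samples))), 1e-9)
  expect_true(all(vs$samples[, "HEX"] == v_ref[["HEX"]]))
  expect_true(all(vs$samples[, "ADK"] == 0))
  expect_gte(min(sweep(vs$samples, 2, lb, "-")), -1e-9)
  expect_lte(max(sweep(vs$samples, 2, ub, "-")), 1e-9)
  # the free degree of freedom (futile cycle) actually varies
  expect_gt(stats::sd(vs$samples[, "FBP"]), 0)
  # fully pinned cone returns the unique solution
  lb2 <- ub2 <- v_ref[rids]
  vs2 <- sample_fluxes(fx$model, lb2, ub2, n = 5, thin = 1, seed = 1)
  expect_equal(unname(vs2$samples[1, ]), unname(v_ref[rids]))
})

test_that("minimal concentration adjustment projects symmetrically in log space", {
  # A <-> B with Keq = 1 and forward flux requires ln B - ln A <= -eps;
  # starting from ln A = 0, ln B = 2 the least-squares projection moves both
  # coordinates by ~1 (displacement ~sqrt(2), split evenly)
  m <- two_species_model(Keq = 1, xA = 1, xB = exp(2))
  x_adj <- adjust_concentrations_min(m, c(A = 1, B = exp(2)),
                                     directions = c(R = 1))
  y <- log(x_adj)
  expect_equal(unname(y[["A"]] - 0), unname(-(y[["B"]] - 2)), tolerance = 1e-4)
  expect_equal(unname(y[["A"]]), 1, tolerance = 1e-3)
  # result is feasible and an already-feasible point is untouched
  sd_ <- steady_state_data(c(R = 1), x_adj)
  expect_equal(nrow(check_direction_consistency(m, sd_)), 0L)
  x_ok <- adjust_concentrations_min(m, c(A = 2, B = 1), directions = c(R = 1))
  expect_equal(x_ok, c(A = 2, B = 1))
})

test_that("QP flux fitting matches hand-worked solutions", {
  # closed A <-> B: S v = 0 forces v1 = v2; measurements (1, 2) -> (1.5, 1.5)
  m <- mass_model(list(species("A"), species("B")),
                  list(reaction("v1", c(A = 1), c(B = 1), Keq = 1),
                       reaction("v2", c(B = 1), c(A = 1), Keq = 1)))
  v <- fit_fluxes(m, measured = c(v1 = 1, v2 = 2))
  expect_equal(unname(v), c(1.5, 1.5), tolerance = 1e-8)
  # with an upper bound of 1.2 the optimum clips to the bound
  v_clip <- fit_fluxes(m, measured = c(v1 = 1, v2 = 2),
                       lb = c(v1 = -1000, v2 = -1000),
                       ub = c(v1 = 1.2, v2 = 1000))
  expect_equal(unname(v_clip), c(1.2, 1.2), tolerance = 1e-8)
})

test_that("futile-cycle inflation preserves the net and adds the stated fraction", {
  expect_equal(futile_cycle_inflate(1, 0, frac = 0.1),
               c(v_fwd = 1.1, v_rev = 0.1))
  out <- futile_cycle_inflate(2.4, 0.4, frac = 0.25)
  expect_equal(unname(out["v_fwd"] - out["v_rev"]), 2)
  expect_equal(unname(out), c(2.9, 0.9))
})
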