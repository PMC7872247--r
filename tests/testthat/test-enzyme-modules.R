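# Closed-form steady-state net flux of the 2-step uni-uni mechanism
# E + S <-> ES (k1, K1), ES <-> E + P (k2, K2), total enzyme et:
# solved by hand from the ES balance plus conservation.
uni_uni_closed_form <- function(k1, K1, k2, K2, et, S, P) {
  ES <- et * (k1 * S + k2 * P / K2) / (k1 * S + k2 * P / K2 + k2 + k1 / K1)
  E <- et - ES
  k2 * (ES - E * P / K2)
}

test_that("module construction wires forms, steps, and the catalytic path", {
  mod <- build_uni_uni("PGI", "g6p", "f6p", keq_net = 0.3, n_steps = 3)
  expect_equal(names(mod$forms), c("PGI", "PGI_g6p", "PGI_f6p"))
  expect_equal(mod$path_steps, c("PGI_bind", "PGI_cat", "PGI_release"))
  expect_false(mod$fitted)
  expect_true(mod$e_total_default)
  bb <- build_ordered_bi_bi("PYK", c("pep", "adp"), c("pyr", "atp"),
                            keq_net = 1e4, e_total = 2e-6)
  expect_equal(length(bb$forms), 4L)
  expect_false(bb$e_total_default)
  expect_error(build_uni_uni("X", "a", "a", keq_net = 1), "must differ")
})

test_that("internal steady-state flux matches the closed-form uni-uni solution", {
  mod <- build_uni_uni("enz", "S", "P", keq_net = 5, e_total = 1e-6)
  lig <- c(S = 1e-3, P = 1e-4)
  set.seed(14)
  for (i in 1:10) {
    k1 <- 10^runif(1, 3, 6); k2 <- 10^runif(1, 1, 4)
    K1 <- 10^runif(1, 1, 4); K2 <- 5 / K1  # Haldane: K1 K2 = 5
    m <- mod
    m$steps$enz_bind$kf <- k1; m$steps$enz_bind$Keq <- K1
    m$steps$enz_cat$kf <- k2; m$steps$enz_cat$Keq <- K2
    f <- steady_state_net_flux(m, lig)
    expect_rel_equal(as.numeric(f),
                     uni_uni_closed_form(k1, K1, k2, K2, 1e-6,
                                         lig[["S"]], lig[["P"]]), 1e-12)
    # internal forms balance: both step fluxes equal the net flux
    sf <- attr(f, "step_fluxes")
    expect_rel_equal(sf[["enz_bind"]], sf[["enz_cat"]], 1e-9)
    expect_equal(sum(attr(f, "forms")), 1e-6, tolerance = 1e-12)
  }
})

test_that("fitting hits the target flux and enforces the Haldane relation", {
  lig <- c(S = 1e-3, P = 1e-4)
  for (keq in c(5, 0.9)) {
    mod <- build_uni_uni("enz", "S", "P", keq_net = keq, e_total = 1e-6)
    fit <- fit_rate_constants(mod, lig, target_flux = 2e-4)
    expect_rel_equal(as.numeric(steady_state_net_flux(fit, lig)), 2e-4, 1e-10)
    expect_rel_equal(haldane_product(fit), keq, 1e-10)
    expect_true(fit$fitted)
  }
  # 3-step and bi-bi mechanisms fit too
  mod3 <- build_uni_uni("enz", "S", "P", keq_net = 5, n_steps = 3)
  fit3 <- fit_rate_constants(mod3, lig, target_flux = 1e-5)
  expect_rel_equal(as.numeric(steady_state_net_flux(fit3, lig)), 1e-5, 1e-10)
  expect_rel_equal(haldane_product(fit3), 5, 1e-10)
  bb <- build_ordered_bi_bi("pyk", c("pep", "adp"), c("pyr", "atp"),
                            keq_net = 2e4)
  lig_bb <- c(pep = 2e-4, adp = 4e-4, pyr = 1e-3, atp = 1.6e-3)
  fbb <- fit_rate_constants(bb, lig_bb, target_flux = 2e-3)
  expect_rel_equal(as.numeric(steady_state_net_flux(fbb, lig_bb)), 2e-3, 1e-10)
  expect_rel_equal(haldane_product(fbb), 2e4, 1e-10)
})

test_that("fitting rejects fluxes that oppose the net driving force", {
  mod <- build_uni_uni("enz", "S", "P", keq_net = 5)
  # Gamma = 0.1 < 5: only forward flux is achievable
  expect_error(fit_rate_constants(mod, c(S = 1e-3, P = 1e-4),
                                  target_flux = -1e-4),
               "opposes the net thermodynamic driving force")
})

test_that("net flux is linear in total enzyme at fixed rate constants", {
  lig <- c(S = 1e-3, P = 1e-4)
  mod <- build_uni_uni("enz", "S", "P", keq_net = 5, e_total = 1e-6)
  fit <- fit_rate_constants(mod, lig, target_flux = 1e-4)
  f1 <- as.numeric(steady_state_net_flux(fit, lig))
  fit$e_total <- 3 * fit$e_total
  f3 <- as.numeric(steady_state_net_flux(fit, lig))
  expect_rel_equal(f3, 3 * f1, 1e-10)
})

test_that("MWC transition shifts enzyme into the inactive T state and slows flux", {
  lig <- c(S = 1e-3, P = 1e-4)
  m_lo <- fit_rate_constants(build_mwc_uni_uni("enz", "S", "P", keq_net = 5,
                                               L = 1e-6),
                             lig, target_flux = 1e-4)
  # raise the allosteric constant with the same catalytic parameters
  m_hi <- m_lo
  m_hi$steps$enz_transition$Keq <- 4
  f_lo <- steady_state_net_flux(m_lo, lig)
  f_hi <- steady_state_net_flux(m_hi, lig)
  expect_lt(as.numeric(f_hi), as.numeric(f_lo))
  fa <- fractional_abundance(m_hi, attr(f_hi, "forms"))
  expect_equal(sum(fa), 1)
  expect_gt(unname(fa[["enz_T"]]), unname(fa[["enz_R"]]))
})

test_that("merging preserves the host steady state and its conservation pool", {
  fx <- make_linear_chain(3, seed = 21)
  host <- fx$model
  rxn <- host$reactions$R1  # X1 <-> X2, reversible
  mod <- build_uni_uni("enzR1", "X1", "X2", keq_net = rxn$Keq,
                       e_total = 1e-6, replaces = "R1")
  v_ref <- fx$ss$fluxes[["R1"]]
  fit <- fit_rate_constants(mod, reference_state(host), v_ref)
  merged <- merge_module(host, fit)
  expect_false("R1" %in% reaction_ids(merged))
  expect_true(all(c("enzR1", "enzR1_X1") %in% species_ids(merged)))
  # reference state (host metabolites + internal form steady state) is still
  # a steady state of the merged model
  r <- max(abs(unclass(stoich_matrix(merged))[!fixed_species(merged), ] %*%
                 make_rate_fn(merged)(reference_state(merged))))
  expect_lt(r, 1e-12)
  # the enzyme conservation pool appears
  pools <- conserved_pools(merged)
  hit <- apply(pools, 1, function(p)
    all(p[c("enzR1", "enzR1_X1")] == 1) &
      all(p[setdiff(colnames(pools), c("enzR1", "enzR1_X1"))] == 0))
  expect_true(any(hit))
  # double merge collides on ids; unmerge restores the original model
  expect_error(merge_module(merged, fit), "id collision")
  restored <- unmerge_module(merged, "enzR1")
  expect_equal(sort(reaction_ids(restored)), sort(reaction_ids(host)))
  expect_equal(reference_state(restored), reference_state(host))
  expect_equal(restored$reactions$R1$kf, host$reactions$R1$kf)
})

test_that("flux splits across isozymes preserve the total", {
  out <- split_flux(2e-3, c(major = 0.75, minor = 0.25))
  expect_equal(unname(out), c(1.5e-3, 0.5e-3))
  expect_equal(sum(out), 2e-3)
  expect_error(split_flux(1, c(a = 0.6, b = 0.5)), "sum to 1")
  expect_error(split_flux(1, c(a = -0.1, b = 1.1)), "non-negative")
})
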