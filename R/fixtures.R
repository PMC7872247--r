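# Bundled network generators with thermodynamically consistent reference
# states, used throughout the examples and tests. Both construct the
# steady state first (flux balance and feasible driving forces by design)
# and then parameterize via PERC inversion, so the emitted (v_ss, x_ss)
# pair is exact.

#' Generate a linear pathway fixture
#'
#' source -> X1 -> ... -> Xn -> sink with an irreversible uptake and exit
#' and randomized reversible interior steps. Equilibrium constants, the
#' pathway flux, and concentrations are drawn from the seed; interior
#' concentrations are chosen so every step keeps a forward driving force
#' (mass-action ratio strictly below Keq), and rate constants follow by
#' PERC inversion, so the reference state is an exact steady state.
#'
#' @param n Number of interior species (>= 2).
#' @param seed Integer seed (same seed, same fixture).
#' @return List with \code{model} (parameterized \code{mass_model}) and
#'   \code{ss} (\code{steady_state_data}).
#' @export
make_linear_chain <- function(n = 3, seed = 1L) {
  stopifnot(n >= 2)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ids <- paste0("X", seq_len(n))
  v0 <- stats::runif(1, 0.5, 2) * 1e-3            # pathway flux, M/h
  x <- numeric(n)
  x[1] <- stats::runif(1, 0.5, 2) * 1e-3          # molar
  Keq <- stats::runif(n - 1, 0.5, 5)
  theta <- stats::runif(n - 1, 0.2, 0.8)          # disequilibrium ratios
  for (i in seq_len(n - 1)) x[i + 1] <- theta[i] * Keq[i] * x[i]
  sp <- c(list(species("src", x0 = 2e-3, fixed = TRUE)),
          lapply(seq_len(n), function(i) species(ids[i], x0 = x[i])),
          list(species("snk", x0 = 1e-6, fixed = TRUE)))
  rx <- c(
    list(reaction("R_in", c(src = 1), stats::setNames(1, ids[1]),
                  reversible = FALSE)),
    lapply(seq_len(n - 1), function(i)
      reaction(paste0("R", i), stats::setNames(1, ids[i]),
               stats::setNames(1, ids[i + 1]), Keq = Keq[i])),
    list(reaction("R_out", stats::setNames(1, ids[n]), c(snk = 1),
                  reversible = FALSE))
  )
  model <- mass_model(sp, rx)
  fluxes <- stats::setNames(rep(v0, n + 1), reaction_ids(model))
  conc <- stats::setNames(c(2e-3, x, 1e-6), species_ids(model))
  ss <- steady_state_data(fluxes, conc)
  model <- parameterize(model, ss)
  list(model = model, ss = ss)
}

#' Generate a toy glycolysis fixture
#'
#' A compact glycolysis-like network with an adenylate subsystem: hexokinase
#' (HEX) and phosphofructokinase (PFK) consume ATP, a lumped lower-glycolysis
#' reaction (GLY, reversible) and pyruvate kinase (PYK) regenerate it, an
#' ATP utilization load (ATPM) drains it, fructose bisphosphatase (FBP)
#' opposes PFK as a futile cycle, and adenylate kinase (ADK, reversible)
#' connects ATP/ADP/AMP. Glucose and pyruvate are fixed boundaries.
#'
#' The reference flux state carries uptake \code{u}, futile-cycle fraction
#' \code{f} (FBP flux = f u, paired with PFK flux (1+f) u) and ATP load
#' (2 - f) u; adenylate kinase is at equilibrium (zero net flux) at the
#' reference, and its rate constant is assigned directly so the adenylate
#' pool stays dynamically connected. Reversible equilibrium constants are
#' set a randomized distance above the reference mass-action ratio, so the
#' reference state is thermodynamically feasible by construction.
#'
#' @param seed Integer seed.
#' @return List with \code{model} (parameterized), \code{ss}
#'   (\code{steady_state_data}), and \code{futile_pair} (the PFK/FBP ids).
#' @export
make_toy_glycolysis <- function(seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  jit <- function(x, w = 0.2) x * stats::runif(length(x), 1 - w, 1 + w)
  u <- jit(1e-3)                     # glucose uptake, M/h
  f <- stats::runif(1, 0.15, 0.3)    # futile-cycle fraction
  conc <- c(glc = 5e-3, g6p = jit(8e-4), fdp = jit(6e-4), pep = jit(2e-4),
            pyr = 1e-3, atp = jit(1.6e-3), adp = jit(4e-4), amp = jit(1e-4))
  sp <- list(
    species("glc", x0 = conc[["glc"]], fixed = TRUE),
    species("g6p", x0 = conc[["g6p"]]),
    species("fdp", x0 = conc[["fdp"]]),
    species("pep", x0 = conc[["pep"]]),
    species("pyr", x0 = conc[["pyr"]], fixed = TRUE),
    species("atp", x0 = conc[["atp"]]),
    species("adp", x0 = conc[["adp"]]),
    species("amp", x0 = conc[["amp"]])
  )
  gamma_gly <- conc[["pep"]]^2 * conc[["atp"]]^2 /
    (conc[["fdp"]] * conc[["adp"]]^2)
  Keq_gly <- gamma_gly / stats::runif(1, 0.1, 0.5)
  gamma_adk <- conc[["atp"]] * conc[["amp"]] / conc[["adp"]]^2
  rx <- list(
    reaction("HEX", c(glc = 1, atp = 1), c(g6p = 1, adp = 1),
             reversible = FALSE, subsystem = "upper glycolysis"),
    reaction("PFK", c(g6p = 1, atp = 1), c(fdp = 1, adp = 1),
             reversible = FALSE, subsystem = "upper glycolysis"),
    reaction("FBP", c(fdp = 1), c(g6p = 1),
             reversible = FALSE, subsystem = "upper glycolysis"),
    reaction("GLY", c(fdp = 1, adp = 2), c(pep = 2, atp = 2),
             Keq = Keq_gly, subsystem = "lower glycolysis"),
    reaction("PYK", c(pep = 1, adp = 1), c(pyr = 1, atp = 1),
             reversible = FALSE, subsystem = "lower glycolysis"),
    reaction("ATPM", c(atp = 1), c(adp = 1),
             reversible = FALSE, subsystem = "energy load"),
    reaction("ADK", c(adp = 2), c(atp = 1, amp = 1),
             Keq = gamma_adk, subsystem = "adenylate")
  )
  model <- mass_model(sp, rx)
  fluxes <- c(HEX = u, PFK = (1 + f) * u, FBP = f * u, GLY = u,
              PYK = 2 * u, ATPM = (2 - f) * u, ADK = 0)
  ss <- steady_state_data(fluxes, conc)
  model <- suppressWarnings(parameterize(model, ss))
  # ADK carries no net reference flux (its PERC is unidentifiable), but the
  # enzyme is present: assign a rate constant giving it a flux capacity of
  # order the uptake so the adenylate pool re-equilibrates dynamically
  model <- set_rate_constants(model, c(ADK = unname(u / conc[["adp"]]^2)))
  list(model = model, ss = ss, futile_pair = c("PFK", "FBP"))
}
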