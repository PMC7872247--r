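#' Gas constant, kJ/(mol K)
#' @export
GAS_CONSTANT <- 8.314e-3

#' Bundle steady-state data
#'
#' Holds a signed steady-state flux map and a positive steady-state
#' concentration map, used to back-calculate pseudo-elementary rate
#' constants (PERCs).
#'
#' @param fluxes Named numeric vector, reaction id -> flux (molar/h, signed).
#' @param concentrations Named numeric vector, species id -> concentration
#'   (molar, > 0).
#' @param temperature Kelvin; defaults to physiological 310.15.
#' @return An object of class \code{steady_state_data}.
#' @export
steady_state_data <- function(fluxes, concentrations, temperature = 310.15) {
  stopifnot(!is.null(names(fluxes)), !is.null(names(concentrations)))
  if (any(concentrations <= 0))
    stop("steady-state concentrations must be strictly positive: ",
         paste(names(concentrations)[concentrations <= 0], collapse = ", "))
  structure(
    list(fluxes = fluxes, concentrations = concentrations,
         temperature = temperature, gas_constant = GAS_CONSTANT),
    class = "steady_state_data"
  )
}

#' Check that a flux state balances at steady state
#'
#' Verifies that S v = 0 over non-fixed species within a relative tolerance.
#'
#' @param model A \code{mass_model}.
#' @param ss A \code{steady_state_data}.
#' @param rtol Relative tolerance on the infinity-norm residual.
#' @return Invisibly, the residual; errors when the flux state is unbalanced.
#' @export
check_flux_balance <- function(model, ss, rtol = 1e-6) {
  S <- stoich_matrix(model)
  v <- ss$fluxes[reaction_ids(model)]
  if (anyNA(v)) stop("missing flux for reaction(s): ",
                     paste(reaction_ids(model)[is.na(v)], collapse = ", "))
  resid <- S[!fixed_species(model), , drop = FALSE] %*% v
  r <- max(abs(resid))
  if (r > rtol * max(abs(v), 1e-300))
    stop("flux state is not at steady state: ||S v||_inf = ", signif(r, 4))
  invisible(r)
}

# Rate-law denominator D = prod(x^a) - prod(x^b)/Keq; PERC kf = v / D.
perc_denominator <- function(rxn, x) {
  xs <- get_conc(x, names(rxn$reactants), "PERC computation")
  fwd <- prod(xs^rxn$reactants)
  if (!rxn$reversible) return(fwd)
  xp <- get_conc(x, names(rxn$products), "PERC computation")
  fwd - prod(xp^rxn$products) / rxn$Keq
}

#' Compute pseudo-elementary rate constants (PERCs)
#'
#' Inverts the mass-action rate law at the observed steady state: for each
#' reaction, \eqn{k_f = v_{ss} / (\prod x^{a} - K_{eq}^{-1}\prod x^{b})}.
#' By construction the parameterized model carries exactly the observed flux
#' at the observed concentrations.
#'
#' A non-zero flux requires a non-zero denominator of matching sign (the flux
#' must run with its thermodynamic driving force); violations are hard
#' errors naming the reaction. Reactions with zero steady-state flux get
#' \code{zero_flux_kf} (default 0) with a warning, since their rate constant
#' is not identifiable from the data.
#'
#' @param model A \code{mass_model}.
#' @param ss A \code{steady_state_data}.
#' @param zero_flux_kf Value assigned to zero-flux reactions.
#' @param check_balance Verify S v = 0 first (skipped for partial data).
#' @return Named numeric vector of kf values with a logical attribute
#'   \code{"zero_flux"} flagging the defaulted entries.
#' @export
compute_percs <- function(model, ss, zero_flux_kf = 0, check_balance = TRUE) {
  if (check_balance) check_flux_balance(model, ss)
  x <- ss$concentrations
  kf <- numeric(length(model$reactions))
  names(kf) <- reaction_ids(model)
  zero <- logical(length(kf)); names(zero) <- names(kf)
  for (rid in names(kf)) {
    rxn <- model$reactions[[rid]]
    if (!is.null(model$custom_rates[[rid]]))
      stop("reaction '", rid, "' has a custom rate law; PERC inversion ",
           "applies only to mass-action kinetics")
    v <- ss$fluxes[[rid]]
    if (is.null(v) || is.na(v))
      stop("no steady-state flux for reaction '", rid, "'")
    D <- perc_denominator(rxn, x)
    if (v == 0) {
      kf[rid] <- zero_flux_kf
      zero[rid] <- TRUE
      next
    }
    if (D == 0)
      stop("reaction '", rid, "': non-zero flux with zero thermodynamic ",
           "driving force (mass-action ratio equals Keq)")
    if (sign(D) != sign(v))
      stop("reaction '", rid, "': flux sign (", sign(v),
           ") opposes the thermodynamic driving force (sign ", sign(D), ")")
    kf[rid] <- v / D
  }
  if (any(zero))
    warning("zero steady-state flux; kf set to ", zero_flux_kf, " for: ",
            paste(names(zero)[zero], collapse = ", "))
  attr(kf, "zero_flux") <- zero
  kf
}

#' Set rate constants on a model
#'
#' @param model A \code{mass_model}.
#' @param kf Named numeric vector (reaction id -> kf); e.g. the output of
#'   \code{\link{compute_percs}}.
#' @return The model with kf values assigned.
#' @export
set_rate_constants <- function(model, kf) {
  bad <- setdiff(names(kf), reaction_ids(model))
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  for (rid in names(kf)) model$reactions[[rid]]$kf <- unname(kf[[rid]])
  model
}

#' Parameterize a model from steady-state data
#'
#' Convenience wrapper: computes PERCs, assigns them, and sets the reference
#' state to the steady-state concentrations.
#'
#' @inheritParams compute_percs
#' @return A parameterized \code{mass_model}.
#' @export
parameterize <- function(model, ss, zero_flux_kf = 0, check_balance = TRUE) {
  kf <- compute_percs(model, ss, zero_flux_kf = zero_flux_kf,
                      check_balance = check_balance)
  model <- set_rate_constants(model, kf)
  for (sid in intersect(names(ss$concentrations), species_ids(model)))
    model$species[[sid]]$x0 <- unname(ss$concentrations[[sid]])
  model
}

#' Check flux directions against thermodynamic driving forces
#'
#' A steady state is thermodynamically consistent when every flux runs down
#' its driving force: \eqn{v (\ln K_{eq} - \ln\Gamma) \ge 0} for each
#' reaction, where Gamma is the mass-action ratio.
#'
#' @param model A \code{mass_model}.
#' @param ss A \code{steady_state_data}.
#' @return Data frame of violations (columns reaction, flux, ln_Keq,
#'   ln_gamma); zero rows means feasible.
#' @export
check_direction_consistency <- function(model, ss) {
  out <- data.frame(reaction = character(0), flux = numeric(0),
                    ln_Keq = numeric(0), ln_gamma = numeric(0))
  for (rxn in model$reactions) {
    if (!is.null(model$custom_rates[[rxn$id]])) next
    v <- ss$fluxes[[rxn$id]]
    if (is.null(v) || is.na(v) || v == 0) next
    g <- log(mass_action_ratio(rxn, ss$concentrations))
    lk <- log(rxn$Keq)  # Inf for irreversible
    force_sign <- sign(lk - g)
    if (v * force_sign < 0 || (force_sign == 0 && v != 0))
      out <- rbind(out, data.frame(reaction = rxn$id, flux = v,
                                   ln_Keq = lk, ln_gamma = g))
  }
  out
}

#' Gibbs free energy of reaction
#'
#' \eqn{\Delta G = R T \ln(\Gamma / K_{eq})}: negative iff the forward
#' direction is thermodynamically favoured at the given state.
#'
#' @param rxn A \code{mass_reaction}.
#' @param x Named concentrations (molar).
#' @param temperature Kelvin.
#' @return kJ/mol. Irreversible reactions have no finite equilibrium
#'   constant; \code{-Inf} is returned with a warning.
#' @export
gibbs_energy <- function(rxn, x, temperature = 310.15) {
  g <- mass_action_ratio(rxn, x)
  if (!rxn$reversible || is.infinite(rxn$Keq)) {
    warning("reaction '", rxn$id,
            "' is irreversible; Gibbs energy is unbounded (-Inf)")
    return(-Inf)
  }
  GAS_CONSTANT * temperature * (log(g) - log(rxn$Keq))
}

#' Convert fluxes from biomass-specific to molar units
#'
#' Fluxomics is commonly reported per gram dry weight
#' (mmol gDW^-1 h^-1); kinetic models need volumetric molar units. With a
#' cell density in gDW per litre of cell volume,
#' \eqn{v_{molar} = v \cdot \rho / 1000}.
#'
#' @param v Flux(es) in mmol gDW^-1 h^-1 (signed).
#' @param density gDW per litre cell volume (> 0).
#' @return Flux(es) in molar per hour.
#' @export
#' @examples
#' convert_flux_units(1, density = 300)  # 0.3 M/h
convert_flux_units <- function(v, density) {
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density <= 0)
    stop("density must be a single positive number (gDW per litre)")
  v * density / 1000
}
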