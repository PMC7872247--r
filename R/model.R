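#' Create a species
#'
#' A species is a metabolite or enzyme form taking part in a kinetic model.
#' Concentrations are molar throughout; time is in hours.
#'
#' @param id Short unique identifier (used in stoichiometry maps and rate laws).
#' @param name Free-text name.
#' @param compartment Compartment label (bookkeeping only; volumes are not
#'   tracked).
#' @param x0 Reference/initial concentration in molar. Must be non-negative;
#'   strictly positive unless the species is a fixed boundary.
#' @param fixed Logical; fixed (boundary) species are held constant and
#'   contribute no ODE.
#' @return An object of class \code{mass_species}.
#' @export
#' @examples
#' species("atp", x0 = 1.6e-3)
species <- function(id, name = id, compartment = "c", x0 = 1, fixed = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(x0) || length(x0) != 1L || is.na(x0) || x0 < 0)
    stop("species '", id, "': x0 must be a single non-negative number")
  structure(
    list(id = id, name = name, compartment = compartment,
         x0 = as.numeric(x0), fixed = isTRUE(fixed)),
    class = "mass_species"
  )
}

#' Create a reaction
#'
#' Reactions carry reactant/product stoichiometry maps, a forward
#' pseudo-elementary rate constant \code{kf} and an equilibrium constant
#' \code{Keq} (dimensionless on the molar scale). The default rate law is
#' mass action,
#' \deqn{v = k_f \left(\prod_s x_s^{a_s} - \frac{1}{K_{eq}} \prod_p x_p^{b_p}\right),}
#' dropping the reverse term for irreversible reactions.
#'
#' Species appearing on both sides are net-cancelled at construction so that
#' rate-law exponents are well defined. Stoichiometric coefficients must be
#' positive integers. Irreversibility is encoded as \code{Keq = Inf}; the
#' reverse term is dropped symbolically and never evaluated.
#'
#' @param id Reaction identifier.
#' @param reactants Named numeric vector of positive integer coefficients.
#' @param products Named numeric vector of positive integer coefficients.
#' @param kf Forward rate constant, units concentration^(1-order) per hour;
#'   may be \code{NA} until parameterized.
#' @param Keq Equilibrium constant (> 0). Ignored (forced to \code{Inf}) when
#'   \code{reversible = FALSE}.
#' @param reversible Logical.
#' @param subsystem Optional subsystem label.
#' @return An object of class \code{mass_reaction}.
#' @export
#' @examples
#' reaction("PYK", c(pep = 1, adp = 1), c(pyr = 1, atp = 1),
#'          kf = 2, reversible = FALSE)
reaction <- function(id, reactants, products, kf = NA_real_, Keq = NA_real_,
                     reversible = TRUE, subsystem = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- check_stoich(reactants, id, "reactants")
  products <- check_stoich(products, id, "products")
  # net-cancel species occurring on both sides
  both <- intersect(names(reactants), names(products))
  for (s in both) {
    net <- products[s] - reactants[s]
    reactants <- reactants[names(reactants) != s]
    products <- products[names(products) != s]
    if (net > 0) products <- c(products, stats::setNames(net, s))
    if (net < 0) reactants <- c(reactants, stats::setNames(-net, s))
  }
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "': empty after net-cancellation")
  if (!is.na(kf) && kf < 0)
    stop("reaction '", id, "': kf must be >= 0")
  if (!reversible) {
    Keq <- Inf
  } else {
    if (!is.na(Keq) && (!is.numeric(Keq) || Keq <= 0))
      stop("reaction '", id, "': Keq must be > 0 for a reversible reaction")
    if (is.infinite(Keq)) reversible <- FALSE
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         kf = as.numeric(kf), Keq = as.numeric(Keq),
         reversible = isTRUE(reversible), subsystem = subsystem),
    class = "mass_reaction"
  )
}

check_stoich <- function(coef, rid, side) {
  if (is.null(coef) || length(coef) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(coef)) || any(!nzchar(names(coef))))
    stop("reaction '", rid, "': ", side, " must be a named vector")
  if (anyDuplicated(names(coef)))
    stop("reaction '", rid, "': duplicated species in ", side)
  if (any(coef <= 0) || any(coef != round(coef)))
    stop("reaction '", rid, "': stoichiometric coefficients must be positive integers")
  stats::setNames(as.numeric(coef), names(coef))
}

#' Reaction order (sum of reactant coefficients)
#' @param rxn A \code{mass_reaction}.
#' @return Integer forward reaction order.
#' @export
reaction_order <- function(rxn) sum(rxn$reactants)

#' Assemble a kinetic model
#'
#' Collects species and reactions into a model with a fixed ordering, so the
#' stoichiometric matrix is reproducible. Every species referenced by a
#' reaction must be declared; ids must be unique.
#'
#' Custom rate laws replace the default mass-action law for the named
#' reactions. They are quoted R expressions whose only free symbols are
#' species ids, \code{kf} and \code{Keq} (the latter two bound to the owning
#' reaction's values). Reactions with a custom rate bypass the mass-action
#' ratio / PERC machinery and are flagged as such.
#'
#' @param species List of \code{mass_species}.
#' @param reactions List of \code{mass_reaction}.
#' @param custom_rates Named list (reaction id -> quoted expression).
#' @return An object of class \code{mass_model}.
#' @export
mass_model <- function(species, reactions, custom_rates = list()) {
  if (inherits(species, "mass_species")) species <- list(species)
  if (inherits(reactions, "mass_reaction")) reactions <- list(reactions)
  sp_ids <- vapply(species, function(s) s$id, character(1))
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(sp_ids)) stop("duplicated species ids: ",
                                  paste(sp_ids[duplicated(sp_ids)], collapse = ", "))
  if (anyDuplicated(rx_ids)) stop("duplicated reaction ids: ",
                                  paste(rx_ids[duplicated(rx_ids)], collapse = ", "))
  names(species) <- sp_ids
  names(reactions) <- rx_ids
  for (r in reactions) {
    refs <- c(names(r$reactants), names(r$products))
    miss <- setdiff(refs, sp_ids)
    if (length(miss))
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(miss, collapse = ", "))
  }
  if (length(custom_rates)) {
    bad <- setdiff(names(custom_rates), rx_ids)
    if (length(bad)) stop("custom rates for unknown reactions: ",
                          paste(bad, collapse = ", "))
    for (rid in names(custom_rates)) {
      vars <- all.vars(custom_rates[[rid]])
      free <- setdiff(vars, c(sp_ids, "kf", "Keq"))
      if (length(free))
        stop("custom rate for '", rid, "' has unresolved symbols: ",
             paste(free, collapse = ", "))
    }
  }
  structure(
    list(species = species, reactions = reactions, custom_rates = custom_rates),
    class = "mass_model"
  )
}

#' @export
print.mass_model <- function(x, ...) {
  nfix <- sum(vapply(x$species, `[[`, logical(1), "fixed"))
  cat("mass_model:", length(x$species), "species (", nfix, "fixed ),",
      length(x$reactions), "reactions\n")
  if (length(x$custom_rates))
    cat("  custom rate laws:", paste(names(x$custom_rates), collapse = ", "), "\n")
  invisible(x)
}

species_ids <- function(model) names(model$species)
reaction_ids <- function(model) names(model$reactions)

#' Fixed-species indicator
#' @param model A \code{mass_model}.
#' @return Named logical vector over species.
#' @export
fixed_species <- function(model)
  vapply(model$species, `[[`, logical(1), "fixed")

#' Reference concentrations
#' @param model A \code{mass_model}.
#' @return Named numeric vector of reference concentrations (molar).
#' @export
reference_state <- function(model)
  vapply(model$species, `[[`, numeric(1), "x0")

#' Stoichiometric matrix
#'
#' @param model A \code{mass_model}.
#' @return Matrix S (n_species x n_reactions) with \code{S[i, j]} the net
#'   coefficient of species i in reaction j (products minus reactants). Rows
#'   of fixed species are present; the logical attribute \code{"fixed"} flags
#'   them.
#' @export
stoich_matrix <- function(model) {
  sp <- species_ids(model)
  rx <- reaction_ids(model)
  S <- matrix(0, nrow = length(sp), ncol = length(rx), dimnames = list(sp, rx))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  attr(S, "fixed") <- fixed_species(model)
  S
}

get_conc <- function(x, ids, what = "rate evaluation") {
  miss <- setdiff(ids, names(x))
  if (length(miss))
    stop("missing species concentration(s) for ", what, ": ",
         paste(miss, collapse = ", "))
  xs <- x[ids]
  if (any(xs < 0))
    stop("negative concentration(s): ",
         paste(ids[xs < 0], collapse = ", "))
  xs
}

#' Mass-action reaction rate
#'
#' Evaluates \eqn{v = k_f(\prod x_s^{a} - K_{eq}^{-1} \prod x_p^{b})}, or
#' \eqn{v = k_f \prod x_s^{a}} for irreversible reactions. At the equilibrium
#' state (mass-action ratio equal to \code{Keq}) the rate is exactly zero.
#'
#' @param rxn A \code{mass_reaction} with \code{kf} set.
#' @param x Named numeric vector of concentrations (molar).
#' @return Rate in molar per hour.
#' @export
mass_action_rate <- function(rxn, x) {
  if (is.na(rxn$kf)) stop("reaction '", rxn$id, "': kf is not set")
  xs <- get_conc(x, names(rxn$reactants))
  fwd <- prod(xs^rxn$reactants)
  if (!rxn$reversible) return(rxn$kf * fwd)
  if (is.na(rxn$Keq)) stop("reaction '", rxn$id, "': Keq is not set")
  xp <- get_conc(x, names(rxn$products))
  rxn$kf * (fwd - prod(xp^rxn$products) / rxn$Keq)
}

#' Mass-action ratio
#'
#' The ratio of product to reactant concentrations, each raised to its
#' stoichiometric coefficient. Its distance from \code{Keq} measures the
#' thermodynamic driving force of the reaction.
#'
#' @param rxn A \code{mass_reaction}.
#' @param x Named numeric vector of concentrations.
#' @return Dimensionless ratio.
#' @export
mass_action_ratio <- function(rxn, x) {
  xs <- get_conc(x, names(rxn$reactants), "mass-action ratio")
  if (any(xs == 0))
    stop("mass-action ratio undefined: zero reactant concentration in '",
         rxn$id, "'")
  xp <- get_conc(x, names(rxn$products), "mass-action ratio")
  prod(xp^rxn$products) / prod(xs^rxn$reactants)
}

# Quoted rate expression for one reaction. Species ids appear as symbols;
# kf/Keq are substituted numerically when available, else left symbolic.
rate_expr <- function(rxn, custom = NULL) {
  if (!is.null(custom)) {
    env <- list(kf = rxn$kf, Keq = rxn$Keq)
    env <- env[!vapply(env, is.na, logical(1))]
    return(do.call(substitute, list(custom, env)))
  }
  pow1 <- function(id, k) {
    if (k == 1) as.name(id) else call("^", as.name(id), k)
  }
  side <- function(coef) {
    ids <- names(coef)
    if (length(ids) == 0L) return(1)
    e <- pow1(ids[1L], coef[1L])
    for (i in seq_along(ids)[-1L]) e <- call("*", e, pow1(ids[i], coef[i]))
    e
  }
  kf <- if (is.na(rxn$kf)) as.name(paste0("kf_", rxn$id)) else rxn$kf
  fwd <- side(rxn$reactants)
  if (!rxn$reversible) return(call("*", kf, fwd))
  keq <- if (is.na(rxn$Keq)) as.name(paste0("Keq_", rxn$id)) else rxn$Keq
  call("*", kf, call("-", fwd, call("/", side(rxn$products), keq)))
}

#' Rate-law expressions for all reactions
#'
#' @param model A \code{mass_model}.
#' @return Named list of quoted R expressions, one per reaction, in reaction
#'   order. Custom rate laws override the default mass-action form.
#' @export
rate_expressions <- function(model) {
  out <- lapply(model$reactions, function(r)
    rate_expr(r, custom = model$custom_rates[[r$id]]))
  names(out) <- reaction_ids(model)
  out
}

#' Assemble the ODE right-hand side symbolically
#'
#' Each species' time derivative combines the rates of the reactions in which
#' it participates: \eqn{dx_i/dt = \sum_j S_{ij} v_j}. Fixed species map to
#' the constant 0.
#'
#' @param model A \code{mass_model} (all rate laws resolvable).
#' @return Named list of quoted expressions (species id -> dx/dt).
#' @export
build_odes <- function(model) {
  S <- stoich_matrix(model)
  rates <- rate_expressions(model)
  fx <- fixed_species(model)
  out <- vector("list", length(model$species))
  names(out) <- species_ids(model)
  for (i in seq_along(out)) {
    if (fx[i]) { out[[i]] <- 0; next }
    expr <- NULL
    for (j in seq_along(rates)) {
      s <- S[i, j]
      if (s == 0) next
      term <- if (s == 1) rates[[j]] else call("*", s, rates[[j]])
      expr <- if (is.null(expr)) {
        if (s == -1) call("-", rates[[j]]) else term
      } else if (s == -1) {
        call("-", expr, rates[[j]])
      } else {
        call("+", expr, term)
      }
    }
    out[[i]] <- if (is.null(expr)) 0 else expr
  }
  out
}

#' Conserved pools (left nullspace of S)
#'
#' Each returned vector l satisfies l'S = 0, so the weighted concentration
#' sum l.x is constant along any trajectory (a conserved moiety). The basis
#' is computed by exact rational row reduction of the stoichiometric matrix
#' and scaled to minimal integers with a positive leading entry.
#'
#' @param model A \code{mass_model}.
#' @return Matrix with one conserved pool per row (0 rows if none), columns
#'   named by the non-fixed species.
#' @export
conserved_pools <- function(model) {
  nf <- !fixed_species(model)
  S <- unclass(stoich_matrix(model))[nf, , drop = FALSE]
  # left nullspace of S = nullspace of t(S); fixed species are clamped, not
  # conserved, so only non-fixed rows enter
  B <- rational_nullspace(t(S))
  colnames(B) <- species_ids(model)[nf]
  B
}
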