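# Mechanistic enzyme modules: stoichiometric expansions of net enzymatic
# reactions into elementary binding/catalysis/release steps, with enzyme
# forms as explicit species.

#' Create an enzyme form
#'
#' An enzyme form is a species representing one microscopic state of an
#' enzyme (free, substrate-bound, alternative conformation, ...). Forms are
#' tagged with free-form categories such as "active"/"inactive" or
#' "R-state"/"T-state"; every form participates in the enzyme's conservation
#' pool.
#'
#' @param id Species id of the form.
#' @param enzyme_id Owning enzyme.
#' @param bound_ligands Named integer vector, ligand species id -> count.
#' @param categories Character vector of tags.
#' @param x0 Initial concentration (molar).
#' @param compartment Compartment label.
#' @return A species of class \code{c("enzyme_form", "mass_species")}.
#' @export
enzyme_form <- function(id, enzyme_id, bound_ligands = integer(0),
                        categories = character(0), x0 = 0,
                        compartment = "c") {
  sp <- species(id, compartment = compartment, x0 = x0, fixed = FALSE)
  sp$enzyme_id <- enzyme_id
  sp$bound_ligands <- bound_ligands
  sp$categories <- categories
  class(sp) <- c("enzyme_form", "mass_species")
  sp
}

new_enzyme_module <- function(enzyme_id, forms, steps, path_steps, net_reactants,
                              net_products, keq_net, e_total,
                              e_total_default = FALSE, replaces = NULL) {
  names(forms) <- vapply(forms, `[[`, character(1), "id")
  names(steps) <- vapply(steps, `[[`, character(1), "id")
  structure(
    list(enzyme_id = enzyme_id, forms = forms, steps = steps,
         path_steps = path_steps, net_reactants = net_reactants,
         net_products = net_products, keq_net = keq_net,
         e_total = e_total, e_total_default = e_total_default,
         replaces = replaces, target_net_flux = NA_real_, fitted = FALSE),
    class = "enzyme_module"
  )
}

#' @export
print.enzyme_module <- function(x, ...) {
  cat("enzyme_module '", x$enzyme_id, "': ", length(x$forms), " forms, ",
      length(x$steps), " elementary steps, Keq_net = ", x$keq_net,
      if (x$fitted) " (fitted)" else " (unfitted)", "\n", sep = "")
  invisible(x)
}

form_ids <- function(module) names(module$forms)

#' Build a uni-uni enzyme module
#'
#' Expands a one-substrate/one-product enzymatic reaction into elementary
#' mass-action steps. With \code{n_steps = 2}: E + S = ES, ES = E + P; with
#' \code{n_steps = 3} an EP complex is added before product release. Step
#' equilibrium constants are unassigned until fitting, constrained by the
#' Haldane relation to multiply to \code{keq_net} along the catalytic path.
#'
#' @param enzyme_id Module id (also the id of the free-enzyme form).
#' @param substrate,product Ligand species ids (must differ).
#' @param keq_net Net equilibrium constant of the catalyzed reaction (> 0).
#' @param n_steps 2 or 3.
#' @param e_total Total enzyme concentration (molar); defaults to 1e-6 and
#'   is flagged as defaulted in the module's provenance.
#' @param replaces Optional host-model reaction id that the module replaces.
#' @return An unfitted \code{enzyme_module}.
#' @export
build_uni_uni <- function(enzyme_id, substrate, product, keq_net,
                          n_steps = 2, e_total = NULL, replaces = NULL) {
  stopifnot(keq_net > 0, n_steps %in% c(2, 3))
  if (identical(substrate, product))
    stop("substrate and product must differ")
  e_default <- is.null(e_total)
  if (e_default) e_total <- 1e-6
  E <- enzyme_form(enzyme_id, enzyme_id, categories = "active")
  ES <- enzyme_form(paste(enzyme_id, substrate, sep = "_"), enzyme_id,
                    bound_ligands = stats::setNames(1L, substrate),
                    categories = "active")
  bind <- reaction(paste0(enzyme_id, "_bind"),
                   stats::setNames(c(1, 1), c(E$id, substrate)),
                   stats::setNames(1, ES$id))
  if (n_steps == 2) {
    cat_ <- reaction(paste0(enzyme_id, "_cat"),
                     stats::setNames(1, ES$id),
                     stats::setNames(c(1, 1), c(E$id, product)))
    forms <- list(E, ES); steps <- list(bind, cat_)
  } else {
    EP <- enzyme_form(paste(enzyme_id, product, sep = "_"), enzyme_id,
                      bound_ligands = stats::setNames(1L, product),
                      categories = "active")
    cat_ <- reaction(paste0(enzyme_id, "_cat"),
                     stats::setNames(1, ES$id), stats::setNames(1, EP$id))
    rel <- reaction(paste0(enzyme_id, "_release"),
                    stats::setNames(1, EP$id),
                    stats::setNames(c(1, 1), c(E$id, product)))
    forms <- list(E, ES, EP); steps <- list(bind, cat_, rel)
  }
  new_enzyme_module(enzyme_id, forms, steps,
                    path_steps = vapply(steps, `[[`, character(1), "id"),
                    net_reactants = stats::setNames(1, substrate),
                    net_products = stats::setNames(1, product),
                    keq_net = keq_net, e_total = e_total,
                    e_total_default = e_default, replaces = replaces)
}

#' Build an ordered bi-bi enzyme module
#'
#' E + A = EA, EA + B = EAB, EAB = EQ + P, EQ = E + Q (compulsory binding
#' order; random-order mechanisms are out of scope).
#'
#' @param enzyme_id Module id.
#' @param substrates Character(2): A binds first.
#' @param products Character(2): P released first.
#' @inheritParams build_uni_uni
#' @return An unfitted \code{enzyme_module}.
#' @export
build_ordered_bi_bi <- function(enzyme_id, substrates, products, keq_net,
                                e_total = NULL, replaces = NULL) {
  stopifnot(length(substrates) == 2, length(products) == 2, keq_net > 0)
  if (length(intersect(substrates, products)))
    stop("substrates and products must be disjoint")
  e_default <- is.null(e_total)
  if (e_default) e_total <- 1e-6
  A <- substrates[1]; B <- substrates[2]; P <- products[1]; Q <- products[2]
  E <- enzyme_form(enzyme_id, enzyme_id, categories = "active")
  EA <- enzyme_form(paste(enzyme_id, A, sep = "_"), enzyme_id,
                    stats::setNames(1L, A), "active")
  EAB <- enzyme_form(paste(enzyme_id, A, B, sep = "_"), enzyme_id,
                     stats::setNames(c(1L, 1L), c(A, B)), "active")
  EQ <- enzyme_form(paste(enzyme_id, Q, sep = "_"), enzyme_id,
                    stats::setNames(1L, Q), "active")
  steps <- list(
    reaction(paste0(enzyme_id, "_bind1"),
             stats::setNames(c(1, 1), c(E$id, A)), stats::setNames(1, EA$id)),
    reaction(paste0(enzyme_id, "_bind2"),
             stats::setNames(c(1, 1), c(EA$id, B)), stats::setNames(1, EAB$id)),
    reaction(paste0(enzyme_id, "_cat"),
             stats::setNames(1, EAB$id),
             stats::setNames(c(1, 1), c(EQ$id, P))),
    reaction(paste0(enzyme_id, "_release"),
             stats::setNames(1, EQ$id),
             stats::setNames(c(1, 1), c(E$id, Q)))
  )
  new_enzyme_module(enzyme_id, list(E, EA, EAB, EQ), steps,
                    path_steps = vapply(steps, `[[`, character(1), "id"),
                    net_reactants = stats::setNames(c(1, 1), c(A, B)),
                    net_products = stats::setNames(c(1, 1), c(P, Q)),
                    keq_net = keq_net, e_total = e_total,
                    e_total_default = e_default, replaces = replaces)
}

#' Build a two-state (MWC-style) allosteric uni-uni module
#'
#' Adds a catalytically inactive T conformation in equilibrium with the
#' active R conformation (allosteric constant \code{L} = [T]/[R] at
#' equilibrium). Catalysis runs on the R state: R + S = RS, RS = R + P.
#' The R = T transition is off the catalytic path; its equilibrium constant
#' is fixed at \code{L} and not subject to the Haldane constraint.
#'
#' @inheritParams build_uni_uni
#' @param L Allosteric equilibrium constant of the R = T transition (> 0).
#' @return An unfitted \code{enzyme_module} with R-state forms tagged
#'   "active"/"R-state" and the T form "inactive"/"T-state".
#' @export
build_mwc_uni_uni <- function(enzyme_id, substrate, product, keq_net, L,
                              e_total = NULL, replaces = NULL) {
  stopifnot(keq_net > 0, L > 0)
  e_default <- is.null(e_total)
  if (e_default) e_total <- 1e-6
  R0 <- enzyme_form(paste0(enzyme_id, "_R"), enzyme_id,
                    categories = c("active", "R-state"))
  RS <- enzyme_form(paste(enzyme_id, "R", substrate, sep = "_"), enzyme_id,
                    stats::setNames(1L, substrate),
                    categories = c("active", "R-state"))
  T0 <- enzyme_form(paste0(enzyme_id, "_T"), enzyme_id,
                    categories = c("inactive", "T-state"))
  steps <- list(
    reaction(paste0(enzyme_id, "_bind"),
             stats::setNames(c(1, 1), c(R0$id, substrate)),
             stats::setNames(1, RS$id)),
    reaction(paste0(enzyme_id, "_cat"),
             stats::setNames(1, RS$id),
             stats::setNames(c(1, 1), c(R0$id, product))),
    reaction(paste0(enzyme_id, "_transition"),
             stats::setNames(1, R0$id), stats::setNames(1, T0$id),
             Keq = L)
  )
  new_enzyme_module(enzyme_id, list(R0, RS, T0), steps,
                    path_steps = c(paste0(enzyme_id, "_bind"),
                                   paste0(enzyme_id, "_cat")),
                    net_reactants = stats::setNames(1, substrate),
                    net_products = stats::setNames(1, product),
                    keq_net = keq_net, e_total = e_total,
                    e_total_default = e_default, replaces = replaces)
}

module_ligands <- function(module) {
  all_sp <- unique(unlist(lapply(module$steps, function(r)
    c(names(r$reactants), names(r$products)))))
  setdiff(all_sp, form_ids(module))
}

# Internal model of the module: forms free, ligands fixed at given values.
module_model <- function(module, ligand_conc, form_conc = NULL) {
  lig <- module_ligands(module)
  miss <- setdiff(lig, names(ligand_conc))
  if (length(miss)) stop("missing ligand concentration(s): ",
                         paste(miss, collapse = ", "))
  sp <- c(
    lapply(module$forms, function(f) {
      if (!is.null(form_conc)) f$x0 <- unname(form_conc[[f$id]])
      f
    }),
    lapply(lig, function(s) species(s, x0 = unname(ligand_conc[[s]]),
                                    fixed = TRUE))
  )
  mass_model(sp, module$steps)
}

#' Net steady-state flux through an enzyme module
#'
#' Solves the module's internal steady state at fixed ligand concentrations
#' and total enzyme \code{e_total} (the elementary rates are linear in the
#' enzyme forms, so this is a linear solve with the conservation
#' constraint), and returns the net catalytic flux through the
#' product-releasing step.
#'
#' @param module A parameterized \code{enzyme_module} (all step kf/Keq set).
#' @param ligand_conc Named ligand concentrations (molar).
#' @return Net flux (molar/h), with attribute \code{"forms"} carrying the
#'   internal steady-state form concentrations.
#' @export
steady_state_net_flux <- function(module, ligand_conc) {
  mm <- module_model(module, ligand_conc)
  fids <- form_ids(module)
  nfx <- length(fids)
  rate_fn <- make_rate_fn(mm)
  lig_vals <- ligand_conc[module_ligands(module)]
  # rates are linear homogeneous in the forms: columns from unit vectors
  C <- vapply(seq_len(nfx), function(i) {
    x <- stats::setNames(rep(0, nfx), fids)
    x[i] <- 1
    unname(rate_fn(c(x, lig_vals)))
  }, numeric(length(module$steps)))
  C <- matrix(C, nrow = length(module$steps))
  S <- unclass(stoich_matrix(mm))[fids, , drop = FALSE]
  A <- S %*% C
  A[nfx, ] <- 1  # replace one balance (they are rank-deficient) by conservation
  rhs <- c(rep(0, nfx - 1), module$e_total)
  forms <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular internal system for enzyme module '", module$enzyme_id, "'"))
  forms <- stats::setNames(as.vector(forms), fids)
  flux <- as.vector(C %*% forms)
  names(flux) <- names(module$steps)
  reporter <- module$path_steps[length(module$path_steps)]
  structure(unname(flux[reporter]), forms = forms, step_fluxes = flux)
}

#' Haldane product of an enzyme module
#'
#' The product of the elementary-step equilibrium constants along the
#' catalytic path. The Haldane relation requires it to equal the module's
#' net equilibrium constant; \code{\link{fit_rate_constants}} enforces this
#' by construction.
#'
#' @param module An \code{enzyme_module} with path-step Keq values assigned.
#' @return The product over \code{module$path_steps}.
#' @export
haldane_product <- function(module) {
  prod(vapply(module$steps[module$path_steps], `[[`, numeric(1), "Keq"))
}

net_mass_action_ratio <- function(module, ligand_conc) {
  xs <- ligand_conc[names(module$net_reactants)]
  xp <- ligand_conc[names(module$net_products)]
  prod(xp^module$net_products) / prod(xs^module$net_reactants)
}

#' Fit elementary rate constants of an enzyme module
#'
#' Finds non-negative elementary rate constants whose internal steady state
#' carries the target net flux at the given ligand concentrations, subject
#' to the Haldane constraint (the catalytic-path equilibrium constants
#' multiply exactly to \code{keq_net}; enforced by eliminating the last
#' path step's Keq, not by penalty). Fitting variables are log-transformed,
#' so positivity holds by construction. Optional Michaelis constants and
#' turnover numbers enter as additional squared residuals.
#'
#' A target flux whose sign opposes the net thermodynamic driving force at
#' the given ligand concentrations is rejected before optimization.
#'
#' @param module An \code{enzyme_module}.
#' @param ligand_conc Named ligand concentrations (molar).
#' @param target_flux Net flux the module must carry (molar/h).
#' @param kinetic_constraints Optional list with entries \code{kcat}
#'   (forward turnover, 1/h) and/or \code{Km} (Michaelis constant of the
#'   first substrate, molar); uni-uni 2-step only.
#' @param rel_tol Required relative flux residual for achievable targets.
#' @return The module with fitted step kf/Keq, \code{fitted = TRUE}.
#' @export
fit_rate_constants <- function(module, ligand_conc, target_flux,
                               kinetic_constraints = NULL, rel_tol = 1e-8) {
  gamma_net <- net_mass_action_ratio(module, ligand_conc)
  drive <- sign(log(module$keq_net) - log(gamma_net))
  if (target_flux != 0 && sign(target_flux) != drive)
    stop("target flux sign (", sign(target_flux),
         ") opposes the net thermodynamic driving force (", drive,
         ") for enzyme module '", module$enzyme_id, "'")
  np <- length(module$path_steps)
  set_params <- function(log_kf, log_keq_front) {
    m <- module
    keq_front <- exp(log_keq_front)
    keq_last <- module$keq_net / prod(keq_front)
    keq_path <- c(keq_front, keq_last)
    for (i in seq_along(m$steps)) {
      m$steps[[i]]$kf <- exp(log_kf[i])
      sid <- m$steps[[i]]$id
      j <- match(sid, m$path_steps)
      if (!is.na(j)) {
        m$steps[[i]]$Keq <- keq_path[j]
      } else if (is.na(m$steps[[i]]$Keq)) {
        stop("off-path step '", sid, "' has no preassigned Keq")
      }
    }
    m
  }
  # analytic seed: even Keq split along the path, unit kf; the internal
  # steady state is linear in total enzyme and jointly linear in all kf, so
  # rescaling every kf by target/f0 hits the target exactly
  log_keq0 <- rep(log(module$keq_net) / np, np - 1)
  log_kf0 <- rep(0, length(module$steps))
  m0 <- set_params(log_kf0, log_keq0)
  f0 <- as.numeric(steady_state_net_flux(m0, ligand_conc))
  if (target_flux == 0) {
    fitted <- m0
  } else {
    if (f0 == 0) stop("degenerate seed flux in rate-constant fitting")
    log_kf0 <- log_kf0 + log(target_flux / f0)
    fitted <- set_params(log_kf0, log_keq0)
  }
  if (!is.null(kinetic_constraints)) {
    scale <- max(abs(target_flux), 1e-12)
    objective <- function(theta) {
      lk <- theta[seq_along(module$steps)]
      lq <- theta[-seq_along(module$steps)]
      m <- set_params(lk, lq)
      f <- tryCatch(as.numeric(steady_state_net_flux(m, ligand_conc)),
                    error = function(e) NA_real_)
      if (is.na(f)) return(1e10)
      r <- ((f - target_flux) / scale)^2
      k1 <- m$steps[[module$path_steps[1]]]
      k2 <- m$steps[[module$path_steps[length(module$path_steps)]]]
      if (!is.null(kinetic_constraints$kcat)) {
        r <- r + (log(k2$kf) - log(kinetic_constraints$kcat))^2
      }
      if (!is.null(kinetic_constraints$Km)) {
        km <- (k1$kf / k1$Keq + k2$kf) / k1$kf
        r <- r + (log(km) - log(kinetic_constraints$Km))^2
      }
      r
    }
    theta0 <- c(log_kf0, log_keq0)
    opt <- stats::nlminb(theta0, objective,
                         control = list(iter.max = 500, eval.max = 1000))
    fitted <- set_params(opt$par[seq_along(module$steps)],
                         opt$par[-seq_along(module$steps)])
  }
  f_fit <- as.numeric(steady_state_net_flux(fitted, ligand_conc))
  rel <- if (target_flux == 0) abs(f_fit) else
    abs(f_fit - target_flux) / abs(target_flux)
  if (is.null(kinetic_constraints) && rel > rel_tol)
    stop("rate-constant fit did not reach the target flux (relative ",
         "residual ", signif(rel, 3), ")")
  fitted$target_net_flux <- target_flux
  fitted$fitted <- TRUE
  fitted
}

#' Merge a fitted enzyme module into a host model
#'
#' Removes the host reaction named by \code{module$replaces} and adds the
#' module's elementary steps and enzyme forms. Form initial concentrations
#' are set to the module's internal steady state at the host's reference
#' ligand concentrations, so the merged model preserves the host's
#' reference steady state (verified: net module flux must match the removed
#' reaction's reference flux to 1e-6 relative). The enzyme conservation
#' pool then appears among \code{\link{conserved_pools}}.
#'
#' @param model A parameterized host \code{mass_model}.
#' @param module A fitted \code{enzyme_module} with \code{replaces} set.
#' @return The merged model; the replaced reaction is retained in the
#'   attribute \code{"merged_modules"} so the merge can be undone with
#'   \code{\link{unmerge_module}}.
#' @export
merge_module <- function(model, module) {
  if (!module$fitted) stop("enzyme module '", module$enzyme_id,
                           "' must be fitted before merging")
  clash <- intersect(c(form_ids(module), names(module$steps)),
                     c(species_ids(model), reaction_ids(model)))
  if (length(clash))
    stop("id collision merging module '", module$enzyme_id, "': ",
         paste(clash, collapse = ", "))
  host_id <- module$replaces
  if (is.null(host_id) || !host_id %in% reaction_ids(model))
    stop("module$replaces ('", host_id, "') is not a reaction of the model")
  x_ref <- reference_state(model)
  host_rxn <- model$reactions[[host_id]]
  v_ref <- mass_action_rate(host_rxn, x_ref)
  flux <- steady_state_net_flux(module, x_ref)
  rel <- abs(as.numeric(flux) - v_ref) / max(abs(v_ref), 1e-300)
  if (rel > 1e-6)
    stop("module net flux (", signif(as.numeric(flux), 6),
         ") does not reproduce the replaced reaction's reference flux (",
         signif(v_ref, 6), "); refit at the model's reference state")
  forms_x <- attr(flux, "forms")
  new_species <- c(model$species,
                   lapply(module$forms, function(f) {
                     f$x0 <- unname(forms_x[[f$id]])
                     f
                   }))
  new_reactions <- c(model$reactions[setdiff(reaction_ids(model), host_id)],
                     module$steps)
  merged <- mass_model(new_species, new_reactions,
                       custom_rates = model$custom_rates)
  log <- c(attr(model, "merged_modules"),
           stats::setNames(list(list(module = module, host = host_rxn)),
                           module$enzyme_id))
  attr(merged, "merged_modules") <- log
  merged
}

#' Undo a module merge
#'
#' Removes the module's forms and steps and restores the replaced host
#' reaction with its original parameters.
#'
#' @param model A model previously produced by \code{\link{merge_module}}.
#' @param enzyme_id Which merged module to remove.
#' @return The restored model.
#' @export
unmerge_module <- function(model, enzyme_id) {
  log <- attr(model, "merged_modules")
  if (is.null(log[[enzyme_id]]))
    stop("no merged module '", enzyme_id, "' recorded on this model")
  entry <- log[[enzyme_id]]
  module <- entry$module
  keep_sp <- setdiff(species_ids(model), form_ids(module))
  keep_rx <- setdiff(reaction_ids(model), names(module$steps))
  restored <- mass_model(model$species[keep_sp],
                         c(model$reactions[keep_rx], list(entry$host)),
                         custom_rates = model$custom_rates)
  log[[enzyme_id]] <- NULL
  if (length(log)) attr(restored, "merged_modules") <- log
  restored
}

#' Fractional abundance of enzyme forms
#'
#' The concentration of each form divided by the total over all forms;
#' fractions sum to exactly 1.
#'
#' @param module An \code{enzyme_module}.
#' @param x Named concentrations containing every form of the module.
#' @return Named fractions over form ids.
#' @export
fractional_abundance <- function(module, x) {
  xs <- x[form_ids(module)]
  if (anyNA(xs)) stop("missing form concentration(s)")
  tot <- sum(xs)
  if (tot <= 0) stop("all enzyme forms at zero concentration")
  xs / tot
}

#' Split a net flux across isozymes
#'
#' @param net_flux Net flux to distribute.
#' @param fractions Non-negative fractions summing to 1 (tolerance 1e-9),
#'   e.g. \code{c(major = 0.75, minor = 0.25)}.
#' @return Per-isozyme fluxes (sum preserved).
#' @export
split_flux <- function(net_flux, fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  fractions * net_flux
}
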