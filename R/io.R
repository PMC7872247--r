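# Model import/export (JSON schema v1, SBML L3V1 core) and tabular IO.

MODEL_SCHEMA_VERSION <- 1L
SPECIES_FIELDS <- c("id", "name", "compartment", "x0", "fixed")
REACTION_FIELDS <- c("id", "reactants", "products", "kf", "Keq",
                     "reversible", "subsystem")

# Keq = Inf has no JSON representation; serialized as the string "inf".
keq_to_json <- function(Keq) {
  if (is.na(Keq)) NULL else if (is.infinite(Keq)) "inf" else Keq
}
keq_from_json <- function(x) {
  if (is.null(x)) NA_real_
  else if (identical(x, "inf")) Inf
  else as.numeric(x)
}

#' Write a model to JSON (schema v1)
#'
#' Top-level keys: \code{version}, \code{units}, \code{species},
#' \code{reactions}, plus an optional \code{enzyme_modules} block for
#' merged enzyme modules. Unknown extra fields read by
#' \code{\link{read_model_json}} are written back verbatim.
#'
#' @param model A \code{mass_model}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  sp <- lapply(model$species, function(s) {
    out <- list(id = s$id, name = s$name, compartment = s$compartment,
                x0 = s$x0, fixed = s$fixed)
    if (!is.null(s$enzyme_id)) out$enzyme_id <- s$enzyme_id
    if (length(s$categories)) out$categories <- as.list(s$categories)
    c(out, s$extra)
  })
  rx <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, reactants = as.list(r$reactants),
                products = as.list(r$products),
                kf = if (is.na(r$kf)) NULL else r$kf,
                Keq = keq_to_json(r$Keq),
                reversible = r$reversible)
    if (!is.null(r$subsystem)) out$subsystem <- r$subsystem
    c(out, r$extra)
  })
  doc <- list(version = MODEL_SCHEMA_VERSION,
              units = list(concentration = "M", time = "h"),
              species = unname(sp), reactions = unname(rx))
  if (length(model$custom_rates))
    doc$custom_rates <- lapply(model$custom_rates, function(e)
      paste(deparse(e), collapse = " "))
  extra_top <- attr(model, "extra_json")
  if (!is.null(extra_top)) doc <- c(doc, extra_top)
  # I(17) significant digits: doubles survive the write/read cycle bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON (schema v1)
#'
#' Validates required fields with field-level messages; a reversible
#' reaction without a \code{Keq} is a schema error naming the reaction.
#' Unknown extra fields are preserved verbatim for forward compatibility.
#'
#' @param path Path to a JSON file written in this package's schema.
#' @return A \code{mass_model}.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$version
  if (is.null(ver) || !(as.integer(ver) <= MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version: ", ver %||% "<missing>")
  if (is.null(doc$species) || is.null(doc$reactions))
    stop("schema error: top-level 'species' and 'reactions' are required")
  sp <- lapply(doc$species, function(e) {
    if (is.null(e$id)) stop("schema error: species entry without 'id'")
    s <- species(e$id, name = e$name %||% e$id,
                 compartment = e$compartment %||% "c",
                 x0 = e$x0 %||% 1, fixed = isTRUE(e$fixed))
    if (!is.null(e$enzyme_id)) {
      s$enzyme_id <- e$enzyme_id
      s$categories <- as.character(unlist(e$categories))
      class(s) <- c("enzyme_form", "mass_species")
    }
    extra <- e[setdiff(names(e), c(SPECIES_FIELDS, "enzyme_id", "categories"))]
    if (length(extra)) s$extra <- extra
    s
  })
  rx <- lapply(doc$reactions, function(e) {
    if (is.null(e$id)) stop("schema error: reaction entry without 'id'")
    reversible <- if (is.null(e$reversible)) TRUE else isTRUE(e$reversible)
    Keq <- keq_from_json(e$Keq)
    if (reversible && is.na(Keq))
      stop("schema error: reversible reaction '", e$id, "' is missing 'Keq'")
    r <- reaction(e$id,
                  reactants = unlist(e$reactants) %||% numeric(0),
                  products = unlist(e$products) %||% numeric(0),
                  kf = if (is.null(e$kf)) NA_real_ else as.numeric(e$kf),
                  Keq = Keq, reversible = reversible,
                  subsystem = e$subsystem)
    extra <- e[setdiff(names(e), REACTION_FIELDS)]
    if (length(extra)) r$extra <- extra
    r
  })
  custom <- lapply(doc$custom_rates %||% list(), function(s)
    str2lang(as.character(s)))
  m <- mass_model(sp, rx, custom_rates = custom)
  extra_top <- doc[setdiff(names(doc), c("version", "units", "species",
                                         "reactions", "custom_rates"))]
  if (length(extra_top)) attr(m, "extra_json") <- extra_top
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SBML export -----------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# Convert a quoted R expression (numbers, symbols, + - * / ^) to MathML.
expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", NULL)
    if (is.null(tag))
      stop("unserializable rate expression: operator '", op,
           "' has no SBML core MathML mapping")
    args <- lapply(as.list(e)[-1], expr_to_mathml)
    return(paste0("<apply><", tag, "/>",
                  paste(unlist(args), collapse = ""), "</apply>"))
  }
  stop("unserializable rate expression component: ", deparse(e))
}

#' Export a model as SBML Level 3 Version 1 core
#'
#' Writes compartments, species with initial concentrations (boundary
#' species flagged), and reactions with their kinetic laws rendered as
#' explicit MathML of the mass-action form (kf and Keq as local
#' parameters). Custom rate laws are rendered from their expressions when
#' they use only core arithmetic; anything else is an error.
#'
#' @param model A parameterized \code{mass_model}.
#' @param path Output file (.xml).
#' @return Invisibly, the path.
#' @export
export_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  compartments <- unique(vapply(model$species, `[[`, character(1), "compartment"))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    '  <model id="massdyn_model" name="massdyn export (concentrations molar, time hours)">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" spatialDimensions="3" size="1" constant="true"/>',
            compartments),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  for (s in model$species) {
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="%s"/>',
      s$id, esc(s$name), s$compartment, format(s$x0, digits = 17),
      tolower(s$fixed), tolower(s$fixed)))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in model$reactions) {
    if (is.na(r$kf) && is.null(model$custom_rates[[r$id]]))
      stop("reaction '", r$id, "': kf must be set before SBML export")
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false">',
      r$id, tolower(r$reversible)))
    sref <- function(coef)
      sprintf('        <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              names(coef), format(unname(coef)))
    if (length(r$reactants))
      lines <- c(lines, "        <listOfReactants>", sref(r$reactants),
                 "        </listOfReactants>")
    if (length(r$products))
      lines <- c(lines, "        <listOfProducts>", sref(r$products),
                 "        </listOfProducts>")
    custom <- model$custom_rates[[r$id]]
    if (is.null(custom)) {
      # mass-action law with kf (and Keq) as named local parameters
      sym_rxn <- r
      sym_rxn$kf <- NA_real_
      if (r$reversible) sym_rxn$Keq <- NA_real_
      ex <- rate_expr(sym_rxn)
      ex <- do.call(substitute, list(ex, stats::setNames(
        list(as.name("kf"), as.name("Keq")),
        c(paste0("kf_", r$id), paste0("Keq_", r$id)))))
      math <- expr_to_mathml(ex)
      params <- sprintf('          <localParameter id="kf" value="%s"/>',
                        format(r$kf, digits = 17))
      if (r$reversible)
        params <- c(params,
                    sprintf('          <localParameter id="Keq" value="%s"/>',
                            format(r$Keq, digits = 17)))
      lines <- c(lines,
                 "        <kineticLaw>",
                 sprintf('          <math xmlns="%s">%s</math>', MATHML_NS, math),
                 "          <listOfLocalParameters>", params,
                 "          </listOfLocalParameters>",
                 "        </kineticLaw>")
    } else {
      ex <- rate_expr(r, custom = custom)
      math <- expr_to_mathml(ex)
      lines <- c(lines,
                 "        <kineticLaw>",
                 sprintf('          <math xmlns="%s">%s</math>', MATHML_NS, math),
                 "        </kineticLaw>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  # well-formedness check (parse fails on malformed output)
  invisible(xml2::read_xml(path))
  invisible(path)
}

# --- tabular IO ------------------------------------------------------------

read_two_column_csv <- function(path, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop(what, " CSV must have two columns (id, value): ", path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read steady-state data from CSV files
#'
#' Each file is a two-column CSV (id, value) with a header row: reaction
#' fluxes in molar/h and species concentrations in molar.
#'
#' @param flux_path,conc_path File paths.
#' @param temperature Kelvin.
#' @return A \code{steady_state_data}.
#' @export
read_steady_state_csv <- function(flux_path, conc_path,
                                  temperature = 310.15) {
  steady_state_data(read_two_column_csv(flux_path, "flux"),
                    read_two_column_csv(conc_path, "concentration"),
                    temperature = temperature)
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns time, id, kind (conc or flux), value.
#'
#' @param traj A \code{mass_trajectory}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- rbind(
    data.frame(time = rep(traj$times, ncol(traj$states)),
               id = rep(colnames(traj$states), each = length(traj$times)),
               kind = "conc", value = as.vector(traj$states)),
    data.frame(time = rep(traj$times, ncol(traj$fluxes)),
               id = rep(colnames(traj$fluxes), each = length(traj$times)),
               kind = "flux", value = as.vector(traj$fluxes))
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a sample set as CSV (sample index x variable id)
#' @param ss A \code{sample_set}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_samples_csv <- function(ss, path) {
  df <- as.data.frame(ss$samples)
  df <- cbind(sample = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dump a polytope to JSON (debugging aid)
#' @param p A \code{polytope}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_polytope_json <- function(p, path) {
  jsonlite::write_json(
    list(space = p$space, variable_ids = p$variable_ids,
         A = apply(p$A, 1, as.numeric, simplify = FALSE),
         b = p$b, lb = p$lb, ub = p$ub),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a run configuration (JSON or YAML)
#'
#' Recognized fields (defaults in parentheses): \code{seed} (1),
#' \code{rtol} (1e-8), \code{atol} (1e-12), \code{atol_ss} (1e-9),
#' \code{rtol_ss} (1e-6), sampler settings \code{n} (15), \code{thin}
#' (100), \code{bound_mode} ("deviation"), \code{d} (0.8), and
#' \code{perturbation} (list with \code{targets}, \code{time},
#' \code{absolute}). All tolerances must be positive.
#'
#' @param path Optional file path; defaults used when NULL.
#' @return Named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(seed = 1L, rtol = 1e-8, atol = 1e-12, atol_ss = 1e-9,
              rtol_ss = 1e-6, n = 15L, thin = 100L,
              bound_mode = "deviation", d = 0.8, perturbation = NULL)
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead")
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg[names(user)] <- user
  }
  for (tol in c("rtol", "atol", "atol_ss", "rtol_ss"))
    if (!is.numeric(cfg[[tol]]) || cfg[[tol]] <= 0)
      stop("config: '", tol, "' must be a positive number")
  cfg
}
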