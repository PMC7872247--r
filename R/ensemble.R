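# Ensemble workflow: assemble candidate models from sampled flux and
# concentration states, filter by dynamic stability, simulate the
# survivors, and aggregate ensemble statistics.

new_candidate <- function(flux_state_id, conc_state_id, model, status,
                          diagnostics = "") {
  structure(list(flux_state_id = flux_state_id, conc_state_id = conc_state_id,
                 model = model, status = status, diagnostics = diagnostics),
            class = "mass_candidate")
}

#' Assemble candidate models from sampled states
#'
#' Builds one candidate per element of the Cartesian product of flux states
#' and concentration states, parameterizing each via PERC computation.
#' Pairs that violate direction consistency (or fail PERC inversion) are
#' marked \code{infeasible} with a diagnostic, never dropped silently.
#'
#' @param base_model A \code{mass_model} (structure + Keq; kf overwritten
#'   per candidate).
#' @param flux_states A \code{sample_set} over reactions (flux space).
#' @param conc_states A \code{sample_set} over non-fixed species.
#' @return List of candidates of length
#'   \code{nrow(flux_states$samples) * nrow(conc_states$samples)}.
#' @export
assemble_ensemble <- function(base_model, flux_states, conc_states) {
  V <- flux_states$samples
  X <- conc_states$samples
  if (nrow(V) == 0L || nrow(X) == 0L)
    stop("flux and concentration sample sets must be non-empty")
  x_full <- reference_state(base_model)
  candidates <- vector("list", nrow(V) * nrow(X))
  k <- 0L
  for (i in seq_len(nrow(V))) {
    for (j in seq_len(nrow(X))) {
      k <- k + 1L
      x <- x_full
      x[colnames(X)] <- X[j, ]
      ss <- steady_state_data(V[i, ], x)
      cand <- tryCatch({
        viol <- check_direction_consistency(base_model, ss)
        if (nrow(viol) > 0L) {
          new_candidate(i, j, NULL, "infeasible",
                        paste("direction violations:",
                              paste(viol$reaction, collapse = ", ")))
        } else {
          m <- withCallingHandlers(
            parameterize(base_model, ss),
            warning = function(w) invokeRestart("muffleWarning"))
          new_candidate(i, j, m, "untested")
        }
      }, error = function(e)
        new_candidate(i, j, NULL, "infeasible", conditionMessage(e)))
      candidates[[k]] <- cand
    }
  }
  candidates
}

#' Filter candidates by dynamic stability
#'
#' Each parameterized candidate is simulated to steady state, perturbed,
#' and re-tested. Candidates that reach a post-perturbation steady state
#' become \code{stable}; an inability to reach a steady state through
#' simulation marks the candidate \code{unstable} with its reason in the
#' discard log. \code{strategy = "eigen"} instead uses the reduced-Jacobian
#' eigenvalue test at the pre-perturbation steady state (fast pre-screen).
#'
#' @param candidates List from \code{\link{assemble_ensemble}}.
#' @param pert A \code{perturbation} (e.g. a 1.5 factor on an ATP
#'   utilization reaction's kf).
#' @param strategy "simulate" (default, matches the discard criterion) or
#'   "eigen".
#' @param horizon Simulation horizon in hours.
#' @param atol_ss,rtol_ss Steady-state criterion tolerances.
#' @param verbose Emit one progress line per candidate.
#' @return An object of class \code{mass_ensemble}: list with
#'   \code{candidates} (status set) and \code{discard_log} (data frame
#'   flux_state_id, conc_state_id, reason).
#' @export
filter_stable <- function(candidates, pert,
                          strategy = c("simulate", "eigen"),
                          horizon = 1e4, atol_ss = 1e-9, rtol_ss = 1e-6,
                          verbose = FALSE) {
  strategy <- match.arg(strategy)
  discards <- list()
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    if (cand$status == "infeasible") {
      discards[[length(discards) + 1L]] <-
        data.frame(flux_state_id = cand$flux_state_id,
                   conc_state_id = cand$conc_state_id,
                   reason = paste("infeasible:", cand$diagnostics))
      next
    }
    res <- tryCatch({
      x_star <- find_steady_state(cand$model, strategy = "hybrid",
                                  atol_ss = atol_ss, rtol_ss = rtol_ss,
                                  t_max = horizon)
      ok <- is_stable(cand$model, x_star, method = strategy,
                      pert = pert, horizon = horizon,
                      atol_ss = atol_ss, rtol_ss = rtol_ss)
      list(ok = isTRUE(ok), diag = attr(ok, "diagnostics"), x_star = x_star)
    }, error = function(e) list(ok = FALSE, diag = conditionMessage(e)))
    if (res$ok) {
      cand$status <- "stable"
      cand$x_star <- res$x_star
    } else {
      cand$status <- "unstable"
      diag <- unlist(res$diag)
      diag <- diag[!is.na(diag)]
      cand$diagnostics <- paste("unable to reach a steady state through",
                                "simulation:",
                                paste(diag, collapse = "; "))
      discards[[length(discards) + 1L]] <-
        data.frame(flux_state_id = cand$flux_state_id,
                   conc_state_id = cand$conc_state_id,
                   reason = cand$diagnostics)
    }
    candidates[[k]] <- cand
    if (verbose)
      message("candidate=", k, " flux_state=", cand$flux_state_id,
              " conc_state=", cand$conc_state_id, " status=", cand$status)
  }
  discard_log <- if (length(discards)) do.call(rbind, discards) else
    data.frame(flux_state_id = integer(0), conc_state_id = integer(0),
               reason = character(0))
  structure(list(candidates = candidates, discard_log = discard_log,
                 trajectories = NULL, times = NULL),
            class = "mass_ensemble")
}

#' @export
print.mass_ensemble <- function(x, ...) {
  st <- vapply(x$candidates, `[[`, character(1), "status")
  cat("mass_ensemble:", length(st), "candidates (",
      sum(st == "stable"), "stable,", sum(st == "unstable"), "unstable,",
      sum(st == "infeasible"), "infeasible )\n")
  if (!is.null(x$trajectories))
    cat("  stacked trajectories on", length(x$times), "time points\n")
  invisible(x)
}

#' Candidate status counts
#' @param ens A \code{mass_ensemble} or candidate list.
#' @return Named integer vector over statuses.
#' @export
ensemble_status <- function(ens) {
  cands <- if (inherits(ens, "mass_ensemble")) ens$candidates else ens
  st <- vapply(cands, `[[`, character(1), "status")
  c(stable = sum(st == "stable"), unstable = sum(st == "unstable"),
    infeasible = sum(st == "infeasible"), untested = sum(st == "untested"))
}

#' Simulate the stable ensemble under a shared perturbation
#'
#' Integrates every stable candidate from its steady state with the shared
#' perturbation applied at t = 0 and interpolates all trajectories onto a
#' common log-spaced time grid, enabling pointwise ensemble statistics.
#' Per-candidate integration failures downgrade the candidate to
#' \code{unstable} with a diagnostic.
#'
#' @param ens A \code{mass_ensemble} from \code{\link{filter_stable}}.
#' @param pert Shared \code{perturbation}.
#' @param t_span Simulation window (hours); grid endpoints equal the span
#'   endpoints.
#' @param grid_n Number of grid points.
#' @return The ensemble with stacked \code{trajectories} (list of
#'   \code{mass_trajectory}, one per stable candidate) and \code{times}.
#' @export
simulate_ensemble <- function(ens, pert, t_span = c(0, 100), grid_n = 50L) {
  stopifnot(inherits(ens, "mass_ensemble"))
  idx <- which(vapply(ens$candidates, `[[`, character(1), "status") == "stable")
  if (length(idx) == 0L) stop("no stable candidates to simulate")
  # log-spaced interior grid with exact endpoints
  t0 <- t_span[1]; t1 <- t_span[2]
  inner <- exp(seq(log(max(t0, t1 * 1e-4)), log(t1), length.out = grid_n - 1L))
  grid <- unique(c(t0, inner))
  grid[length(grid)] <- t1
  trajs <- vector("list", length(ens$candidates))
  for (k in idx) {
    cand <- ens$candidates[[k]]
    x0 <- if (!is.null(cand$x_star)) cand$x_star else
      find_steady_state(cand$model, strategy = "hybrid")
    tr <- tryCatch({
      full <- integrate_model(cand$model, x0, t_span, pert = pert,
                              times = sort(unique(c(grid, pert$time))))
      interpolate_trajectory(full, grid)
    }, error = function(e) e)
    if (inherits(tr, "error")) {
      cand$status <- "unstable"
      cand$diagnostics <- paste("integration failure:", conditionMessage(tr))
      ens$candidates[[k]] <- cand
      ens$discard_log <- rbind(ens$discard_log,
                               data.frame(flux_state_id = cand$flux_state_id,
                                          conc_state_id = cand$conc_state_id,
                                          reason = cand$diagnostics))
    } else {
      trajs[[k]] <- tr
    }
  }
  ens$trajectories <- trajs
  ens$times <- grid
  ens
}

#' Adenylate energy charge
#'
#' Atkinson's energy charge, \eqn{(ATP + ADP/2)/(ATP + ADP + AMP)}: a 0-1
#' index of the cellular energy state.
#'
#' @param x_atp,x_adp,x_amp Concentrations (vectors allowed).
#' @return Energy charge in [0, 1].
#' @export
#' @examples
#' energy_charge(1, 1, 1)  # 0.5
energy_charge <- function(x_atp, x_adp, x_amp) {
  tot <- x_atp + x_adp + x_amp
  if (any(tot <= 0)) stop("energy charge undefined: total adenylate pool is zero")
  (x_atp + x_adp / 2) / tot
}

# Evaluate a quantity on one trajectory: species id, reaction id, or a
# function(states, fluxes) -> numeric vector over time.
eval_quantity <- function(traj, quantity) {
  if (is.function(quantity)) return(quantity(traj$states, traj$fluxes))
  if (quantity %in% colnames(traj$states)) return(traj$states[, quantity])
  if (quantity %in% colnames(traj$fluxes)) return(traj$fluxes[, quantity])
  stop("quantity '", quantity, "' is neither a species, a flux, nor a function")
}

#' Aggregate an ensemble quantity over time
#'
#' Computes per-time-point statistics of a quantity across the stable
#' candidates' stacked trajectories. \code{ci95} is the normal-theory
#' confidence band mean +/- 1.96 sd/sqrt(n); \code{median}/\code{iqr} use
#' empirical percentiles with linear interpolation.
#'
#' @param ens A simulated \code{mass_ensemble}.
#' @param quantity Species id, reaction id, or
#'   \code{function(states, fluxes)} returning one value per time point
#'   (e.g. an energy-charge expression).
#' @param stats Subset of c("mean", "ci95", "median", "iqr").
#' @return Data frame with column \code{time}, one column per statistic
#'   (ci95 yields \code{ci95_lo}/\code{ci95_hi}, iqr yields \code{q25}/
#'   \code{q75}), and \code{n_candidates}.
#' @export
aggregate_ensemble <- function(ens, quantity,
                               stats = c("mean", "ci95", "median", "iqr")) {
  stats <- match.arg(stats, several.ok = TRUE)
  if (is.null(ens$trajectories))
    stop("ensemble has no stacked trajectories; run simulate_ensemble first")
  trajs <- Filter(Negate(is.null), ens$trajectories)
  n <- length(trajs)
  if (n < 2L && any(stats %in% c("ci95", "iqr")))
    stop("dispersion statistics need at least 2 stable candidates")
  M <- vapply(trajs, eval_quantity, numeric(length(ens$times)),
              quantity = quantity)
  if (length(ens$times) == 1L) M <- matrix(M, nrow = 1)
  out <- data.frame(time = ens$times)
  if ("mean" %in% stats) out$mean <- rowMeans(M)
  if ("ci95" %in% stats) {
    se <- apply(M, 1, stats::sd) / sqrt(n)
    mu <- rowMeans(M)
    out$ci95_lo <- mu - 1.96 * se
    out$ci95_hi <- mu + 1.96 * se
  }
  if ("median" %in% stats)
    out$median <- apply(M, 1, stats::median)
  if ("iqr" %in% stats) {
    out$q25 <- apply(M, 1, stats::quantile, probs = 0.25, names = FALSE)
    out$q75 <- apply(M, 1, stats::quantile, probs = 0.75, names = FALSE)
  }
  out$n_candidates <- n
  out
}
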