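# Dynamic simulation: ODE integration, steady states, linearization.

#' Define a perturbation
#'
#' A perturbation changes parameters or species values at a single instant.
#' Target names are reaction ids (acting on that reaction's kf) or species
#' ids (acting on the concentration / boundary value). Values are
#' multiplicative factors by default, absolute replacements when
#' \code{absolute = TRUE}. State trajectories stay continuous across the
#' application instant unless a species value itself is targeted.
#'
#' @param targets Named numeric vector.
#' @param time Application instant (hours).
#' @param absolute Logical; interpret values as replacements.
#' @return An object of class \code{perturbation}.
#' @export
#' @examples
#' perturbation(c(ATPM = 1.5))  # 50% increase in ATP utilization rate
perturbation <- function(targets, time = 0, absolute = FALSE) {
  stopifnot(is.numeric(targets), !is.null(names(targets)))
  if (!absolute && any(targets <= 0))
    stop("multiplicative perturbation factors must be > 0")
  structure(list(targets = targets, time = time, absolute = isTRUE(absolute)),
            class = "perturbation")
}

#' Apply a perturbation to a model and state
#'
#' @param model A \code{mass_model}.
#' @param x Named state vector.
#' @param pert A \code{perturbation} (or NULL for identity).
#' @return List with elements \code{model} and \code{x}.
#' @export
apply_perturbation <- function(model, x, pert) {
  if (is.null(pert)) return(list(model = model, x = x))
  for (nm in names(pert$targets)) {
    val <- pert$targets[[nm]]
    if (nm %in% reaction_ids(model)) {
      old <- model$reactions[[nm]]$kf
      if (is.na(old)) stop("perturbation targets unparameterized reaction '", nm, "'")
      model$reactions[[nm]]$kf <- if (pert$absolute) val else old * val
    } else if (nm %in% species_ids(model)) {
      x[nm] <- if (pert$absolute) val else x[nm] * val
      model$species[[nm]]$x0 <- unname(x[nm])
    } else {
      stop("perturbation target '", nm, "' is neither a reaction nor a species")
    }
  }
  list(model = model, x = x)
}

# Flux evaluator: named concentrations -> named flux vector.
make_rate_fn <- function(model) {
  exprs <- rate_expressions(model)
  unresolved <- unique(unlist(lapply(exprs, all.vars)))
  unresolved <- setdiff(unresolved, species_ids(model))
  if (length(unresolved))
    stop("unresolved parameters in rate laws (model not parameterized?): ",
         paste(unresolved, collapse = ", "))
  rids <- reaction_ids(model)
  function(x) {
    e <- as.list(x)
    vapply(exprs, function(ex) eval(ex, e), numeric(1), USE.NAMES = FALSE) |>
      stats::setNames(rids)
  }
}

# Symbolic derivative matrix G[j, i] = dv_j / dx_i as unevaluated calls.
rate_gradient_exprs <- function(model) {
  exprs <- rate_expressions(model)
  sp <- species_ids(model)
  lapply(exprs, function(ex) {
    vars <- intersect(all.vars(ex), sp)
    stats::setNames(lapply(vars, function(v) stats::D(ex, v)), vars)
  })
}

#' Jacobian of the ODE right-hand side
#'
#' Computes J = S G with G the matrix of partial derivatives of the rate
#' laws with respect to concentrations, obtained symbolically and evaluated
#' at \code{x}. Rows of fixed species are zero (their derivative is held at
#' zero).
#'
#' @param model A parameterized \code{mass_model}.
#' @param x Named state vector.
#' @return n x n matrix over all species, dimnames set.
#' @export
jacobian <- function(model, x) {
  S <- unclass(stoich_matrix(model))
  sp <- species_ids(model)
  G <- matrix(0, length(model$reactions), length(sp),
              dimnames = list(reaction_ids(model), sp))
  e <- as.list(x)
  grads <- rate_gradient_exprs(model)
  for (j in seq_along(grads)) {
    for (v in names(grads[[j]]))
      G[j, v] <- eval(grads[[j]][[v]], e)
  }
  J <- S %*% G
  J[fixed_species(model), ] <- 0
  J
}

# Jacobian restricted to non-fixed rows/cols, projected onto the
# stoichiometric subspace (removes structural zero modes from conserved
# pools by reduction rather than thresholding).
reduced_jacobian <- function(model, x) {
  nf <- !fixed_species(model)
  J <- jacobian(model, x)[nf, nf, drop = FALSE]
  S <- unclass(stoich_matrix(model))[nf, , drop = FALSE]
  N <- range_basis(S)
  if (ncol(N) == 0L) return(matrix(0, 0, 0))
  t(N) %*% J %*% N
}

new_trajectory <- function(times, states, fluxes) {
  structure(list(times = times, states = states, fluxes = fluxes),
            class = "mass_trajectory")
}

#' @export
print.mass_trajectory <- function(x, ...) {
  cat("mass_trajectory:", length(x$times), "time points over [",
      x$times[1], ",", x$times[length(x$times)], "] h,",
      ncol(x$states), "species,", ncol(x$fluxes), "fluxes\n")
  invisible(x)
}

# Integrate one segment with lsoda; states of fixed species held constant.
integrate_segment <- function(model, x0, times, rtol, atol) {
  nf <- !fixed_species(model)
  nf_ids <- species_ids(model)[nf]
  S_nf <- unclass(stoich_matrix(model))[nf, , drop = FALSE]
  rate_fn <- make_rate_fn(model)
  fixed_vals <- x0[!nf]
  grads <- rate_gradient_exprs(model)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- rate_fn(c(y, fixed_vals))
    list(as.vector(S_nf %*% v))
  }
  jac <- function(t, y, parms) {
    x <- c(pmax(y, 0), fixed_vals)
    e <- as.list(x)
    G <- matrix(0, length(grads), length(nf_ids))
    for (j in seq_along(grads)) {
      ids <- intersect(names(grads[[j]]), nf_ids)
      for (v in ids)
        G[j, match(v, nf_ids)] <- eval(grads[[j]][[v]], e)
    }
    S_nf %*% G
  }
  out <- deSolve::lsoda(y = x0[nf], times = times, func = rhs, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure (istate = ", attr(out, "istate")[1],
         ") near t = ", max(out[, 1]),
         "; consider loosening tolerances or checking rate constants")
  tt <- out[, 1]
  st <- out[, -1, drop = FALSE]
  neg <- st < 0
  if (any(st < -100 * atol))
    stop("negative concentrations beyond tolerance during integration")
  st[neg] <- 0
  full <- matrix(rep(x0, each = nrow(st)), nrow = nrow(st),
                 dimnames = list(NULL, species_ids(model)))
  full[, nf_ids] <- st
  fl <- t(apply(full, 1, rate_fn))
  if (length(model$reactions) == 1L) {
    fl <- matrix(fl, ncol = 1)
  }
  colnames(fl) <- reaction_ids(model)
  list(times = tt, states = full, fluxes = fl)
}

#' Integrate the kinetic model
#'
#' Deterministic stiff integration (adaptive-step LSODA) of
#' \eqn{dx/dt = S v(x)} over non-fixed species, with an optional
#' single-instant perturbation. Fluxes are recomputed from the states.
#' Conserved pools are preserved to integration tolerance.
#'
#' @param model A parameterized \code{mass_model}.
#' @param x0 Named initial state (defaults to the model's reference state).
#' @param t_span Length-2 numeric, start and end time in hours.
#' @param pert Optional \code{perturbation} applied at \code{pert$time}.
#' @param n_out Number of output points (log-spaced after the first decade
#'   when \code{log_spaced}, else linear).
#' @param times Explicit output grid overriding \code{n_out}.
#' @param rtol,atol Integrator tolerances.
#' @return A \code{mass_trajectory} (times, states, fluxes).
#' @export
integrate_model <- function(model, x0 = reference_state(model),
                            t_span = c(0, 10), pert = NULL,
                            n_out = 201L, times = NULL,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  x0 <- x0[species_ids(model)]
  if (anyNA(x0)) stop("x0 missing species")
  if (any(x0 < 0)) stop("negative initial concentrations")
  if (is.null(times)) times <- seq(t_span[1], t_span[2], length.out = n_out)
  if (is.null(pert) || pert$time <= t_span[1]) {
    if (!is.null(pert)) {
      ap <- apply_perturbation(model, x0, pert)
      model <- ap$model; x0 <- ap$x
    }
    seg <- integrate_segment(model, x0, times, rtol, atol)
    return(new_trajectory(seg$times, seg$states, seg$fluxes))
  }
  if (pert$time >= t_span[2])
    return(integrate_model(model, x0, t_span, NULL, n_out, times, rtol, atol))
  t1 <- sort(unique(c(times[times <= pert$time], pert$time)))
  if (length(t1) < 2L) t1 <- c(t_span[1], pert$time)
  seg1 <- integrate_segment(model, x0, t1, rtol, atol)
  x_mid <- seg1$states[nrow(seg1$states), ]
  ap <- apply_perturbation(model, x_mid, pert)
  t2 <- sort(unique(c(pert$time, times[times > pert$time])))
  seg2 <- integrate_segment(ap$model, ap$x, t2, rtol, atol)
  keep1 <- seg1$times < pert$time
  new_trajectory(
    c(seg1$times[keep1], seg2$times),
    rbind(seg1$states[keep1, , drop = FALSE], seg2$states),
    rbind(seg1$fluxes[keep1, , drop = FALSE], seg2$fluxes)
  )
}

ss_residual <- function(model, x) {
  nf <- !fixed_species(model)
  S_nf <- unclass(stoich_matrix(model))[nf, , drop = FALSE]
  v <- make_rate_fn(model)(x)
  list(dxdt = as.vector(S_nf %*% v), v = v)
}

ss_criterion_met <- function(model, x, atol_ss, rtol_ss) {
  r <- ss_residual(model, x)
  max(abs(r$dxdt)) < max(atol_ss, rtol_ss * max(abs(r$v), 0))
}

# Damped Gauss-Newton in log-concentration space on the conserved-pool
# augmented residual [S v(x); L x - L x0].
newton_steady_state <- function(model, x0, atol_ss, rtol_ss,
                                max_iter = 200L) {
  nf <- !fixed_species(model)
  nf_ids <- species_ids(model)[nf]
  S_nf <- unclass(stoich_matrix(model))[nf, , drop = FALSE]
  L <- conserved_pools(model)[, nf_ids, drop = FALSE]
  pools0 <- if (nrow(L)) as.vector(L %*% x0[nf_ids]) else numeric(0)
  rate_fn <- make_rate_fn(model)
  grads <- rate_gradient_exprs(model)
  fixed_vals <- x0[!nf]
  resid <- function(y) {
    x <- c(stats::setNames(exp(y), nf_ids), fixed_vals)
    v <- rate_fn(x)
    c(as.vector(S_nf %*% v),
      if (nrow(L)) as.vector(L %*% exp(y)) - pools0 else numeric(0))
  }
  jac_y <- function(y) {
    xv <- exp(y)
    x <- c(stats::setNames(xv, nf_ids), fixed_vals)
    e <- as.list(x)
    G <- matrix(0, length(grads), length(nf_ids))
    for (j in seq_along(grads)) {
      ids <- intersect(names(grads[[j]]), nf_ids)
      for (v in ids) G[j, match(v, nf_ids)] <- eval(grads[[j]][[v]], e)
    }
    top <- S_nf %*% G %*% diag(xv, length(xv))
    if (nrow(L)) rbind(top, L %*% diag(xv, length(xv))) else top
  }
  y <- log(pmax(x0[nf_ids], 1e-12))
  f <- resid(y)
  for (it in seq_len(max_iter)) {
    x <- c(stats::setNames(exp(y), nf_ids), fixed_vals)
    if (ss_criterion_met(model, x, atol_ss, rtol_ss) &&
        (nrow(L) == 0 || max(abs(utils::tail(f, nrow(L)))) <
           1e-9 * max(1, max(abs(pools0)))))
      return(list(x = x, converged = TRUE, residual = max(abs(f))))
    J <- jac_y(y)
    step <- tryCatch(qr.solve(J, -f, tol = 1e-14),
                     error = function(e) -crossprod(J, f) / max(1, sum(J^2)))
    # Armijo backtracking on the residual norm
    alpha <- 1
    f_norm <- sum(f^2)
    repeat {
      y_new <- y + alpha * step
      y_new <- pmin(pmax(y_new, -60), 60)
      f_new <- resid(y_new)
      if (sum(f_new^2) <= (1 - 1e-4 * alpha) * f_norm || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-8 && sum(f_new^2) >= f_norm)
      return(list(x = c(stats::setNames(exp(y), nf_ids), fixed_vals),
                  converged = FALSE, residual = max(abs(f))))
    y <- y_new; f <- f_new
  }
  list(x = c(stats::setNames(exp(y), nf_ids), fixed_vals),
       converged = FALSE, residual = max(abs(f)))
}

integrate_to_steady_state <- function(model, x0, atol_ss, rtol_ss,
                                      t_max = 1e6, rtol = 1e-8, atol = 1e-12) {
  x <- x0
  t_hi <- 1
  while (t_hi <= t_max) {
    traj <- integrate_model(model, x, c(0, t_hi), n_out = 26L,
                            rtol = rtol, atol = atol)
    x <- traj$states[nrow(traj$states), ]
    if (ss_criterion_met(model, x, atol_ss, rtol_ss))
      return(list(x = x, converged = TRUE,
                  residual = max(abs(ss_residual(model, x)$dxdt))))
    t_hi <- t_hi * 10
  }
  list(x = x, converged = FALSE,
       residual = max(abs(ss_residual(model, x)$dxdt)))
}

#' Find a steady state
#'
#' Drives \eqn{\|dx/dt\|_\infty} below
#' \eqn{\max(\mathrm{atol}_{ss}, \mathrm{rtol}_{ss}\|v\|_\infty)}.
#' Strategies: \code{"integrate"} simulates with an expanding horizon until
#' the criterion holds; \code{"newton"} runs a damped Gauss-Newton on the
#' conserved-pool-reduced system seeded at \code{x0} (log-concentration
#' variables keep states positive); \code{"hybrid"} integrates briefly and
#' then polishes with Newton.
#'
#' @param model A parameterized \code{mass_model}.
#' @param x0 Named start state (defaults to reference).
#' @param strategy One of "hybrid", "integrate", "newton".
#' @param atol_ss,rtol_ss Steady-state criterion tolerances.
#' @param t_max Horizon bound for the integrate strategy (hours).
#' @return Named steady-state vector over all species (attribute
#'   \code{"residual"} carries the final \eqn{\|dx/dt\|_\infty}).
#' @export
find_steady_state <- function(model, x0 = reference_state(model),
                              strategy = c("hybrid", "integrate", "newton"),
                              atol_ss = 1e-9, rtol_ss = 1e-6, t_max = 1e6) {
  strategy <- match.arg(strategy)
  x0 <- x0[species_ids(model)]
  if (ss_criterion_met(model, x0, atol_ss, rtol_ss)) {
    res <- max(abs(ss_residual(model, x0)$dxdt))
    return(structure(x0, residual = res))
  }
  out <- switch(
    strategy,
    newton = newton_steady_state(model, x0, atol_ss, rtol_ss),
    integrate = integrate_to_steady_state(model, x0, atol_ss, rtol_ss, t_max),
    hybrid = {
      pre <- tryCatch(
        integrate_model(model, x0, c(0, 100), n_out = 11L),
        error = function(e) NULL)
      seed <- if (is.null(pre)) x0 else pre$states[nrow(pre$states), ]
      o <- newton_steady_state(model, seed, atol_ss, rtol_ss)
      if (!o$converged)
        o <- integrate_to_steady_state(model, seed, atol_ss, rtol_ss, t_max)
      o
    }
  )
  if (!out$converged)
    stop("steady state not found (best ||dx/dt||_inf = ",
         signif(out$residual, 4), ")")
  structure(out$x, residual = out$residual)
}

#' Assess local or simulated stability of a steady state
#'
#' \code{method = "eigen"}: all eigenvalues of the Jacobian projected onto
#' the stoichiometric subspace (conserved-pool zero modes removed by
#' reduction) must have real part below \code{eps_zero}.
#' \code{method = "simulate"}: the state is perturbed and integrated; stable
#' if the steady-state criterion is re-satisfied within the horizon.
#'
#' @param model A parameterized \code{mass_model}.
#' @param x_star Steady state from \code{\link{find_steady_state}}.
#' @param method "eigen" or "simulate".
#' @param eps_zero Eigenvalue zero tolerance.
#' @param pert Perturbation for the simulate method (default: 5% bump to all
#'   non-fixed concentrations).
#' @param horizon Simulation horizon (hours).
#' @param atol_ss,rtol_ss Steady-state criterion tolerances.
#' @return Logical with attribute \code{"diagnostics"}.
#' @export
is_stable <- function(model, x_star, method = c("eigen", "simulate"),
                      eps_zero = 1e-9, pert = NULL, horizon = 1e4,
                      atol_ss = 1e-9, rtol_ss = 1e-6) {
  method <- match.arg(method)
  x_star <- x_star[species_ids(model)]
  if (method == "eigen") {
    Jr <- reduced_jacobian(model, x_star)
    if (nrow(Jr) == 0L)
      return(structure(TRUE, diagnostics = "no dynamic modes"))
    ev <- eigen(Jr, only.values = TRUE)$values
    ok <- all(Re(ev) < eps_zero)
    return(structure(ok, diagnostics = list(eigenvalues = ev)))
  }
  nfix <- !fixed_species(model)
  if (is.null(pert))
    pert <- perturbation(stats::setNames(rep(1.05, sum(nfix)),
                                         species_ids(model)[nfix]))
  ap <- apply_perturbation(model, x_star, pert)
  out <- tryCatch(
    integrate_to_steady_state(ap$model, ap$x, atol_ss, rtol_ss, t_max = horizon),
    error = function(e) list(converged = FALSE, residual = NA_real_,
                             error = conditionMessage(e))
  )
  structure(isTRUE(out$converged),
            diagnostics = list(residual = out$residual,
                               error = out$error))
}

#' Dynamic timescales at a steady state
#'
#' Returns \eqn{\tau = -1/\mathrm{Re}(\lambda)} for every eigenvalue of the
#' reduced Jacobian with negative real part, sorted ascending (fastest
#' first). Zero modes are omitted.
#'
#' @param model A parameterized \code{mass_model}.
#' @param x_star Steady state.
#' @param eps_zero Zero tolerance on real parts.
#' @return Numeric vector of timescales (hours).
#' @export
timescales <- function(model, x_star, eps_zero = 1e-9) {
  Jr <- reduced_jacobian(model, x_star[species_ids(model)])
  if (nrow(Jr) == 0L) return(numeric(0))
  ev <- eigen(Jr, only.values = TRUE)$values
  re <- Re(ev)
  sort(-1 / re[re < -eps_zero])
}

#' Interpolate a trajectory onto a new time grid
#'
#' Monotone (Fritsch-Carlson) cubic interpolation per species and flux;
#' endpoints of the original grid are reproduced exactly. Extrapolation is
#' an error.
#'
#' @param traj A \code{mass_trajectory}.
#' @param times Requested times, all within the trajectory's range.
#' @return A \code{mass_trajectory} on the requested grid.
#' @export
interpolate_trajectory <- function(traj, times) {
  rng <- range(traj$times)
  eps <- 1e-12 * max(1, abs(rng))
  if (any(times < rng[1] - eps) || any(times > rng[2] + eps))
    stop("interpolation request outside the trajectory time range")
  times <- pmin(pmax(times, rng[1]), rng[2])
  interp_cols <- function(M) {
    out <- vapply(seq_len(ncol(M)), function(j) {
      f <- stats::splinefun(traj$times, M[, j], method = "monoH.FC")
      f(times)
    }, numeric(length(times)))
    if (length(times) == 1L) out <- matrix(out, nrow = 1)
    colnames(out) <- colnames(M)
    out
  }
  new_trajectory(times, interp_cols(traj$states), interp_cols(traj$fluxes))
}
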