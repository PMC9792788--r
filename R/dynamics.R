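# Replicator dynamics: right-hand side, trajectory integration, endpoint
# classification and convergence-speed measurement.

#' Replicator right-hand side
#'
#' The rate of change of each strategy proportion,
#' \code{dv/dt = v (1 - v) (U1 - U2)}. Two routes are provided: the
#' closed-form payoff differences (\code{"delta"}, default) and the
#' payoff-tensor expectation (\code{"tensor"}), which serves as an
#' independent cross-check of the derivation.
#'
#' @param state population state (x, y, z, p).
#' @param params a \code{cdts_params} object.
#' @param method \code{"delta"} or \code{"tensor"}.
#' @param check validate that the state lies in the unit hypercube
#'   (within \code{tol}).
#' @param tol tolerance for the state check.
#' @param tensor optional precomputed payoff tensor (tensor route only).
#' @return named numeric vector of rates \code{c(x=, y=, z=, p=)}.
#' @export
replicator_rhs <- function(state, params, method = c("delta", "tensor"),
                           check = TRUE, tol = 1e-6, tensor = NULL) {
  method <- match.arg(method)
  s <- as_state(state)
  if (check) check_state(s, tol = tol)
  deltas <- if (method == "delta") {
    payoff_deltas(params, pmin(pmax(s, 0), 1)) # deltas are polynomial; clamp is a no-op in range
  } else {
    gp <- group_payoffs(params, pmin(pmax(s, 0), 1), tensor = tensor)
    vapply(gp, function(u) u[["U1"]] - u[["U2"]], numeric(1))
  }
  s * (1 - s) * deltas
}

# Unchecked polynomial RHS used by the finite-difference Jacobian: the
# replicator field extends smoothly outside [0,1].
rhs_raw <- function(state, params, method = "delta", tensor = NULL) {
  s <- as_state(state)
  deltas <- if (method == "delta") {
    q <- params
    y <- s[["y"]]; p <- s[["p"]]
    c(
      (q$C12 - q$C11) + (1 - p) * (q$R12 - q$alpha * q$R13) -
        (1 - p) * (1 - y) * q$F1 * (1 - q$alpha),
      (1 - p) * (q$R21 - q$R22) + (q$C22 - q$C21),
      (q$C32 - q$C31) + (q$R32 - q$R34) + (q$R31 + q$R34 - q$R32 - q$R33) * p,
      (q$C46 - q$C45) + q$theta * (q$C44 - q$C46 + q$R41 - q$R43) +
        y * q$beta * (q$C43 - q$C46 + q$R41 - q$R42) +
        y * q$theta * (q$C46 - q$C44 - q$R41 + q$R43)
    )
  } else {
    gp <- group_payoffs_raw(params, s, tensor = tensor)
    gp[1, ] - gp[2, ]
  }
  unname(s * (1 - s) * deltas)
}

# group_payoffs without state validation or Ubar, returning the 2x4 matrix
# of expected strategy payoffs; tolerates states outside [0,1] (the mixing
# weights are then formal, which is exactly what finite differencing needs).
group_payoffs_raw <- function(params, s, tensor = NULL) {
  if (is.null(tensor)) tensor <- build_payoff_tensor(params)
  w <- rbind(s, 1 - s)
  U <- matrix(0, nrow = 2, ncol = 4)
  idx <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  for (r in seq_len(nrow(idx))) {
    iv <- idx[r, ]
    wr <- c(w[iv[1], 1], w[iv[2], 2], w[iv[3], 3], w[iv[4], 4])
    for (g in 1:4) {
      U[iv[g], g] <- U[iv[g], g] +
        tensor[iv[1], iv[2], iv[3], iv[4], g] * prod(wr[-g])
    }
  }
  U
}

#' Integrate the replicator dynamics
#'
#' Solves the four-dimensional replicator ODE system from an initial
#' state with an adaptive solver (\code{deSolve}, \code{lsodar}), stopping
#' early once the RHS max-norm falls below \code{rhs_stop} (the system has
#' effectively reached a rest point). Output states are clamped to the
#' unit hypercube; the dynamics preserve it analytically, so clamping only
#' absorbs floating-point drift.
#'
#' @param params a \code{cdts_params} object.
#' @param init initial state (components in \code{[0, 1]}).
#' @param horizon integration horizon in model time units.
#' @param rel_tol,abs_tol solver tolerances.
#' @param dt output sampling step.
#' @param rhs_stop early-stopping threshold on the RHS max-norm.
#' @return a data.frame of class \code{cdts_trajectory} with columns
#'   \code{t, x, y, z, p}; the parameter set and solver settings are
#'   carried in attributes.
#' @examples
#' traj <- simulate_replicator(baseline_params(), c(0.3, 0.3, 0.3, 0.3))
#' classify_endpoint(traj)
#' @export
simulate_replicator <- function(params, init, horizon = 200,
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                dt = 0.1, rhs_stop = 1e-10) {
  stopifnot(inherits(params, "cdts_params"))
  init <- check_state(init, tol = 0)
  times <- seq(0, horizon, by = dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  ode_fn <- function(t, state, parms) {
    list(rhs_raw(state, parms))
  }
  root_fn <- function(t, state, parms) {
    max(abs(rhs_raw(state, parms))) - rhs_stop
  }
  sol <- try(deSolve::ode(
    y = init, times = times, func = ode_fn, parms = params,
    method = "lsodar", rtol = rel_tol, atol = abs_tol,
    rootfunc = root_fn
  ), silent = TRUE)
  if (inherits(sol, "try-error") || anyNA(sol[, -1])) {
    stop("replicator integration failed: ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "solver returned NA states", call. = FALSE)
  }
  sol <- as.data.frame(unclass(sol))
  names(sol) <- c("t", GROUPS)
  excursion <- max(c(0, -min(as.matrix(sol[GROUPS])),
                     max(as.matrix(sol[GROUPS])) - 1))
  for (g in GROUPS) sol[[g]] <- pmin(pmax(sol[[g]], 0), 1)
  structure(
    sol,
    class = c("cdts_trajectory", "data.frame"),
    params = params,
    solver = list(method = "lsodar", rel_tol = rel_tol, abs_tol = abs_tol,
                  horizon = horizon, dt = dt, rhs_stop = rhs_stop),
    max_excursion = excursion,
    init = init
  )
}

# Coordinates of the 16 corner rest points, in the conventional labelling.
CORNERS <- local({
  d <- data.frame(
    id = paste0("E", 1:16),
    x = c(0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1),
    y = c(0, 0, 0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1),
    z = c(0, 0, 1, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1),
    p = c(0, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
  rownames(d) <- d$id
  d
})

#' The 16 corner rest points
#'
#' @return a data.frame with columns \code{id, x, y, z, p}.
#' @export
corner_states <- function() CORNERS

#' Classify a trajectory endpoint
#'
#' Finds the corner nearest (max-norm) to the final state; the trajectory
#' counts as converged only if that distance is below \code{epsilon} and
#' the RHS max-norm at the final state is below \code{rhs_epsilon}. The
#' RHS tolerance is much tighter than the positional one on purpose: near
#' a saddle corner a trajectory can sit within \code{epsilon} with a tiny
#' but non-vanishing outward drift, and only the RHS criterion separates
#' genuine settlement from slow transit.
#'
#' A corner with a strictly positive Jacobian eigenvalue can never be the
#' limit of an interior replicator trajectory; when the final state sits
#' at such a corner it got there by numerical absorption onto an
#' invariant face (the \code{v (1 - v)} factor underflows and freezes the
#' escape direction). Such endpoints are reported with
#' \code{saddle_capture = TRUE} and are not counted as converged.
#'
#' @param traj a \code{cdts_trajectory}.
#' @param epsilon positional convergence tolerance.
#' @param rhs_epsilon tolerance on the RHS max-norm at the final state.
#' @return a list of class \code{cdts_endpoint}: \code{converged},
#'   \code{corner} (id or \code{NA}), \code{distance}, \code{final_state},
#'   \code{final_time}.
#' @export
classify_endpoint <- function(traj, epsilon = 1e-3, rhs_epsilon = 1e-6) {
  stopifnot(inherits(traj, "cdts_trajectory"), nrow(traj) > 0)
  final <- unlist(traj[nrow(traj), GROUPS])
  dists <- apply(as.matrix(CORNERS[, GROUPS]), 1,
                 function(cc) max(abs(cc - final)))
  k <- which.min(dists)
  params <- attr(traj, "params")
  rhs_norm <- max(abs(replicator_rhs(final, params, check = FALSE)))
  near <- dists[k] < epsilon && rhs_norm < rhs_epsilon
  repelled <- near &&
    any(as.numeric(corner_eigenvalues(params, CORNERS$id[k])) > 0)
  converged <- near && !repelled
  structure(
    list(
      converged = converged,
      corner = if (converged) CORNERS$id[k] else NA_character_,
      nearest = CORNERS$id[k],
      distance = unname(dists[k]),
      rhs_norm = rhs_norm,
      saddle_capture = repelled,
      final_state = final,
      final_time = traj$t[nrow(traj)]
    ),
    class = "cdts_endpoint"
  )
}

#' @export
print.cdts_endpoint <- function(x, ...) {
  status <- if (x$converged) "converged to"
    else if (isTRUE(x$saddle_capture)) "numerically captured at saddle"
    else "NOT converged;"
  cat(sprintf(
    "<cdts_endpoint> %s nearest %s (max dist %.2e, |rhs| %.2e) at t = %.1f\n",
    status, x$nearest, x$distance, x$rhs_norm, x$final_time))
  invisible(x)
}

#' Time for a component to settle at its limit
#'
#' Integrates the dynamics and returns the first time after which the
#' named component stays within \code{epsilon} of its limiting value
#' (0 or 1). Used to compare evolution speeds between parameter variants.
#'
#' @param params a \code{cdts_params} object.
#' @param init initial state.
#' @param component one of \code{"x", "y", "z", "p"}.
#' @param epsilon settling tolerance on the component.
#' @param horizon integration horizon.
#' @param ... further arguments to \code{\link{simulate_replicator}}.
#' @return the settling time (model time units), or \code{NA} with a
#'   warning and attribute \code{converged = FALSE} if the component has
#'   not settled at a pure strategy by the horizon.
#' @export
convergence_time <- function(params, init, component = c("x", "y", "z", "p"),
                             epsilon = 1e-3, horizon = 200, ...) {
  component <- match.arg(component)
  traj <- simulate_replicator(params, init, horizon = horizon, ...)
  v <- traj[[component]]
  limit <- round(v[length(v)])
  if (abs(v[length(v)] - limit) >= epsilon) {
    warning("component '", component,
            "' has not converged to a pure strategy by the horizon")
    return(structure(NA_real_, converged = FALSE))
  }
  dev <- abs(v - limit)
  outside <- which(dev >= epsilon)
  t_conv <- if (length(outside) == 0) traj$t[1] else {
    k <- max(outside)
    if (k == length(v)) return(structure(NA_real_, converged = FALSE))
    traj$t[k + 1]
  }
  structure(t_conv, converged = TRUE, limit = limit)
}
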