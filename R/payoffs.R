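# Payoff matrix, expected group payoffs, payoff differences and the seven
# sign-determining expressions.

#' Build the per-profile payoff tensor
#'
#' Evaluates the payoff matrix of the game on a parameter set: for each of
#' the 16 pure-strategy profiles, the payoff of each of the four players.
#' Index 1 of each strategy dimension is the strategy whose proportion the
#' state tracks (self-built, part-time, leasing, physical preference).
#'
#' @param params a \code{cdts_params} object.
#' @return a 2x2x2x2x4 numeric array with dimnames
#'   \code{x, y, z, p, player}.
#' @export
build_payoff_tensor <- function(params) {
  stopifnot(inherits(params, "cdts_params"))
  q <- params
  tens <- array(
    NA_real_, dim = c(2, 2, 2, 2, 4),
    dimnames = list(
      x = c("self-built", "relying-on"),
      y = c("part-time", "full-time"),
      z = c("leasing", "no-leasing"),
      p = c("physical", "internet"),
      player = PLAYERS
    )
  )
  for (xi in 1:2) for (yi in 1:2) for (zi in 1:2) for (pi in 1:2) {
    self <- xi == 1L; part <- yi == 1L; lease <- zi == 1L; phys <- pi == 1L

    # institution: offline benefit when the patient is physical-preference,
    # otherwise the online benefit (F1 drag applies under full-time mode;
    # relying-on keeps only the alpha share) plus the T3 relief effect.
    online <- if (self) q$R12 - (!part) * q$F1 else q$alpha * (q$R13 - (!part) * q$F1)
    inst <- (if (phys) q$R11 else online + q$T3) -
      (if (self) q$C11 else q$C12) + (if (lease) q$T2 else 0)

    # platform: earns only from internet-preference patients; leasing adds T1.
    plat <- if (phys) {
      -(if (part) q$C21 else q$C22)
    } else {
      (if (part) q$R21 else q$R22) - (if (part) q$C21 else q$C22) +
        (if (lease) q$T1 else 0)
    }

    prov <- if (lease) {
      (if (phys) q$R31 else q$R32) - q$C31
    } else {
      (if (phys) q$R33 else q$R34) - q$C32
    }

    # patient: device terms depend only on leasing availability; online
    # visits split between platform and institution portals with prob
    # beta (part-time) or theta (full-time).
    dev <- if (lease) q$R44 - q$C41 else q$R45 - q$C42
    pat <- if (phys) {
      q$R41 - q$C45 + dev
    } else if (part) {
      q$beta * (q$R42 - q$C43) + (1 - q$beta) * (q$R41 - q$C46) + dev
    } else {
      q$theta * (q$R43 - q$C44) + (1 - q$theta) * (q$R41 - q$C46) + dev
    }

    tens[xi, yi, zi, pi, ] <- c(inst, plat, prov, pat)
  }
  class(tens) <- c("cdts_payoffs", class(tens))
  tens
}

#' Expected payoffs of each group's two strategies
#'
#' For each group, the expected payoff of its first strategy (U1), of its
#' second strategy (U2), and the population mean
#' \code{Ubar = v*U1 + (1-v)*U2}, with the other three groups mixing
#' according to the state. Computed by contracting the payoff tensor, so
#' it is an independent route to the same quantities as the closed-form
#' payoff differences.
#'
#' @param params a \code{cdts_params} object.
#' @param state a population state (\code{cdts_state} or numeric x, y, z, p).
#' @param tensor optional precomputed \code{build_payoff_tensor(params)}.
#' @return a list with one element per group (\code{x, y, z, p}), each a
#'   named vector \code{c(U1, U2, Ubar)}.
#' @export
group_payoffs <- function(params, state, tensor = NULL) {
  s <- check_state(state, tol = 0)
  if (is.null(tensor)) tensor <- build_payoff_tensor(params)
  w <- rbind(s, 1 - s)            # w[k, g]: prob. group g plays strategy k
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
  out <- lapply(seq_along(GROUPS), function(g) {
    c(U1 = U[1, g], U2 = U[2, g],
      Ubar = unname(s[g] * U[1, g] + (1 - s[g]) * U[2, g]))
  })
  names(out) <- GROUPS
  out
}

#' Closed-form payoff differences U1 - U2 per group
#'
#' The four payoff-advantage functions that drive the replicator dynamics,
#' derived from the payoff matrix (all dynamically inert parameters cancel):
#' \deqn{\Delta_x = (C_{12}-C_{11}) + (1-p)(R_{12}-\alpha R_{13}) - (1-p)(1-y)F_1(1-\alpha)}
#' \deqn{\Delta_y = (1-p)(R_{21}-R_{22}) + (C_{22}-C_{21})}
#' \deqn{\Delta_z = (C_{32}-C_{31}) + (R_{32}-R_{34}) + (R_{31}+R_{34}-R_{32}-R_{33})p}
#' \deqn{\Delta_p = (C_{46}-C_{45}) + \theta(C_{44}-C_{46}+R_{41}-R_{43})
#'   + y\beta(C_{43}-C_{46}+R_{41}-R_{42}) + y\theta(C_{46}-C_{44}-R_{41}+R_{43})}
#' Note \eqn{\Delta_x, \Delta_y, \Delta_p} do not involve z, and
#' \eqn{\Delta_z} depends only on p.
#'
#' @inheritParams group_payoffs
#' @return named numeric vector \code{c(x=, y=, z=, p=)} of payoff
#'   differences (payoff units).
#' @export
payoff_deltas <- function(params, state) {
  stopifnot(inherits(params, "cdts_params"))
  s <- check_state(state, tol = 0)
  q <- params
  y <- s[["y"]]; p <- s[["p"]]
  dx <- (q$C12 - q$C11) + (1 - p) * (q$R12 - q$alpha * q$R13) -
    (1 - p) * (1 - y) * q$F1 * (1 - q$alpha)
  dy <- (1 - p) * (q$R21 - q$R22) + (q$C22 - q$C21)
  dz <- (q$C32 - q$C31) + (q$R32 - q$R34) +
    (q$R31 + q$R34 - q$R32 - q$R33) * p
  dp <- (q$C46 - q$C45) + q$theta * (q$C44 - q$C46 + q$R41 - q$R43) +
    y * q$beta * (q$C43 - q$C46 + q$R41 - q$R42) +
    y * q$theta * (q$C46 - q$C44 - q$R41 + q$R43)
  c(x = dx, y = dy, z = dz, p = dp)
}

# Closed forms of the seven sign-determining expressions.
EXPRESSION_FORMS <- list(
  e1 = function(q) (q$R21 - q$C21) - (q$R22 - q$C22),
  e2 = function(q) (q$R32 - q$C31) - (q$R34 - q$C32),
  e3 = function(q) (q$R31 - q$C31) - (q$R33 - q$C32),
  e4 = function(q) (q$R12 - q$F1 - q$C11) - (q$alpha * (q$R13 - q$F1) - q$C12),
  e5 = function(q) (q$R12 - q$C11) - (q$alpha * q$R13 - q$C12),
  e6 = function(q) (q$R41 - q$C45) -
    ((1 - q$theta) * (q$R41 - q$C46) + q$theta * (q$R43 - q$C44)),
  e7 = function(q) (q$R41 - q$C45) -
    ((1 - q$beta) * (q$R41 - q$C46) + q$beta * (q$R42 - q$C43))
)

classify_sign <- function(v, tol = 1e-12) {
  ifelse(abs(v) <= tol, "boundary", ifelse(v > 0, "+", "-"))
}

#' The seven sign-determining expressions
#'
#' Evaluates the seven payoff-difference expressions whose signs decide
#' which corner equilibria can be evolutionarily stable:
#' \itemize{
#'  \item e1: platform net benefit, part-time minus full-time mode.
#'  \item e2: provider net benefit of leasing vs not, internet-preference patients.
#'  \item e3: provider net benefit of leasing vs not, physical-preference patients.
#'  \item e4: institution self-built minus relying-on net benefit, full-time mode.
#'  \item e5: institution self-built minus relying-on net benefit, part-time mode.
#'  \item e6: patient offline minus online net benefit, full-time mode.
#'  \item e7: patient offline minus online net benefit, part-time mode.
#' }
#'
#' @param params a \code{cdts_params} object.
#' @param boundary_tol values with absolute size at or below this are
#'   classified \code{"boundary"} (neither strictly + nor -).
#' @return a data.frame of class \code{cdts_expressions} with columns
#'   \code{id}, \code{value}, \code{sign}.
#' @export
expression_values <- function(params, boundary_tol = 1e-12) {
  stopifnot(inherits(params, "cdts_params"))
  vals <- vapply(EXPRESSION_FORMS, function(f) f(params), numeric(1))
  out <- data.frame(
    id = names(EXPRESSION_FORMS),
    value = unname(vals),
    sign = classify_sign(unname(vals), boundary_tol),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cdts_expressions", class(out))
  out
}

# Convenience accessor used throughout: named numeric e1..e7.
expr_vector <- function(params) {
  vapply(EXPRESSION_FORMS, function(f) f(params), numeric(1))
}
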