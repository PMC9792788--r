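# Corner-equilibrium stability: closed-form Jacobian eigenvalues, the
# finite-difference cross-check, ESS classification by the Lyapunov first
# method, the ten stability conditions, and their compatibility logic.

# At a corner every v is 0 or 1, so the Jacobian is diagonal with entries
# d/dv [v(1-v)Delta_v] = (1 - 2v) Delta_v (the cross-derivative terms carry
# a factor v(1-v) = 0). The published stability table lists the four
# eigenvalues of corners E1, E3, E4 and E9 in group order (y, z, x, p) and
# all other corners in (x, y, z, p); the per-corner order is preserved here
# for traceability.
CORNER_EIG_ORDER <- local({
  orders <- rep(list(c("x", "y", "z", "p")), 16)
  names(orders) <- paste0("E", 1:16)
  for (id in c("E1", "E3", "E4", "E9")) orders[[id]] <- c("y", "z", "x", "p")
  orders
})

# Corners that can be stable, and the stability condition id attached to each.
CONDITION_CORNERS <- c(E1 = 1L, E3 = 2L, E4 = 3L, E5 = 4L, E7 = 5L,
                       E9 = 6L, E10 = 7L, E11 = 8L, E12 = 9L, E15 = 10L)

#' Closed-form Jacobian eigenvalues at a corner
#'
#' At a corner the Jacobian of the replicator system is diagonal; the
#' eigenvalue for group g is \code{(1 - 2 v_g) * Delta_g} evaluated at the
#' corner. Eigenvalues are returned in the published per-corner row order
#' (see \code{attr(., "groups")}).
#'
#' @param params a \code{cdts_params} object.
#' @param corner a corner id \code{"E1"..."E16"}.
#' @return numeric vector of four eigenvalues (payoff units), named by
#'   group, with attributes \code{corner} and \code{groups}.
#' @export
corner_eigenvalues <- function(params, corner) {
  stopifnot(inherits(params, "cdts_params"))
  if (!corner %in% CORNERS$id) stop("unknown corner id: ", corner, call. = FALSE)
  cc <- unlist(CORNERS[corner, GROUPS])
  deltas <- payoff_deltas(params, cc)
  eig <- (1 - 2 * cc) * deltas
  ord <- CORNER_EIG_ORDER[[corner]]
  out <- eig[ord]
  attr(out, "corner") <- corner
  attr(out, "groups") <- ord
  out
}

#' Finite-difference Jacobian of the replicator field
#'
#' Central-difference Jacobian of the replicator RHS. By default it
#' differences the payoff-tensor route, making it an independent numerical
#' oracle for the closed-form corner eigenvalues: at any corner the matrix
#' is diagonal and its diagonal reproduces \code{\link{corner_eigenvalues}}
#' (up to the per-corner row ordering).
#'
#' @param params a \code{cdts_params} object.
#' @param state the state at which to differentiate.
#' @param h step size.
#' @param method RHS route to difference (\code{"tensor"} default).
#' @return a 4x4 matrix, rows/columns ordered (x, y, z, p).
#' @export
numeric_jacobian <- function(params, state, h = 1e-5,
                             method = c("tensor", "delta")) {
  method <- match.arg(method)
  s <- as_state(state)
  tensor <- if (method == "tensor") build_payoff_tensor(params) else NULL
  J <- matrix(NA_real_, 4, 4, dimnames = list(GROUPS, GROUPS))
  for (j in 1:4) {
    up <- s; up[j] <- up[j] + h
    dn <- s; dn[j] <- dn[j] - h
    J[, j] <- (rhs_raw(up, params, method = method, tensor = tensor) -
                 rhs_raw(dn, params, method = method, tensor = tensor)) / (2 * h)
  }
  J
}

#' Classify the 16 corner equilibria
#'
#' Applies the Lyapunov first method at every corner: a corner is an ESS
#' if and only if all four Jacobian eigenvalues are strictly negative; any
#' strictly positive eigenvalue makes it unstable; an eigenvalue within
#' \code{boundary_tol} of zero (and none positive) leaves the method
#' silent, and the corner is reported \code{"inconclusive"}.
#'
#' @param params a \code{cdts_params} object.
#' @param boundary_tol tolerance around zero for eigenvalue signs.
#' @return a data.frame of class \code{cdts_stability}, one row per
#'   corner, with coordinates, the four eigenvalues (published row order),
#'   sign pattern, verdict, and the attached stability condition id
#'   (\code{NA} for never-stable corners). The ESS subset is in
#'   \code{attr(., "ess")}.
#' @examples
#' rep <- classify_equilibria(baseline_params())
#' attr(rep, "ess")
#' @export
classify_equilibria <- function(params, boundary_tol = 1e-12) {
  stopifnot(inherits(params, "cdts_params"))
  rows <- lapply(CORNERS$id, function(id) {
    eig <- corner_eigenvalues(params, id)
    signs <- classify_sign(as.numeric(eig), boundary_tol)
    verdict <- if (any(signs == "+")) "unstable"
      else if (any(signs == "boundary")) "inconclusive"
      else "ESS"
    data.frame(
      id = id,
      CORNERS[id, GROUPS],
      lambda1 = eig[[1]], lambda2 = eig[[2]],
      lambda3 = eig[[3]], lambda4 = eig[[4]],
      groups = paste(attr(eig, "groups"), collapse = ","),
      signs = paste(signs, collapse = ","),
      verdict = verdict,
      condition = if (id %in% names(CONDITION_CORNERS))
        CONDITION_CORNERS[[id]] else NA_integer_,
      stringsAsFactors = FALSE, row.names = id
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cdts_stability", "data.frame")
  attr(out, "ess") <- out$id[out$verdict == "ESS"]
  attr(out, "boundary_tol") <- boundary_tol
  out
}

#' ESS set of a parameter set
#'
#' @param x a \code{cdts_stability} report or a \code{cdts_params} object.
#' @param ... passed to \code{\link{classify_equilibria}} when \code{x}
#'   is a parameter set.
#' @return character vector of corner ids classified as ESS.
#' @export
ess_set <- function(x, ...) {
  if (inherits(x, "cdts_params")) x <- classify_equilibria(x, ...)
  stopifnot(inherits(x, "cdts_stability"))
  attr(x, "ess")
}

# Sign requirements per condition (columns of the compatibility table):
# condition c holds iff every listed expression has the required strict sign.
# The remaining eigenvalues of the corresponding corner are forced negative
# by the model assumptions.
CONDITION_SIGNS <- list(
  `1`  = c(e1 = "-", e2 = "-", e4 = "-", e6 = "-"),
  `2`  = c(e1 = "-", e2 = "+", e4 = "-", e6 = "-"),
  `3`  = c(e1 = "+", e2 = "-", e5 = "-", e7 = "-"),
  `4`  = c(e1 = "-", e2 = "-", e4 = "+", e6 = "-"),
  `5`  = c(e3 = "-", e7 = "+"),
  `6`  = c(e1 = "+", e2 = "+", e5 = "-", e7 = "-"),
  `7`  = c(e1 = "-", e2 = "+", e4 = "+", e6 = "-"),
  `8`  = c(e1 = "+", e2 = "-", e5 = "+", e7 = "-"),
  `9`  = c(e3 = "+", e7 = "+"),
  `10` = c(e1 = "+", e2 = "+", e5 = "+", e7 = "-")
)

#' Which stability conditions a parameter set satisfies
#'
#' Evaluates the seven expressions and checks each of the ten conditions'
#' required sign patterns. A condition whose required expressions include
#' a boundary (numerically zero) value while all others match is reported
#' separately rather than classified.
#'
#' @param params a \code{cdts_params} object.
#' @param boundary_tol tolerance around zero for expression signs.
#' @return integer vector of satisfied condition ids, with attribute
#'   \code{boundary} listing conditions undecidable at this tolerance.
#' @export
check_conditions <- function(params, boundary_tol = 1e-12) {
  ev <- expression_values(params, boundary_tol)
  signs <- stats::setNames(ev$sign, ev$id)
  satisfied <- integer(0)
  boundary <- integer(0)
  for (cid in names(CONDITION_SIGNS)) {
    req <- CONDITION_SIGNS[[cid]]
    got <- signs[names(req)]
    if (all(got == req)) {
      satisfied <- c(satisfied, as.integer(cid))
    } else if (any(got == "boundary") && all(got == req | got == "boundary")) {
      boundary <- c(boundary, as.integer(cid))
    }
  }
  structure(satisfied, boundary = boundary)
}

#' The condition-compatibility table
#'
#' The sign each of the seven expressions must take under each of the ten
#' stability conditions (\code{NA} where a condition does not constrain an
#' expression), together with the corner each condition stabilises.
#'
#' @return a list with \code{signs} (7 x 10 character matrix, rows
#'   \code{e1..e7}, columns conditions 1-10) and \code{corners} (named
#'   integer vector mapping corner id to condition id).
#' @export
compatibility_matrix <- function() {
  m <- matrix(NA_character_, nrow = 7, ncol = 10,
              dimnames = list(paste0("e", 1:7), as.character(1:10)))
  for (cid in names(CONDITION_SIGNS)) {
    req <- CONDITION_SIGNS[[cid]]
    m[names(req), cid] <- unname(req)
  }
  list(signs = m, corners = CONDITION_CORNERS)
}

#' Can a set of conditions hold simultaneously?
#'
#' A set of conditions is jointly satisfiable iff no expression is
#' required to be both strictly positive and strictly negative. This
#' reproduces the published mutual-exclusion structure: e.g. conditions
#' \{1, 9\} may co-occur, conditions 3, 6, 8 and 10 only occur alone.
#'
#' @param conditions integer vector of condition ids (1-10).
#' @return \code{TRUE} if the combined sign requirements are consistent.
#' @export
permitted_conditions <- function(conditions) {
  conditions <- as.integer(conditions)
  stopifnot(all(conditions %in% 1:10))
  m <- compatibility_matrix()$signs[, as.character(conditions), drop = FALSE]
  for (i in seq_len(nrow(m))) {
    req <- m[i, !is.na(m[i, ])]
    if (length(unique(req)) > 1) return(FALSE)
  }
  TRUE
}
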