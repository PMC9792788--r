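# Canonical parameter names of the four-population game. Strategy sets:
#   institutions {self-built, relying-on}, platforms {part-time, full-time},
#   providers {leasing, no-leasing}, patients {physical, internet}.
PARAM_NAMES <- c(
  "C11", "C12",                         # institution operating cost, self-built / relying-on
  "C21", "C22",                         # platform staffing cost, part-time / full-time
  "C31", "C32",                         # provider operating cost, leasing / no-leasing
  "C41", "C42",                         # patient device acquisition, leasing available / buy-only
  "C43", "C44",                         # patient visit cost on platform, part-time / full-time
  "C45", "C46",                         # patient cost at institution, offline / online
  "R11",                                # institution offline benefit
  "R12", "R13",                         # institution online benefit, self-built / relying-on (pre-share)
  "R21", "R22",                         # platform benefit, part-time / full-time
  "R31", "R32", "R33", "R34",           # provider benefit: lease x (physical, internet), no-lease x (physical, internet)
  "R41", "R42", "R43",                  # patient benefit: institution, platform part-time, platform full-time
  "R44", "R45",                         # patient device benefit, leasing / buy-only
  "alpha", "beta", "theta",             # share kept when relying-on; platform-choice probabilities
  "F1",                                 # full-time-mode drag on institutions' online platforms
  "T1", "T2", "T3"                      # leasing spillovers and internet-preference relief effect
)

# Parameters that cancel out of every payoff difference (they enter both
# strategies of each group identically in the payoff matrix), hence never
# affect the dynamics. They may be omitted from configs and default to 0.
CANCELLED_PARAMS <- c("R11", "R44", "R45", "C41", "C42", "T1", "T2", "T3")

GROUPS <- c("x", "y", "z", "p")
PLAYERS <- c("institution", "platform", "provider", "patient")

#' Construct a validated game parameter set
#'
#' Builds the full set of model constants for the four-population
#' diagnosis-and-treatment game: per-strategy costs \code{C11..C46},
#' benefits \code{R11..R45}, the relying-on benefit share \code{alpha},
#' the platform-choice probabilities \code{beta} (part-time mode) and
#' \code{theta} (full-time mode), the full-time-mode drag \code{F1} on
#' institutions' online platforms, and the spillover effects
#' \code{T1..T3}. All payoffs are in abstract payoff units.
#'
#' The eight parameters that cancel from every payoff difference
#' (\code{R11}, \code{R44}, \code{R45}, \code{C41}, \code{C42},
#' \code{T1}, \code{T2}, \code{T3}) may be omitted; they default to 0 and
#' the defaulting is reported via \code{message()} unless \code{quiet}.
#'
#' @param values named list or numeric vector of parameter values.
#' @param quiet suppress the note listing defaulted parameters.
#' @return an object of class \code{cdts_params} (a named list).
#' @examples
#' p <- baseline_params()
#' p$R21
#' @export
cdts_params <- function(values, quiet = FALSE) {
  values <- as.list(values)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("parameter values must be named", call. = FALSE)
  }
  unknown <- setdiff(names(values), PARAM_NAMES)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(PARAM_NAMES, names(values))
  defaulted <- intersect(missing, CANCELLED_PARAMS)
  hard_missing <- setdiff(missing, CANCELLED_PARAMS)
  if (length(hard_missing) > 0) {
    stop("missing required parameter(s): ", paste(hard_missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in defaulted) values[[nm]] <- 0
  if (length(defaulted) > 0 && !quiet) {
    message("defaulted cancelled parameter(s) to 0: ",
            paste(defaulted, collapse = ", "))
  }
  values <- lapply(values, as.numeric)
  bad <- names(values)[!vapply(values, function(v) length(v) == 1 && is.finite(v),
                               logical(1))]
  if (length(bad) > 0) {
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- values[PARAM_NAMES]
  class(out) <- "cdts_params"
  attr(out, "defaulted") <- defaulted
  out
}

#' @export
print.cdts_params <- function(x, ...) {
  cat("<cdts_params> four-population game parameters (payoff units)\n")
  v <- unlist(x)
  print(noquote(format(v, digits = 4)))
  invisible(x)
}

#' The calibrated baseline parameter set
#'
#' The canonical simulation calibration for the cardiovascular /
#' cerebrovascular chronic-disease case, with the eight dynamically inert
#' parameters at their 0 defaults.
#'
#' @return a \code{cdts_params} object.
#' @export
baseline_params <- function() {
  cdts_params(list(
    C11 = 0.7, C12 = 0.6, C21 = 0.5, C22 = 0.7, C31 = 0.7, C32 = 0.5,
    C43 = 0.9, C44 = 1.0, C45 = 1.0, C46 = 0.9,
    R12 = 1.7, R13 = 3.0, R21 = 1.7, R22 = 2.5,
    R31 = 1.4, R32 = 1.5, R33 = 1.0, R34 = 1.4,
    R41 = 1.5, R42 = 1.0, R43 = 1.6,
    alpha = 0.7, beta = 0.4, theta = 0.6, F1 = 0.3
  ), quiet = TRUE)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named overrides applied.
#'
#' @param params a \code{cdts_params} object.
#' @param ... named scalar overrides, e.g. \code{R32 = 2}.
#' @return a \code{cdts_params} object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "cdts_params"))
  overrides <- list(...)
  if (length(overrides) == 0) return(params)
  unknown <- setdiff(names(overrides), PARAM_NAMES)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- unclass(params)
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  cdts_params(vals, quiet = TRUE)
}

# The model's structural assumption inequalities. Each entry: label and a
# predicate on the parameter list returning TRUE when satisfied.
ASSUMPTIONS <- list(
  list(label = "C11 > C12",   check = function(p) p$C11 > p$C12),
  list(label = "C21 < C22",   check = function(p) p$C21 < p$C22),
  list(label = "C31 > C32",   check = function(p) p$C31 > p$C32),
  list(label = "C41 < C42",   check = function(p) p$C41 < p$C42),
  list(label = "R21 < R22",   check = function(p) p$R21 < p$R22),
  list(label = "R31 < R32",   check = function(p) p$R31 < p$R32),
  list(label = "R33 < R34",   check = function(p) p$R33 < p$R34),
  list(label = "R32 > R34",   check = function(p) p$R32 > p$R34),
  list(label = "R31 > R33",   check = function(p) p$R31 > p$R33),
  list(label = "theta > beta", check = function(p) p$theta > p$beta)
)

#' Validate a parameter set against the model assumptions
#'
#' Checks the structural inequalities the game is built on (cost and
#' benefit orderings such as \code{C11 > C12} or \code{theta > beta}) plus
#' the range constraints on \code{alpha}, \code{beta}, \code{theta}.
#' The device-cost ordering \code{C41 < C42} is skipped (and reported as
#' skipped) when both are at their inert 0 default, since the device
#' acquisition terms cancel from every payoff difference.
#'
#' @param params a \code{cdts_params} object.
#' @param mode \code{"warn"} reports violations; \code{"strict"} turns a
#'   non-empty violation list into an error.
#' @return an object of class \code{cdts_validation}: a list with
#'   \code{violations}, \code{skipped}, and \code{valid}.
#' @export
validate_parameters <- function(params, mode = c("warn", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cdts_params"))
  violations <- character(0)
  skipped <- character(0)
  for (a in ASSUMPTIONS) {
    if (a$label == "C41 < C42" && params$C41 == 0 && params$C42 == 0) {
      skipped <- c(skipped, a$label)
      next
    }
    if (!isTRUE(a$check(params))) violations <- c(violations, a$label)
  }
  for (nm in c("alpha", "beta", "theta")) {
    v <- params[[nm]]
    if (v < 0 || v > 1) violations <- c(violations, paste(nm, "in [0,1]"))
  }
  out <- structure(
    list(violations = violations, skipped = skipped,
         valid = length(violations) == 0),
    class = "cdts_validation"
  )
  if (mode == "strict" && !out$valid) {
    stop("parameter assumptions violated: ",
         paste(violations, collapse = "; "), call. = FALSE)
  }
  out
}

#' @export
print.cdts_validation <- function(x, ...) {
  if (x$valid) {
    cat("All model assumptions satisfied.\n")
  } else {
    cat("Violated assumptions:\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  if (length(x$skipped) > 0) {
    cat("Skipped (inert defaults):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a population state
#'
#' A state is the vector of four strategy proportions: \code{x}
#' institutions self-built, \code{y} platforms part-time, \code{z}
#' providers leasing, \code{p} patients with physical preference.
#'
#' @param x,y,z,p proportions in \code{[0, 1]}.
#' @return a named numeric vector of class \code{cdts_state}.
#' @export
cdts_state <- function(x, y, z, p) {
  s <- c(x = x, y = y, z = z, p = p)
  check_state(s)
  class(s) <- c("cdts_state", "numeric")
  s
}

# Accept plain numeric length-4 vectors anywhere a state is expected.
as_state <- function(state) {
  if (inherits(state, "cdts_state")) return(unclass(state))
  state <- as.numeric(state)
  if (length(state) != 4) stop("a population state has four components (x, y, z, p)",
                               call. = FALSE)
  names(state) <- GROUPS
  state
}

check_state <- function(state, tol = 1e-8) {
  s <- as_state(state)
  if (any(!is.finite(s))) stop("non-finite state component", call. = FALSE)
  if (any(s < -tol | s > 1 + tol)) {
    stop("state components must lie in [0, 1]: got (",
         paste(format(s, digits = 6), collapse = ", "), ")", call. = FALSE)
  }
  invisible(s)
}
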