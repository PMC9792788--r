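# The named simulation experiments: the calibrated baseline, the parameter
# variants that realise each stability condition, and the seven
# speed-sensitivity comparisons. Expected qualitative outcomes are stored
# as data so tests and reports read them from one registry.

SCENARIO_REGISTRY <- local({
  eq <- function(id, overrides, conditions, ess, low, high) {
    list(id = id, type = "equilibrium", overrides = overrides,
         expected = list(conditions = conditions, ess = ess,
                         endpoint_low = low, endpoint_high = high))
  }
  sens <- function(id, base, param, values, component, expression,
                   init = c(0.3, 0.3, 0.3, 0.3)) {
    # values[1] is the reference setting, values[2] the adjustment the
    # narrative says accelerates the named stakeholder's evolution. The
    # init picks the basin in which both variants drive that component to
    # the same limit wherever possible, so the speed comparison is
    # well-posed.
    list(id = id, type = "sensitivity", overrides = base,
         compare = list(param = param, values = values,
                        component = component, expression = expression,
                        init = init))
  }
  fig5_over <- list(R22 = 1.8, R42 = 1.5)
  reg <- list(
    eq("baseline", list(), c(1L, 9L), c("E1", "E12"), "E1", "E12"),
    eq("fig1", list(), c(1L, 9L), c("E1", "E12"), "E1", "E12"),
    eq("fig2", list(R32 = 2), c(2L, 9L), c("E3", "E12"), "E3", "E12"),
    eq("fig3", list(R13 = 2), c(4L, 9L), c("E5", "E12"), "E5", "E12"),
    eq("fig4", list(R32 = 2, R13 = 2), c(7L, 9L), c("E10", "E12"), "E10", "E12"),
    eq("fig5", fig5_over, 3L, "E4", "E4", "E4"),
    eq("fig6", c(fig5_over, list(R32 = 2)), 6L, "E9", "E9", "E9"),
    eq("fig7", c(fig5_over, list(R13 = 2)), 8L, "E11", "E11", "E11"),
    eq("fig8", c(fig5_over, list(R13 = 2, R32 = 2)), 10L, "E15", "E15", "E15"),
    sens("fig9",  fig5_over, "C43", c(0.9, 0.5), "p", "e7"),
    sens("fig10", fig5_over, "R42", c(1.5, 1.9), "p", "e7"),
    sens("fig11", list(), "alpha", c(0.5, 0.9), "x", "e5"),
    sens("fig12", list(R22 = 1.8), "R21", c(1.3, 1.7), "y", "e1",
         init = c(0.7, 0.7, 0.7, 0.7)),
    sens("fig13", list(R22 = 1.8, R21 = 1.3), "C21", c(0.5, 0.1), "y", "e1"),
    sens("fig14", list(R32 = 2), "R32", c(2, 2.4), "z", "e2"),
    sens("fig15", list(R32 = 2, C31 = 0.9), "C31", c(0.9, 0.6), "z", "e2")
  )
  names(reg) <- vapply(reg, `[[`, character(1), "id")
  reg
})

#' List the registered scenario ids
#'
#' @return character vector (\code{"baseline"}, \code{"fig1"} ...
#'   \code{"fig15"}).
#' @export
scenario_ids <- function() names(SCENARIO_REGISTRY)

#' Load a named scenario
#'
#' Resolves a registered scenario to its full parameter set (overrides
#' applied to the calibrated baseline) together with its recorded expected
#' outcome (equilibrium scenarios) or its sensitivity comparison
#' (parameter, variant values, affected component and expression).
#'
#' @param id a scenario id, see \code{\link{scenario_ids}}.
#' @return a list of class \code{cdts_scenario}: \code{id}, \code{type},
#'   \code{overrides}, \code{params} (resolved \code{cdts_params}), and
#'   \code{expected} or \code{compare}.
#' @examples
#' load_scenario("fig2")$params$R32
#' @export
load_scenario <- function(id) {
  if (!id %in% names(SCENARIO_REGISTRY)) {
    stop("unknown scenario id: ", id, "; known ids: ",
         paste(scenario_ids(), collapse = ", "), call. = FALSE)
  }
  sc <- SCENARIO_REGISTRY[[id]]
  sc$params <- do.call(modify_params, c(list(baseline_params()), sc$overrides))
  class(sc) <- "cdts_scenario"
  sc
}

#' Run a scenario end-to-end
#'
#' For an equilibrium scenario: evaluates the seven expressions, the
#' satisfied conditions, the full corner-stability report, and integrates
#' the dynamics from each initial state, classifying the endpoints. For a
#' sensitivity scenario: evaluates the relevant expression and measures
#' the settling time of the named component under both parameter variants
#' from the same initial state.
#'
#' @param scenario a \code{cdts_scenario} or a scenario id.
#' @param inits named list of initial states (equilibrium scenarios);
#'   defaults to \code{low = (0.3, 0.3, 0.3, 0.3)} and
#'   \code{high = (0.7, 0.7, 0.7, 0.7)}.
#' @param init initial state for sensitivity scenarios; \code{NULL} uses
#'   the scenario's registered canonical init.
#' @param epsilon convergence tolerance.
#' @param horizon integration horizon.
#' @param ... further solver arguments to \code{\link{simulate_replicator}}.
#' @return a list of class \code{cdts_scenario_report}.
#' @export
run_scenario <- function(scenario,
                         inits = list(low = c(0.3, 0.3, 0.3, 0.3),
                                      high = c(0.7, 0.7, 0.7, 0.7)),
                         init = NULL,
                         epsilon = 1e-3, horizon = 200, ...) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "cdts_scenario"))
  params <- scenario$params
  validate_parameters(params, mode = "strict")

  if (scenario$type == "equilibrium") {
    stab <- classify_equilibria(params)
    endpoints <- lapply(inits, function(s0) {
      traj <- simulate_replicator(params, s0, horizon = horizon, ...)
      classify_endpoint(traj, epsilon = epsilon)
    })
    report <- list(
      id = scenario$id, type = scenario$type,
      params = params,
      expressions = expression_values(params),
      conditions = as.integer(check_conditions(params)),
      stability = stab,
      ess = ess_set(stab),
      endpoints = endpoints,
      expected = scenario$expected
    )
  } else {
    cmp <- scenario$compare
    if (is.null(init)) init <- cmp$init
    variants <- lapply(cmp$values, function(v) {
      do.call(modify_params, stats::setNames(list(params, v), c("", cmp$param)))
    })
    expr_vals <- vapply(variants, function(q) expr_vector(q)[[cmp$expression]],
                        numeric(1))
    times <- vapply(variants, function(q) {
      as.numeric(convergence_time(q, init, component = cmp$component,
                                  epsilon = epsilon, horizon = horizon, ...))
    }, numeric(1))
    report <- list(
      id = scenario$id, type = scenario$type,
      params = params,
      compare = data.frame(
        param = cmp$param, value = cmp$values,
        expression = cmp$expression, expression_value = expr_vals,
        component = cmp$component, settle_time = times,
        stringsAsFactors = FALSE
      ),
      faster_variant = cmp$values[which.min(times)],
      init = as_state(init)
    )
  }
  class(report) <- "cdts_scenario_report"
  report
}

#' @export
print.cdts_scenario_report <- function(x, ...) {
  cat("<cdts_scenario_report>", x$id, "(", x$type, ")\n")
  if (x$type == "equilibrium") {
    cat("  conditions:", paste(x$conditions, collapse = ", "),
        " ESS:", paste(x$ess, collapse = ", "), "\n")
    for (nm in names(x$endpoints)) {
      e <- x$endpoints[[nm]]
      cat(sprintf("  init %-5s -> %s (dist %.1e)\n", nm,
                  ifelse(e$converged, e$corner, "no convergence"), e$distance))
    }
  } else {
    print(x$compare)
  }
  invisible(x)
}

#' Run every registered scenario
#'
#' @param ids scenario ids to run (default: all).
#' @param ... passed to \code{\link{run_scenario}}.
#' @return named list of \code{cdts_scenario_report} objects.
#' @export
run_all_scenarios <- function(ids = scenario_ids(), ...) {
  stats::setNames(lapply(ids, run_scenario, ...), ids)
}
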