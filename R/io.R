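# Configuration loading and report/trajectory serialization.

#' Read a parameter configuration file
#'
#' Flat key-value YAML or JSON (by extension) using the model's symbol
#' names (\code{C11 ... C46}, \code{R11 ... R45}, \code{alpha},
#' \code{beta}, \code{theta}, \code{F1}, \code{T1 ... T3}). Unknown keys
#' are rejected; omitted cancelled parameters default to 0 with a note.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @param quiet suppress the defaulting note.
#' @return a \code{cdts_params} object.
#' @export
read_params_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension '.", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  if (!is.list(raw)) raw <- as.list(raw)
  nonnum <- names(raw)[!vapply(raw, is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    stop("non-numeric value for key(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  cdts_params(raw, quiet = quiet)
}

#' Write a parameter configuration file
#'
#' @param params a \code{cdts_params} object.
#' @param path output path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return the path, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "cdts_params"))
  vals <- unclass(params)
  attributes(vals) <- list(names = names(vals))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config extension '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns \code{t, x, y, z, p}, no row names.
#'
#' @param traj a \code{cdts_trajectory}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cdts_trajectory"))
  write.csv(as.data.frame(traj)[, c("t", GROUPS)], path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by \code{\link{write_trajectory}}.
#' @return a data.frame with columns \code{t, x, y, z, p}.
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  stopifnot(identical(names(d), c("t", GROUPS)))
  d
}

#' Serialize a stability report to JSON
#'
#' Per corner: coordinates, eigenvalues in the published row order, their
#' group labels, sign pattern, verdict and attached condition; plus the
#' satisfied-condition set and the ESS list. Key order is fixed for
#' diffability.
#'
#' @param params a \code{cdts_params} object.
#' @param path output JSON path.
#' @param boundary_tol passed to the classifiers.
#' @return the report list, invisibly.
#' @export
write_stability_report <- function(params, path, boundary_tol = 1e-12) {
  stab <- classify_equilibria(params, boundary_tol)
  conds <- check_conditions(params, boundary_tol)
  report <- list(
    expressions = expression_values(params, boundary_tol),
    conditions = as.integer(conds),
    ess = as.list(ess_set(stab)),
    corners = lapply(seq_len(nrow(stab)), function(i) {
      r <- stab[i, ]
      list(id = r$id, state = c(r$x, r$y, r$z, r$p),
           eigenvalues = c(r$lambda1, r$lambda2, r$lambda3, r$lambda4),
           groups = strsplit(r$groups, ",")[[1]],
           signs = strsplit(r$signs, ",")[[1]],
           verdict = r$verdict,
           condition = if (is.na(r$condition)) NULL else r$condition)
    })
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(report)
}

#' Serialize a scenario report to JSON
#'
#' @param report a \code{cdts_scenario_report}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_scenario_report <- function(report, path) {
  stopifnot(inherits(report, "cdts_scenario_report"))
  out <- list(id = report$id, type = report$type)
  if (report$type == "equilibrium") {
    out$expressions <- report$expressions
    out$conditions <- report$conditions
    out$ess <- as.list(report$ess)
    out$endpoints <- lapply(report$endpoints, function(e) {
      list(converged = e$converged, corner = e$corner,
           nearest = e$nearest, distance = e$distance,
           final_state = as.list(e$final_state), final_time = e$final_time)
    })
  } else {
    out$compare <- report$compare
    out$faster_variant <- report$faster_variant
    out$init <- as.list(report$init)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
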