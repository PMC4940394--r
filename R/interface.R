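# Result serialization: JSON/CSV exports and per-case reports.

#' Full report for one phenotype
#'
#' Collects the case's dominant S-system equations, symbolic steady-state
#' solution, log-gain matrix, and (when a parameter point is supplied or
#' predictable) the eigenvalues at a representative point and the global
#' tolerances there.
#'
#' @param case a `ds_case`.
#' @param pvals optional named parameter values; defaults to the predicted
#'   interior point when the case is valid.
#' @return a list suitable for [jsonlite::toJSON()] via [write_case_report()].
#' @export
case_report <- function(case, pvals = NULL) {
  rep <- list(case_number = case$number,
              signature = case$signature_string,
              equations = deparse_gma(case$ssystem),
              has_solution = case$solution$exists)
  if (case$solution$exists) {
    rep$solution <- case$solution$strings
    rep$gains <- case$solution$gains
  }
  if (is.null(pvals) && !is.null(case$boundary)) {
    pvals <- tryCatch(valid_interior_parameter_set(case), error = function(e) NULL)
  }
  if (!is.null(pvals)) {
    rep$pvals <- as.list(unlist(pvals))
    st <- tryCatch(ssys_eigenvalues(case$ssystem, pvals), error = function(e) NULL)
    if (!is.null(st)) {
      rep$eigenvalues_real <- Re(st$eigenvalues)
      rep$eigenvalues_imaginary <- Im(st$eigenvalues)
      rep$positive_roots <- st$positive_roots
    }
    tol <- tryCatch(measure_tolerances(case, pvals), error = function(e) NULL)
    if (!is.null(tol)) rep$tolerances <- tol
  }
  rep
}

#' Write a case report as JSON
#'
#' @param case a `ds_case`.
#' @param path output file.
#' @param pvals optional parameter values (see [case_report()]).
#' @export
write_case_report <- function(case, path, pvals = NULL) {
  jsonlite::write_json(case_report(case, pvals), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a linear inequality system as JSON
#'
#' @param iq an `ineq_system` (e.g. [boundary_conditions()]).
#' @param path output file.
#' @export
write_ineq_json <- function(iq, path) {
  jsonlite::write_json(list(variables = iq$vars,
                            coefficients = unname(apply(iq$A, 1, as.list)),
                            constants = iq$b,
                            relations = iq$rel),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the phenotypic repertoire as CSV
#'
#' @param system a `gma_system`.
#' @param path output file.
#' @param ... passed to [repertoire()].
#' @export
write_repertoire_csv <- function(system, path, ...) {
  utils::write.csv(repertoire(system, ...), path, row.names = FALSE)
  invisible(path)
}
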