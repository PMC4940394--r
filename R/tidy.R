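# broom-style tidiers for the package's core objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ineq_system
#' @export
tidy.ineq_system <- function(x, ...) {
  if (nrow(x$A) == 0) {
    return(tibble::tibble(row = integer(0), variable = character(0),
                          coefficient = numeric(0), constant = numeric(0),
                          relation = character(0)))
  }
  rows <- lapply(seq_len(nrow(x$A)), function(i) {
    nz <- which(x$A[i, ] != 0)
    tibble::tibble(row = i, variable = x$vars[nz], coefficient = unname(x$A[i, nz]),
                   constant = x$b[i], relation = x$rel[i])
  })
  do.call(rbind, rows)
}

#' @method tidy ds_case
#' @export
tidy.ds_case <- function(x, ...) {
  if (is.null(x$boundary)) {
    return(tidy.ineq_system(ineq_system(x$system$independent)))
  }
  tidy(x$boundary)
}

#' @method glance ds_case
#' @export
glance.ds_case <- function(x, ...) {
  tibble::tibble(case_number = x$number,
                 signature = x$signature_string,
                 has_solution = x$solution$exists,
                 valid = case_is_valid(x),
                 n_boundary_rows = if (is.null(x$boundary)) NA_integer_ else nrow(x$boundary$A))
}

#' @method tidy ssystem_solution
#' @export
tidy.ssystem_solution <- function(x, ...) {
  if (!x$exists) {
    return(tibble::tibble(dependent = character(0), independent = character(0),
                          gain = numeric(0)))
  }
  out <- expand.grid(dependent = x$dependent, independent = x$independent,
                     stringsAsFactors = FALSE)
  out$gain <- as.numeric(x$gains[cbind(out$dependent, out$independent)])
  tibble::as_tibble(out)
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  tibble::tibble(eigenvalue = seq_along(x$eigenvalues),
                 real = Re(x$eigenvalues),
                 imaginary = Im(x$eigenvalues))
}

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(positive_roots = x$positive_roots,
                 margin = x$margin,
                 borderline = x$borderline)
}
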