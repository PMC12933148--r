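#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an objective breakdown
#' @param x an `objective_breakdown`.
#' @param ... unused.
#' @return tibble with one row per tracer term.
#' @export
tidy.objective_breakdown <- function(x, ...) x$terms

#' @rdname tidy.objective_breakdown
#' @export
glance.objective_breakdown <- function(x, ...) {
  tibble(total = x$total, failed = x$failed)
}

#' Tidy an optimization result
#' @param x an `optimization_result`.
#' @param ... unused.
#' @return tibble with one row per parameter (`parameter`, `estimate`).
#' @export
tidy.optimization_result <- function(x, ...) {
  tibble(parameter = names(x$params),
         estimate = unlist(x$params, use.names = FALSE))
}

#' @rdname tidy.optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  tibble(f = x$f, converged = x$converged, evaluations = x$evaluations,
         seed = x$seed)
}

#' Tidy a sequestration curve
#' @param x a `seq_curve`.
#' @param ... unused.
#' @return the curve as a plain tibble.
#' @export
tidy.seq_curve <- function(x, ...) as_tibble(x)

#' @rdname tidy.seq_curve
#' @export
glance.seq_curve <- function(x, ...) {
  tibble(element = attr(x, "element"),
         production_Pg_y = attr(x, "production_Pg_y"),
         n_pools = length(setdiff(unique(x$pool), "total")),
         t_max = max(x$t_years))
}
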