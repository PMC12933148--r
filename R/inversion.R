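#' Volume-based precision weights
#'
#' Diagonal precision per tracer: `w_i = v_i / (sigma2_tracer * V_obs)`,
#' where `v_i` is the box volume and `V_obs` the total observed volume for
#' that tracer; weight is exactly zero where the observation is missing.
#' Large, well-observed boxes count more; each tracer term is normalized by
#' its observational variance so the six terms are commensurate.
#'
#' @param grid an [ocean_grid()].
#' @param obs an [make_observations()] set (long tibble).
#' @param per_tracer_variance named numeric vector of observational
#'   variances per tracer; by default the variance of the observed values of
#'   each tracer.
#' @return long tibble: `box`, `tracer`, `weight`.
#' @export
precision_weights <- function(grid, obs, per_tracer_variance = NULL) {
  v <- grid_volumes(grid)
  obs |>
    as_tibble() |>
    group_by(.data$tracer) |>
    mutate(
      variance = if (is.null(per_tracer_variance)) {
        stats::var(.data$value[.data$observed])
      } else {
        per_tracer_variance[[.data$tracer[1]]]
      },
      weight = ifelse(.data$observed,
                      v[.data$box] / (.data$variance *
                                        sum(v[.data$box][.data$observed])),
                      0)
    ) |>
    ungroup() |>
    select("box", "tracer", "weight")
}

#' Bayesian tracer-misfit objective
#'
#' The negative log-posterior (up to a constant) of the cycle parameters
#' given gridded observations of the six tracers:
#' `f = 1/2 sum_x e_x' W_x e_x` over x in (DIP, DOP, DIC, DOC, ALK, O2),
#' with `e_x` = model minus observation on observed boxes and `W_x` the
#' volume-based precision of [precision_weights()]. Bulk model DOC is the
#' sum of the three modeled DOC pools. A failed forward solve returns a
#' large penalty (1e12) with a flag rather than raising, so optimizers can
#' proceed.
#'
#' @param params a [cycle_params()].
#' @param A transport operator.
#' @param forcing forcing table.
#' @param obs observation set.
#' @param grid an [ocean_grid()].
#' @param weights precomputed [precision_weights()] (recomputed if NULL).
#' @param dip_inventory global-mean DIP constraint (mol m^-3).
#' @return list of class `objective_breakdown`: `total`, `terms` (tibble
#'   `tracer`, `term`), `params`, `failed` (logical), `message`.
#' @export
tracer_objective <- function(params, A, forcing, obs, grid, weights = NULL,
                             dip_inventory = 2e-3) {
  if (is.null(weights)) weights <- precision_weights(grid, obs)
  state <- tryCatch(
    solve_cycles(params, A, forcing, grid, dip_inventory = dip_inventory),
    error = function(e) e
  )
  if (inherits(state, "error")) {
    return(structure(list(total = 1e12,
                          terms = tibble(tracer = OBSERVED_TRACERS,
                                         term = NA_real_),
                          params = params, failed = TRUE,
                          message = conditionMessage(state)),
                     class = "objective_breakdown"))
  }
  model <- tibble(
    box = rep(state$box, 6),
    tracer = rep(OBSERVED_TRACERS, each = nrow(state)),
    model = c(state$DIP, state$DOP, state$DIC,
              state$DOC + state$DOC_l + state$DOC_r, state$ALK, state$O2)
  )
  joined <- obs |>
    as_tibble() |>
    left_join(model, by = c("box", "tracer")) |>
    left_join(weights, by = c("box", "tracer"))
  terms <- joined |>
    group_by(.data$tracer) |>
    summarise(term = 0.5 * sum(.data$weight * (.data$model - .data$value)^2),
              .groups = "drop")
  structure(list(total = sum(terms$term), terms = terms, params = params,
                 failed = FALSE, message = NULL),
            class = "objective_breakdown")
}

#' @export
#' @method print objective_breakdown
print.objective_breakdown <- function(x, ...) {
  cat("<objective_breakdown> f =", format(x$total), "\n")
  if (x$failed) cat("  forward solve FAILED:", x$message, "\n")
  print(x$terms)
  invisible(x)
}

#' Fit cycle parameters to tracer observations
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of [tracer_objective()]
#' over a chosen subset of the optimizable parameters, in log space (all
#' optimizable parameters are positive). Gradients are finite-difference;
#' the evaluation budget caps the number of objective calls. Reproducible:
#' the search is deterministic given the initial point, and `seed` controls
#' the optional jittered start.
#'
#' @param A,forcing,obs,grid,dip_inventory as in [tracer_objective()].
#' @param free character vector of parameter names to optimize (must appear
#'   in [param_bounds()]).
#' @param initial a [cycle_params()] supplying the starting point and the
#'   values of all fixed parameters.
#' @param budget maximum objective evaluations, default 500.
#' @param jitter_sd lognormal sd applied to the free starting values
#'   (0 = start exactly at `initial`).
#' @param seed integer seed for the start jitter.
#' @param reltol convergence tolerance passed to the optimizer (factr
#'   scale), default 1e-10.
#' @return list of class `optimization_result`: `params` (best
#'   `cycle_params`), `f` (best objective), `trace` (tibble of evaluations),
#'   `converged`, `evaluations`, `seed`.
#' @export
fit_cycle_params <- function(A, forcing, obs, grid, free,
                             initial = cycle_params(), budget = 500,
                             jitter_sd = 0, seed = 1, dip_inventory = 2e-3,
                             reltol = 1e-10) {
  bounds <- param_bounds()
  unknown <- setdiff(free, bounds$name)
  if (length(unknown) > 0) {
    abort(paste0("not optimizable: ", paste(unknown, collapse = ", ")))
  }
  bounds <- bounds[match(free, bounds$name), ]
  weights <- precision_weights(grid, obs)

  x0 <- log(unlist(initial[free]))
  if (jitter_sd > 0) {
    x0 <- x0 + with_local_seed(seed, rnorm(length(x0), 0, jitter_sd))
  }
  x0 <- pmin(pmax(x0, log(bounds$lower)), log(bounds$upper))

  evals <- 0L
  trace <- list()
  fn <- function(x) {
    if (evals >= budget) return(1e12) # budget exhausted: flat wall
    evals <<- evals + 1L
    p <- initial
    p[free] <- as.list(exp(x))
    ob <- tryCatch(
      tracer_objective(do.call(cycle_params, unclass(p)), A, forcing, obs,
                       grid, weights = weights,
                       dip_inventory = dip_inventory),
      error = function(e) list(total = 1e12, failed = TRUE)
    )
    trace[[length(trace) + 1L]] <<-
      c(eval = evals, f = ob$total, setNames(exp(x), free))
    ob$total
  }
  f0 <- fn(x0)
  if (f0 < 1e-12) { # already at a perfect fit: nothing to optimize
    res <- list(par = x0, value = f0, convergence = 0L)
  } else {
    res <- tryCatch(
      optim(x0, fn, method = "L-BFGS-B",
            lower = log(bounds$lower), upper = log(bounds$upper),
            control = list(maxit = max(5, ceiling(budget / (2 * length(free) + 1))),
                           factr = reltol / .Machine$double.eps)),
      error = function(e) list(par = x0, value = f0, convergence = 52L,
                               message = conditionMessage(e))
    )
  }
  tr <- as_tibble(do.call(rbind, trace))
  best <- which.min(tr$f)
  p <- initial
  p[free] <- as.list(unlist(tr[best, free]))
  structure(list(
    params = do.call(cycle_params, unclass(p)),
    f = tr$f[best],
    trace = tr,
    converged = (identical(res$convergence, 0L) ||
                   identical(res$convergence, 0)) && evals < budget,
    evaluations = evals,
    seed = seed
  ), class = "optimization_result")
}

#' @export
#' @method print optimization_result
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> best f =", format(x$f),
      "| evaluations:", x$evaluations,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Volume-weighted goodness of fit
#'
#' Weighted coefficient of determination:
#' `R2 = 1 - sum(w (m - o)^2) / sum(w (o - mean_w(o))^2)`.
#'
#' @param model_field,obs_field per-box fields.
#' @param weights non-negative weights (e.g. box volumes); boxes with zero
#'   weight are ignored. At least two weighted boxes required.
#' @return scalar R^2.
#' @export
goodness_of_fit <- function(model_field, obs_field, weights) {
  keep <- weights > 0 & is.finite(obs_field) & is.finite(model_field)
  if (sum(keep) < 2) abort("need at least two observed boxes")
  w <- weights[keep]; m <- model_field[keep]; o <- obs_field[keep]
  om <- weighted.mean(o, w)
  tss <- sum(w * (o - om)^2)
  if (tss == 0) abort("observations have zero weighted variance")
  1 - sum(w * (m - o)^2) / tss
}
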