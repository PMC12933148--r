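#' Run the full desk-scale model pipeline
#'
#' Bundles the whole chain — steady-state P and C cycles, regenerated-pulse
#' survival integration, sequestration curves for both elements and their
#' C:P ratio — into one reproducible run object that the sensitivity
#' experiments take as their base.
#'
#' @param transport list with `grid` and `A` (e.g.
#'   [build_synthetic_transport()]).
#' @param forcing a [make_forcing()] table (default: built from the grid).
#' @param params a [cycle_params()].
#' @param t_grid residence-time thresholds (years), default
#'   [default_t_grid()].
#' @param sink_rate surface restoring rate (y^-1), default 500.
#' @param dip_inventory global-mean DIP constraint (mol m^-3).
#' @param ... passed to [survival_integrate()] via
#'   [sequestration_curve()].
#' @return list of class `pump_run`: `grid`, `A`, `forcing`, `params`,
#'   `sink`, `t_grid`, `state` (full equilibrium), `curve_C`, `curve_P`,
#'   `cp` (C:P ratio curve), `dip_inventory`.
#' @export
run_model <- function(transport, forcing = NULL, params = cycle_params(),
                      t_grid = default_t_grid(), sink_rate = 500,
                      dip_inventory = 2e-3, ...) {
  grid <- transport$grid
  A <- transport$A
  if (is.null(forcing)) forcing <- make_forcing(grid)
  state <- solve_cycles(params, A, forcing, grid,
                        dip_inventory = dip_inventory)
  sink <- restoring_sink(grid, sink_rate)
  curve_C <- sequestration_curve(state, A, sink, t_grid, element = "C",
                                 grid = grid, ...)
  curve_P <- sequestration_curve(state, A, sink, t_grid, element = "P",
                                 grid = grid, ...)
  structure(list(grid = grid, A = A, forcing = forcing, params = params,
                 sink = sink, t_grid = t_grid, state = state,
                 curve_C = curve_C, curve_P = curve_P,
                 cp = cp_curve(curve_C, curve_P),
                 dip_inventory = dip_inventory),
            class = "pump_run")
}

#' @export
#' @method print pump_run
print.pump_run <- function(x, ...) {
  cat("<pump_run> ", x$grid$n_boxes, " boxes; production ",
      signif(attr(x$curve_C, "production_Pg_y"), 3), " Pg C y^-1, ",
      signif(attr(x$curve_P, "production_Pg_y"), 3), " Pg P y^-1\n", sep = "")
  invisible(x)
}

#' Labile-DOP routing sensitivity
#'
#' Re-solves the phosphorus cycle with a share of total organic-P
#' production routed into an added labile DOP pool (12-hour lifetime,
#' matching labile DOC); the POP share is reduced as the residual. The
#' carbon cycle is held fixed at the base run's solution (its curves are
#' cached, only P-side survival curves and the C:P ratio recompute). This
#' probes how fast-cycling phosphorus reshapes sequestration stoichiometry:
#' more labile routing lowers the short-horizon C:P and raises the
#' century-horizon C:P.
#'
#' @param base a [run_model()] result.
#' @param fractions shares of organic-P production routed to labile DOP,
#'   default `c(0.01, 0.10, 0.20, 0.40, 0.60)`. Each must lie in \[0, 1)
#'   and leave a non-negative POP share.
#' @return list of class `labile_dop_sensitivity`: `summary` (tibble:
#'   `fraction`, `phi_top_0`, `phi_top_1y`, `cp_production`, `cp_1y`,
#'   `cp_century`), `cp_curves` (long tibble `fraction`, `t_years`,
#'   `cp_ratio`), `curves` (named list of `seq_curve`s), `base`.
#' @export
run_labile_dop_sensitivity <- function(base,
                                       fractions = c(0.01, 0.10, 0.20,
                                                     0.40, 0.60)) {
  if (any(fractions < 0 | fractions >= 1)) {
    abort("labile fractions must lie in [0, 1)")
  }
  res <- purrr::map(fractions, function(f) {
    if (base$params$sigma_dop + f > 1) {
      abort("sigma_dop + labile fraction exceeds 1")
    }
    p2 <- update_params(base$params, sigma_dopl = f)
    ps <- solve_p_cycle(p2, base$A, base$forcing, base$grid,
                        dip_inventory = base$dip_inventory)
    curve_p <- sequestration_curve(ps, base$A, base$sink, base$t_grid,
                                   element = "P", grid = base$grid)
    cp <- cp_curve(base$curve_C, curve_p)
    tot <- filter(curve_p, .data$pool == "total")
    list(
      curve = curve_p, cp = cp,
      summary = tibble(
        fraction = f,
        phi_top_0 = attr(curve_p, "production_Pg_y"),
        phi_top_1y = interp_curve(tot$t_years, tot$flux_Pg_y, 1),
        cp_production = cp$cp_ratio[cp$t_years == 0],
        cp_1y = approx(cp$t_years, cp$cp_ratio, xout = 1)$y,
        cp_century = approx(cp$t_years, cp$cp_ratio, xout = 100)$y
      )
    )
  })
  structure(list(
    summary = bind_rows(purrr::map(res, "summary")),
    cp_curves = bind_rows(purrr::map2(res, fractions, function(r, f) {
      mutate(r$cp, fraction = f)
    })),
    curves = setNames(purrr::map(res, "curve"), paste0("f", fractions)),
    base = base
  ), class = "labile_dop_sensitivity")
}

#' Equal carbon/phosphorus remineralization experiment
#'
#' Removes the elemental asymmetry in remineralization and measures what it
#' does to sequestration stoichiometry and efficiency. Two modes:
#' `"P_from_C"` sets the phosphorus remineralization parameters equal to
#' carbon's at every location (`bP = bC`, `kP = kC`); `"means"` assigns
#' both elements spatially uniform values (`b_common`, `k_common`),
#' intended to be the flux-weighted global means of the base model. Both
#' cycles are re-solved under the override (no re-optimization), curves are
#' recomputed, and TOC sequestration efficiencies are compared with the
#' base at the standard thresholds. Relative differences are reported as
#' `(base - alt)/alt` (the "percent lower" convention).
#'
#' @param base a [run_model()] result.
#' @param mode `"P_from_C"` or `"means"`.
#' @param b_common,k_common uniform Martin exponent and remineralization
#'   rate (y^-1) used by mode `"means"`; defaults 1.28 and 0.057, the
#'   full-scale flux-weighted reference values.
#' @param thresholds efficiency thresholds (years), default
#'   `c(10, 100, 200, 1000)`.
#' @return list of class `equal_remin_experiment`: `params`, `state`,
#'   `curve_C`, `curve_P`, `cp`, `efficiency` (tibble: `t_years`,
#'   `eff_base`, `eff_alt`, `rel_diff`), `cp_production`, `cp_century`,
#'   `mode`.
#' @export
run_equal_remin_experiment <- function(base, mode = c("P_from_C", "means"),
                                       b_common = 1.28, k_common = 0.057,
                                       thresholds = c(10, 100, 200, 1000)) {
  mode <- match.arg(mode)
  p <- base$params
  p2 <- if (mode == "P_from_C") {
    update_params(p, bP0 = p$bC0, bPth = p$bCth, kdP = p$kdC, Q10P = p$Q10C)
  } else {
    update_params(p, bC0 = b_common, bCth = 0, bP0 = b_common, bPth = 0,
                  kdC = k_common / SEC_PER_YEAR,
                  kdP = k_common / SEC_PER_YEAR, Q10C = 1, Q10P = 1)
  }
  state <- solve_cycles(p2, base$A, base$forcing, base$grid,
                        dip_inventory = base$dip_inventory)
  curve_c <- sequestration_curve(state, base$A, base$sink, base$t_grid,
                                 element = "C", grid = base$grid)
  curve_p <- sequestration_curve(state, base$A, base$sink, base$t_grid,
                                 element = "P", grid = base$grid)
  cp <- cp_curve(curve_c, curve_p)
  thresholds <- thresholds[thresholds <= max(base$t_grid)]
  e_base <- sequestration_efficiency(base$curve_C, thresholds)$efficiency
  e_alt <- sequestration_efficiency(curve_c, thresholds)$efficiency
  structure(list(
    params = p2, state = state, curve_C = curve_c, curve_P = curve_p,
    cp = cp,
    efficiency = tibble(
      t_years = thresholds,
      eff_base = e_base,
      eff_alt = e_alt,
      rel_diff = (e_base - e_alt) / e_alt
    ),
    cp_production = cp$cp_ratio[cp$t_years == 0],
    cp_century = approx(cp$t_years, cp$cp_ratio, xout = 100)$y,
    mode = mode
  ), class = "equal_remin_experiment")
}

#' Retained mass from a production perturbation
#'
#' Linear accounting: a sustained `delta_production` increase in global
#' organic carbon production leaves `delta * efficiency(t)` sequestered
#' beyond each residence-time threshold.
#'
#' @param efficiency a [sequestration_efficiency()] table (columns
#'   `t_years`, `efficiency`).
#' @param delta_production perturbation size (Pg C), default 1.
#' @return tibble: `t_years`, `efficiency`, `retained_Pg` =
#'   `delta_production * efficiency`.
#' @export
run_perturbation_accounting <- function(efficiency, delta_production = 1) {
  eff <- efficiency$efficiency
  tibble(t_years = efficiency$t_years,
         efficiency = eff,
         retained_Pg = delta_production * eff)
}

#' Write a sequestration curve to CSV
#'
#' Wide layout: `t_years`, one column per pool, `total` last.
#'
#' @param curve a `seq_curve`; @param path output file.
#' @return `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  wide <- tidyr::pivot_wider(as_tibble(curve), names_from = "pool",
                             values_from = "flux_Pg_y")
  pools <- setdiff(names(wide), c("t_years", "total"))
  utils::write.csv(wide[, c("t_years", pools, "total")], path,
                   row.names = FALSE)
  invisible(path)
}
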