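#' Biogeochemical cycle parameters
#'
#' A named registry of every tunable in the coupled phosphorus/carbon/oxygen
#' cycle model, with bounds for the optimizable subset. Rates are SI (s^-1),
#' depths are metres, fractions dimensionless. The registry is data-driven:
#' the optimizable set is whatever [param_bounds()] lists, so it can be
#' edited without code changes.
#'
#' Key parameters:
#' \describe{
#'   \item{bC0, bCth, bP0, bPth}{Martin particle-flux attenuation exponents
#'     via `b = b0 + bth * theta_bar`, per element (C, P).}
#'   \item{kdC, kdP}{reference semilabile DOC / DOP remineralization rates
#'     (s^-1) at the reference temperature `T0` = 30 degC.}
#'   \item{Q10C, Q10P}{temperature sensitivity of the semilabile rates
#'     (`k = kd * Q10^((T - T0)/10)`).}
#'   \item{cc, dd}{production C:P stoichiometry `r = 1 / (cc * DIP + dd)`;
#'     `cc` in m^3 mol^-1, `dd` dimensionless (`1/dd` is the zero-phosphate
#'     C:P limit).}
#'   \item{sigma_dop, sigma_dopl}{fractions of organic-P production routed to
#'     semilabile and labile DOP; the POP share is the residual.}
#'   \item{sigma_docs, sigma_docr}{fractions of non-labile organic-C
#'     production routed to semilabile and refractory DOC; POC is the
#'     residual.}
#'   \item{kappa_l}{labile DOM decay rate, fixed 12-hour lifetime.}
#'   \item{kappa_r}{refractory DOC decay rate, fixed 16,000-year lifetime.}
#'   \item{pic_rain_ratio, pic_dissolution_scale}{PIC production as a
#'     fraction of POC production, and the e-folding depth (m) of its
#'     dissolution below the euphotic base.}
#'   \item{o2_to_p}{O2:P stoichiometry of production/remineralization,
#'     fixed 150.}
#'   \item{restore_rate, dic_surface_ref, alk_surface_ref}{fast surface
#'     restoring closure for DIC/ALK (rate s^-1; targets mol m^-3 and
#'     mol-eq m^-3).}
#'   \item{o2_sat_intercept, o2_sat_slope}{linear O2 saturation vs
#'     temperature (mol m^-3, mol m^-3 per degC) for surface restoring.}
#' }
#'
#' @param ... name = value overrides of the defaults.
#' @return a named list of class `cycle_params`.
#' @export
cycle_params <- function(...) {
  p <- list(
    bC0 = 1.05, bCth = 0.45,
    bP0 = 0.95, bPth = 0.35,
    kdC = 1 / (5 * SEC_PER_YEAR),
    kdP = 1 / (40 * SEC_PER_YEAR),
    Q10C = 2.0, Q10P = 2.0,
    T0 = 30,
    cc = 3.0, dd = 1 / 300,
    sigma_dop = 0.30, sigma_dopl = 0.0,
    sigma_docs = 0.30, sigma_docr = 0.02,
    kappa_l = 1 / 43200,                       # 12 h lifetime
    kappa_r = 1 / (16000 * SEC_PER_YEAR),      # 16,000 y lifetime
    pic_rain_ratio = 0.07,
    pic_dissolution_scale = 3000,
    o2_to_p = 150,
    restore_rate = 1 / (30 * 86400),           # 30 d surface restoring
    dic_surface_ref = 1.95,
    alk_surface_ref = 2.30,
    o2_sat_intercept = 0.35,
    o2_sat_slope = -0.006
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(over)] <- over
  validate_params(p)
  structure(p, class = "cycle_params")
}

validate_params <- function(p) {
  rates <- c("kdC", "kdP", "kappa_l", "kappa_r", "restore_rate")
  if (any(unlist(p[rates]) < 0)) abort("all rates must be >= 0")
  fr <- c("sigma_dop", "sigma_dopl", "sigma_docs", "sigma_docr",
          "pic_rain_ratio")
  if (any(unlist(p[fr]) < 0 | unlist(p[fr]) > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (p$sigma_dop + p$sigma_dopl > 1) abort("sigma_dop + sigma_dopl must be <= 1")
  if (p$sigma_docs + p$sigma_docr > 1) abort("sigma_docs + sigma_docr must be <= 1")
  if (p$Q10C < 1 || p$Q10P < 1) abort("Q10 must be >= 1")
  invisible(p)
}

#' @export
#' @method print cycle_params
print.cycle_params <- function(x, ...) {
  cat("<cycle_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Update parameters
#' @param params a [cycle_params()] object.
#' @param ... name = value overrides.
#' @return updated `cycle_params`.
#' @export
update_params <- function(params, ...) {
  do.call(cycle_params, modifyList(unclass(params), list(...)))
}

#' Bounds for the optimizable parameters
#'
#' @return tibble with columns `name`, `lower`, `upper`. All listed
#'   parameters are strictly positive, so optimization works in log space.
#' @export
param_bounds <- function() {
  tibble(
    name  = c("bC0", "bCth", "bP0", "bPth", "kdC", "kdP", "Q10C", "Q10P",
              "cc", "dd", "sigma_dop", "sigma_docs", "sigma_docr",
              "pic_rain_ratio", "pic_dissolution_scale"),
    lower = c(0.3, 1e-3, 0.3, 1e-3, 1e-11, 1e-12, 1.0, 1.0,
              1e-3, 1e-4, 0.01, 0.01, 1e-4, 1e-3, 200),
    upper = c(3, 2, 3, 2, 1e-6, 1e-6, 6, 6,
              50, 0.02, 0.9, 0.9, 0.3, 0.3, 6000)
  )
}

#' Write / read parameters as a plain-text config
#'
#' `key: value` lines; `#` starts a comment. Units are annotated as comments
#' on write.
#'
#' @param params a [cycle_params()].
#' @param path file path.
#' @return `path` invisibly; `read_params` returns a `cycle_params`.
#' @export
write_params <- function(params, path) {
  lines <- vapply(names(params), function(nm) {
    sprintf("%s: %.17g", nm, params[[nm]])
  }, character(1))
  writeLines(c("# cycle parameters (rates s^-1, depths m, fractions unitless)",
               lines), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  do.call(cycle_params, vals)
}
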