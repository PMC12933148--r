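#' Surface restoring sink for regenerated tracers
#'
#' The absorbing boundary of the first-passage computation: regenerated
#' tracer that re-enters the euphotic zone is removed by restoring its
#' concentration there to zero with a fast rate (default 500 y^-1, i.e. a
#' 1/500-year timescale), which approximates an absorbing surface.
#'
#' @param grid an [ocean_grid()].
#' @param rate restoring rate, y^-1 (> 0), default 500.
#' @return list of class `restoring_sink`: `mask` (logical per box, the
#'   euphotic mask), `rate_per_year`, `rate_per_sec`.
#' @export
restoring_sink <- function(grid, rate = 500) {
  if (rate <= 0) abort("restoring rate must be positive")
  structure(list(mask = grid$boxes$euphotic, rate_per_year = rate,
                 rate_per_sec = rate / SEC_PER_YEAR),
            class = "restoring_sink")
}

#' Regenerated-tracer pulse fields per organic pool
#'
#' The spatial pattern of the regenerated pulse is the steady-state
#' remineralization rate of each organic pool: where a pool's organic
#' matter is respired is where its regenerated inorganic product enters the
#' interior. The volume integral of each field equals that pool's global
#' remineralization (= production at steady state).
#'
#' @param equilibrium an `equilibrium_state` with remineralization
#'   diagnostics.
#' @param element `"C"` or `"P"`.
#' @return named list of per-box rate fields (mol m^-3 s^-1): pools
#'   `POC, DOC, DOC_l, DOC_r` for carbon, `POP, DOP, DOP_l` for phosphorus.
#' @export
remin_source_fields <- function(equilibrium, element = c("C", "P")) {
  element <- match.arg(element)
  pools <- if (element == "C") c("POC", "DOC", "DOC_l", "DOC_r")
           else c("POP", "DOP", "DOP_l")
  cols <- paste0("remin_", pools)
  missing <- setdiff(cols, names(equilibrium))
  if (length(missing) > 0) {
    abort(paste0("equilibrium is missing remineralization diagnostic(s): ",
                 paste(missing, collapse = ", ")))
  }
  setNames(lapply(cols, function(cc) equilibrium[[cc]]), pools)
}

#' Survival of a regenerated pulse: trapezoid time integration
#'
#' Integrates `dR/dt = A R - (rate * mask) R` from `R(0) = r0` and reports
#' the global volume-integrated inventory `M(t) = v' R(t)` on the requested
#' time grid. `M(t)` is the amount of the initial pulse whose first return
#' to the euphotic zone takes longer than `t` — the survival function of
#' the interior residence time.
#'
#' Stepping is trapezoid (Crank-Nicolson) with step-doubling: each step is
#' taken once at `dt` and twice at `dt/2`; the Richardson-extrapolated
#' combination is kept and the difference controls the local error. The
#' step grows geometrically (ratio `growth`) from `dt0` up to `dt_max`, is
#' halved when the error estimate exceeds `tol_step`, and lands exactly on
#' every requested threshold (no output-time interpolation). During the
#' initial drain of the euphotic boxes the restoring term is stiff (rate
#' ~500 y^-1); there the controller applies the looser `tol_drain` — for a
#' second-order scheme, resolving that brief exponential drain to full
#' tolerance would cost thousands of steps while only the (short-lived)
#' euphotic fraction of the pulse is affected.
#'
#' @param A transport operator (s^-1).
#' @param sink a [restoring_sink()].
#' @param r0 per-box initial pulse field (mol m^-3 s^-1 for remin-rate
#'   pulses; any linear units propagate).
#' @param t_grid output times (years), starting at 0, increasing.
#' @param grid an [ocean_grid()].
#' @param dt0,dt_max,growth step schedule (years), defaults 1e-3, 10, 1.2.
#' @param tol_step relative local error tolerance per step, default 1e-7 (the
#'   extrapolated step error is typically two to three orders tighter).
#' @param tol_drain local tolerance while `t < 30 / rate` (the stiff
#'   euphotic drain), default 1e-4.
#' @param max_halvings retries before giving up on a step, default 40.
#' @return tibble: `t_years`, `inventory` (`M(t)`, volume-integrated pulse
#'   units, e.g. mol s^-1). `M` is checked to be non-increasing.
#' @export
survival_integrate <- function(A, sink, r0, t_grid, grid,
                               dt0 = 1e-3, dt_max = 10, growth = 1.2,
                               tol_step = 1e-7, tol_drain = 1e-4,
                               max_halvings = 40) {
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    abort("t_grid must start at 0 and be strictly increasing")
  }
  v <- grid_volumes(grid)
  n <- length(r0)
  B <- (A - Diagonal(x = sink$rate_per_sec * as.numeric(sink$mask))) *
    SEC_PER_YEAR  # y^-1
  t_drain <- if (sink$rate_per_year > 0) 30 / sink$rate_per_year else 0

  # the trapezoid propagator P(dt) = (I - dt/2 B)^-1 (I + dt/2 B) is cached
  # per step size; for systems up to a few hundred boxes it is formed
  # densely once so each step is a single matrix-vector product
  dense <- n <= 600
  if (dense) Bd <- as.matrix(B)
  Id <- diag(n)
  Isp <- Diagonal(n)
  fac_cache <- new.env(parent = emptyenv())
  get_prop <- function(dt) {
    key <- sprintf("%a", dt)
    f <- fac_cache[[key]]
    if (is.null(f)) {
      f <- if (dense) {
        solve(Id - (dt / 2) * Bd, Id + (dt / 2) * Bd)
      } else {
        Matrix::lu(Isp - (dt / 2) * B)
      }
      fac_cache[[key]] <- f
    }
    f
  }
  cn_step <- if (dense) {
    function(R, dt) as.numeric(get_prop(dt) %*% R)
  } else {
    function(R, dt) {
      as.numeric(solve(get_prop(dt), R + (dt / 2) * as.numeric(B %*% R)))
    }
  }

  R <- as.numeric(r0)
  M0 <- sum(v * R)
  out_M <- numeric(length(t_grid))
  out_M[1] <- M0
  # dt lives on a geometric ladder dt0 * growth^k so accepted step sizes
  # repeat and the cached propagators are reused; the rung moves up when the
  # error estimate is comfortably below tolerance and down when it exceeds
  # it (hysteresis avoids accept/reject cycling)
  k_max <- ceiling(log(dt_max / dt0) / log(growth))
  t <- 0; k <- 0L; i_out <- 2L; M_prev <- M0
  while (i_out <= length(t_grid)) {
    dt_rung <- min(dt0 * growth^k, dt_max)
    # land exactly on requested thresholds: no output-time interpolation
    dt_take <- min(dt_rung, t_grid[i_out] - t)
    tol_now <- if (t < t_drain) tol_drain else tol_step
    accepted <- FALSE
    for (try in seq_len(max_halvings)) {
      R1 <- cn_step(R, dt_take)
      Rh <- cn_step(cn_step(R, dt_take / 2), dt_take / 2)
      err <- sum(v * abs(R1 - Rh)) / max(sum(v * abs(Rh)), 1e-300)
      if (is.finite(err) && err <= tol_now) {
        R <- (4 * Rh - R1) / 3
        accepted <- TRUE
        break
      }
      k <- k - 1L
      dt_take <- min(min(dt0 * growth^k, dt_max), t_grid[i_out] - t)
    }
    if (!accepted) abort("survival_integrate: step size control failed")
    t <- t + dt_take
    M_t <- sum(v * R)
    if (M_t > M_prev + 1e-9 * abs(M0)) {
      abort("survival_integrate: inventory increased beyond round-off")
    }
    M_prev <- M_t
    if (abs(t - t_grid[i_out]) <= 1e-12 * max(t_grid[i_out], 1)) {
      out_M[i_out] <- max(M_t, 0)
      i_out <- i_out + 1L
    }
    if (err < 0.25 * tol_now && k < k_max) k <- k + 1L
  }
  tibble(t_years = t_grid, inventory = out_M)
}

#' Dense matrix-exponential first-passage oracle
#'
#' Brute-force check of [survival_integrate()]:
#' `M(t) = v' expm(t (A - Lambda)) r0` with `Lambda` the restoring diagonal,
#' evaluated by dense matrix exponentials. Only for small systems.
#'
#' @inheritParams survival_integrate
#' @param max_boxes refuse larger systems (default 500); use
#'   [survival_integrate()] instead.
#' @return tibble `t_years`, `inventory`.
#' @export
firstpassage_oracle <- function(A, sink, r0, t_grid, grid, max_boxes = 500) {
  n <- nrow(A)
  if (n > max_boxes) {
    abort("system too large for the dense oracle; use survival_integrate()")
  }
  v <- grid_volumes(grid)
  B <- as.matrix(A - Diagonal(x = sink$rate_per_sec * as.numeric(sink$mask))) *
    SEC_PER_YEAR
  M <- vapply(t_grid, function(t) {
    if (t == 0) return(sum(v * r0))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(B * t)))
    sum(v * as.numeric(E %*% r0))
  }, numeric(1))
  tibble(t_years = t_grid, inventory = M)
}

#' Residence-time-partitioned sequestration curve
#'
#' For each organic pool of one element, releases the regenerated pulse
#' from its steady-state remineralization pattern and integrates the
#' survival function. The value at threshold `t` is the sequestration flux
#' `Phi_{tau >= t}`: the part of global production (Pg element y^-1) whose
#' regenerated inorganic form remains in the interior at least `t` years
#' before first surfacing. At `t = 0` the curve equals total global
#' remineralization, i.e. production at steady state. The residence clock
#' starts at remineralization (the sinking interval is excluded).
#'
#' @param equilibrium an `equilibrium_state`.
#' @param A transport operator (s^-1).
#' @param sink a [restoring_sink()].
#' @param t_grid thresholds (years), starting at 0; default
#'   [default_t_grid()].
#' @param element `"C"` or `"P"`.
#' @param grid an [ocean_grid()] (default: attached to `equilibrium`).
#' @param ... passed to [survival_integrate()].
#' @return tibble of class `seq_curve`, long format: `t_years`, `pool`
#'   (including `"total"`), `flux_Pg_y`. Attributes: `element`,
#'   `production_Pg_y` (total production, = the curve at t = 0).
#' @export
sequestration_curve <- function(equilibrium, A, sink,
                                t_grid = default_t_grid(),
                                element = c("C", "P"),
                                grid = attr(equilibrium, "grid"), ...) {
  element <- match.arg(element)
  sources <- remin_source_fields(equilibrium, element)
  per_pool <- purrr::imap(sources, function(r0, pool) {
    m <- survival_integrate(A, sink, r0, t_grid, grid, ...)
    tibble(t_years = m$t_years, pool = pool,
           flux_Pg_y = mol_s_to_Pg_y(m$inventory, element))
  })
  long <- bind_rows(per_pool)
  total <- long |>
    group_by(.data$t_years) |>
    summarise(pool = "total", flux_Pg_y = sum(.data$flux_Pg_y),
              .groups = "drop")
  out <- bind_rows(long, total) |> arrange(.data$pool, .data$t_years)
  structure(out, class = c("seq_curve", class(tibble())),
            element = element,
            production_Pg_y = total$flux_Pg_y[total$t_years == 0])
}

#' Default residence-time threshold grid
#'
#' 0 plus log-spaced thresholds from `t_min` to `t_max` years.
#'
#' @param t_min,t_max span (years), defaults 1e-2 and 2000.
#' @param n number of positive thresholds, default 25.
#' @return numeric vector starting at 0.
#' @export
default_t_grid <- function(t_min = 1e-2, t_max = 2000, n = 25) {
  c(0, 10^seq(log10(t_min), log10(t_max), length.out = n))
}

#' C:P ratio of sequestration fluxes across residence time
#'
#' Elementwise molar ratio of the total carbon to total phosphorus
#' sequestration flux on a shared threshold grid.
#'
#' @param curve_c,curve_p `seq_curve` objects for C and P on identical
#'   `t_grid`s.
#' @param underflow P fluxes below this (Pg P y^-1) give `NA` ratios,
#'   default 1e-12.
#' @return tibble: `t_years`, `cp_ratio` (mol C : mol P).
#' @export
cp_curve <- function(curve_c, curve_p, underflow = 1e-12) {
  tc <- filter(curve_c, .data$pool == "total")
  tp <- filter(curve_p, .data$pool == "total")
  if (!isTRUE(all.equal(tc$t_years, tp$t_years))) {
    abort("curves must share an identical threshold grid")
  }
  molC <- tc$flux_Pg_y / MOLAR_MASS[["C"]]
  molP <- tp$flux_Pg_y / MOLAR_MASS[["P"]]
  ratio <- ifelse(tp$flux_Pg_y <= underflow, NA_real_, molC / molP)
  tibble(t_years = tc$t_years, cp_ratio = ratio)
}

#' Sequestration efficiency at residence-time thresholds
#'
#' Fraction of total production that remains sequestered beyond each
#' threshold: `Phi_{tau >= t} / production`, in \[0, 1\]. Thresholds must lie
#' within the curve's computed span (no extrapolation).
#'
#' @param curve a `seq_curve`.
#' @param thresholds years, default `c(10, 100, 200, 1000)`.
#' @param production_total Pg element y^-1; defaults to the curve's t = 0
#'   value.
#' @return tibble: `t_years`, `flux_Pg_y`, `efficiency`.
#' @export
sequestration_efficiency <- function(curve,
                                     thresholds = c(10, 100, 200, 1000),
                                     production_total =
                                       attr(curve, "production_Pg_y")) {
  tot <- filter(curve, .data$pool == "total")
  if (any(thresholds < 0) || any(thresholds > max(tot$t_years))) {
    abort("thresholds must lie within the computed t_grid span")
  }
  flux <- interp_curve(tot$t_years, tot$flux_Pg_y, thresholds)
  tibble(t_years = thresholds, flux_Pg_y = flux,
         efficiency = flux / production_total)
}

# log-flux vs time interpolation on the positive part of the grid; exact at 0
interp_curve <- function(t, flux, tq) {
  out <- numeric(length(tq))
  out[tq == 0] <- flux[t == 0][1]
  pos <- tq > 0
  if (any(pos)) {
    tp <- t[t > 0]; fp <- flux[t > 0]
    lf <- log(pmax(fp, 1e-300))
    out[pos] <- exp(approx(tp, lf, xout = tq[pos], rule = 2)$y)
  }
  out
}
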