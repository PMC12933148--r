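#' Normalized euphotic-column temperature
#'
#' Vertically averages temperature over the top three model layers
#' (thickness-weighted), then normalizes across water columns so the Martin
#' exponent parameterization `b = b0 + bth * theta_bar` sees a dimensionless
#' field. Min-max normalization to \[0, 1\] is the default (warmest column
#' maps to 1); z-score is available.
#'
#' @param temperature per-box temperature (degC), in box order.
#' @param grid an [ocean_grid()].
#' @param method `"minmax"` (default) or `"zscore"`.
#' @param n_layers_avg layers to average over (default 3); if the grid has
#'   fewer, the available layers are used with a warning.
#' @return per-box numeric vector, constant within each water column.
#' @export
normalized_surface_temperature <- function(temperature, grid,
                                           method = c("minmax", "zscore"),
                                           n_layers_avg = 3) {
  method <- match.arg(method)
  b <- grid$boxes
  if (grid$n_layers < n_layers_avg) {
    warn(paste0("grid has fewer than ", n_layers_avg,
                " layers; averaging over the available ", grid$n_layers))
    n_layers_avg <- grid$n_layers
  }
  top <- b$layer <= n_layers_avg
  tb <- tibble(column = b$column[top],
               w = b$thickness[top],
               t = temperature[top]) |>
    group_by(.data$column) |>
    summarise(tbar = sum(.data$t * .data$w) / sum(.data$w), .groups = "drop")
  if (method == "minmax") {
    rng <- range(tb$tbar)
    tb$theta <- if (diff(rng) == 0) 0 else (tb$tbar - rng[1]) / diff(rng)
  } else {
    s <- sd(tb$tbar)
    tb$theta <- if (s == 0) 0 else (tb$tbar - mean(tb$tbar)) / s
  }
  tb$theta[match(b$column, tb$column)]
}

#' Martin particle-flux attenuation exponent
#'
#' `b = b0 + bth * theta_bar`, elementwise. Larger `b` means shallower
#' remineralization of sinking particles.
#'
#' @param theta_bar normalized temperature field
#'   ([normalized_surface_temperature()]).
#' @param b0 intercept; @param bth temperature slope.
#' @return per-box `b` field. Errors if any value is non-positive.
#' @export
martin_b <- function(theta_bar, b0, bth) {
  if (any(!is.finite(theta_bar))) abort("theta_bar must be finite")
  b <- b0 + bth * theta_bar
  if (any(b <= 0)) abort("Martin exponent b must be positive everywhere")
  b
}

#' Q10 remineralization rate
#'
#' `k = kd * Q10^((T - T0)/10)`: the reference rate `kd` applies at `T0`
#' (30 degC); each 10 degC of cooling divides the rate by `Q10`.
#'
#' @param temperature per-box temperature (degC).
#' @param kd reference rate (s^-1) at `T0`; must be >= 0.
#' @param Q10 temperature sensitivity; must be >= 1.
#' @param T0 reference temperature (degC), fixed default 30.
#' @return per-box rate field (s^-1).
#' @export
q10_rate <- function(temperature, kd, Q10, T0 = 30) {
  if (kd < 0) abort("kd must be >= 0")
  if (Q10 < 1) abort("Q10 must be >= 1")
  kd * Q10^((temperature - T0) / 10)
}

#' Phosphate-dependent C:P production stoichiometry
#'
#' `r = 1 / (cc * DIP + dd)` (mol C : mol P): carbon-rich organic matter
#' where phosphate is scarce, approaching the constant `1/dd` as DIP -> 0.
#'
#' @param DIP phosphate concentration field (mol m^-3).
#' @param cc slope (m^3 mol^-1); @param dd intercept (dimensionless).
#' @return per-box molar C:P ratio. Errors on a non-positive denominator.
#' @export
cp_ratio <- function(DIP, cc, dd) {
  den <- cc * DIP + dd
  if (any(den <= 0)) abort("cc * DIP + dd must be positive everywhere")
  1 / den
}

#' Empirical DIP uptake rate coefficient
#'
#' Production of organic phosphorus is gamma * DIP; gamma is diagnosed from
#' satellite NPP and observed surface DIP so that the modeled carbon
#' production matches NPP when modeled DIP equals the observed climatology:
#' `gamma = NPP / (r_CP(DIP_obs) * DIP_obs)` on euphotic boxes, zero
#' elsewhere.
#'
#' @param satellite_npp per-box NPP (mol C m^-3 s^-1, zero outside the
#'   euphotic zone).
#' @param surface_dip_obs per-box observed DIP (mol m^-3) on euphotic boxes.
#' @param cc,dd stoichiometry parameters (see [cp_ratio()]).
#' @param grid an [ocean_grid()].
#' @return per-box gamma (s^-1).
#' @export
uptake_coefficient <- function(satellite_npp, surface_dip_obs, cc, dd, grid) {
  eu <- grid$boxes$euphotic
  gamma <- numeric(grid$n_boxes)
  if (any(eu & satellite_npp > 0 & surface_dip_obs <= 0)) {
    abort("observed DIP is zero where NPP is positive; gamma undefined")
  }
  idx <- eu & satellite_npp > 0
  r <- cp_ratio(surface_dip_obs[idx], cc, dd)
  gamma[idx] <- satellite_npp[idx] / (r * surface_dip_obs[idx])
  gamma
}

# map water-column ids to 1..n_col and back
column_index <- function(grid) {
  cols <- sort(unique(grid$boxes$column))
  list(cols = cols, of_box = match(grid$boxes$column, cols), n = length(cols))
}

#' Export integration matrix
#'
#' Maps a per-box production-rate field (mol m^-3 s^-1, nonzero on euphotic
#' boxes) to the export flux at the euphotic base per water column (mol s^-1):
#' production is volume-integrated over each column's euphotic boxes.
#'
#' @param grid an [ocean_grid()].
#' @return sparse `n_columns x n_boxes` matrix.
#' @export
export_matrix <- function(grid) {
  ci <- column_index(grid)
  b <- grid$boxes
  eu <- which(b$euphotic)
  sparseMatrix(i = ci$of_box[eu], j = eu, x = b$volume[eu],
               dims = c(ci$n, grid$n_boxes))
}

#' Martin-curve particle remineralization operator
#'
#' Linear map from export flux at the euphotic base (mol s^-1 per water
#' column) to remineralization rates below (mol m^-3 s^-1 per box). In each
#' column the flux at depth `z` below the export depth `z0` follows the
#' Martin power law `f(z) = f(z0) (z/z0)^-b`; the remineralization in layer
#' k is the flux convergence across its interfaces divided by the box
#' volume, and the flux reaching the seafloor remineralizes in the bottom
#' wet box (no burial). The map conserves mass: the volume-weighted column
#' sum of remineralization equals the export.
#'
#' @param b per-box Martin exponent (constant within a column; the value at
#'   each column's shallowest box is used). All values must be positive.
#' @param grid an [ocean_grid()].
#' @return sparse `n_boxes x n_columns` matrix.
#' @export
particle_operator <- function(b, grid) {
  if (any(b <= 0)) abort("Martin exponent b must be positive")
  ci <- column_index(grid)
  bx <- grid$boxes
  z0 <- grid$euphotic_base
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (c_idx in seq_len(ci$n)) {
    in_col <- which(ci$of_box == c_idx)
    below <- in_col[!bx$euphotic[in_col]]
    if (length(below) == 0) {
      # column entirely euphotic: everything remineralizes in its bottom box
      bb <- in_col[which.max(bx$depth_bot[in_col])]
      ii <- c(ii, bb); jj <- c(jj, c_idx); xx <- c(xx, 1 / bx$volume[bb])
      next
    }
    below <- below[order(bx$depth_top[below])]
    bcol <- b[in_col[which.min(bx$depth_top[in_col])]]
    ftop <- (bx$depth_top[below] / z0)^(-bcol)
    fbot <- (bx$depth_bot[below] / z0)^(-bcol)
    frac <- ftop - fbot
    frac[length(frac)] <- frac[length(frac)] + fbot[length(fbot)] # seafloor
    ii <- c(ii, below); jj <- c(jj, rep(c_idx, length(below)))
    xx <- c(xx, frac / bx$volume[below])
  }
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(grid$n_boxes, ci$n))
}

#' Exponential-profile dissolution operator (PIC)
#'
#' Same contract as [particle_operator()] but with an exponential flux
#' profile `f(z) = f(z0) exp(-(z - z0)/d)` with e-folding depth `d`;
#' the seafloor remainder dissolves in the bottom wet box.
#'
#' @param scale e-folding depth `d` (m), positive.
#' @param grid an [ocean_grid()].
#' @return sparse `n_boxes x n_columns` matrix.
#' @export
dissolution_operator <- function(scale, grid) {
  if (scale <= 0) abort("dissolution scale must be positive")
  ci <- column_index(grid)
  bx <- grid$boxes
  z0 <- grid$euphotic_base
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (c_idx in seq_len(ci$n)) {
    in_col <- which(ci$of_box == c_idx)
    below <- in_col[!bx$euphotic[in_col]]
    if (length(below) == 0) {
      bb <- in_col[which.max(bx$depth_bot[in_col])]
      ii <- c(ii, bb); jj <- c(jj, c_idx); xx <- c(xx, 1 / bx$volume[bb])
      next
    }
    below <- below[order(bx$depth_top[below])]
    ftop <- exp(-(bx$depth_top[below] - z0) / scale)
    fbot <- exp(-(bx$depth_bot[below] - z0) / scale)
    frac <- ftop - fbot
    frac[length(frac)] <- frac[length(frac)] + fbot[length(fbot)]
    ii <- c(ii, below); jj <- c(jj, rep(c_idx, length(below)))
    xx <- c(xx, frac / bx$volume[below])
  }
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(grid$n_boxes, ci$n))
}

#' Flux-weighted global mean
#'
#' Volume- and weight-averaged scalar: `sum(f w v) / sum(w v)` over wet
#' boxes; the standard way spatially varying rate parameters are summarized
#' (vertical averages weighted by DOM remineralization).
#'
#' @param field per-box field; @param weight_field per-box non-negative
#'   weights (not all zero); @param grid an [ocean_grid()].
#' @return scalar.
#' @export
flux_weighted_mean <- function(field, weight_field, grid) {
  if (any(weight_field < 0)) abort("weights must be >= 0")
  wv <- weight_field * grid$boxes$volume
  tot <- sum(wv)
  if (tot == 0) abort("total weight is zero")
  sum(field * wv) / tot
}

# nominal sinking speed used only to report a diagnostic particulate
# standing stock (flux / speed); the flux scheme itself is instantaneous
PARTICLE_SINK_SPEED <- 100 / 86400 # m s^-1 (100 m/d)

#' Solve the steady-state phosphorus cycle
#'
#' Four reservoirs: DIP, POP, semilabile DOP and labile DOP (`DOP_l`,
#' 12-hour lifetime). Uptake `gamma * DIP` (euphotic boxes) is split by
#' `(1 - sigma_dop - sigma_dopl, sigma_dop, sigma_dopl)` into POP / DOP /
#' `DOP_l`. POP export is redistributed by the Martin-curve
#' [particle_operator()] with exponent `bP = bP0 + bPth * theta_bar`;
#' DOP decays at the Q10 rate `kP`; `DOP_l` decays at `kappa_l`; all decay
#' returns to DIP. The steady transport-reaction system is singular (total
#' P is conserved), so one redundant DIP equation is replaced by the
#' constraint that the volume-weighted global mean DIP equal
#' `dip_inventory`.
#'
#' @param params a [cycle_params()].
#' @param A sparse transport operator (s^-1).
#' @param forcing a [make_forcing()] table (needs `temperature`, `npp`,
#'   `dip_obs`).
#' @param grid an [ocean_grid()].
#' @param dip_inventory imposed volume-weighted global-mean DIP
#'   (mol m^-3), default 2e-3.
#' @return a tibble of class `equilibrium_state`, one row per box, with
#'   concentration columns (`DIP`, `POP`, `DOP`, `DOP_l`), production and
#'   remineralization rate columns per organic pool (`prod_*`, `remin_*`,
#'   mol m^-3 s^-1), and diagnosed `gamma`, `theta_bar`, `b_P`, `k_P`
#'   fields. Attributes carry `params`, `element` = "P" and the grid.
#' @export
solve_p_cycle <- function(params, A, forcing, grid, dip_inventory = 2e-3) {
  n <- grid$n_boxes
  v <- grid_volumes(grid)
  fb <- as_tibble(forcing)
  theta <- normalized_surface_temperature(fb$temperature, grid)
  bP <- martin_b(theta, params$bP0, params$bPth)
  kP <- q10_rate(fb$temperature, params$kdP, params$Q10P, params$T0)
  gamma <- uptake_coefficient(fb$npp, fb$dip_obs, params$cc, params$dd, grid)

  s_pop <- 1 - params$sigma_dop - params$sigma_dopl
  Gam <- Diagonal(x = gamma)
  Kp <- Diagonal(x = kP)
  Kl <- Diagonal(x = rep(params$kappa_l, n))
  Ppop <- particle_operator(bP, grid) %*% export_matrix(grid) # box -> box remin map

  Z <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                    dims = c(n, n))
  M <- rbind(
    cbind(A - Gam + s_pop * (Ppop %*% Gam), Kp, Kl),
    cbind(params$sigma_dop * Gam, A - Kp, Z),
    cbind(params$sigma_dopl * Gam, Z, A - Kl)
  )
  rhs <- numeric(3 * n)
  # replace one redundant DIP equation (largest-volume box) with the
  # global-mean-DIP constraint; exact because volume-weighted block row sums
  # of M vanish
  pin <- which.max(v)
  Mr <- as(M, "TsparseMatrix")
  keep <- !(Mr@i == pin - 1L)
  M <- sparseMatrix(i = Mr@i[keep] + 1L, j = Mr@j[keep] + 1L, x = Mr@x[keep],
                    dims = c(3L * n, 3L * n)) +
    sparseMatrix(i = rep(pin, n), j = seq_len(n), x = v / sum(v),
                 dims = c(3L * n, 3L * n))
  rhs[pin] <- dip_inventory
  x <- as.numeric(solve(M, rhs))

  DIP <- x[seq_len(n)]
  DOP <- x[n + seq_len(n)]
  DOP_l <- x[2L * n + seq_len(n)]
  tol <- 1e-8 * max(abs(DIP), 1e-12)
  if (min(DIP, DOP, DOP_l) < -tol) {
    abort("negative concentrations beyond tolerance in the P-cycle solve")
  }
  uptake <- gamma * DIP
  prod_POP <- s_pop * uptake
  remin_POP <- as.numeric(Ppop %*% prod_POP)
  state <- tibble(
    box = grid$boxes$box,
    DIP = DIP, DOP = DOP, DOP_l = DOP_l,
    POP = remin_POP_standing_stock(prod_POP, grid),
    uptake_P = uptake,
    prod_POP = prod_POP,
    prod_DOP = params$sigma_dop * uptake,
    prod_DOP_l = params$sigma_dopl * uptake,
    remin_POP = remin_POP,
    remin_DOP = kP * DOP,
    remin_DOP_l = params$kappa_l * DOP_l,
    gamma = gamma, theta_bar = theta, b_P = bP, k_P = kP
  )
  structure(state, class = c("equilibrium_state", class(state)),
            params = params, grid = grid, element = "P",
            dip_inventory = dip_inventory)
}

# diagnostic particulate standing stock: column-cumulative flux / (w_sink)
remin_POP_standing_stock <- function(prod_field, grid) {
  ci <- column_index(grid)
  bx <- grid$boxes
  area <- if ("area" %in% names(bx)) bx$area else bx$volume / bx$thickness
  stock <- numeric(grid$n_boxes)
  for (c_idx in seq_len(ci$n)) {
    in_col <- which(ci$of_box == c_idx)
    in_col <- in_col[order(bx$depth_top[in_col])]
    flux_bot <- cumsum(prod_field[in_col] * bx$volume[in_col]) # mol/s
    stock[in_col] <- flux_bot / area[in_col] / PARTICLE_SINK_SPEED
  }
  stock
}

#' Solve the steady-state carbon and oxygen cycles
#'
#' Seven tracers given a converged phosphorus state: DIC, ALK, PIC, POC and
#' three DOC pools of decreasing lability. Non-labile organic carbon
#' production is `r_CP(model DIP)` times the organic-P production, split
#' into POC / semilabile DOC / refractory DOC by
#' `(1 - sigma_docs - sigma_docr, sigma_docs, sigma_docr)`. Labile DOC
#' production is the residual `max(0, NPP - non-labile production)` so total
#' organic carbon production matches the prescribed NPP; it decays with a
#' 12-hour lifetime. POC is routed through the Martin operator with
#' exponent `bC`; semilabile DOC decays at the Q10 rate `kC`; refractory
#' DOC at `kappa_r`. PIC is produced at `pic_rain_ratio` times POC
#' production and dissolves over `pic_dissolution_scale`. DIC and ALK are
#' closed with fast surface restoring toward reference values (a stand-in
#' for gas exchange / carbonate chemistry that leaves the regenerated-tracer
#' accounting untouched); O2 is coupled stoichiometrically (`o2_to_p`) and
#' surface-restored to a linear-in-T saturation. With purely linear
#' stoichiometric coupling, O2 can go negative in poorly ventilated
#' interiors (read it as an oxygen deficit, the linear analogue of suboxia);
#' the non-negativity invariant applies to the P and C tracers.
#'
#' @param params a [cycle_params()].
#' @param A sparse transport operator (s^-1).
#' @param p_state an `equilibrium_state` from [solve_p_cycle()].
#' @param forcing a [make_forcing()] table.
#' @param grid an [ocean_grid()].
#' @param labile if `FALSE`, the labile residual adjustment is disabled and
#'   `DOC_l` is identically zero (used in symmetry tests).
#' @return tibble of class `equilibrium_state` with the P-state columns plus
#'   C/O2 concentrations (`DIC`, `ALK`, `PIC`, `POC`, `DOC`, `DOC_l`,
#'   `DOC_r`, `O2`), production/remineralization rates per organic C pool,
#'   and diagnosed `r_CP`, `b_C`, `k_C` fields. Attribute `element` = "CP".
#' @export
solve_c_cycle <- function(params, A, p_state, forcing, grid, labile = TRUE) {
  n <- grid$n_boxes
  fb <- as_tibble(forcing)
  eu <- grid$boxes$euphotic
  theta <- p_state$theta_bar
  bC <- martin_b(theta, params$bC0, params$bCth)
  kC <- q10_rate(fb$temperature, params$kdC, params$Q10C, params$T0)
  r_cp <- cp_ratio(p_state$DIP, params$cc, params$dd)

  prod_OC <- r_cp * p_state$uptake_P          # non-labile organic C production
  s_poc <- 1 - params$sigma_docs - params$sigma_docr
  prod_POC <- s_poc * prod_OC
  prod_DOCs <- params$sigma_docs * prod_OC
  prod_DOCr <- params$sigma_docr * prod_OC
  prod_DOCl <- numeric(n)
  if (labile) {
    resid <- fb$npp - prod_OC
    neg_tol <- -1e-10 * max(fb$npp, 0)
    if (all(resid[eu & fb$npp > 0] <= 0) && any(resid[eu] < neg_tol)) {
      warn("labile DOC production non-positive everywhere (NPP below modeled non-labile production); clamped at 0")
    }
    prod_DOCl <- pmax(0, resid) * as.numeric(eu)
  }

  Pmap <- particle_operator(bC, grid) %*% export_matrix(grid)
  remin_POC <- as.numeric(Pmap %*% prod_POC)

  solve_tracer <- function(decay, source) {
    as.numeric(solve(A - Diagonal(x = decay), -source))
  }
  DOCs <- solve_tracer(kC, prod_DOCs)
  DOCr <- solve_tracer(rep(params$kappa_r, n), prod_DOCr)
  DOCl <- solve_tracer(rep(params$kappa_l, n), prod_DOCl)
  remin_DOCs <- kC * DOCs
  remin_DOCr <- params$kappa_r * DOCr
  remin_DOCl <- params$kappa_l * DOCl

  prod_PIC <- params$pic_rain_ratio * prod_POC
  Dmap <- dissolution_operator(params$pic_dissolution_scale, grid)
  diss_PIC <- as.numeric((Dmap %*% export_matrix(grid)) %*% prod_PIC)

  restore <- params$restore_rate * as.numeric(eu)
  Rm <- Diagonal(x = restore)
  prod_C_tot <- prod_OC + prod_DOCl
  remin_C_tot <- remin_POC + remin_DOCs + remin_DOCr + remin_DOCl
  DIC <- as.numeric(solve(A - Rm,
                          prod_C_tot + prod_PIC - remin_C_tot - diss_PIC -
                            restore * params$dic_surface_ref))
  ALK <- as.numeric(solve(A - Rm,
                          2 * prod_PIC - 2 * diss_PIC -
                            restore * params$alk_surface_ref))
  o2_sat <- params$o2_sat_intercept + params$o2_sat_slope * fb$temperature
  remin_P_tot <- p_state$remin_POP + p_state$remin_DOP + p_state$remin_DOP_l
  O2 <- as.numeric(solve(A - Rm,
                         params$o2_to_p * (remin_P_tot - p_state$uptake_P) -
                           restore * o2_sat))

  state <- as_tibble(as.data.frame(p_state)) |>
    mutate(
      DIC = DIC, ALK = ALK, DOC = DOCs, DOC_l = DOCl, DOC_r = DOCr, O2 = O2,
      POC = remin_POP_standing_stock(prod_POC, grid),
      PIC = remin_POP_standing_stock(prod_PIC, grid),
      prod_POC = prod_POC, prod_DOC = prod_DOCs, prod_DOC_r = prod_DOCr,
      prod_DOC_l = prod_DOCl, prod_PIC = prod_PIC,
      remin_POC = remin_POC, remin_DOC = remin_DOCs,
      remin_DOC_r = remin_DOCr, remin_DOC_l = remin_DOCl,
      diss_PIC = diss_PIC,
      r_CP = r_cp, b_C = bC, k_C = kC
    )
  structure(state, class = c("equilibrium_state", "tbl_df", "tbl", "data.frame"),
            params = params, grid = attr(p_state, "grid"), element = "CP",
            dip_inventory = attr(p_state, "dip_inventory"))
}

#' Solve both element cycles
#'
#' Convenience wrapper: [solve_p_cycle()] then [solve_c_cycle()].
#'
#' @inheritParams solve_p_cycle
#' @inheritParams solve_c_cycle
#' @return combined `equilibrium_state` tibble.
#' @export
solve_cycles <- function(params, A, forcing, grid, dip_inventory = 2e-3,
                         labile = TRUE) {
  p <- solve_p_cycle(params, A, forcing, grid, dip_inventory)
  solve_c_cycle(params, A, p, forcing, grid, labile = labile)
}

#' Global production/remineralization balance per organic pool
#'
#' At steady state with no burial, the volume-integrated production of each
#' organic pool equals its volume-integrated remineralization. Reports both
#' integrals (mol s^-1) and the relative residual.
#'
#' @param state an `equilibrium_state`.
#' @param grid an [ocean_grid()] (defaults to the grid attached to `state`).
#' @return tibble with columns `pool`, `production`, `remineralization`,
#'   `residual` (relative).
#' @export
steady_state_balance <- function(state, grid = attr(state, "grid")) {
  v <- grid_volumes(grid)
  pools <- sub("^prod_", "", grep("^prod_", names(state), value = TRUE))
  pools <- setdiff(pools, "PIC")
  purrr::map_dfr(pools, function(p) {
    prod <- sum(state[[paste0("prod_", p)]] * v)
    rem <- sum(state[[paste0("remin_", p)]] * v)
    tibble(pool = p, production = prod, remineralization = rem,
           residual = abs(prod - rem) / max(abs(prod), 1e-300))
  })
}
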