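#' Generate synthetic forcing fields
#'
#' Stands in for the climatological inputs of the full-scale model: a
#' surface-warm temperature field (exponential thermocline with a meridional
#' envelope), a satellite-style NPP field whose global integral is
#' prescribed, and a surface DIP climatology. The NPP spatial shape is
#' surface-DIP-weighted with a tropical latitudinal envelope (productive
#' low-latitude band), with seeded lognormal heterogeneity; only the global
#' integral is a hard constraint, mirroring how the full-scale model is
#' tuned to match satellite NPP products.
#'
#' @param grid an [ocean_grid()].
#' @param surface_t,deep_t surface and abyssal temperature (degC),
#'   defaults 28 and 2.
#' @param thermocline_scale e-folding depth of the thermocline (m),
#'   default 700.
#' @param meridional_amplitude equator-to-pole surface cooling (degC),
#'   default 14; 0 gives horizontally uniform layers.
#' @param npp_total global NPP (Pg C y^-1), default 55 (the satellite-era
#'   climatological magnitude). Must be positive.
#' @param dip_surface_mean volume-weighted mean of the surface DIP
#'   climatology over euphotic boxes (mol m^-3), default 5e-4.
#' @param npp_jitter_sd lognormal sd of the NPP spatial heterogeneity,
#'   default 0.3.
#' @param seed integer; fixed seed gives byte-identical fields.
#' @return tibble of class `forcing_fields`, one row per box, columns
#'   `box`, `temperature` (degC), `npp` (mol C m^-3 s^-1, zero outside the
#'   euphotic mask), `dip_obs` (mol m^-3 on euphotic boxes, NA below).
#'   Attributes: `npp_total_Pg_y`, `seed`.
#' @export
make_forcing <- function(grid, surface_t = 28, deep_t = 2,
                         thermocline_scale = 700, meridional_amplitude = 14,
                         npp_total = 55, dip_surface_mean = 5e-4,
                         npp_jitter_sd = 0.3, seed = 1) {
  if (npp_total <= 0) abort("npp_total must be positive")
  if (dip_surface_mean <= 0) abort("dip_surface_mean must be positive")
  b <- grid$boxes
  latmax <- max(abs(b$lat), 1e-12)
  ynorm <- b$lat / latmax
  dT <- pmax(surface_t - deep_t - meridional_amplitude * ynorm^2, 0)
  temperature <- deep_t + dT * exp(-b$depth_mid / thermocline_scale)

  eu <- b$euphotic
  # surface DIP climatology: nutrient-rich high latitudes
  dip_shape <- 0.4 + 1.2 * ynorm^2
  dip_obs <- rep(NA_real_, grid$n_boxes)
  mean_shape <- sum((dip_shape * b$volume)[eu]) / sum(b$volume[eu])
  dip_obs[eu] <- dip_surface_mean * dip_shape[eu] / mean_shape

  # NPP: DIP-weighted with a tropical envelope + seeded heterogeneity
  envelope <- exp(-(ynorm / 0.75)^2)
  shape <- numeric(grid$n_boxes)
  shape[eu] <- dip_obs[eu] * envelope[eu]
  if (npp_jitter_sd > 0) {
    jit <- with_local_seed(seed, exp(rnorm(sum(eu), 0, npp_jitter_sd)))
    shape[eu] <- shape[eu] * jit
  }
  target <- Pg_y_to_mol_s(npp_total, "C")
  npp <- shape * target / sum(shape * b$volume)

  out <- tibble(box = b$box, temperature = temperature, npp = npp,
                dip_obs = dip_obs)
  structure(out, class = c("forcing_fields", class(out)),
            npp_total_Pg_y = npp_total, seed = seed)
}

OBSERVED_TRACERS <- c("DIP", "DOP", "DIC", "DOC", "ALK", "O2")

#' Generate noisy synthetic observations from an equilibrium state
#'
#' Builds an observation set for the six observed tracers (DIP, DOP, DIC,
#' bulk DOC, ALK, O2) from a model equilibrium, for parameter-recovery
#' experiments with known ground truth. Bulk DOC is the sum of the three
#' modeled DOC pools. Noise is multiplicative lognormal (concentrations stay
#' positive); with zero noise and no missingness the observations equal the
#' model fields exactly. A `missing_fraction` of boxes per tracer is marked
#' unobserved (weight zero downstream).
#'
#' @param equilibrium an `equilibrium_state` containing all six tracers
#'   (i.e. from [solve_c_cycle()]/[solve_cycles()]).
#' @param noise_sd relative noise sd: a single number or a vector named by
#'   tracer. Default 0.
#' @param missing_fraction fraction of boxes per tracer left unobserved
#'   (default 0).
#' @param seed integer seed; reproducible per seed.
#' @return long tibble of class `observation_set`: columns `box`, `tracer`,
#'   `value`, `observed` (logical). Attributes: `seed`, `provenance`.
#' @export
make_observations <- function(equilibrium, noise_sd = 0, missing_fraction = 0,
                              seed = 1) {
  need <- c("DIP", "DOP", "DIC", "DOC", "DOC_l", "DOC_r", "ALK", "O2")
  missing <- setdiff(need, names(equilibrium))
  if (length(missing) > 0) {
    abort(paste0("equilibrium is missing tracer(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1)")
  }
  fields <- list(
    DIP = equilibrium$DIP,
    DOP = equilibrium$DOP,
    DIC = equilibrium$DIC,
    DOC = equilibrium$DOC + equilibrium$DOC_l + equilibrium$DOC_r,
    ALK = equilibrium$ALK,
    O2 = equilibrium$O2
  )
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    noise_sd <- setNames(rep(noise_sd, length(OBSERVED_TRACERS)),
                         OBSERVED_TRACERS)
  }
  n <- length(fields$DIP)
  obs <- with_local_seed(seed, {
    purrr::map_dfr(OBSERVED_TRACERS, function(tr) {
      sdl <- noise_sd[[tr]] %||% 0
      val <- fields[[tr]]
      if (sdl > 0) val <- val * exp(rnorm(n, 0, sdl))
      observed <- rep(TRUE, n)
      if (missing_fraction > 0) {
        drop <- sample.int(n, round(missing_fraction * n))
        observed[drop] <- FALSE
      }
      tibble(box = equilibrium$box, tracer = tr, value = val,
             observed = observed)
    })
  })
  structure(obs, class = c("observation_set", class(obs)),
            seed = seed, provenance = paste0("synthetic(seed=", seed, ")"))
}
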