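# Fixtures are built in code; expensive ones are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# two stacked boxes (surface euphotic + interior), equal volume by default
two_box_grid <- function(v1 = 1e15, v2 = 1e15) {
  ocean_grid(
    tibble::tibble(
      box = 1:2, column = 1L, layer = 1:2,
      depth_top = c(0, 100), depth_bot = c(100, 200),
      volume = c(v1, v2)
    ),
    layer_interfaces = c(0, 100, 200),
    euphotic_layers = 1
  )
}

# one water column with explicit interfaces; euphotic = top layer
column_grid <- function(interfaces, area = 1e10, euphotic_layers = 1) {
  n <- length(interfaces) - 1
  ocean_grid(
    tibble::tibble(
      box = seq_len(n), column = 1L, layer = seq_len(n),
      depth_top = interfaces[-length(interfaces)],
      depth_bot = interfaces[-1],
      volume = area * diff(interfaces)
    ),
    layer_interfaces = interfaces,
    euphotic_layers = euphotic_layers
  )
}

# random mass-conserving diffusive operator: chain connectivity plus random
# extra exchanges; conserves and preserves constants by construction
random_conserving_transport <- function(n_boxes = 50, seed = 7) {
  nlay <- 5
  nlat <- ceiling(n_boxes / nlay)
  grid <- synthetic_grid(n_lat = nlat, n_lon = 1, n_layers = nlay)
  pairs <- withr::with_seed(seed, {
    extra <- matrix(sample.int(grid$n_boxes, 40, replace = TRUE), ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    chain <- cbind(seq_len(grid$n_boxes - 1), 2:grid$n_boxes)
    g <- rbind(chain, extra)
    tibble::tibble(from = g[, 1], to = g[, 2],
                   conductance = exp(runif(nrow(g), 0, 3)) * 1e7)
  })
  list(grid = grid, A = transport_from_exchanges(grid, pairs))
}

# standard desk-scale ocean (96 boxes) with forcing and full equilibrium
desk_ocean <- function() {
  memo("desk_ocean", {
    tr <- build_synthetic_transport(synthetic_grid(8, 2, 6), seed = 11)
    forcing <- make_forcing(tr$grid, seed = 12)
    state <- solve_cycles(cycle_params(), tr$A, forcing, tr$grid)
    c(tr, list(forcing = forcing, state = state))
  })
}

# 200-box ocean used by the symmetry and recovery checks
ocean200 <- function() {
  memo("ocean200", {
    tr <- build_synthetic_transport(synthetic_grid(10, 2, 10), seed = 21)
    forcing <- make_forcing(tr$grid, seed = 22)
    c(tr, list(forcing = forcing))
  })
}

# sink with no removal (for conservation checks)
null_sink <- function(grid) {
  structure(list(mask = rep(FALSE, grid$n_boxes), rate_per_year = 0,
                 rate_per_sec = 0), class = "restoring_sink")
}

# parameter set that makes the carbon cycle an exact r-scaled copy of the
# phosphorus cycle (constant production C:P = 1/dd, matching pools/splits)
mirror_params <- function(r = 117) {
  cycle_params(
    cc = 0, dd = 1 / r,
    bC0 = 1.0, bCth = 0.4, bP0 = 1.0, bPth = 0.4,
    kdC = 5e-9, kdP = 5e-9, Q10C = 2, Q10P = 2,
    sigma_dop = 0.3, sigma_dopl = 0,
    sigma_docs = 0.3, sigma_docr = 0,
    pic_rain_ratio = 0
  )
}
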