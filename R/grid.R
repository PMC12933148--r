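#' Construct an ocean grid from a wet-box table
#'
#' The grid is a generic wet-box list with an index map, so that 2-box toys,
#' single columns, and full 3-D latitude-longitude-depth configurations share
#' one code path. Boxes are identified by an integer `box` index (1..n); each
#' box belongs to a water `column` and a vertical `layer` (1 = surface).
#'
#' @param boxes a data frame with one row per wet box and columns
#'   `box` (integer index 1..n), `column` (integer water-column id),
#'   `layer` (integer, 1 = surface), `lat` (degrees), `lon` (degrees),
#'   `depth_top`, `depth_bot` (m, positive down), `volume` (m^3).
#' @param layer_interfaces numeric vector of layer interface depths (m,
#'   strictly increasing, starting at 0).
#' @param euphotic_layers integer, number of surface layers forming the
#'   euphotic zone (default 2). Production and surface restoring act there.
#' @return an object of class `ocean_grid`: a list with elements `boxes`
#'   (tibble, with derived `depth_mid`, `thickness`, `euphotic` columns),
#'   `layer_interfaces`, `n_layers`, `n_boxes`, `euphotic_layers`,
#'   `euphotic_base` (depth of the euphotic zone base, m).
#' @export
ocean_grid <- function(boxes, layer_interfaces, euphotic_layers = 2) {
  boxes <- as_tibble(boxes)
  required <- c("box", "column", "layer", "depth_top", "depth_bot", "volume")
  missing <- setdiff(required, names(boxes))
  if (length(missing) > 0) {
    abort(paste0("grid box table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(diff(layer_interfaces) > 0)) {
    abort("layer_interfaces must be strictly increasing")
  }
  if (any(boxes$volume <= 0)) abort("all wet-box volumes must be strictly positive")
  if (!setequal(boxes$box, seq_len(nrow(boxes)))) {
    abort("boxes$box must be a permutation of 1..n")
  }
  boxes <- arrange(boxes, .data$box)
  n_layers <- length(layer_interfaces) - 1L
  if (max(boxes$layer) > n_layers) abort("box layer index exceeds n_layers")
  thick <- diff(layer_interfaces)
  if (max(abs((boxes$depth_bot - boxes$depth_top) - thick[boxes$layer])) >
      1e-6 * max(thick)) {
    abort("box thickness must equal the layer interface difference")
  }
  euphotic_layers <- min(euphotic_layers, n_layers)
  boxes$thickness <- boxes$depth_bot - boxes$depth_top
  boxes$depth_mid <- (boxes$depth_top + boxes$depth_bot) / 2
  boxes$euphotic <- boxes$layer <= euphotic_layers
  if (!"lat" %in% names(boxes)) boxes$lat <- 0
  if (!"lon" %in% names(boxes)) boxes$lon <- 0
  structure(
    list(
      boxes = boxes,
      layer_interfaces = layer_interfaces,
      n_layers = n_layers,
      n_boxes = nrow(boxes),
      euphotic_layers = euphotic_layers,
      euphotic_base = layer_interfaces[euphotic_layers + 1L]
    ),
    class = "ocean_grid"
  )
}

#' @export
#' @method print ocean_grid
print.ocean_grid <- function(x, ...) {
  cat("<ocean_grid> ", x$n_boxes, " wet boxes, ", x$n_layers, " layers, ",
      length(unique(x$boxes$column)), " columns; euphotic base ",
      signif(x$euphotic_base, 4), " m\n", sep = "")
  invisible(x)
}

#' Geometric layer thicknesses for a synthetic ocean
#'
#' Layers thicken geometrically with depth, mimicking typical z-coordinate
#' ocean grids (e.g. 36 m at the surface growing to several km at the bottom
#' in 24-layer global configurations).
#'
#' @param n_layers number of layers.
#' @param depth_total total depth (m).
#' @param top_thickness thickness of the surface layer (m).
#' @return interface depth vector of length `n_layers + 1` starting at 0.
#' @export
geometric_interfaces <- function(n_layers, depth_total, top_thickness) {
  if (n_layers < 2) abort("need at least 2 layers")
  if (top_thickness * n_layers >= depth_total) {
    # uniform or shrinking: fall back to uniform spacing
    return(seq(0, depth_total, length.out = n_layers + 1))
  }
  f <- function(r) top_thickness * (r^n_layers - 1) / (r - 1) - depth_total
  r <- uniroot(f, c(1 + 1e-9, 10))$root
  c(0, cumsum(top_thickness * r^(0:(n_layers - 1))))
}

#' Regular latitude-depth-longitude synthetic grid
#'
#' A closed rectangular single basin. Latitude cells are equal-width over
#' `lat_range`; the basin has a fixed zonal width split into `n_lon`
#' longitude cells; layers thicken geometrically with depth. All boxes are
#' wet (flat bottom).
#'
#' @param n_lat,n_lon,n_layers grid dimensions (>= 2 latitude cells and
#'   >= 2 layers).
#' @param depth_total total depth (m), default 4000.
#' @param top_thickness surface layer thickness (m), default 100.
#' @param lat_range latitude span, degrees, default c(-65, 65).
#' @param basin_width zonal basin width (m), default 6e6.
#' @param euphotic_layers number of euphotic surface layers, default 2.
#' @return an [ocean_grid()].
#' @export
synthetic_grid <- function(n_lat = 12, n_lon = 2, n_layers = 8,
                           depth_total = 4000, top_thickness = 100,
                           lat_range = c(-65, 65), basin_width = 6e6,
                           euphotic_layers = 2) {
  if (n_lat < 2 || n_layers < 2) abort("need at least 2 layers and 2 columns")
  interfaces <- geometric_interfaces(n_layers, depth_total, top_thickness)
  earth_radius <- 6.371e6
  lat_edges <- seq(lat_range[1], lat_range[2], length.out = n_lat + 1)
  lat_mid <- (utils::head(lat_edges, -1) + utils::tail(lat_edges, -1)) / 2
  dy <- diff(lat_edges) * pi / 180 * earth_radius
  dx <- basin_width / n_lon
  thick <- diff(interfaces)

  idx <- expand.grid(ilayer = seq_len(n_layers), ilon = seq_len(n_lon),
                     ilat = seq_len(n_lat))
  boxes <- tibble(
    box = seq_len(nrow(idx)),
    ilat = idx$ilat, ilon = idx$ilon, layer = idx$ilayer,
    column = (idx$ilat - 1L) * n_lon + idx$ilon,
    lat = lat_mid[idx$ilat],
    lon = (idx$ilon - 0.5) * 360 / n_lon,
    depth_top = interfaces[idx$ilayer],
    depth_bot = interfaces[idx$ilayer + 1L],
    area = dy[idx$ilat] * dx,
    volume = dy[idx$ilat] * dx * thick[idx$ilayer]
  )
  g <- ocean_grid(boxes, interfaces, euphotic_layers = euphotic_layers)
  g$n_lat <- n_lat
  g$n_lon <- n_lon
  g$lat_edges <- lat_edges
  g$dx <- dx
  g$dy <- dy
  g
}

#' Box volumes of a grid
#' @param grid an [ocean_grid()].
#' @return numeric vector of box volumes (m^3), in box order.
#' @export
grid_volumes <- function(grid) grid$boxes$volume

#' Volume-weighted global integral of a per-box field
#' @param field numeric per-box field (per-m^3 units).
#' @param grid an [ocean_grid()].
#' @return scalar integral (field units times m^3).
#' @export
grid_integral <- function(field, grid) sum(field * grid$boxes$volume)
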