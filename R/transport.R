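#' Tracer transport operators
#'
#' A transport operator is a sparse square matrix `A` (units s^-1) over the
#' wet boxes, with the convention `dc/dt = A c + sources`. Two invariants
#' define a physically admissible advective-diffusive operator:
#' uniform-field preservation (`A 1 = 0`: transporting a constant does
#' nothing) and mass conservation (`v' A = 0` with `v` the box volumes:
#' volume-weighted column sums vanish). A monotone discretization also has
#' non-negative off-diagonal entries.
#'
#' @name transport
NULL

# run expr with a private RNG stream, leaving the session RNG untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# assemble A = diag(1/V) M from symmetric exchanges (m^3 s^-1) and directed
# advective flows (m^3 s^-1); both conserve mass exactly, and constants are
# preserved when the flow field is non-divergent.
assemble_operator <- function(grid, exchanges, flows = NULL) {
  v <- grid_volumes(grid)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  if (!is.null(exchanges) && nrow(exchanges) > 0) {
    a <- exchanges$from; b <- exchanges$to; g <- exchanges$conductance
    add(a, b, g); add(b, a, g); add(a, a, -g); add(b, b, -g)
  }
  if (!is.null(flows) && nrow(flows) > 0) {
    q <- flows$flow
    up <- ifelse(q >= 0, flows$from, flows$to)   # upwind donor box
    dn <- ifelse(q >= 0, flows$to, flows$from)
    aq <- abs(q)
    keep <- aq > 0
    add(dn[keep], up[keep], aq[keep])
    add(up[keep], up[keep], -aq[keep])
  }
  M <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(grid$n_boxes, grid$n_boxes))
  Diagonal(x = 1 / v) %*% M
}

#' Build a mass-conserving synthetic circulation
#'
#' Discretizes a single-basin meridional overturning streamfunction (zonally
#' uniform, zero on all boundaries) with upwind advection, plus central
#' diffusion in all three directions. Both transport invariants hold by
#' construction: advective face flows derive from discrete streamfunction
#' differences (non-divergent), and diffusive exchanges are symmetric.
#' A seeded lognormal jitter on the diffusive conductances breaks the
#' symmetry of the field without touching either invariant.
#'
#' @param grid an [ocean_grid()] produced by [synthetic_grid()] (needs the
#'   `ilat`/`ilon` index columns).
#' @param overturning_sv overturning streamfunction amplitude, Sverdrup
#'   (1 Sv = 1e6 m^3 s^-1). Default 20.
#' @param kh,kv horizontal and vertical diffusivity, m^2 s^-1 (defaults
#'   1e3 and 1e-4). Must be non-negative.
#' @param seed integer seed for the conductance jitter; fixed seed gives a
#'   byte-identical operator.
#' @param jitter_sd standard deviation of the lognormal conductance jitter
#'   (0 disables it).
#' @return a list with elements `grid` and `A` (sparse `dgCMatrix`, s^-1).
#'   Construction fails if either invariant is violated beyond round-off.
#' @export
build_synthetic_transport <- function(grid = synthetic_grid(),
                                      overturning_sv = 20,
                                      kh = 1e3, kv = 1e-4,
                                      seed = 1, jitter_sd = 0.2) {
  if (kh < 0 || kv < 0) abort("diffusivities must be >= 0")
  if (is.null(grid$n_lat)) abort("grid must carry lat/lon/layer indexing (use synthetic_grid())")
  b <- grid$boxes
  nlat <- grid$n_lat; nlon <- grid$n_lon; nlay <- grid$n_layers
  thick <- diff(grid$layer_interfaces)
  zmid <- (utils::head(grid$layer_interfaces, -1) + utils::tail(grid$layer_interfaces, -1)) / 2
  idx <- array(0L, dim = c(nlat, nlon, nlay))
  idx[cbind(b$ilat, b$ilon, b$layer)] <- b$box

  # streamfunction on cell corners of the lat-depth plane; zero on boundaries
  psi0 <- overturning_sv * 1e6
  psi <- outer(sin(pi * (0:nlat) / nlat), sin(pi * (0:nlay) / nlay)) * psi0

  flows <- list()
  # meridional flow through lat-face i (between ilat i and i+1), layer k
  for (i in seq_len(nlat - 1)) for (k in seq_len(nlay)) {
    q <- (psi[i + 1, k] - psi[i + 1, k + 1]) / nlon
    for (l in seq_len(nlon)) {
      flows[[length(flows) + 1]] <-
        c(from = idx[i, l, k], to = idx[i + 1, l, k], flow = q)
    }
  }
  # vertical flow through interface k (between layer k and k+1), lat band i;
  # positive = upward = from the deeper box into the shallower box
  for (i in seq_len(nlat)) for (k in seq_len(nlay - 1)) {
    q <- (psi[i, k + 1] - psi[i + 1, k + 1]) / nlon
    for (l in seq_len(nlon)) {
      flows[[length(flows) + 1]] <-
        c(from = idx[i, l, k + 1], to = idx[i, l, k], flow = q)
    }
  }
  flows <- as_tibble(do.call(rbind, flows))

  exch <- list()
  dy <- grid$dy; dx <- grid$dx
  # meridional diffusion
  for (i in seq_len(nlat - 1)) for (l in seq_len(nlon)) for (k in seq_len(nlay)) {
    g <- kh * dx * thick[k] / ((dy[i] + dy[i + 1]) / 2)
    exch[[length(exch) + 1]] <- c(from = idx[i, l, k], to = idx[i + 1, l, k],
                                  conductance = g)
  }
  # zonal diffusion (closed basin)
  if (nlon > 1) {
    for (i in seq_len(nlat)) for (l in seq_len(nlon - 1)) for (k in seq_len(nlay)) {
      g <- kh * dy[i] * thick[k] / dx
      exch[[length(exch) + 1]] <- c(from = idx[i, l, k], to = idx[i, l + 1, k],
                                    conductance = g)
    }
  }
  # vertical diffusion
  for (i in seq_len(nlat)) for (l in seq_len(nlon)) for (k in seq_len(nlay - 1)) {
    area <- dy[i] * dx
    g <- kv * area / (zmid[k + 1] - zmid[k])
    exch[[length(exch) + 1]] <- c(from = idx[i, l, k], to = idx[i, l, k + 1],
                                  conductance = g)
  }
  exch <- as_tibble(do.call(rbind, exch))
  if (jitter_sd > 0) {
    exch$conductance <- exch$conductance *
      with_local_seed(seed, exp(rnorm(nrow(exch), 0, jitter_sd)))
  }

  A <- assemble_operator(grid, exch, flows)
  rep <- validate_operator(A, grid)
  if (rep$conservation_residual > 1e-10) {
    abort("synthetic transport violates mass conservation (v'A = 0)")
  }
  if (rep$uniform_residual > 1e-10) {
    abort("synthetic transport violates uniform-field preservation (A1 = 0)")
  }
  list(grid = grid, A = as(A, "CsparseMatrix"))
}

#' Build an operator from explicit exchanges and flows
#'
#' Low-level constructor for hand-built fixtures (a 2-box exchange, a column,
#' a random conserving network). Exchanges are symmetric volumetric
#' conductances; flows are directed volumetric transports discretized upwind.
#'
#' @param grid an [ocean_grid()].
#' @param exchanges data frame with columns `from`, `to`, `conductance`
#'   (m^3 s^-1), or NULL.
#' @param flows data frame with columns `from`, `to`, `flow` (m^3 s^-1,
#'   positive = from -> to), or NULL. Constants are preserved only when the
#'   flow field is non-divergent.
#' @return sparse operator `A` (s^-1).
#' @export
transport_from_exchanges <- function(grid, exchanges = NULL, flows = NULL) {
  as(assemble_operator(grid, exchanges, flows), "CsparseMatrix")
}

#' Validate transport operator invariants
#'
#' @param A sparse operator (s^-1).
#' @param grid matching [ocean_grid()].
#' @param tol tolerance on relative residuals used for the `ok` flag.
#' @return a one-row tibble: `conservation_residual`
#'   (max |v'A| scaled by ||v|| * max|A|), `uniform_residual`
#'   (max |A 1| / max|A|), `negative_offdiag` (count of off-diagonal entries
#'   below `-tol * max|A|`), and `ok`.
#' @export
validate_operator <- function(A, grid, tol = 1e-10) {
  v <- grid_volumes(grid)
  if (nrow(A) != grid$n_boxes || ncol(A) != grid$n_boxes) {
    abort("operator dimensions do not match grid")
  }
  amax <- max(abs(A))
  if (amax == 0) amax <- 1
  cons <- max(abs(crossprod(A, v))) / (sqrt(sum(v^2)) * amax)
  unif <- max(abs(A %*% rep(1, ncol(A)))) / amax
  offd <- A - Diagonal(x = diag(A))
  nneg <- sum(offd@x < -tol * amax)
  tibble(
    conservation_residual = as.numeric(cons),
    uniform_residual = as.numeric(unif),
    negative_offdiag = nneg,
    ok = cons <= tol && unif <= tol && nneg == 0
  )
}

#' Write / read a transport archive
#'
#' Plain-text archive: a directory holding `meta.json` (layer interfaces,
#' euphotic layer count, operator units), `boxes.csv` (the wet-box table)
#' and `operator.csv` (coordinate-sparse triplets `i,j,x`). The operator may
#' be stored in `s-1` or `yr-1`; units are recorded in the metadata and
#' auto-detected from the diagonal magnitude when absent (a message reports
#' the decision). Invariants are validated on load.
#'
#' @param transport a list with `grid` and `A` (as from
#'   [build_synthetic_transport()]).
#' @param path directory to create/overwrite.
#' @param units units to record, `"s-1"` (default) or `"yr-1"` (the matrix is
#'   converted on write).
#' @return `path`, invisibly.
#' @export
write_transport_archive <- function(transport, path, units = c("s-1", "yr-1")) {
  units <- match.arg(units)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- transport$grid
  A <- transport$A
  if (units == "yr-1") A <- A * SEC_PER_YEAR
  jsonlite::write_json(
    list(layer_interfaces = g$layer_interfaces,
         euphotic_layers = g$euphotic_layers,
         n_boxes = g$n_boxes, units = units),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(g$boxes[, c("box", "column", "layer", "lat", "lon",
                               "depth_top", "depth_bot", "volume")],
                   file.path(path, "boxes.csv"), row.names = FALSE)
  T3 <- as(as(A, "CsparseMatrix"), "TsparseMatrix")
  utils::write.csv(data.frame(i = T3@i + 1L, j = T3@j + 1L,
                              x = sprintf("%.17g", T3@x)),
                   file.path(path, "operator.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_transport_archive
#' @param dialect archive dialect; only the plain-text `"csv"` dialect is
#'   supported. `"netcdf"` and `"hdf5"` are recognised names that error with
#'   a pointer to the csv layout.
#' @param tol conservation tolerance applied on load.
#' @export
read_transport_archive <- function(path, dialect = c("csv", "netcdf", "hdf5"),
                                   tol = 1e-8) {
  dialect <- match.arg(dialect)
  if (dialect != "csv") {
    abort(paste0("dialect '", dialect, "' is not available in this build; ",
                 "convert the archive to the csv triplet layout ",
                 "(meta.json + boxes.csv + operator.csv)"))
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) abort("archive is missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  boxes <- utils::read.csv(file.path(path, "boxes.csv"))
  if (!"volume" %in% names(boxes)) {
    abort("archive boxes.csv is missing required field: volume")
  }
  grid <- ocean_grid(boxes, meta$layer_interfaces,
                     euphotic_layers = meta$euphotic_layers %||% 2)
  trip <- utils::read.csv(file.path(path, "operator.csv"))
  A <- sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                    dims = c(grid$n_boxes, grid$n_boxes))
  units <- meta$units
  if (is.null(units)) {
    # s^-1 operators have tiny diagonals (|diag| ~ 1e-7); yr^-1 are O(1e-2+)
    units <- if (max(abs(diag(A))) > 1e-4) "yr-1" else "s-1"
    message("operator units not recorded; auto-detected '", units, "'")
  } else {
    message("operator units: '", units, "'")
  }
  if (units == "yr-1") A <- A / SEC_PER_YEAR
  rep <- validate_operator(A, grid, tol = tol)
  if (rep$conservation_residual > tol) {
    abort("archived operator fails mass conservation (v'A = 0) beyond tolerance")
  }
  list(grid = grid, A = as(A, "CsparseMatrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
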