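test_that("remin source fields partition the total remineralization", {
  d <- desk_ocean()
  src <- remin_source_fields(d$state, "C")
  expect_named(src, c("POC", "DOC", "DOC_l", "DOC_r"))
  expect_true(all(unlist(src) >= 0))
  total <- d$state$remin_POC + d$state$remin_DOC + d$state$remin_DOC_l +
    d$state$remin_DOC_r
  expect_equal(Reduce(`+`, src), total, tolerance = 1e-14)
  # each pool's pulse integrates to its global remineralization
  v <- grid_volumes(d$grid)
  expect_equal(sum(src$DOC * v), sum(d$state$remin_DOC * v))
  # no biology: all sources vanish
  f0 <- d$forcing; f0$npp <- rep(0, nrow(f0))
  st0 <- solve_cycles(cycle_params(), d$A, f0, d$grid)
  expect_true(all(unlist(remin_source_fields(st0, "P")) == 0))
  expect_error(remin_source_fields(d$forcing, "C"), "missing")
})

test_that("labile-pool regeneration is concentrated in the euphotic zone", {
  d <- desk_ocean()
  src <- remin_source_fields(d$state, "C")
  v <- grid_volumes(d$grid)
  eu <- d$grid$boxes$euphotic
  frac_eu <- sum((src$DOC_l * v)[eu]) / sum(src$DOC_l * v)
  expect_gt(frac_eu, 0.95) # 12-h lifetime barely escapes the surface
})

test_that("survival integration has the right degenerate limits", {
  d <- desk_ocean()
  sink <- restoring_sink(d$grid)
  tg <- c(0, 0.1, 1, 10)
  m0 <- survival_integrate(d$A, sink, numeric(d$grid$n_boxes), tg, d$grid)
  expect_true(all(m0$inventory == 0))
  expect_error(restoring_sink(d$grid, rate = 0), "positive")
  expect_error(survival_integrate(d$A, sink, rep(1, d$grid$n_boxes),
                                  c(1, 2), d$grid), "start at 0")
})

test_that("interior box draining through an absorbing surface decays at the exchange rate", {
  V <- 1e15
  g <- two_box_grid(v1 = V, v2 = V)
  lam <- 0.05 / SEC_PER_YEAR
  A <- transport_from_exchanges(
    g, tibble::tibble(from = 1, to = 2, conductance = lam * V))
  sink <- restoring_sink(g, rate = 5000) # restoring much faster than exchange
  r0 <- c(0, 1)
  tg <- c(0, 1, 5, 10, 20, 50)
  m <- survival_integrate(A, sink, r0, tg, g)
  lam_y <- lam * SEC_PER_YEAR
  expect_equal(m$inventory, V * exp(-lam_y * tg), tolerance = 1e-3)
})

test_that("trapezoid integrator agrees with the dense matrix-exponential oracle", {
  tr <- random_conserving_transport(50, seed = 7)
  f <- make_forcing(tr$grid, seed = 7)
  st <- solve_cycles(cycle_params(), tr$A, f, tr$grid)
  sink <- restoring_sink(tr$grid)
  r0 <- remin_source_fields(st, "C")$POC
  tg <- default_t_grid(t_max = 1000, n = 12)
  mi <- survival_integrate(tr$A, sink, r0, tg, tr$grid)
  mo <- firstpassage_oracle(tr$A, sink, r0, tg, tr$grid)
  expect_lt(max(abs(mi$inventory - mo$inventory) / mo$inventory), 1e-6)
})

test_that("the dense oracle is linear, conservative without a sink, and size-capped", {
  tr <- random_conserving_transport(40, seed = 3)
  g <- tr$grid
  sink <- restoring_sink(g)
  r0 <- withr::with_seed(4, runif(g$n_boxes))
  tg <- c(0, 1, 10)
  m1 <- firstpassage_oracle(tr$A, sink, r0, tg, g)
  m2 <- firstpassage_oracle(tr$A, sink, 2 * r0, tg, g)
  expect_equal(m2$inventory, 2 * m1$inventory, tolerance = 1e-12)
  mc <- firstpassage_oracle(tr$A, null_sink(g), r0, tg, g)
  expect_equal(mc$inventory, rep(mc$inventory[1], 3), tolerance = 1e-10)
  big <- synthetic_grid(30, 2, 10) # 600 boxes
  expect_error(firstpassage_oracle(Matrix::Diagonal(600), sink,
                                   rep(1, 600), tg, big), "too large")
})

test_that("sequestration curves are monotone, additive, and anchored at production", {
  d <- desk_ocean()
  sink <- restoring_sink(d$grid)
  tg <- default_t_grid(t_max = 500, n = 10)
  for (el in c("C", "P")) {
    cur <- sequestration_curve(d$state, d$A, sink, tg, element = el)
    wide <- tidyr::pivot_wider(tidy(cur), names_from = "pool",
                               values_from = "flux_Pg_y")
    pools <- setdiff(names(wide), c("t_years", "total"))
    # every pool curve and the total are non-increasing
    for (p in c(pools, "total")) {
      expect_true(all(diff(wide[[p]]) <= 1e-10 * wide[[p]][1] + 1e-300))
    }
    # pool curves sum to the total at every threshold
    expect_equal(rowSums(wide[, pools]), wide$total, tolerance = 1e-10)
    # t = 0 flux equals global production (= remineralization) of the element
    v <- grid_volumes(d$grid)
    prod <- sum(Reduce(`+`, remin_source_fields(d$state, el)) * v)
    expect_equal(wide$total[1], mol_s_to_Pg_y(prod, el), tolerance = 1e-10)
    expect_equal(attr(cur, "production_Pg_y"), wide$total[1])
  }
})

test_that("the restoring sink approximates an absorbing surface", {
  d <- desk_ocean()
  tg <- c(0, 1, 10, 100)
  st <- d$state
  c500 <- sequestration_curve(st, d$A, restoring_sink(d$grid, 500), tg,
                              element = "C")
  c5000 <- sequestration_curve(st, d$A, restoring_sink(d$grid, 5000), tg,
                               element = "C")
  t500 <- dplyr::filter(c500, pool == "total", t_years >= 1)
  t5000 <- dplyr::filter(c5000, pool == "total", t_years >= 1)
  expect_lt(max(abs(t500$flux_Pg_y - t5000$flux_Pg_y) / t500$flux_Pg_y), 0.01)
})

test_that("deeper regeneration never shortens residence times", {
  tr <- build_synthetic_transport(synthetic_grid(6, 1, 6), seed = 5)
  g <- tr$grid
  sink <- restoring_sink(g)
  tg <- c(0, 0.5, 2, 10, 50, 200)
  col <- g$boxes$column == 3
  below <- which(col & !g$boxes$euphotic)
  below <- below[order(g$boxes$depth_mid[below])]
  curves <- lapply(below, function(b) {
    r0 <- numeric(g$n_boxes); r0[b] <- 1 / g$boxes$volume[b]
    survival_integrate(tr$A, sink, r0, tg, g)$inventory
  })
  for (i in seq_len(length(curves) - 1)) {
    expect_true(all(curves[[i + 1]][-1] >= curves[[i]][-1] * (1 - 1e-9)))
  }
})

test_that("a 12-hour labile pool contributes negligibly beyond one year", {
  d <- desk_ocean()
  sink <- restoring_sink(d$grid)
  src <- remin_source_fields(d$state, "C")
  m <- survival_integrate(d$A, sink, src$DOC_l, c(0, 1, 10), d$grid)
  expect_lt(m$inventory[2] / m$inventory[1], 0.01)
})

test_that("C:P ratio curves collapse to a flat line under mirrored cycles", {
  d <- desk_ocean()
  r <- 117
  st <- solve_cycles(mirror_params(r), d$A, d$forcing, d$grid,
                     labile = FALSE)
  sink <- restoring_sink(d$grid)
  tg <- default_t_grid(t_max = 500, n = 8)
  cc <- sequestration_curve(st, d$A, sink, tg, element = "C")
  cp <- sequestration_curve(st, d$A, sink, tg, element = "P")
  ratio <- cp_curve(cc, cp)
  expect_lt(max(abs(ratio$cp_ratio - r)) / r, 1e-8)
  expect_error(cp_curve(cc, sequestration_curve(st, d$A, sink, c(0, 1, 7),
                                                element = "P")),
               "identical")
})

test_that("sequestration efficiency is bounded and refuses extrapolation", {
  d <- desk_ocean()
  sink <- restoring_sink(d$grid)
  cur <- sequestration_curve(d$state, d$A, sink,
                             default_t_grid(t_max = 500, n = 10),
                             element = "C")
  eff <- sequestration_efficiency(cur, thresholds = c(0, 1, 10, 100))
  expect_equal(eff$efficiency[1], 1, tolerance = 1e-12)
  expect_true(all(eff$efficiency >= 0 & eff$efficiency <= 1))
  expect_true(all(diff(eff$efficiency) <= 0))
  expect_error(sequestration_efficiency(cur, thresholds = 5000),
               "within the computed")
})
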