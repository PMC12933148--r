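test_that("normalized column temperature handles degenerate and two-column cases", {
  g3 <- synthetic_grid(2, 1, 3, depth_total = 300, top_thickness = 100)
  # constant temperature: degenerate range maps to 0
  expect_equal(normalized_surface_temperature(rep(5, g3$n_boxes), g3),
               rep(0, g3$n_boxes))
  # two columns averaging 0 and 30 degC map to 0 and 1
  tt <- ifelse(g3$boxes$column == 1, 0, 30)
  th <- normalized_surface_temperature(tt, g3)
  expect_equal(unique(th[g3$boxes$column == 1]), 0)
  expect_equal(unique(th[g3$boxes$column == 2]), 1)
  # fewer than three layers: warns and uses what is there
  g2 <- synthetic_grid(2, 1, 2, depth_total = 200, top_thickness = 100)
  expect_warning(normalized_surface_temperature(rep(1, g2$n_boxes), g2),
                 "fewer")
})

test_that("realistic fields give theta_bar in [0,1] with warm tropics near 1", {
  d <- desk_ocean()
  th <- d$state$theta_bar
  expect_true(all(th >= 0 & th <= 1))
  warmest <- which(d$forcing$temperature == max(d$forcing$temperature))
  expect_gt(th[warmest[1]], 0.9)
  expect_lt(abs(d$grid$boxes$lat[warmest[1]]), 35) # tropics
})

test_that("Martin exponent and Q10 rate laws follow their closed forms", {
  expect_equal(martin_b(0.5, 1.0, 0.3), 1.15)
  expect_equal(martin_b(c(0, 0.7), 1.2, 0), c(1.2, 1.2)) # bth = 0: uniform
  expect_error(martin_b(1, 0.1, -0.2), "positive")
  kd <- 3e-9
  expect_equal(q10_rate(30, kd, 2), kd)
  expect_equal(q10_rate(20, kd, 2), kd / 2) # one decade of cooling halves k
  expect_error(q10_rate(10, -1, 2), "kd")
})

test_that("C:P stoichiometry is 1/(cc DIP + dd), monotone in DIP", {
  dip <- seq(1e-4, 3e-3, length.out = 7)
  expect_equal(cp_ratio(dip, 0, 1 / 106), rep(106, 7)) # Redfield limit
  r <- cp_ratio(dip, 3, 1 / 300)
  expect_true(all(diff(r) < 0))
  expect_error(cp_ratio(1e-3, -10, 1e-4), "positive")
})

test_that("uptake coefficient is proportional to NPP and self-consistent", {
  d <- desk_ocean()
  f <- d$forcing
  p <- cycle_params()
  g1 <- uptake_coefficient(f$npp, f$dip_obs, p$cc, p$dd, d$grid)
  g2 <- uptake_coefficient(2 * f$npp, f$dip_obs, p$cc, p$dd, d$grid)
  expect_equal(g2, 2 * g1)
  expect_true(all(g1[!d$grid$boxes$euphotic] == 0))
  # with DIP at the observed climatology, modeled C production = NPP
  eu <- d$grid$boxes$euphotic
  cprod <- g1[eu] * f$dip_obs[eu] * cp_ratio(f$dip_obs[eu], p$cc, p$dd)
  expect_equal(cprod, f$npp[eu], tolerance = 1e-12)
  bad <- f$dip_obs; bad[which(eu)[1]] <- 0
  expect_error(uptake_coefficient(f$npp, bad, p$cc, p$dd, d$grid), "zero")
})

test_that("particle operator matches the power-law closed form and conserves mass", {
  # layers z0 -> 2 z0 -> 4 z0, b = 1: interior fractions 1/2 and 1/4,
  # seafloor remainder 1/4 into the bottom box
  z0 <- 100
  g <- column_grid(c(0, z0, 2 * z0, 4 * z0))
  P <- particle_operator(rep(1, 3), g)
  v <- grid_volumes(g)
  remin <- as.numeric(P %*% 1) * v # mol/s per box from unit export
  expect_equal(remin, c(0, 1 / 2, 1 / 2), tolerance = 1e-14)
  Ptrunc <- particle_operator(rep(1, 3), g)
  # split bottom box into interior power-law part and the remainder
  interior_frac2 <- (2 * z0 / z0)^-1 - (4 * z0 / z0)^-1
  expect_equal(interior_frac2, 1 / 4)

  # steep attenuation: >= 99.9% remineralizes in the first subsurface layer
  g8 <- column_grid(seq(0, 800, by = 100))
  P50 <- particle_operator(rep(50, 8), g8)
  r50 <- as.numeric(P50 %*% 1) * grid_volumes(g8)
  expect_gt(r50[2], 0.999)

  # arbitrary b: column sum of remineralization equals the export
  for (b in c(0.4, 0.9, 1.7)) {
    Pb <- particle_operator(rep(b, 8), g8)
    expect_equal(sum(as.numeric(Pb %*% 1) * grid_volumes(g8)), 1,
                 tolerance = 1e-12)
  }
})

test_that("no-biology limit gives uniform DIP at the imposed inventory", {
  d <- desk_ocean()
  f0 <- d$forcing
  f0$npp <- rep(0, nrow(f0))
  st <- solve_p_cycle(cycle_params(), d$A, f0, d$grid, dip_inventory = 2e-3)
  expect_equal(st$DIP, rep(2e-3, d$grid$n_boxes), tolerance = 1e-10)
  expect_equal(max(abs(c(st$DOP, st$DOP_l))), 0, tolerance = 1e-20)
})

test_that("P-cycle solution satisfies the independently assembled equations", {
  tr <- build_synthetic_transport(synthetic_grid(2, 1, 6), seed = 13)
  g <- tr$grid
  f <- make_forcing(g, seed = 14)
  p <- cycle_params(sigma_dopl = 0.1)
  st <- solve_p_cycle(p, tr$A, f, g, dip_inventory = 1.8e-3)
  v <- grid_volumes(g)

  # independent Martin redistribution of POP export, by explicit loops
  th <- normalized_surface_temperature(f$temperature, g)
  gam <- st$gamma
  s_pop <- 1 - p$sigma_dop - p$sigma_dopl
  prod_pop <- s_pop * gam * st$DIP
  remin_pop <- numeric(g$n_boxes)
  z0 <- g$euphotic_base
  for (col in unique(g$boxes$column)) {
    ix <- which(g$boxes$column == col)
    ex <- sum((prod_pop * v)[ix[g$boxes$euphotic[ix]]])
    below <- ix[!g$boxes$euphotic[ix]]
    below <- below[order(g$boxes$depth_top[below])]
    b <- (p$bP0 + p$bPth * th[ix[1]])
    fr <- (g$boxes$depth_top[below] / z0)^-b - (g$boxes$depth_bot[below] / z0)^-b
    fr[length(fr)] <- fr[length(fr)] + (g$boxes$depth_bot[below[length(below)]] / z0)^-b
    remin_pop[below] <- ex * fr / v[below]
  }
  kP <- p$kdP * p$Q10P^((f$temperature - p$T0) / 10)
  res_dip <- as.numeric(tr$A %*% st$DIP) - gam * st$DIP + kP * st$DOP +
    p$kappa_l * st$DOP_l + remin_pop
  res_dop <- as.numeric(tr$A %*% st$DOP) - kP * st$DOP +
    p$sigma_dop * gam * st$DIP
  res_dopl <- as.numeric(tr$A %*% st$DOP_l) - p$kappa_l * st$DOP_l +
    p$sigma_dopl * gam * st$DIP
  scale <- max(abs(gam * st$DIP))
  expect_lt(max(abs(c(res_dip, res_dop, res_dopl))), 1e-10 * scale)
  expect_equal(weighted.mean(st$DIP, v), 1.8e-3, tolerance = 1e-12)
  expect_equal(st$remin_POP, remin_pop, tolerance = 1e-12)
})

test_that("equilibrium is stationary under long forward integration", {
  tr <- build_synthetic_transport(synthetic_grid(2, 1, 6), seed = 13)
  g <- tr$grid
  f <- make_forcing(g, seed = 14)
  p <- cycle_params(sigma_dopl = 0.1)
  st <- solve_p_cycle(p, tr$A, f, g, dip_inventory = 1.8e-3)
  # assemble the full (unpinned) linear system densely and push the
  # equilibrium through exp(M t) for 2000 years
  n <- g$n_boxes
  kP <- st$k_P
  gam <- st$gamma
  s_pop <- 1 - p$sigma_dop - p$sigma_dopl
  Ppop <- particle_operator(st$b_P, g) %*% export_matrix(g)
  Ad <- as.matrix(tr$A)
  G <- diag(gam); KP <- diag(kP); KL <- diag(rep(p$kappa_l, n))
  M <- rbind(
    cbind(Ad - G + s_pop * (as.matrix(Ppop) %*% G), KP, KL),
    cbind(p$sigma_dop * G, Ad - KP, matrix(0, n, n)),
    cbind(p$sigma_dopl * G, matrix(0, n, n), Ad - KL)
  )
  x0 <- c(st$DIP, st$DOP, st$DOP_l)
  expect_lt(max(abs(M %*% x0)), 1e-14 * max(abs(x0)) * max(abs(M)))
  xT <- as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(M * SEC_PER_YEAR * 2000))) %*% x0)
  expect_equal(xT, x0, tolerance = 1e-6)
})

test_that("each organic pool's global production balances its remineralization", {
  d <- desk_ocean()
  bal <- steady_state_balance(d$state)
  active <- bal$production > 0
  expect_true(all(bal$residual[active] < 1e-8))
  # P and C concentrations non-negative (O2 is a deficit-capable tracer)
  conc <- c(d$state$DIP, d$state$DOP, d$state$DOP_l, d$state$DIC,
            d$state$DOC, d$state$DOC_l, d$state$DOC_r)
  expect_gt(min(conc), -1e-10 * max(conc))
})

test_that("with mirrored parameters the carbon cycle is an exact r-scaled P cycle", {
  d <- desk_ocean()
  r <- 117
  p <- mirror_params(r)
  st <- solve_cycles(p, d$A, d$forcing, d$grid, labile = FALSE)
  expect_equal(st$DOC, r * st$DOP, tolerance = 1e-10)
  expect_equal(st$prod_POC, r * st$prod_POP, tolerance = 1e-12)
  expect_equal(st$remin_POC, r * st$remin_POP, tolerance = 1e-12)
  expect_equal(st$remin_DOC, r * st$remin_DOP, tolerance = 1e-10)
  expect_true(all(st$prod_DOC_l == 0))
  expect_true(all(st$DOC_l == 0))
})

test_that("labile DOC production closes the gap to prescribed NPP", {
  d <- desk_ocean()
  st <- d$state
  v <- grid_volumes(d$grid)
  toc_prod <- sum((st$prod_POC + st$prod_DOC + st$prod_DOC_r +
                     st$prod_DOC_l) * v)
  npp_int <- grid_integral(d$forcing$npp, d$grid)
  # labile adjustment active: TOC production integral equals the NPP integral
  expect_equal(toc_prod, npp_int, tolerance = 1e-10)
  # NPP set exactly to the non-labile production: DOC_l vanishes
  f2 <- d$forcing
  f2$npp <- st$prod_POC + st$prod_DOC + st$prod_DOC_r
  st2 <- solve_c_cycle(cycle_params(), d$A,
                       solve_p_cycle(cycle_params(), d$A, d$forcing, d$grid),
                       f2, d$grid)
  expect_lt(max(st2$prod_DOC_l), 1e-12 * max(st2$prod_POC))
})

test_that("flux-weighted means behave as weighted averages", {
  d <- desk_ocean()
  g <- d$grid
  expect_equal(flux_weighted_mean(rep(3.2, g$n_boxes),
                                  runif(g$n_boxes), g), 3.2)
  w <- numeric(g$n_boxes); w[17] <- 2
  fld <- rnorm(g$n_boxes)
  expect_equal(flux_weighted_mean(fld, w, g), fld[17])
  expect_error(flux_weighted_mean(fld, numeric(g$n_boxes), g), "zero")
})
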