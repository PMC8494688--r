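make_still_water <- function(g, h = -100) {
  # a water state with all face fluxes zero (no flow anywhere)
  st <- soil_water_state(g, h)
  st$flux <- list(
    qx = NULL, qy = NULL,
    qz = matrix(0, g$nx * g$ny, g$nz + 1),
    balance = list()
  )
  st
}

test_that("degradation rate combines moisture, temperature and depth factors", {
  cp <- compound_properties(logKow = 1, half_life = 20, theta_ref = 0.3,
                            moisture_exponent = 0.7)
  kref <- log(2) / 20
  expect_equal(degradation_rate(cp, 0.3, 20, -5), kref)
  expect_equal(degradation_rate(cp, 0.15, 20, -5), kref * 0.5^0.7,
               tolerance = 1e-12)
  expect_equal(degradation_rate(cp, 0.45, 20, -5), kref) # capped at 1
  expect_equal(degradation_rate(cp, 0.3, 30, -5), kref * exp(0.0948 * 10),
               tolerance = 1e-12)
  expect_equal(degradation_rate(cp, 0.3, -3, -5), 0) # frozen soil
  expect_equal(degradation_rate(cp, 0.3, 20, -150), 0) # below the factor table
  expect_error(degradation_rate(cp, -0.1, 20, -5), "negative")
})

test_that("first-order decay follows the closed form and halves mass per half-life", {
  g <- small_column(nz = 10)
  cp <- compound_properties(logKow = 1, K_D = 0, half_life = log(2) / 0.05,
                            theta_ref = 1e-9) # moisture factor 1 everywhere
  st <- make_still_water(g)
  sol <- soil_solute_state(g, cp, C = 1)
  m0 <- soil_solute_mass(g, sol, st$theta, cp)
  for (i in 1:100) {
    sol <- transport_step(g, sol, st, cp, 0, temperature = 20, dt = 0.1)
  }
  expect_equal(unique(round(sol$C, 12)), round(exp(-0.5), 12)) # C(10 d), k=0.05
  m1 <- soil_solute_mass(g, sol, st$theta, cp)
  expect_rel_equal(m1, m0 * exp(-0.5), 1e-10)
  expect_rel_equal(sol$degraded, m0 * (1 - exp(-0.5)), 1e-10)
  # half-life check at dt = 0.1 d
  half <- soil_solute_state(g, cp, C = 1)
  nsteps <- round(log(2) / 0.05 / 0.1)
  for (i in seq_len(nsteps)) {
    half <- transport_step(g, half, st, cp, 0, temperature = 20, dt = 0.1)
  }
  expect_rel_equal(soil_solute_mass(g, half, st$theta, cp), m0 / 2, 0.005)
})

test_that("advection of a pulse moves at the retarded pore velocity", {
  lay <- vg_layers(data.frame(
    z_top = 0, z_bottom = -200, theta_r = 0.05, theta_s = 0.40,
    alpha = 0.03, n = 1.6, K_s = 60, l = 0.5, rho_b = 2, tau = 0.5
  ))
  g <- soil_grid(1, 1, 100, 1, 1, 1, lay)
  # fixed water state: uniform theta, uniform downward flux
  st <- soil_water_state(g, -10)
  theta <- st$theta[1]
  v_pore <- 5 # cm/d
  q <- v_pore * theta
  st$flux <- list(qx = NULL, qy = NULL,
                  qz = matrix(q, 1, g$nz + 1), balance = list())
  # retardation R = (theta + rho_b K_D) / theta = 2
  KD <- theta / 2 # rho_b = 2 -> rho_b * K_D = theta
  cp <- compound_properties(logKow = 1, D = 1e-9, K_D = KD, half_life = Inf)
  C0 <- rep(0, g$nz); C0[11:20] <- 1 # top-hat
  sol <- soil_solute_state(g, cp, C = C0, C_bottom = 0)
  m0 <- soil_solute_mass(g, sol, st$theta, cp)
  com0 <- sum(-g$zc * sol$C[1:g$ncell]) / sum(sol$C)
  for (i in 1:40) sol <- transport_step(g, sol, st, cp, 0, 20, dt = 0.1)
  com1 <- sum(-g$zc * sol$C) / sum(sol$C)
  expect_equal(com1 - com0, 10, tolerance = 0.35) # v/R * 4 d = 10 cm
  expect_rel_equal(soil_solute_mass(g, sol, st$theta, cp), m0, 1e-8)
  # upwinding is monotone: no values outside the initial range
  expect_true(all(sol$C <= 1 + 1e-12 & sol$C >= -1e-15))
})

test_that("still, inert soil is a fixed point and ledgers close with a sink", {
  g <- small_column(nz = 10)
  cp <- compound_properties(logKow = 1, K_D = 0.1, half_life = Inf)
  st <- make_still_water(g)
  sol <- soil_solute_state(g, cp, C = 0.5)
  s2 <- transport_step(g, sol, st, cp, 0, 20, dt = 1)
  expect_equal(s2$C, sol$C, tolerance = 1e-14)
  # a root sink removes exactly what the ledger says
  sink <- numeric(g$ncell); sink[3] <- -1e-3 # g/cm^3/d uptake
  s3 <- transport_step(g, sol, st, cp, sink, 20, dt = 0.5)
  expect_lt(s3$step_balance$closure, 1e-12)
  expect_equal(s3$step_balance$sink_applied, -5e-4)
  # draining more than the cell holds is an error naming the cell
  big <- numeric(g$ncell); big[3] <- -10
  expect_error(transport_step(g, sol, st, cp, big, 20, dt = 1), "cell 3")
})

test_that("bottom inflow carries the boundary concentration", {
  g <- small_column(nz = 10)
  cp <- compound_properties(logKow = 1, K_D = 0, half_life = Inf)
  st <- soil_water_state(g, -10)
  st$flux <- list(qx = NULL, qy = NULL,
                  qz = matrix(-0.5, 1, g$nz + 1), balance = list()) # upward
  sol <- soil_solute_state(g, cp, C = 0, C_bottom = 2e-6)
  s2 <- transport_step(g, sol, st, cp, 0, 20, dt = 1)
  expect_rel_equal(s2$step_balance$bottom_in, 0.5 * 1 * 2e-6 * 1, 1e-12)
  expect_gt(s2$C[g$ncell], 0) # enters through the lowest cell
  expect_equal(s2$C[1:5], rep(0, 5)) # has not reached the top yet
})

test_that("layer means are water-volume weighted", {
  g <- small_column(nz = 10)
  cp <- compound_properties(logKow = 1, half_life = Inf)
  sol <- soil_solute_state(g, cp, C = c(rep(0, 5), rep(2, 5)))
  theta <- rep(0.3, g$ncell)
  lm <- layer_means(g, sol, theta, data.frame(z_top = 0, z_bottom = -10))
  expect_equal(lm$C_mean, 1)
  # non-uniform weights: brute-force sum(theta C V)/sum(theta V)
  theta2 <- seq(0.1, 0.4, length.out = g$ncell)
  lm2 <- layer_means(g, sol, theta2, data.frame(z_top = 0, z_bottom = -10))
  expect_equal(lm2$C_mean, sum(theta2 * sol$C) / sum(theta2),
               tolerance = 1e-12)
  expect_error(
    layer_means(g, sol, theta, data.frame(z_top = -40, z_bottom = -50)),
    "no cells"
  )
})
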