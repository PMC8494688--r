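test_that("two-resistance permeability follows the lipophilicity relation", {
  # logKow = 6.25: P_M = 1 m/s, P limited by the cell wall
  expect_equal(permeability_from_logkow(6.25, units = "m_s"),
               2.4994e-4, tolerance = 1e-4)
  # logKow = 2: P_M = 10^-5.1, series combination
  PM <- 10^(1.2 * 2 - 7.5)
  expect_equal(permeability_from_logkow(2, units = "m_s"),
               1 / (1 / 2.5e-4 + 1 / PM), tolerance = 1e-12)
  expect_equal(permeability_from_logkow(2, units = "m_s"), 7.697e-6,
               tolerance = 1e-4)
  # unit conversion consistency
  expect_equal(permeability_from_logkow(2),
               ms_to_cmd(permeability_from_logkow(2, units = "m_s")))
  # the shipped dummy compound evaluates to the lipophilicity-derived
  # permeability of about 13.4 cm/d
  expect_equal(permeability_from_logkow(dummy_substance_b()$logKow), 13.4,
               tolerance = 0.004)
})

test_that("segment exchange reproduces rates and the analytic relaxation", {
  up <- uptake_parameters(epsilon = 0, P = 13.4)
  # instantaneous uptake rate at C_R = 0: S_R = (2/r) P C_S
  dt <- 1e-8
  ex <- segment_exchange(1e-6, 0, 0, 0.05, 1, up, dt)
  V_R <- pi * 0.05^2 * 1
  rate <- ex$mass / (V_R * dt) # g cm^-3 d^-1
  expect_equal(rate, 5.36e-4, tolerance = 1e-3)
  # P = 0, eps = 0: nothing moves
  ex0 <- segment_exchange(1e-6, 5e-7, 0.3, 0.05, 1, uptake_parameters(0, 0), 1)
  expect_equal(ex0$mass, 0)
  expect_equal(ex0$C_R, 5e-7)
  # diffusive equilibrium: C_R -> C_S as t -> infinity
  exinf <- segment_exchange(1e-6, 0, 0, 0.05, 1, up, 1e6)
  expect_equal(exinf$C_R, 1e-6, tolerance = 1e-12)
})

test_that("exchange integration matches an independent stiff ODE solve", {
  skip_if_not_installed("deSolve")
  up <- uptake_parameters(epsilon = 0.4, P = 13.4)
  r <- 0.02; l <- 1.5; J <- 0.8; C_S <- 2e-6; C_R0 <- 3e-7
  dt <- 0.013
  rhs <- function(t, y, p) {
    list((2 / r) * (up$P * (C_S - y) + up$epsilon * J * C_S))
  }
  num <- deSolve::lsoda(c(C = C_R0), c(0, dt), rhs, NULL,
                        rtol = 1e-12, atol = 1e-20)
  ex <- segment_exchange(C_S, C_R0, J, r, l, up, dt)
  expect_rel_equal(ex$C_R, num[2, "C"], 3e-9)
  expect_rel_equal(ex$mass, pi * r^2 * l * (num[2, "C"] - C_R0), 3e-9)
  # efflux under reversed water flow upwinds the root concentration
  dtb <- 0.002
  exb <- segment_exchange(0, 1e-6, -0.8, r, l, up, dtb)
  rhsb <- function(t, y, p) {
    list((2 / r) * (up$P * (0 - y) + up$epsilon * (-0.8) * y))
  }
  numb <- deSolve::lsoda(c(C = 1e-6), c(0, dtb), rhsb, NULL,
                         rtol = 1e-12, atol = 1e-20)
  expect_rel_equal(exb$C_R, numb[2, "C"], 3e-9)
  expect_lt(exb$mass, 0) # solute returned to the soil
})

test_that("the literal advective-efflux variant always carries soil solution", {
  lit <- uptake_parameters(epsilon = 0.5, P = 0,
                           literal_advective_efflux = TRUE)
  ex <- segment_exchange(1e-6, 0, -0.5, 0.05, 1, lit, 0.1)
  # as printed the advective term uses the soil concentration even for
  # efflux, so mass flows INTO the root against the water flow direction
  expect_lt(ex$mass, 0) # eps * J * C_S with J < 0: negative source
  up <- uptake_parameters(epsilon = 0.5, P = 0)
  ex2 <- segment_exchange(1e-6, 0, -0.5, 0.05, 1, up, 0.1)
  expect_equal(ex2$mass, 0) # default: efflux carries root water (empty)
})

test_that("soil sink field mirrors the exchanged masses exactly", {
  g <- small_column()
  rs <- chain_root(2)
  m <- map_segments_to_grid(rs, g)
  S <- soil_sink_field(c(1e-8, 0), rs$id, m, g, dt = 0.01)
  expect_equal(S[1], -1e-6) # 1e-8 g over 0.01 d in a 1 cm^3 cell
  # two segments in one cell add
  rs2 <- y_root()
  g2 <- soil_grid(4, 4, 4, 1, 1, 1, sandy_layer())
  m2 <- map_segments_to_grid(rs2, g2)
  S2 <- soil_sink_field(c(0, 2e-9, 3e-9), rs2$id, m2, g2, dt = 0.1)
  expect_rel_equal(sum(S2) * g2$V * 0.1, -5e-9, 1e-12)
  # global ledger: cells match segments for arbitrary signed masses
  rs3 <- generate_stochastic_root_system(maize_root_params(), seed = 4)
  g3 <- soil_grid(75, 15, 145, 1, 1, 1, sandy_layer())
  m3 <- map_segments_to_grid(rs3, g3)
  mass <- stats::rnorm(nrow(rs3)) * 1e-9
  S3 <- soil_sink_field(mass, rs3$id, m3, g3, dt = 0.5)
  expect_rel_equal(-sum(S3) * g3$V * 0.5, sum(mass), 1e-10)
})

test_that("uptake is clipped to the dissolved mass available per cell", {
  g <- small_column()
  rs <- chain_root(1)
  m <- map_segments_to_grid(rs, g)
  up <- uptake_parameters(epsilon = 0, P = 50)
  ex <- segment_exchange(1e-3, 0, 0, rs$radius, rs$length, up, 1)
  avail <- numeric(g$ncell)
  avail[1] <- ex$mass * 0.4 # cell holds less than the demand
  expect_warning(
    lim <- limit_exchange(ex, 0, rs$id, m, g, avail, up, rs),
    "clipped"
  )
  expect_rel_equal(lim$mass, ex$mass * 0.4, 1e-12)
  expect_rel_equal(lim$C_R, ex$C_R * 0.4, 1e-12)
})

test_that("root advection transports to the collar and conserves mass", {
  rs <- chain_root(5)
  tab <- constant_hydraulics(5e-3, 0.5)
  sol <- solve_xylem(rs, -200, list(T_pot = 0.2), t = 1, table = tab)
  st <- root_solute_state(rs$id, C_R = 1e-6)
  up <- uptake_parameters(epsilon = 1, P = 0)
  st2 <- root_advection_step(rs, sol, st, up, dt = 0.005)
  # uniform concentration, steady flow: collar export = T_act * C_R * dt
  expect_rel_equal(st2$m_collar, 0.2 * 1e-6 * 0.005, 0.02)
  expect_lt(st2$step_balance$closure, 1e-12)
})

test_that("root tissue degradation decays mass e-fold per 1/k_R", {
  rs <- chain_root(1)
  sol <- structure(
    tibble::tibble(id = 1L, h_x = 0, q_r = 0, J_wr = 0, Q_ax = 0,
                   Lr = 0, Kx = 0, A_R = 1),
    T_act = 0, mode = "flux"
  )
  up <- uptake_parameters(epsilon = 0, P = 0, k_R = 0.1)
  st <- root_solute_state(1L, C_R = 1e-6)
  m0 <- root_solute_mass(st, rs, up)
  for (i in 1:100) st <- root_advection_step(rs, sol, st, up, dt = 0.1)
  expect_rel_equal(root_solute_mass(st, rs, up), m0 * exp(-1), 1e-9)
  expect_rel_equal(st$degraded, m0 * (1 - exp(-1)), 1e-9)
})

test_that("a two-segment chain matches a brute-force upwind ODE solve", {
  skip_if_not_installed("deSolve")
  rs <- chain_root(2)
  tab <- constant_hydraulics(5e-3, 0.5)
  sol <- solve_xylem(rs, -150, list(T_pot = 0.05), t = 1, table = tab)
  W <- pi * rs$radius^2 * rs$length
  Q <- sol$Q_ax # Q[2] tip->seg1, Q[1] seg1->collar
  rhs <- function(t, y, p) {
    list(c(
      (Q[2] * y[2] - Q[1] * y[1]) / W[1],
      (-Q[2] * y[2]) / W[2]
    ))
  }
  y0 <- c(2e-6, 1e-6)
  dt <- 0.02
  num <- deSolve::lsoda(y0, c(0, dt), rhs, NULL, rtol = 1e-10, atol = 1e-14)
  st <- root_solute_state(rs$id, C_R = y0)
  st2 <- root_advection_step(rs, sol, st, uptake_parameters(1, 0), dt)
  expect_equal(st2$C_R, unname(num[2, 2:3]), tolerance = 1e-6)
})

test_that("newly emerged segments start empty and preserve root mass", {
  st <- root_solute_state(1:2, C_R = c(1e-6, 2e-6))
  st2 <- emerge_segments(st, c(2L, 3L, 4L))
  expect_equal(st2$ids, 1:4)
  expect_equal(st2$C_R, c(1e-6, 2e-6, 0, 0))
  rs <- chain_root(4)
  up <- uptake_parameters(0.5, 0)
  expect_equal(root_solute_mass(st2, rs, up), root_solute_mass(st, rs, up))
  expect_identical(emerge_segments(st, integer()), st)
})

test_that("root concentrations obey the max principle without sorption or decay", {
  sc <- make_toy_uniform_scenario(0.5, 20, days = 3)
  run <- run_scenario(sc)
  Cmax_soil <- max(sc$initial$C) # concentrations only decline in this setup
  expect_lte(max(run$root_solute$C_R), Cmax_soil * (1 + 1e-9))
})
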