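test_that("an infinitely permeable segment takes the soil potential", {
  rs <- chain_root(1)
  tab <- constant_hydraulics(1e6, 0.5) # huge radial conductivity
  sol <- solve_xylem(rs, -300, list(T_pot = 1e-6), t = 1, table = tab)
  expect_equal(sol$h_x, -300, tolerance = 1e-4)
})

test_that("identical sibling laterals take up equal amounts", {
  rs <- y_root()
  tab <- constant_hydraulics(2e-3, 0.3, n_orders = 2)
  sol <- solve_xylem(rs, -500, list(T_pot = 0.05), t = 1, table = tab)
  q <- sol$q_r[match(2:3, sol$id)]
  expect_equal(q[1], q[2], tolerance = 1e-12)
  expect_rel_equal(sum(sol$q_r), 0.05, 1e-10) # flux mode: T_act = T_pot
})

test_that("network heads match a dense linear solve", {
  rs <- chain_root(3, radius = 0.02)
  Lr <- 2e-4; Kx <- 0.5
  tab <- constant_hydraulics(Lr, Kx)
  hs <- c(-100, -250, -400)
  T_pot <- 0.004
  sol <- solve_xylem(rs, hs, list(T_pot = T_pot), t = 1, table = tab)
  # dense brute-force: unknown total potentials at 3 nodes + collar
  k <- Lr * 2 * pi * 0.02 * 1
  g <- Kx / 1
  Hs <- hs + rs$z2
  A <- matrix(0, 4, 4)
  b <- numeric(4)
  edges <- cbind(1:3, c(4L, 1L, 2L)) # node i -- parent node (collar = 4)
  for (e in 1:3) {
    i <- edges[e, 1]; j <- edges[e, 2]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
  }
  for (i in 1:3) {
    A[i, i] <- A[i, i] + k
    b[i] <- k * Hs[i]
  }
  b[4] <- -T_pot
  H <- solve(A, b)
  expect_equal(sol$h_x, H[1:3] - rs$z2, tolerance = 1e-12)
  expect_equal(sol$q_r, k * (Hs - H[1:3]), tolerance = 1e-8)
})

test_that("collar switches to head control under water stress", {
  rs <- chain_root(10, radius = 0.01)
  tab <- constant_hydraulics(1e-5, 0.1) # very resistive root
  dry <- -14000
  sol <- solve_xylem(rs, dry, list(T_pot = 5, h_crit = -15000),
                     t = 1, table = tab)
  expect_equal(attr(sol, "mode"), "head")
  expect_equal(attr(sol, "h_collar"), -15000)
  expect_lt(attr(sol, "T_act"), 5)
  expect_rel_equal(sum(sol$q_r), attr(sol, "T_act"), 1e-8)
  # wet soil: flux-controlled, T_act = T_pot exactly
  wet <- solve_xylem(rs, -100, list(T_pot = 1e-4, h_crit = -15000),
                     t = 1, table = tab)
  expect_equal(attr(wet, "mode"), "flux")
  expect_equal(attr(wet, "T_act"), 1e-4)
  # continuity at the switching point: impose the critical head and
  # recover the same solution as the flux-controlled solve of its T_act
  Tstar <- attr(sol, "T_act")
  again <- solve_xylem(rs, dry, list(T_pot = Tstar, h_crit = -1e9),
                       t = 1, table = tab)
  expect_equal(attr(again, "h_collar"), -15000, tolerance = 1e-6)
  expect_equal(again$h_x, sol$h_x, tolerance = 1e-6)
})

test_that("hydraulic lift is permitted and flagged in head mode", {
  rs <- chain_root(5)
  tab <- constant_hydraulics(5e-3, 0.5)
  # soil much drier than the critical head: water exits through the collar
  sol <- solve_xylem(rs, -30000, list(T_pot = 0.5, h_crit = -15000),
                     t = 1, table = tab)
  expect_equal(attr(sol, "mode"), "head")
  expect_lt(attr(sol, "T_act"), 0)
  expect_true(attr(sol, "hydraulic_lift"))
})

test_that("SUF sums to one, is head-invariant and near-uniform for the tuned single root", {
  rs <- generate_single_root(100, 89, radius = 0.003)
  tab <- constant_hydraulics(2e-4, 0.5)
  suf <- compute_suf(rs, tab, t = 120)
  expect_rel_equal(sum(suf$suf), 1, 1e-10)
  expect_true(all(suf$suf >= 0))
  suf2 <- compute_suf(rs, tab, t = 120, uniform_head = -100)
  expect_lt(max(abs(suf$suf - suf2$suf)), 1e-12)
  spread <- (max(suf$suf) - min(suf$suf)) / mean(suf$suf)
  expect_lt(spread, 0.05)
  # two identical siblings split the standard uptake evenly
  ysuf <- compute_suf(y_root(), constant_hydraulics(2e-3, 0.3, n_orders = 2))
  sib <- ysuf$suf[match(2:3, ysuf$id)]
  expect_equal(sib[1], sib[2], tolerance = 1e-12)
})
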