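# shared miniature fixtures, built in code

sandy_layer <- function(z_bottom = -150) {
  vg_layers(data.frame(
    z_top = 0, z_bottom = z_bottom, theta_r = 0.05, theta_s = 0.40,
    alpha = 0.03, n = 1.6, K_s = 60, l = 0.5, rho_b = 1.5, tau = 0.5
  ))
}

small_column <- function(nz = 30, dx = 1, dz = 1) {
  soil_grid(1, 1, nz, dx, dx, dz, sandy_layer())
}

# a hand-built chain of n vertical 1-cm segments under the collar
chain_root <- function(n, radius = 0.05, emergence = 0) {
  root_system(tibble::tibble(
    id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    x1 = 0.5, y1 = 0.5, z1 = -(seq_len(n) - 1),
    x2 = 0.5, y2 = 0.5, z2 = -seq_len(n),
    radius = radius, order = 0L,
    emergence_time = rep_len(emergence, n), branch_id = 1L
  ), collar_position = c(0.5, 0.5, 0))
}

# Y-shaped root: one 1-cm stem with two mirrored laterals
y_root <- function(radius = 0.05) {
  root_system(tibble::tibble(
    id = 1:3,
    parent_id = c(NA_integer_, 1L, 1L),
    x1 = c(0, 0, 0), y1 = c(0, 0, 0), z1 = c(0, -1, -1),
    x2 = c(0, 1, -1), y2 = 0, z2 = c(-1, -2, -2),
    radius = radius, order = c(0L, 1L, 1L),
    emergence_time = 0, branch_id = c(1L, 2L, 3L)
  ), collar_position = c(0, 0, 0))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
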