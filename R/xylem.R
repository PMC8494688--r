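#' Solve water flow in the root hydraulic network
#'
#' Steady-state Doussan-type solve of xylem water potentials on the alive
#' segment network. Axial flow between the distal nodes of parent and
#' child segments is driven by total water potential (pressure head +
#' elevation) through the axial conductance Kx/l; radial flow into each
#' segment is driven by the local soil-xylem pressure head difference
#' through the radial conductance Lr * 2*pi*r*l (Darcy-like membrane
#' law, no gravity across the membrane).
#'
#' The collar is first solved flux-controlled (imposed potential
#' transpiration). If the resulting collar pressure head falls below the
#' critical head, the system is re-solved with the collar head fixed at
#' `h_crit` (water-potential-controlled mode) and actual transpiration
#' drops below potential. Negative actual transpiration in that mode
#' (hydraulic lift through the collar) is permitted and flagged.
#'
#' @param rs a [root_system()] (only segments alive at `t` are used).
#' @param soil_heads soil pressure head seen by each alive segment, cm
#'   (vector aligned with `alive_segments(rs, t)`, or a scalar).
#' @param collar_bc list with `T_pot` (potential transpiration, cm^3/d,
#'   >= 0) and `h_crit` (critical collar pressure head, cm, default
#'   -15000).
#' @param t time, days after planting (sets segment ages).
#' @param table a [hydraulic_table()].
#' @return an object of class `hydraulic_solution`: a tibble with one row
#'   per alive segment (`id`, `h_x` xylem pressure head at the distal
#'   node, `q_r` radial volumetric uptake cm^3/d, `J_wr` radial flux cm/d
#'   positive into the root, `Q_ax` axial collar-ward volumetric flow
#'   cm^3/d, `Lr`, `Kx`, `A_R`), with attributes `T_act`, `mode`
#'   (`"flux"` or `"head"`), `h_collar` and `hydraulic_lift`.
#' @export
solve_xylem <- function(rs, soil_heads, collar_bc, t = Inf, table) {
  al <- alive_segments(rs, t)
  n <- nrow(al)
  if (n == 0) stop("solve_xylem(): no alive segments at t = ", t)
  stopifnot(collar_bc$T_pot >= 0)
  h_crit <- if (is.null(collar_bc$h_crit)) -15000 else collar_bc$h_crit
  h_s <- rep_len(soil_heads, n)
  age <- pmax(0, t - al$emergence_time)
  if (any(!is.finite(age))) age <- rep(1e6, n) # t = Inf: mature everywhere
  hp <- lookup_hydraulics(table, al$order, age)
  g <- hp$Kx / al$length # axial conductance of each segment's edge
  A_R <- 2 * pi * al$radius * al$length
  k <- hp$Lr * A_R # radial conductance
  if (all(g == 0) || all(k == 0)) {
    stop("solve_xylem(): singular hydraulic network (zero conductances)")
  }
  zc <- collar_position(rs)[3]
  z <- al$z2 # distal node elevations
  Hs <- h_s + z
  pidx <- match(al$parent_id, al$id) # NA = collar
  pnode <- ifelse(is.na(pidx), n + 1L, pidx)
  # sparse symmetric system over n segment nodes + collar node n+1
  ii <- c(seq_len(n), seq_len(n), pnode, pnode)
  jj <- c(seq_len(n), pnode, seq_len(n), pnode)
  vv <- c(g + k, -g, -g, g)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n + 1, n + 1))
  b <- c(k * Hs, -collar_bc$T_pot)
  H <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) {
    stop("solve_xylem(): singular hydraulic network: ", conditionMessage(e))
  })
  mode <- "flux"
  h_collar <- H[n + 1] - zc
  T_act <- collar_bc$T_pot
  if (h_collar < h_crit - 1e-9) {
    mode <- "head"
    Hc <- h_crit + zc
    An <- A[seq_len(n), seq_len(n), drop = FALSE]
    bn <- b[seq_len(n)]
    at_collar <- which(is.na(pidx))
    bn[at_collar] <- bn[at_collar] + g[at_collar] * Hc
    Hn <- as.numeric(Matrix::solve(An, bn))
    H <- c(Hn, Hc)
    h_collar <- h_crit
    T_act <- sum(g[at_collar] * (Hn[at_collar] - Hc))
  }
  q_r <- k * (Hs - H[seq_len(n)])
  Q_ax <- g * (H[seq_len(n)] - H[pnode])
  out <- tibble::tibble(
    id = al$id,
    h_x = H[seq_len(n)] - z,
    q_r = q_r,
    J_wr = q_r / A_R,
    Q_ax = Q_ax,
    Lr = hp$Lr, Kx = hp$Kx, A_R = A_R
  )
  structure(out,
    T_act = T_act, mode = mode, h_collar = h_collar,
    hydraulic_lift = mode == "head" && T_act < 0,
    class = c("hydraulic_solution", class(out))
  )
}

#' Actual transpiration of a hydraulic solution
#' @param sol a `hydraulic_solution`.
#' @return cm^3/d.
#' @export
actual_transpiration <- function(sol) attr(sol, "T_act")

#' Standard uptake fraction (SUF)
#'
#' Per-segment share of root water uptake under a spatially uniform soil
#' water potential and unit collar flux: a property of the hydraulic
#' architecture alone, independent of the uniform potential chosen. The
#' solve uses a uniform total soil water potential so that gravity does
#' not redistribute the standard uptake.
#'
#' @param rs a [root_system()].
#' @param table a [hydraulic_table()].
#' @param t time, days after planting.
#' @param uniform_head the uniform total potential, cm (result-invariant).
#' @return a tibble of class `suf` with `id`, `z` (distal node elevation),
#'   `suf` (fractions summing to 1).
#' @export
compute_suf <- function(rs, table, t = Inf, uniform_head = -1000) {
  al <- alive_segments(rs, t)
  # uniform TOTAL potential: pass pressure heads that cancel elevation
  sol <- solve_xylem(
    rs, uniform_head - al$z2,
    collar_bc = list(T_pot = 1, h_crit = -Inf), t = t, table = table
  )
  out <- tibble::tibble(id = sol$id, z = al$z2, suf = sol$q_r / sum(sol$q_r))
  structure(out, class = c("suf", class(out)))
}
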