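#' Root uptake parameters
#'
#' Passive uptake parameters of the Trapp-style single-compartment root:
#' `epsilon` is the fraction of solute carried into the root with the
#' water flux through the apoplastic bypass (1 - sigma, sigma the
#' reflection coefficient); `P` the overall membrane + cell-wall
#' permeability (cm/d), either a number or `"from_logkow"` to derive it
#' from the compound lipophilicity via [permeability_from_logkow()].
#'
#' @param epsilon advective uptake fraction in `[0, 1]`.
#' @param P overall root permeability, cm/d, or `"from_logkow"`.
#' @param P_W cell-wall permeability, m/s (used when `P = "from_logkow"`).
#' @param literal_advective_efflux if TRUE, the advective term always
#'   carries the soil concentration even when water leaves the root
#'   (the conservation equation as printed); the default upwinds the
#'   carried concentration by the sign of the radial flux so that efflux
#'   returns root solution to the soil.
#' @param theta_R root water content (-), default 1 (no root sorption:
#'   the lumped compartment is water).
#' @param rho_R dry root tissue density, g/cm^3 (default 0).
#' @param K_D_R root tissue sorption coefficient, cm^3/g (default 0).
#' @param k_R first-order degradation rate in the root, 1/d (default 0).
#' @param compound optional [compound_properties()] used to resolve
#'   `"from_logkow"`.
#' @return a list of class `uptake_parameters` with `P` resolved to cm/d.
#' @export
uptake_parameters <- function(epsilon = 0.5, P = 0, P_W = 2.5e-4,
                              literal_advective_efflux = FALSE,
                              theta_R = 1, rho_R = 0, K_D_R = 0, k_R = 0,
                              compound = NULL) {
  if (epsilon < 0 || epsilon > 1) {
    stop("uptake_parameters(): epsilon must lie in [0, 1]")
  }
  if (identical(P, "from_logkow")) {
    if (is.null(compound)) {
      stop("uptake_parameters(): P = \"from_logkow\" needs compound properties (logKow)")
    }
    P <- permeability_from_logkow(compound$logKow, P_W)
  }
  stopifnot(is.numeric(P), P >= 0)
  if (theta_R <= 0) stop("uptake_parameters(): theta_R must be positive")
  structure(
    list(
      epsilon = epsilon, P = P, P_W = P_W,
      literal_advective_efflux = literal_advective_efflux,
      theta_R = theta_R, rho_R = rho_R, K_D_R = K_D_R, k_R = k_R
    ),
    class = "uptake_parameters"
  )
}

#' Root solute state
#'
#' Per-segment dissolved concentration in the root plus the collar and
#' fate accumulators. Newly emerged segments enter with zero
#' concentration (solute is applied to the soil, not carried into new
#' tissue).
#'
#' @param ids segment ids currently tracked.
#' @param C_R initial dissolved concentration per segment, g/cm^3 root
#'   water (scalar or vector).
#' @return an object of class `root_solute_state`.
#' @export
root_solute_state <- function(ids = integer(), C_R = 0) {
  structure(
    list(
      ids = as.integer(ids), C_R = rep_len(as.numeric(C_R), length(ids)),
      m_collar = 0, degraded = 0, soil_return = 0, uptake = 0
    ),
    class = "root_solute_state"
  )
}

#' Track newly emerged segments
#'
#' Adds segments that became alive this step with zero solute
#' concentration; the states of existing segments are untouched (total
#' root mass is unchanged by emergence).
#'
#' @param state a [root_solute_state()].
#' @param newly_alive integer ids of segments that emerged this step.
#' @return updated state.
#' @export
emerge_segments <- function(state, newly_alive) {
  newly_alive <- setdiff(as.integer(newly_alive), state$ids)
  if (length(newly_alive) == 0) return(state)
  state$ids <- c(state$ids, newly_alive)
  state$C_R <- c(state$C_R, numeric(length(newly_alive)))
  state
}

#' Total solute mass in the root system
#'
#' @param state a [root_solute_state()].
#' @param rs the [root_system()] (for segment volumes).
#' @param params [uptake_parameters()] (for the root retardation).
#' @return mass, g.
#' @export
root_solute_mass <- function(state, rs, params) {
  i <- match(state$ids, rs$id)
  V_R <- pi * rs$radius[i]^2 * rs$length[i]
  RR <- params$theta_R + params$rho_R * params$K_D_R
  sum(RR * V_R * state$C_R)
}

#' Radial solute exchange between soil and one set of segments
#'
#' Integrates the per-segment uptake law over `dt` with the soil
#' concentration held fixed (operator splitting): the rate of change of
#' the root concentration is (A_R/V_R) (P (C_S - C_R) + eps J_wr C_adv)
#' divided by the root retardation capacity, with `C_adv` the soil
#' concentration during influx and (by default) the root concentration
#' during efflux. The linear ODE is solved exactly (exponential
#' relaxation), which is unconditionally stable even for highly permeable
#' membranes on fine roots.
#'
#' @param C_S soil concentration seen by each segment, g/cm^3.
#' @param C_R current root concentration per segment, g/cm^3.
#' @param J_wr radial water flux per segment, cm/d (positive into root).
#' @param radius,length segment geometry, cm.
#' @param params [uptake_parameters()].
#' @param dt sub-step, days (> 0).
#' @return list with `mass` (signed solute mass moved into each segment
#'   over `dt`, g; negative = efflux to soil) and `C_R` (updated root
#'   concentrations).
#' @export
segment_exchange <- function(C_S, C_R, J_wr, radius, length, params, dt) {
  stopifnot(dt > 0)
  if (params$theta_R <= 0) stop("segment_exchange(): non-positive theta_R")
  n <- max(length(C_S), length(C_R), length(J_wr), length(radius), length(length))
  C_S <- rep_len(C_S, n); C_R0 <- rep_len(C_R, n); J <- rep_len(J_wr, n)
  r <- rep_len(radius, n); l <- rep_len(length, n)
  b <- 2 / r # A_R / V_R for a cylinder
  RR <- params$theta_R + params$rho_R * params$K_D_R
  V_R <- pi * r^2 * l
  P <- params$P; eps <- params$epsilon
  Jin <- pmax(J, 0)
  Jout <- if (params$literal_advective_efflux) 0 else pmax(-J, 0)
  Jlit <- if (params$literal_advective_efflux) pmin(J, 0) else 0
  # dC_R/dt = (b/RR) [ (P + eps*Jin + eps*Jlit) C_S - (P + eps*Jout) C_R ]
  a <- b * (P + eps * Jout) / RR # decay rate toward equilibrium, 1/d
  fsrc <- b * (P + eps * Jin + eps * Jlit) * C_S / RR
  C_new <- ifelse(
    a > 0,
    fsrc / a + (C_R0 - fsrc / a) * exp(-a * dt),
    C_R0 + fsrc * dt
  )
  mass <- RR * V_R * (C_new - C_R0)
  list(mass = mass, C_R = C_new)
}

#' Root uptake sink field on the soil grid
#'
#' Converts per-segment exchanged masses into the per-cell solute sink of
#' the soil conservation equation: S_S(cell) = -sum_i mass_i * fraction_i
#' / (V_cell * dt). The cell sums equal minus the segment sums exactly.
#'
#' @param mass signed exchanged mass per segment over `dt`, g (positive =
#'   into the root).
#' @param ids segment ids aligned with `mass`.
#' @param mapping a [map_segments_to_grid()] result.
#' @param grid the [soil_grid()].
#' @param dt the step the masses refer to, days.
#' @return per-cell sink rate S_S, g cm^-3 d^-1 (negative where roots
#'   take up solute).
#' @export
soil_sink_field <- function(mass, ids, mapping, grid, dt) {
  -distribute_to_cells(mapping, ids, mass, grid$ncell) / (grid$V * dt)
}

#' Limit exchange to the solute mass available in each soil cell
#'
#' Uptake may not extract more than the dissolved mass present in a cell.
#' Exchanged masses are scaled back per cell where needed (segment masses
#' are rebalanced by their cell fractions) and the root concentrations
#' are recomputed accordingly; a warning reports the clipping.
#'
#' @param exch result of [segment_exchange()].
#' @param C_R_before root concentrations before the exchange.
#' @param ids,mapping,grid as in [soil_sink_field()].
#' @param available dissolved solute mass per cell, g.
#' @param params [uptake_parameters()].
#' @param rs the alive [root_system()] rows aligned with `ids`.
#' @return a corrected exchange list (`mass`, `C_R`).
#' @export
limit_exchange <- function(exch, C_R_before, ids, mapping, grid, available,
                           params, rs) {
  demand <- distribute_to_cells(mapping, ids, pmax(exch$mass, 0), grid$ncell)
  over <- demand > available + 1e-300
  if (!any(over)) return(exch)
  scale_cell <- rep(1, grid$ncell)
  scale_cell[over] <- pmax(available[over], 0) / demand[over]
  # per-segment scale: fraction-weighted mean of its cells' scales
  seg_scale <- gather_from_cells(mapping, ids, scale_cell)
  seg_scale[exch$mass <= 0] <- 1 # efflux is never limited by soil supply
  mass <- exch$mass * seg_scale
  i <- match(ids, rs$id)
  RR <- params$theta_R + params$rho_R * params$K_D_R
  V_R <- pi * rs$radius[i]^2 * rs$length[i]
  C_R <- C_R_before + mass / (RR * V_R)
  warning(
    "root solute uptake clipped in ", sum(over),
    " soil cell(s) to the available dissolved mass"
  )
  list(mass = mass, C_R = C_R)
}

#' Advect solute along the root network to the collar
#'
#' First-order upwind advection of the root solute with the axial
#' volumetric flows of the current hydraulic solution, integrated with a
#' classical Runge-Kutta scheme on internal sub-steps that respect the
#' per-segment CFL limit. Collar-ward flow out of the topmost segments
#' accrues to the collar mass (translocation to the shoot); reversed flow
#' at the collar (downward xylem flow after rain) carries zero
#' concentration into the root. First-order root-tissue degradation `k_R`
#' is part of the same integral, so the step ledger closes to rounding.
#'
#' @param rs alive [root_system()] rows (parents first).
#' @param sol the [solve_xylem()] solution for the same segments.
#' @param state a [root_solute_state()] tracking at least these segments.
#' @param params [uptake_parameters()].
#' @param dt step, days.
#' @return updated `root_solute_state`; `step_balance` reports collar
#'   export, degradation and the closure error of this step.
#' @export
root_advection_step <- function(rs, sol, state, params, dt) {
  ids <- sol$id
  i_state <- match(ids, state$ids)
  if (anyNA(i_state)) {
    stop("root_advection_step(): state does not track all alive segments")
  }
  i_rs <- match(ids, rs$id)
  RR <- params$theta_R + params$rho_R * params$K_D_R
  V_R <- pi * rs$radius[i_rs]^2 * rs$length[i_rs]
  W <- RR * V_R # solute capacity per segment, cm^3
  Q <- sol$Q_ax # collar-ward flow through the segment, cm^3/d
  parent <- match(rs$parent_id[i_rs], ids) # NA = collar
  # junction closure: Q_i - q_r,i - sum(children Q) must vanish
  child_in <- tapply2(Q, ifelse(is.na(parent), length(ids) + 1L, parent),
                      length(ids) + 1L)[seq_along(ids)]
  imb <- abs(Q - sol$q_r - child_in)
  scaleQ <- max(abs(Q), abs(sol$q_r), 1e-3)
  if (max(imb) > 1e-9 * scaleQ) {
    stop(
      "root_advection_step(): axial flux imbalance at segment ",
      ids[which.max(imb)], " (", format(max(imb)), " cm^3/d)"
    )
  }
  C <- state$C_R[i_state]
  mass0 <- sum(W * C)
  # stability / accuracy: outflow of a segment = collar-ward Q_i (if > 0)
  # plus reversed flow into children (Q_child < 0 drains the parent)
  rev_out <- tapply2(pmax(-Q, 0), ifelse(is.na(parent), length(ids) + 1L, parent),
                     length(ids) + 1L)[seq_along(ids)]
  outflow <- pmax(Q, 0) + rev_out
  rate <- outflow / W + params$k_R
  # classical RK4 on the upwind network ODE; sub-steps keep the local
  # rate * dts small so transients are resolved, not just stable
  dt_sub <- if (max(rate) > 0) 0.45 / max(rate) else dt
  nsub <- max(1L, as.integer(ceiling(dt / dt_sub - 1e-12)))
  dts <- dt / nsub
  at_collar <- is.na(parent)
  pidx <- ifelse(at_collar, length(ids) + 1L, parent)
  n <- length(ids)
  deriv <- function(M, mc, md) {
    Cc <- M / W
    Cdon <- ifelse(Q >= 0, Cc, c(Cc, 0)[pidx]) # reversed collar flow is clean
    fl <- Q * Cdon # segment -> parent mass flow, g/d
    dM <- -fl + tapply2(fl, pidx, n + 1L)[seq_len(n)] - params$k_R * M
    dmc <- sum(fl[at_collar])
    list(dM = dM, dmc = dmc, dmd = params$k_R * sum(M))
  }
  M <- W * C
  m_collar <- 0
  degraded <- 0
  for (s in seq_len(nsub)) {
    k1 <- deriv(M, m_collar, degraded)
    k2 <- deriv(M + dts / 2 * k1$dM, 0, 0)
    k3 <- deriv(M + dts / 2 * k2$dM, 0, 0)
    k4 <- deriv(M + dts * k3$dM, 0, 0)
    M <- M + dts / 6 * (k1$dM + 2 * k2$dM + 2 * k3$dM + k4$dM)
    m_collar <- m_collar + dts / 6 *
      (k1$dmc + 2 * k2$dmc + 2 * k3$dmc + k4$dmc)
    degraded <- degraded + dts / 6 *
      (k1$dmd + 2 * k2$dmd + 2 * k3$dmd + k4$dmd)
  }
  C <- M / W
  mass1 <- sum(W * C)
  closure <- abs(mass1 - (mass0 - m_collar - degraded)) /
    max(mass0, mass1, 1e-300)
  out <- state
  out$C_R[i_state] <- C
  out$m_collar <- state$m_collar + m_collar
  out$degraded <- state$degraded + degraded
  out$step_balance <- list(
    collar_export = m_collar, degraded = degraded,
    substeps = nsub, closure = closure
  )
  out
}
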