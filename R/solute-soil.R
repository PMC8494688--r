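#' Soil solute state
#'
#' Dissolved concentration field plus fate accumulators. Sorbed mass is in
#' linear equilibrium with the dissolved phase (retardation capacity
#' theta + rho_b * K_D per cell), so only the dissolved concentration is
#' stored; total mass per cell is `(theta + rho_b K_D) * C * V`.
#'
#' @param grid a [soil_grid()].
#' @param compound a [compound_properties()].
#' @param C initial dissolved concentration, g/cm^3 water: scalar,
#'   per-depth vector (length `nz`) or per-cell vector.
#' @param C_bottom prescribed dissolved concentration at the bottom
#'   boundary (carried by upward inflow), g/cm^3.
#' @return an object of class `soil_solute_state`.
#' @export
soil_solute_state <- function(grid, compound, C = 0, C_bottom = 0) {
  if (length(C) == grid$nz) C <- expand_iz(grid, C)
  C <- rep_len(as.numeric(C), grid$ncell)
  if (any(C < 0)) stop("soil_solute_state(): negative concentration")
  structure(
    list(
      C = C, C_bottom = C_bottom,
      degraded = 0, bottom_in = 0, bottom_out = 0, root_uptake = 0
    ),
    class = "soil_solute_state"
  )
}

# per-cell sorption partition rho_b * K_D (cm^3/cm^3)
cell_sorption <- function(grid, compound) {
  lay <- grid$layers
  KD <- rep_len(compound$K_D, nrow(lay))
  expand_iz(grid, (lay$rho_b * KD)[grid$layer_of_iz])
}

cell_tau <- function(grid) expand_iz(grid, grid$layers$tau[grid$layer_of_iz])

#' Total dissolved + sorbed solute mass in the soil
#'
#' @param grid a [soil_grid()].
#' @param state a [soil_solute_state()].
#' @param theta per-cell water content.
#' @param compound a [compound_properties()].
#' @return mass, g.
#' @export
soil_solute_mass <- function(grid, state, theta, compound) {
  sum((theta + cell_sorption(grid, compound)) * state$C) * grid$V
}

#' One solute transport and fate step in the soil
#'
#' Finite-volume update of Eq.-7-type solute conservation: first-order
#' upwind advection with the Darcy face fluxes of the water step, impeded
#' aqueous diffusion (D tau theta, harmonic face mean), linear equilibrium
#' sorption (retardation), exact first-order degradation of dissolved and
#' sorbed mass, and the root uptake sink. Advection and diffusion are
#' integrated with internal CFL-limited sub-steps (never silently
#' unstable); lateral faces are periodic; inflow across the bottom face
#' carries the prescribed boundary concentration while the top boundary
#' carries no solute either way (rain is solute-free, evaporation leaves
#' solute behind).
#'
#' @param grid a [soil_grid()].
#' @param state a [soil_solute_state()].
#' @param water the [soil_water_state()] returned by the water step over
#'   the same `dt` (its `flux` element is required).
#' @param compound a [compound_properties()].
#' @param sink root uptake sink S_S, g cm^-3 d^-1 per cell (negative =
#'   uptake, as in the conservation equation); scalar 0 for none.
#' @param theta_prev per-cell water content to which the state's
#'   concentrations refer (water content before the water step); total
#'   mass is conserved through the re-equilibration to the new content.
#'   Default: the new content (no re-equilibration).
#' @param temperature per-cell (or per-depth, or scalar) soil temperature,
#'   degC, for the degradation rate.
#' @param dt step, days.
#' @return updated `soil_solute_state`; element `step_balance` reports the
#'   mass ledger of this step (all in g): `mass_before`, `mass_after`,
#'   `bottom_in`, `bottom_out`, `degraded`, `sink_applied`, `closure`
#'   (relative closure error).
#' @export
transport_step <- function(grid, state, water, compound, sink = 0,
                           temperature = 20, dt, theta_prev = NULL) {
  stopifnot(dt > 0)
  if (is.null(water$flux)) {
    stop("transport_step(): water state carries no face fluxes")
  }
  theta <- water$theta
  sorb <- cell_sorption(grid, compound)
  cap <- (theta + sorb) * grid$V # retardation capacity, cm^3
  if (is.null(theta_prev)) theta_prev <- theta
  M <- (theta_prev + sorb) * grid$V * state$C # total mass per cell, g
  mass_before <- sum(M)
  faces <- grid_faces(grid)
  tau <- cell_tau(grid)
  Dcell <- compound$D * tau * theta # diffusive mobility per cell
  nxy <- grid$nx * grid$ny
  bcells <- bottom_cells(grid)
  qzb <- water$flux$qz[, grid$nz + 1] # positive down = out
  Ab <- grid$dx * grid$dy
  # face advective volumetric flows (cm^3/d) and diffusive conductances
  adv <- list(); dif <- list()
  for (nm in names(faces)) {
    f <- faces[[nm]]
    q <- switch(nm,
      x = water$flux$qx, y = water$flux$qy,
      z = as.numeric(water$flux$qz[, 2:grid$nz, drop = FALSE])
    )
    Dh <- 2 * Dcell[f$from] * Dcell[f$to] /
      pmax(Dcell[f$from] + Dcell[f$to], 1e-300)
    adv[[nm]] <- q * f$A
    dif[[nm]] <- Dh * f$A / f$d
  }
  # CFL sub-stepping
  out_rate <- numeric(grid$ncell)
  for (nm in names(faces)) {
    f <- faces[[nm]]
    Qp <- pmax(adv[[nm]], 0); Qm <- pmax(-adv[[nm]], 0)
    out_rate[f$from] <- out_rate[f$from] + Qp + dif[[nm]]
    out_rate[f$to] <- out_rate[f$to] + Qm + dif[[nm]]
  }
  out_rate[bcells] <- out_rate[bcells] + pmax(qzb, 0) * Ab
  rate <- out_rate / pmax(cap, 1e-300)
  dt_sub <- if (max(rate) > 0) 0.9 / max(rate) else dt
  nsub <- max(1L, as.integer(ceiling(dt / dt_sub - 1e-12)))
  dts <- dt / nsub
  bottom_in <- 0; bottom_out <- 0
  for (s in seq_len(nsub)) {
    C <- M / pmax(cap, 1e-300)
    dM <- numeric(grid$ncell)
    for (nm in names(faces)) {
      f <- faces[[nm]]
      Q <- adv[[nm]]
      Cup <- ifelse(Q >= 0, C[f$from], C[f$to])
      fl <- Q * Cup + dif[[nm]] * (C[f$from] - C[f$to]) # from -> to, g/d
      dM[f$from] <- dM[f$from] - fl * dts
      dM[f$to] <- dM[f$to] + fl * dts
    }
    # bottom boundary: outflow carries cell C, inflow the boundary C
    mb_out <- pmax(qzb, 0) * Ab * C[bcells] * dts
    mb_in <- pmax(-qzb, 0) * Ab * state$C_bottom * dts
    dM[bcells] <- dM[bcells] - mb_out + mb_in
    bottom_out <- bottom_out + sum(mb_out)
    bottom_in <- bottom_in + sum(mb_in)
    M <- M + dM
  }
  # degradation (exact exponential on total mass)
  if (length(temperature) == grid$nz) temperature <- expand_iz(grid, temperature)
  kS <- degradation_rate(
    compound, theta, rep_len(temperature, grid$ncell), expand_iz(grid, grid$zc)
  )
  deg <- M * (1 - exp(-kS * dt))
  M <- M - deg
  degraded <- sum(deg)
  # root uptake sink (S_S negative = uptake)
  sink <- rep_len(sink, grid$ncell)
  dM_sink <- sink * grid$V * dt
  M2 <- M + dM_sink
  if (any(M2 < -1e-13 * max(mass_before, 1e-300))) {
    bad <- which.min(M2)
    stop(
      "transport_step(): sink exceeds available solute mass in cell ", bad,
      " (", format(M2[bad]), " g); limit the exchange upstream"
    )
  }
  M2[M2 < 0] <- 0
  C_new <- M2 / pmax(cap, 1e-300)
  mass_after <- sum(M2)
  closure <- abs(
    mass_after - (mass_before + bottom_in - bottom_out - degraded + sum(dM_sink))
  ) / max(mass_before, mass_after, 1e-300)
  out <- state
  out$C <- C_new
  out$degraded <- state$degraded + degraded
  out$bottom_in <- state$bottom_in + bottom_in
  out$bottom_out <- state$bottom_out + bottom_out
  out$root_uptake <- state$root_uptake - sum(dM_sink)
  out$step_balance <- list(
    mass_before = mass_before, mass_after = mass_after,
    bottom_in = bottom_in, bottom_out = bottom_out,
    degraded = degraded, sink_applied = sum(dM_sink),
    substeps = nsub, closure = closure
  )
  out
}

#' Per-layer mean dissolved concentration
#'
#' Water-volume-weighted mean of the dissolved concentration for a set of
#' depth layers (reporting layers, not necessarily soil-property layers).
#'
#' @param grid a [soil_grid()].
#' @param state a [soil_solute_state()].
#' @param theta per-cell water content (weights).
#' @param layer_bounds data frame with `z_top`, `z_bottom` (cm, <= 0).
#' @return a tibble `z_top`, `z_bottom`, `C_mean` (g/cm^3).
#' @export
layer_means <- function(grid, state, theta, layer_bounds) {
  z <- expand_iz(grid, grid$zc)
  out <- tibble::as_tibble(layer_bounds)
  out$C_mean <- vapply(seq_len(nrow(out)), function(k) {
    idx <- z <= out$z_top[k] + 1e-12 & z >= out$z_bottom[k] - 1e-12
    if (!any(idx)) {
      stop(
        "layer_means(): no cells in layer [", out$z_top[k], ", ",
        out$z_bottom[k], "] cm"
      )
    }
    sum(theta[idx] * state$C[idx]) / sum(theta[idx])
  }, numeric(1))
  out
}
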