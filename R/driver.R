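#' Run a coupled soil-root uptake simulation
#'
#' Orchestrates the coupled loop. Each step of length at most `dt_max`
#' (steps never straddle forcing-day boundaries):
#' update the alive segment set and its soil mapping, solve the xylem
#' network (with collar switching), advance Richards flow with the root
#' water sink, exchange solute radially (analytic integration, limited to
#' the dissolved mass available per cell), advance soil solute transport
#' and fate, advect root solute to the collar, and accrue daily metrics
#' and ledgers. The run is deterministic given the scenario (any
#' stochastic root source carries its own seed).
#'
#' @param sc a [scenario()].
#' @param window simulation window in days, `c(t0, t1)`; default the full
#'   forcing range.
#' @param out_dir optional directory: time series and ledgers are written
#'   as CSV.
#' @param progress print one line per day.
#' @return an object of class `uptake_run`: list with `metrics` (daily
#'   tibble with TSCF/PUF), `water_ledger`, `solute_ledger` (daily
#'   tibbles), `layer_concentrations`, `cum_water_sink_z`,
#'   `cum_solute_sink_z` (per grid depth), final `water`, `solute`,
#'   `root_solute` states, the `grid`, root system `rs` and `scenario`.
#' @export
run_scenario <- function(sc, window = NULL, out_dir = NULL, progress = FALSE) {
  grid <- scenario_grid(sc)
  rs <- scenario_root(sc)
  full_map <- map_segments_to_grid(rs, grid, t = Inf)
  if (is.null(window)) window <- range(sc$forcing$day) + c(0, 1)
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stop("run_scenario(): empty simulation window")
  if (t0 < min(sc$forcing$day) || t1 > max(sc$forcing$day) + 1) {
    stop("run_scenario(): forcing does not cover the window [", t0, ", ", t1, "]")
  }
  forc_row <- function(t) {
    i <- findInterval(t + 1e-12, sc$forcing$day)
    sc$forcing[max(1, min(i, nrow(sc$forcing))), ]
  }
  # initial states
  f0 <- forc_row(t0)
  water <- if (identical(sc$initial$h, "hydrostatic")) {
    hydrostatic_state(grid, f0$h_bottom)
  } else {
    soil_water_state(grid, sc$initial$h)
  }
  water$time <- t0
  solute <- soil_solute_state(grid, sc$compound, sc$initial$C,
                              sc$initial$C_bottom)
  rsol <- root_solute_state()
  tracked <- integer(0)
  zc_day <- sc$temperature$planting_doy
  Tz <- soil_temperature(
    zc_day + t0, grid$zc,
    sc$temperature$mean_T, sc$temperature$amplitude,
    sc$temperature$damping_depth, sc$temperature$peak_day
  )
  cum_ws_z <- numeric(grid$nz)
  cum_ss_z <- numeric(grid$nz)
  metrics_rows <- list(); wled_rows <- list(); sled_rows <- list()
  layer_rows <- list()
  init_soil_mass <- soil_solute_mass(grid, solute, water$theta, sc$compound)
  # daily accumulators
  reset_day <- function() {
    list(
      T_act = 0, T_pot = 0, m_upt = 0, m_collar = 0,
      top_in = 0, bottom_out_w = 0, transp = 0, storage0 = sum(water$theta),
      soil_mass0 = soil_solute_mass(grid, solute, water$theta, sc$compound),
      root_mass0 = root_solute_mass(rsol, rs, sc$uptake),
      deg_soil = 0, deg_root = 0, bot_in_s = 0, bot_out_s = 0,
      wC = 0, w = 0, stressed = 0, steps = 0
    )
  }
  day_acc <- reset_day()
  t <- t0
  eps_t <- 1e-9
  while (t < t1 - eps_t) {
    day <- floor(t + eps_t)
    f <- forc_row(t)
    dt <- min(sc$numerics$dt_max, day + 1 - t, t1 - t)
    # (1) alive segments and mapping
    al <- alive_segments(rs, t + dt)
    have_roots <- nrow(al) > 0
    if (have_roots) {
      new_ids <- setdiff(al$id, tracked)
      rsol <- emerge_segments(rsol, new_ids)
      tracked <- c(tracked, new_ids)
      amap <- full_map[full_map$id %in% al$id, ]
      # (2) xylem solve with soil heads seen by segments
      h_seg <- gather_from_cells(amap, al$id, water$h)
      sol <- solve_xylem(
        rs, h_seg, list(T_pot = f$T_pot, h_crit = sc$numerics$h_crit),
        t = t + dt, table = sc$hydraulics
      )
      sol <- limit_water_uptake(sol, al, amap, grid, water$theta, dt,
                                h_lim = sc$numerics$h_crit)
      S_w <- water_sink_from_roots(sol$q_r, al$id, amap, grid)
      T_act <- attr(sol, "T_act")
    } else {
      sol <- NULL
      S_w <- 0
      T_act <- 0
    }
    # (3) Richards step
    theta_prev <- water$theta
    water <- richards_step(
      grid, water, S_w, f$net_top_flux, f$h_bottom, dt,
      control = sc$numerics$richards
    )
    # (4) radial solute exchange + soil sink
    if (have_roots) {
      i_state <- match(al$id, rsol$ids)
      C_seg <- gather_from_cells(amap, al$id, solute$C)
      C_R_before <- rsol$C_R[i_state]
      exch <- segment_exchange(
        C_seg, C_R_before, sol$J_wr, al$radius, al$length, sc$uptake, dt
      )
      avail <- water$theta * grid$V * solute$C # dissolved mass per cell
      exch <- limit_exchange(exch, C_R_before, al$id, amap, grid, avail,
                             sc$uptake, al)
      rsol$C_R[i_state] <- exch$C_R
      rsol$uptake <- rsol$uptake + sum(exch$mass)
      rsol$soil_return <- rsol$soil_return - sum(pmin(exch$mass, 0))
      S_S <- soil_sink_field(exch$mass, al$id, amap, grid, dt)
    } else {
      exch <- list(mass = 0)
      S_S <- 0
    }
    # (5) soil transport and fate
    solute <- transport_step(
      grid, solute, water, sc$compound, sink = S_S,
      temperature = Tz, dt = dt, theta_prev = theta_prev
    )
    # (6) root advection and collar accrual
    if (have_roots) {
      m_col0 <- rsol$m_collar
      rsol <- root_advection_step(al, sol, rsol, sc$uptake, dt)
      day_acc$m_collar <- day_acc$m_collar + rsol$m_collar - m_col0
      day_acc$deg_root <- day_acc$deg_root + rsol$step_balance$degraded
      day_acc$m_upt <- day_acc$m_upt + sum(exch$mass)
      upt_cells <- S_w * grid$V * dt # water uptake volume per cell
      day_acc$wC <- day_acc$wC + sum(upt_cells * solute$C)
      day_acc$w <- day_acc$w + sum(upt_cells)
      cum_ws_z <- cum_ws_z + colSums(matrix(upt_cells, grid$nx * grid$ny))
      cum_ss_z <- cum_ss_z +
        colSums(matrix(-S_S * grid$V * dt, grid$nx * grid$ny))
      if (attr(sol, "mode") == "head") day_acc$stressed <- day_acc$stressed + dt
    }
    # (7) ledgers
    bal <- water$flux$balance
    day_acc$T_act <- day_acc$T_act + T_act * dt
    day_acc$T_pot <- day_acc$T_pot + f$T_pot * dt
    day_acc$top_in <- day_acc$top_in +
      sum(water$flux$qz[, 1]) * grid$dx * grid$dy * dt
    day_acc$bottom_out_w <- day_acc$bottom_out_w +
      sum(water$flux$qz[, grid$nz + 1]) * grid$dx * grid$dy * dt
    day_acc$transp <- day_acc$transp + sum(S_w) * grid$V * dt
    sb <- solute$step_balance
    day_acc$deg_soil <- day_acc$deg_soil + sb$degraded
    day_acc$bot_in_s <- day_acc$bot_in_s + sb$bottom_in
    day_acc$bot_out_s <- day_acc$bot_out_s + sb$bottom_out
    day_acc$steps <- day_acc$steps + 1
    if (any(!is.finite(solute$C)) || any(!is.finite(water$h))) {
      stop("run_scenario(): non-finite state at t = ", t + dt)
    }
    t <- t + dt
    # day closing
    if (abs(t - round(t)) < eps_t || t >= t1 - eps_t) {
      depth <- rooting_depth(rs, t)
      Cm <- rootzone_mean_concentration(grid, solute$C, water$theta,
                                        max(depth, grid$dz))
      Cma <- rootzone_mean_concentration(grid, solute$C, water$theta,
                                         max(depth, grid$dz), "arithmetic")
      Cflux <- if (day_acc$w > 0) day_acc$wC / day_acc$w else NA_real_
      metrics_rows[[length(metrics_rows) + 1]] <- tibble::tibble(
        day = day, T_act = day_acc$T_act, T_pot = day_acc$T_pot,
        m_upt = day_acc$m_upt, m_collar = day_acc$m_collar,
        C_mean = Cm, C_mean_arith = Cma, C_flux = Cflux,
        rooting_depth = depth, stressed_time = day_acc$stressed
      )
      wled_rows[[length(wled_rows) + 1]] <- tibble::tibble(
        day = day,
        storage_change = (sum(water$theta) - day_acc$storage0) * grid$V,
        top_in = day_acc$top_in, bottom_out = day_acc$bottom_out_w,
        transpiration = day_acc$transp
      )
      soil_mass <- soil_solute_mass(grid, solute, water$theta, sc$compound)
      root_mass <- root_solute_mass(rsol, rs, sc$uptake)
      sled_rows[[length(sled_rows) + 1]] <- tibble::tibble(
        day = day,
        soil_mass_start = day_acc$soil_mass0, soil_mass_end = soil_mass,
        root_mass_start = day_acc$root_mass0, root_mass_end = root_mass,
        collar = day_acc$m_collar,
        degraded_soil = day_acc$deg_soil, degraded_root = day_acc$deg_root,
        bottom_in = day_acc$bot_in_s, bottom_out = day_acc$bot_out_s,
        uptake = day_acc$m_upt
      )
      layer_rows[[length(layer_rows) + 1]] <- dplyr::mutate(
        layer_means(grid, solute, water$theta, reporting_layers(grid)),
        day = day, .before = 1
      )
      if (progress) {
        message(sprintf(
          "day %4d  T_act %.3g cm3  m_collar %.3g g  C_mean %.3g",
          day, day_acc$T_act, day_acc$m_collar, Cm
        ))
      }
      day_acc <- reset_day()
      Tz <- soil_temperature(
        zc_day + t, grid$zc,
        sc$temperature$mean_T, sc$temperature$amplitude,
        sc$temperature$damping_depth, sc$temperature$peak_day
      )
    }
  }
  metrics <- tscf_daily(dplyr::bind_rows(metrics_rows))
  run <- structure(
    list(
      metrics = metrics,
      water_ledger = dplyr::bind_rows(wled_rows),
      solute_ledger = dplyr::bind_rows(sled_rows),
      layer_concentrations = dplyr::bind_rows(layer_rows),
      cum_water_sink_z = cum_ws_z, cum_solute_sink_z = cum_ss_z,
      initial_soil_mass = init_soil_mass,
      water = water, solute = solute, root_solute = rsol,
      grid = grid, rs = rs, scenario = sc, window = c(t0, t1)
    ),
    class = "uptake_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Feddes-style supply limit: a cell cannot be drained below its water
# content at the critical head within one step. Segment uptake is scaled
# by the (length-weighted) cell supply factors and the axial flows are
# rebuilt from the limited radial flows so the network stays balanced.
limit_water_uptake <- function(sol, al, mapping, grid, theta, dt, h_lim,
                               frac = 0.2) {
  demand <- distribute_to_cells(mapping, al$id, pmax(sol$q_r, 0), grid$ncell)
  th_lim <- grid_vg(grid, rep(h_lim, grid$ncell), vg_theta)
  supply <- frac * pmax(theta - th_lim, 0) * grid$V / dt
  over <- demand > supply
  if (any(over)) {
    fac <- rep(1, grid$ncell)
    fac[over] <- supply[over] / demand[over]
    seg_fac <- gather_from_cells(mapping, al$id, fac)
    seg_fac[sol$q_r <= 0] <- 1
    sol$q_r <- sol$q_r * seg_fac
    sol$J_wr <- sol$J_wr * seg_fac
    attr(sol, "T_act") <- sum(sol$q_r)
  }
  # rebuild collar-ward axial flows from radial flows (tips-to-collar sweep)
  parent <- match(al$parent_id, al$id)
  Q <- sol$q_r
  for (i in rev(seq_along(Q))) {
    p <- parent[i]
    if (!is.na(p)) Q[p] <- Q[p] + Q[i]
  }
  sol$Q_ax <- Q
  sol
}

# the five standard reporting layers, clipped to the grid depth
reporting_layers <- function(grid) {
  lb <- tibble::tibble(
    z_top = c(0, -30, -60, -75, -90),
    z_bottom = c(-30, -60, -75, -90, -100)
  )
  lb <- lb[lb$z_top > -grid$Lz + 1e-9, ]
  lb$z_bottom <- pmax(lb$z_bottom, -grid$Lz)
  lb
}

#' @export
print.uptake_run <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf(
    "<uptake_run> %s: days %g-%g, cumulative transpiration %.4g cm3, collar mass %.4g g\n",
    x$scenario$name, x$window[1], x$window[2],
    sum(x$metrics$T_act), x$root_solute$m_collar
  ))
  if (n > 0) {
    last <- x$metrics[n, ]
    cat(sprintf("  last day TSCF %.4g, PUF %.4g\n", last$TSCF, last$PUF))
  }
  invisible(x)
}

#' Write run outputs as CSV
#'
#' @param run an `uptake_run`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(run$water_ledger, file.path(dir, "water_ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(run$solute_ledger, file.path(dir, "solute_ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(run$layer_concentrations,
                   file.path(dir, "layer_concentrations.csv"),
                   row.names = FALSE)
  utils::write.csv(
    tibble::tibble(
      z = run$grid$zc,
      water_uptake = run$cum_water_sink_z,
      solute_uptake = run$cum_solute_sink_z
    ),
    file.path(dir, "cumulative_sinks.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Export a 3D field as a legacy VTK rectilinear grid
#'
#' Plain-text VTK (version 2.0) snapshot of per-cell fields, readable by
#' ParaView and friends.
#'
#' @param grid a [soil_grid()].
#' @param fields named list of per-cell vectors.
#' @param path destination `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_rectilinear <- function(grid, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 2.0", "rhizofate snapshot", "ASCII",
    "DATASET RECTILINEAR_GRID",
    sprintf("DIMENSIONS %d %d %d", grid$nx + 1, grid$ny + 1, grid$nz + 1),
    sprintf("X_COORDINATES %d float", grid$nx + 1),
    paste(seq(0, grid$Lx, by = grid$dx), collapse = " "),
    sprintf("Y_COORDINATES %d float", grid$ny + 1),
    paste(seq(0, grid$Ly, by = grid$dy), collapse = " "),
    sprintf("Z_COORDINATES %d float", grid$nz + 1),
    paste(seq(0, -grid$Lz, by = -grid$dz), collapse = " "),
    sprintf("CELL_DATA %d", grid$ncell)
  ), con)
  for (nm in names(fields)) {
    writeLines(c(
      sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default",
      paste(format(fields[[nm]], digits = 9), collapse = " ")
    ), con)
  }
  invisible(path)
}
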