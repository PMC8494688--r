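#' Soil water state
#'
#' Holds pressure heads, water contents and the inter-cell Darcy fluxes of
#' the last step on a [soil_grid()].
#'
#' @param grid a [soil_grid()].
#' @param h per-cell pressure head, cm: an array `(nx, ny, nz)`, a
#'   per-depth vector of length `nz`, or a scalar.
#' @param time days.
#' @return an object of class `soil_water_state` with elements `h`,
#'   `theta` (consistent with `h` through the retention curve), `time`
#'   and `flux` (NULL until a step has been taken).
#' @export
soil_water_state <- function(grid, h, time = 0) {
  if (length(h) == grid$nz) h <- expand_iz(grid, h)
  h <- rep_len(as.numeric(h), grid$ncell)
  theta <- grid_vg(grid, h, vg_theta)
  structure(
    list(h = h, theta = theta, time = time, flux = NULL),
    class = "soil_water_state"
  )
}

#' Hydrostatic-equilibrium state
#'
#' Zero-flux equilibrium above a prescribed bottom pressure head: uniform
#' total potential, h(z) = h_bottom - (z - z_bottom).
#'
#' @param grid a [soil_grid()].
#' @param h_bottom pressure head at the bottom boundary, cm.
#' @return a [soil_water_state()].
#' @export
hydrostatic_state <- function(grid, h_bottom) {
  soil_water_state(grid, h_bottom - (grid$zc - grid$z_bottom))
}

#' @export
print.soil_water_state <- function(x, ...) {
  cat(sprintf(
    "<soil_water_state> t = %.4g d, h in [%.4g, %.4g] cm, theta in [%.4g, %.4g]\n",
    x$time, min(x$h), max(x$h), min(x$theta), max(x$theta)
  ))
  invisible(x)
}

# cached grid connectivity for the 7-point stencil (faces listed once)
grid_faces <- function(grid) {
  if (!is.null(grid$cache$faces)) return(grid$cache$faces)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  id <- seq_len(grid$ncell)
  faces <- list()
  if (nx > 1) {
    to <- cell_index(grid, (ix %% nx) + 1L, iy, iz)
    faces$x <- list(from = id, to = to, A = grid$dy * grid$dz, d = grid$dx)
  }
  if (ny > 1) {
    to <- cell_index(grid, ix, (iy %% ny) + 1L, iz)
    faces$y <- list(from = id, to = to, A = grid$dx * grid$dz, d = grid$dy)
  }
  if (nz > 1) {
    keep <- iz < nz
    to <- cell_index(grid, ix[keep], iy[keep], iz[keep] + 1L)
    faces$z <- list(from = id[keep], to = to, A = grid$dx * grid$dy, d = grid$dz)
  }
  grid$cache$faces <- faces
  faces
}

top_cells <- function(grid) seq_len(grid$nx * grid$ny)
bottom_cells <- function(grid) {
  grid$ncell - grid$nx * grid$ny + seq_len(grid$nx * grid$ny)
}

#' One implicit Richards step
#'
#' Advances variably saturated flow by `dt` days with a mass-conservative
#' mixed-form modified-Picard scheme (7-point finite volumes, geometric-
#' mean face conductivities, laterally periodic, net-flux top boundary,
#' prescribed-head bottom boundary). On non-convergence the step is
#' recursively halved; exhausting the halving budget raises an error with
#' diagnostics.
#'
#' @param grid a [soil_grid()].
#' @param state a [soil_water_state()].
#' @param sink root water extraction S_w per cell, 1/d (vector of length
#'   `ncell` or scalar 0).
#' @param top_net_flux net surface flux, cm/d, positive = infiltration.
#' @param bottom_head prescribed pressure head at the bottom face, cm.
#' @param dt time step, days (> 0).
#' @param control list: `tol_theta` (Picard water-content increment
#'   tolerance, default 1e-8), `tol_h` (head increment, cm, default 1e-5),
#'   `max_iter` (default 50), `max_halvings` (default 15), `h_atm`
#'   (atmospheric-equilibrium surface head, cm, default -1e5: evaporative
#'   demand ramps to zero as the surface cells dry towards this head),
#'   `dh_max` (Picard head-increment clamp, cm, default 1000).
#' @return the updated `soil_water_state`; element `flux` holds the face
#'   fluxes `qx`, `qy` (periodic, cm/d, positive toward increasing index),
#'   `qz` (dim `nx*ny x (nz+1)`, positive downward, rows 1 and nz+1 the
#'   boundary faces) and `balance` diagnostics.
#' @export
richards_step <- function(grid, state, sink = 0, top_net_flux = 0,
                          bottom_head, dt, control = list()) {
  stopifnot(dt > 0)
  ctl <- utils::modifyList(
    list(tol_theta = 1e-8, tol_h = 1e-5, max_iter = 50, max_halvings = 15,
         h_atm = -1e5, dh_max = 1000),
    control
  )
  sink <- rep_len(sink, grid$ncell)
  if (any(!is.finite(sink))) stop("richards_step(): non-finite sink")
  res <- richards_recurse(grid, state, sink, top_net_flux, bottom_head,
                          dt, ctl, depth = 0)
  res
}

richards_recurse <- function(grid, state, sink, q_top, h_b, dt, ctl, depth) {
  out <- try(richards_once(grid, state, sink, q_top, h_b, dt, ctl),
             silent = TRUE)
  if (!inherits(out, "try-error")) return(out)
  if (depth >= ctl$max_halvings) {
    stop(
      "richards_step(): no convergence after ", ctl$max_iter,
      " Picard iterations and ", depth, " dt halvings (dt = ", dt,
      " d): ", attr(out, "condition")$message
    )
  }
  mid <- richards_recurse(grid, state, sink, q_top, h_b, dt / 2, ctl, depth + 1)
  fin <- richards_recurse(grid, mid, sink, q_top, h_b, dt / 2, ctl, depth + 1)
  # average the face fluxes so that downstream transport sees mean-rate fluxes
  if (!is.null(fin$flux$qx)) fin$flux$qx <- (mid$flux$qx + fin$flux$qx) / 2
  if (!is.null(fin$flux$qy)) fin$flux$qy <- (mid$flux$qy + fin$flux$qy) / 2
  fin$flux$qz <- (mid$flux$qz + fin$flux$qz) / 2
  bm <- mid$flux$balance; bf <- fin$flux$balance
  fin$flux$balance <- list(
    iterations = bm$iterations + bf$iterations,
    max_residual = max(bm$max_residual, bf$max_residual),
    substeps = bm$substeps + bf$substeps,
    storage_change = bm$storage_change + bf$storage_change,
    top_inflow = bm$top_inflow + bf$top_inflow,
    bottom_outflow = bm$bottom_outflow + bf$bottom_outflow,
    sink_volume = bm$sink_volume + bf$sink_volume
  )
  fin
}

richards_once <- function(grid, state, sink, q_top, h_b, dt, ctl) {
  faces <- grid_faces(grid)
  N <- grid$ncell
  z <- expand_iz(grid, grid$zc)
  hn <- state$h
  thn <- state$theta
  h <- hn
  tc <- top_cells(grid)
  bc <- bottom_cells(grid)
  lay_b <- grid$layers[grid$layer_of_iz[grid$nz], ]
  Kb_fixed <- vg_K(h_b, lay_b)
  V <- grid$V
  Atop <- grid$dx * grid$dy
  iter_used <- NA_integer_
  relax <- 1
  prev_mx <- Inf
  # cached assembly pattern: off-diagonals (from,to) and (to,from), then diag
  if (is.null(grid$cache$rich)) {
    fromAll <- unlist(lapply(faces, `[[`, "from"), use.names = FALSE)
    toAll <- unlist(lapply(faces, `[[`, "to"), use.names = FALSE)
    grid$cache$rich <- list(
      fromAll = fromAll, toAll = toAll,
      ii = c(fromAll, toAll, seq_len(N)),
      jj = c(toAll, fromAll, seq_len(N)),
      geom = unlist(lapply(faces, function(f) {
        rep(f$A / (f$d * V), length(f$from))
      }), use.names = FALSE)
    )
  }
  pat <- grid$cache$rich
  for (m in seq_len(ctl$max_iter)) {
    th <- grid_vg(grid, h, vg_theta)
    cap <- grid_vg(grid, h, vg_capacity)
    K <- grid_vg(grid, h, vg_K)
    H <- h + z
    cf <- sqrt(K[pat$fromAll] * K[pat$toAll]) * pat$geom
    flux_div <- cf * (H[pat$toAll] - H[pat$fromAll])
    rhs <- -(th - thn) / dt - sink
    diag_v <- cap / dt
    # within one direction the face from/to indices are duplicate-free,
    # so plain indexed accumulation is safe (and fast)
    o <- 0L
    for (f in faces) {
      nf <- length(f$from)
      sl <- o + seq_len(nf)
      rhs[f$from] <- rhs[f$from] + flux_div[sl]
      rhs[f$to] <- rhs[f$to] - flux_div[sl]
      diag_v[f$from] <- diag_v[f$from] + cf[sl]
      diag_v[f$to] <- diag_v[f$to] + cf[sl]
      o <- o + nf
    }
    # atmospheric limit: evaporative demand ramps to zero as surface dries
    q_top_eff <- rep(q_top, length(tc))
    if (q_top < 0) {
      f_evap <- pmin(1, pmax(0, (h[tc] - ctl$h_atm) / (-0.5 * ctl$h_atm)))
      q_top_eff <- q_top * f_evap
    }
    rhs[tc] <- rhs[tc] + q_top_eff / grid$dz
    # bottom Dirichlet through a half-cell
    Kfb <- sqrt(K[bc] * Kb_fixed)
    cb <- Kfb * Atop / ((grid$dz / 2) * V)
    Hb <- h_b + grid$z_bottom
    rhs[bc] <- rhs[bc] + cb * (Hb - H[bc])
    diag_v[bc] <- diag_v[bc] + cb
    A <- Matrix::sparseMatrix(
      i = pat$ii, j = pat$jj, x = c(-cf, -cf, diag_v), dims = c(N, N)
    )
    dh <- richards_solve(grid, A, rhs)
    dh <- pmin(pmax(dh, -ctl$dh_max), ctl$dh_max)
    # adaptive under-relaxation: damp only on clear growth (oscillation)
    mx <- max(abs(dh))
    if (m > 3 && mx > 1.5 * prev_mx) relax <- max(relax * 0.5, 0.2)
    else relax <- min(1, relax * 2)
    prev_mx <- mx
    h <- h + relax * dh
    if (max(abs(cap * dh)) < ctl$tol_theta && max(abs(dh)) < ctl$tol_h) {
      iter_used <- m
      break
    }
  }
  if (is.na(iter_used)) stop("Picard iteration did not converge")
  theta <- grid_vg(grid, h, vg_theta)
  K <- grid_vg(grid, h, vg_K)
  H <- h + z
  nxy <- grid$nx * grid$ny
  if (q_top < 0) {
    q_top_eff <- q_top *
      pmin(1, pmax(0, (h[tc] - ctl$h_atm) / (-0.5 * ctl$h_atm)))
  } else {
    q_top_eff <- rep(q_top, length(tc))
  }
  qx <- qy <- NULL
  if (!is.null(faces$x)) {
    qx <- sqrt(K[faces$x$from] * K[faces$x$to]) *
      (H[faces$x$from] - H[faces$x$to]) / grid$dx
  }
  if (!is.null(faces$y)) {
    qy <- sqrt(K[faces$y$from] * K[faces$y$to]) *
      (H[faces$y$from] - H[faces$y$to]) / grid$dy
  }
  qz <- matrix(0, nxy, grid$nz + 1)
  qz[, 1] <- q_top_eff
  if (!is.null(faces$z)) {
    qzi <- sqrt(K[faces$z$from] * K[faces$z$to]) *
      (H[faces$z$from] - H[faces$z$to]) / grid$dz
    qz[, 2:grid$nz] <- matrix(qzi, nxy, grid$nz - 1)
  }
  Kfb <- sqrt(K[bc] * Kb_fixed)
  qz[, grid$nz + 1] <- Kfb * (H[bc] - (h_b + grid$z_bottom)) / (grid$dz / 2)
  # per-cell closure residual (should be at the Picard tolerance)
  div <- face_divergence(grid, qx, qy, qz)
  resid <- (theta - state$theta) / dt - div + sink
  balance <- list(
    iterations = iter_used,
    max_residual = max(abs(resid)),
    substeps = 1L,
    storage_change = sum(theta - state$theta) * V,
    top_inflow = sum(qz[, 1]) * Atop * dt,
    bottom_outflow = sum(qz[, grid$nz + 1]) * Atop * dt,
    sink_volume = sum(sink) * V * dt
  )
  structure(
    list(
      h = h, theta = theta, time = state$time + dt,
      flux = list(qx = qx, qy = qy, qz = qz, balance = balance)
    ),
    class = "soil_water_state"
  )
}

# SPD solve for the Picard linear systems. A Cholesky factorisation is
# kept as a frozen preconditioner for conjugate gradients and only
# refreshed when CG convergence degrades: the system changes slowly
# between Picard iterations and steps, so one factorisation serves many
# solves (important on large grids where a factorisation costs seconds).
richards_solve <- function(grid, A, rhs, tol = 1e-10, maxit = 60) {
  cache <- grid$cache
  refresh <- function() {
    As <- Matrix::forceSymmetric(A)
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(As, LDL = FALSE, super = TRUE)
    } else {
      cache$chol <- Matrix::update(cache$chol, As)
    }
    cache$fresh <- TRUE
  }
  if (grid$ncell <= 50000) {
    # small systems: a fresh numeric factorisation is cheap, solve exactly
    refresh()
    return(as.numeric(Matrix::solve(cache$chol, rhs)))
  }
  if (is.null(cache$chol) || isTRUE(cache$stale)) {
    refresh()
    cache$stale <- FALSE
  }
  rhs_norm <- sqrt(sum(rhs^2))
  if (rhs_norm == 0) return(numeric(length(rhs)))
  target <- max(tol * rhs_norm, 1e-300)
  for (attempt in 1:2) {
    x <- numeric(length(rhs))
    r <- rhs
    z <- as.numeric(Matrix::solve(cache$chol, r))
    p <- z
    rz <- sum(r * z)
    used <- maxit
    for (it in seq_len(maxit)) {
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) <= target) {
        used <- it
        break
      }
      z <- as.numeric(Matrix::solve(cache$chol, r))
      rz2 <- sum(r * z)
      p <- z + (rz2 / rz) * p
      rz <- rz2
    }
    if (sqrt(sum(r^2)) <= target) {
      # schedule a refresh if the preconditioner is drifting
      cache$stale <- used > 20
      return(x)
    }
    if (attempt == 1) refresh() else break
  }
  # exact fallback with the just-refreshed factorisation
  as.numeric(Matrix::solve(cache$chol, rhs))
}

# net inflow per unit cell volume (1/d) from face fluxes
face_divergence <- function(grid, qx, qy, qz) {
  N <- grid$ncell
  faces <- grid_faces(grid)
  div <- numeric(N)
  if (!is.null(qx)) {
    fl <- qx * faces$x$A / grid$V
    div[faces$x$from] <- div[faces$x$from] - fl
    div[faces$x$to] <- div[faces$x$to] + fl
  }
  if (!is.null(qy)) {
    fl <- qy * faces$y$A / grid$V
    div[faces$y$from] <- div[faces$y$from] - fl
    div[faces$y$to] <- div[faces$y$to] + fl
  }
  nxy <- grid$nx * grid$ny
  qzm <- qz # nxy x nz+1, positive down
  inflow <- qzm[, seq_len(grid$nz), drop = FALSE]
  outflow <- qzm[, seq_len(grid$nz) + 1, drop = FALSE]
  div <- div + as.numeric(inflow - outflow) / grid$dz
  div
}

# sum `x` into bins given by index `g` over 1..N (dense result)
tapply2 <- function(x, g, N) {
  out <- numeric(N)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- as.numeric(agg)
  out
}

#' Root water sink field
#'
#' Distributes per-segment radial volumetric uptake onto the soil grid:
#' S_w(cell) = sum_i q_r,i * fraction_i / V_cell.
#'
#' @param q_r per-segment radial volumetric rates, cm^3/d, aligned with
#'   `ids`.
#' @param ids segment ids aligned with `q_r`.
#' @param mapping a [map_segments_to_grid()] result.
#' @param grid the [soil_grid()].
#' @return per-cell sink, 1/d (vector of length `ncell`).
#' @export
water_sink_from_roots <- function(q_r, ids, mapping, grid) {
  distribute_to_cells(mapping, ids, q_r, grid$ncell) / grid$V
}
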