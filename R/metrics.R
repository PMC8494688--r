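#' Within-root Peclet number
#'
#' Ratio of convective to diffusive solute transport over one root
#' diameter, Pe = d v / D. Values well above 1 justify neglecting axial
#' diffusion inside the xylem.
#'
#' @param d root diameter, cm.
#' @param v axial convective velocity, cm/d.
#' @param D aqueous diffusion coefficient, cm^2/d (> 0).
#' @return Peclet number (-), vectorised.
#' @export
peclet <- function(d, v, D) {
  if (any(D <= 0)) stop("peclet(): D must be positive")
  d * v / D
}

#' Daily TSCF and PUF
#'
#' Transpiration stream concentration factor and plant uptake factor of a
#' daily record: TSCF = (m_collar / T_act) / C_mean and
#' PUF = (m_upt / T_act) / C_mean, with `C_mean` the mean dissolved soil
#' concentration over the root zone (surface down to the day's maximum
#' rooting depth). Days without transpiration leave the metric undefined
#' (NA), not zero.
#'
#' @param record a data frame with columns `m_collar` (g, mass reaching
#'   the collar that day), `m_upt` (g, net mass entering the root system),
#'   `T_act` (cm^3, water transpired) and `C_mean` (g/cm^3).
#' @return the input tibble with `TSCF` and `PUF` columns appended.
#' @export
tscf_daily <- function(record) {
  record <- tibble::as_tibble(record)
  ok <- record$T_act > 0 & record$C_mean > 0
  record$TSCF <- ifelse(ok, (record$m_collar / record$T_act) / record$C_mean, NA_real_)
  record$PUF <- ifelse(ok, (record$m_upt / record$T_act) / record$C_mean, NA_real_)
  record
}

#' @rdname tscf_daily
#' @export
puf_daily <- tscf_daily

#' Mean root-zone concentration
#'
#' Water-volume-weighted (default) or arithmetic mean dissolved
#' concentration over all cells from the surface down to `depth`.
#'
#' @param grid a [soil_grid()].
#' @param C per-cell dissolved concentration.
#' @param theta per-cell water content.
#' @param depth positive depth, cm.
#' @param weighting `"water"` (default) or `"arithmetic"`.
#' @return mean concentration, g/cm^3.
#' @export
rootzone_mean_concentration <- function(grid, C, theta, depth,
                                        weighting = c("water", "arithmetic")) {
  weighting <- match.arg(weighting)
  z <- expand_iz(grid, grid$zc)
  idx <- z >= -max(depth, grid$dz) - 1e-12
  if (weighting == "water") {
    sum(theta[idx] * C[idx]) / sum(theta[idx])
  } else {
    mean(C[idx])
  }
}

#' Cumulative water and solute sink depth profiles
#'
#' Time-integrated root water extraction and solute uptake per depth
#' layer, from the per-depth accumulators of a simulation run.
#'
#' @param run an `uptake_run` (see [run_scenario()]).
#' @param layer_bounds data frame with `z_top`, `z_bottom` (cm); default:
#'   the run's native grid layers of 1 cell thickness aggregated to the
#'   five standard reporting layers down to 100 cm.
#' @return a tibble `z_top`, `z_bottom`, `water_uptake` (cm^3),
#'   `solute_uptake` (g).
#' @export
layer_cumulative_sinks <- function(run, layer_bounds = NULL) {
  if (is.null(layer_bounds)) {
    layer_bounds <- tibble::tibble(
      z_top = c(0, -30, -60, -75, -90),
      z_bottom = c(-30, -60, -75, -90, -100)
    )
  }
  zc <- run$grid$zc
  out <- tibble::as_tibble(layer_bounds)
  pick <- function(acc) {
    vapply(seq_len(nrow(out)), function(k) {
      idx <- zc <= out$z_top[k] + 1e-12 & zc >= out$z_bottom[k] - 1e-12
      sum(acc[idx])
    }, numeric(1))
  }
  out$water_uptake <- pick(run$cum_water_sink_z)
  out$solute_uptake <- pick(run$cum_solute_sink_z)
  out
}

#' Mass-balance report of a run
#'
#' Per-day and cumulative ledgers of the soil and root solute pools:
#' soil mass, root mass, collar mass, degraded mass and boundary fluxes,
#' with the relative closure error. A closure error above `tol` is
#' flagged.
#'
#' @param run an `uptake_run`.
#' @param tol flag threshold on the relative closure error (default
#'   1e-4).
#' @return a tibble (one row per day plus attributes `closure` and
#'   `flagged`).
#' @export
mass_balance_report <- function(run, tol = 1e-4) {
  led <- run$solute_ledger
  initial <- led$soil_mass_start[1] + led$root_mass_start[1]
  expected <- initial + cumsum(led$bottom_in) - cumsum(led$bottom_out)
  actual <- led$soil_mass_end + led$root_mass_end + cumsum(led$collar) +
    cumsum(led$degraded_soil) + cumsum(led$degraded_root)
  scale <- pmax(abs(expected), abs(actual), 1e-300)
  closure <- abs(actual - expected) / scale
  out <- tibble::tibble(
    day = led$day,
    soil_mass = led$soil_mass_end,
    root_mass = led$root_mass_end,
    collar_mass = cumsum(led$collar),
    degraded_mass = cumsum(led$degraded_soil) + cumsum(led$degraded_root),
    bottom_in = cumsum(led$bottom_in),
    bottom_out = cumsum(led$bottom_out),
    closure_error = closure
  )
  attr(out, "closure") <- max(closure)
  attr(out, "flagged") <- max(closure) > tol
  out
}
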