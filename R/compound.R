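#' Compound properties
#'
#' Physico-chemical and fate parameters of the simulated compound, in
#' cm-day-gram units. Degradation follows the first-order rate `k_ref`
#' (from `half_life`) at reference conditions (moisture `theta_ref`,
#' 20 degC, topsoil), modified by moisture, temperature and depth factors
#' (see [degradation_rate()]).
#'
#' @param logKow base-10 octanol-water partition coefficient (-).
#' @param D aqueous diffusion coefficient, cm^2/d.
#' @param K_D sorption partition coefficient in soil, cm^3/g (scalar or
#'   one value per soil layer).
#' @param half_life degradation half-life at reference conditions, days
#'   (Inf = no degradation).
#' @param theta_ref reference water content for the moisture factor (-).
#' @param moisture_exponent exponent B of the moisture factor (default
#'   0.7).
#' @param temp_coefficient Arrhenius-type coefficient alpha (1/K) of
#'   f_T = exp(alpha (T - 20)), default 0.0948 (Q10 about 2.6).
#' @param depth_factor data frame with `z_top`, `z_bottom` (cm, <= 0) and
#'   `f` in `[0, 1]`: the depth modifier of degradation; depths not
#'   covered get f = 0.
#' @return a list of class `compound_properties`.
#' @export
compound_properties <- function(logKow, D = 0.43, K_D = 0,
                                half_life = Inf, theta_ref = 0.3,
                                moisture_exponent = 0.7,
                                temp_coefficient = 0.0948,
                                depth_factor = default_depth_factor()) {
  stopifnot(is.finite(logKow), D > 0, all(K_D >= 0), half_life > 0)
  if (any(depth_factor$f < 0 | depth_factor$f > 1)) {
    stop("compound_properties(): depth factors must lie in [0, 1]")
  }
  structure(
    list(
      logKow = logKow, D = D, K_D = K_D,
      k_ref = log(2) / half_life,
      theta_ref = theta_ref, moisture_exponent = moisture_exponent,
      temp_coefficient = temp_coefficient,
      depth_factor = tibble::as_tibble(depth_factor)
    ),
    class = "compound_properties"
  )
}

#' @rdname compound_properties
#' @export
default_depth_factor <- function() {
  tibble::tibble(
    z_top = c(0, -30, -60), z_bottom = c(-30, -60, -100),
    f = c(1, 0.5, 0.3)
  )
}

#' FOCUS-style readily degradable, marginally volatile dummy compound
#'
#' Defaults for the moderately polar test substance used in the shipped
#' scenarios: half-life 20 d at reference conditions, weak sorption, and
#' a lipophilicity whose two-resistance root permeability evaluates to
#' 13.4 cm/d (see [permeability_from_logkow()]).
#'
#' @param ... overrides passed to [compound_properties()].
#' @return a `compound_properties` object.
#' @export
dummy_substance_b <- function(...) {
  args <- utils::modifyList(
    list(logKow = 1.41, D = 0.43, K_D = 0.2, half_life = 20, theta_ref = 0.3),
    list(...)
  )
  do.call(compound_properties, args)
}

#' Two-resistance root membrane permeability from lipophilicity
#'
#' The overall permeability of the cell-wall + membrane pathway:
#' log10 P_M = 1.20 logKow - 7.50 (P_M in m/s), combined in series with
#' the cell-wall permeability P_W: P = 1 / (1/P_W + 1/P_M).
#'
#' @param logKow octanol-water partition coefficient, log10.
#' @param P_W cell-wall permeability, m/s (default 2.5e-4).
#' @param units `"cm_d"` (default) or `"m_s"` for the returned value.
#' @return overall root permeability P.
#' @export
permeability_from_logkow <- function(logKow, P_W = 2.5e-4, units = "cm_d") {
  units <- match.arg(units, c("cm_d", "m_s"))
  P_M <- 10^(1.20 * logKow - 7.50)
  P <- 1 / (1 / P_W + 1 / P_M)
  if (units == "cm_d") ms_to_cmd(P) else P
}

#' First-order soil degradation rate under local conditions
#'
#' k_S = k_ref * min(1, (theta/theta_ref)^B) * f_T(T) * f_z(z), with
#' f_T = exp(alpha (T - 20 degC)) for T > 0 degC and 0 below freezing
#' (normalised to 1 at 20 degC), and f_z a piecewise-constant depth
#' factor (0 where the table has no entry).
#'
#' @param compound a [compound_properties()].
#' @param theta soil water content (-), vectorised.
#' @param temperature soil temperature, degC, vectorised.
#' @param z elevation, cm (<= 0), vectorised.
#' @return degradation rate, 1/d.
#' @export
degradation_rate <- function(compound, theta, temperature, z) {
  if (any(theta < 0)) stop("degradation_rate(): negative water content")
  n <- max(length(theta), length(temperature), length(z))
  theta <- rep_len(theta, n)
  temperature <- rep_len(temperature, n)
  z <- rep_len(z, n)
  f_m <- pmin(1, (theta / compound$theta_ref)^compound$moisture_exponent)
  f_T <- ifelse(temperature > 0,
                exp(compound$temp_coefficient * (temperature - 20)), 0)
  df <- compound$depth_factor
  f_z <- numeric(n)
  for (k in seq_len(nrow(df))) {
    idx <- z <= df$z_top[k] + 1e-12 & z > df$z_bottom[k] - 1e-12
    f_z[idx] <- df$f[k]
  }
  compound$k_ref * f_m * f_T * f_z
}

#' Depth-damped sinusoidal soil temperature
#'
#' Synthetic soil temperature forcing: an annual sine at the surface,
#' exponentially damped and phase-lagged with depth.
#'
#' @param day day of year (or days after planting plus an offset).
#' @param z elevation, cm (<= 0).
#' @param mean_T annual mean, degC.
#' @param amplitude surface annual amplitude, degC.
#' @param damping_depth e-folding depth, cm.
#' @param peak_day day of the surface maximum.
#' @return temperature, degC (vectorised over `day` and `z`).
#' @export
soil_temperature <- function(day, z, mean_T = 10, amplitude = 9,
                             damping_depth = 180, peak_day = 200) {
  depth <- -z
  mean_T + amplitude * exp(-depth / damping_depth) *
    cos(2 * pi * (day - peak_day) / 365 - depth / damping_depth)
}
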