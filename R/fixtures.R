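#' Hamburg-like layered soil profile
#'
#' Synthetic sandy-loam-over-sand van Genuchten profile shaped like the
#' northern-German regulatory leaching scenario (2.6 % organic matter in
#' the plough layer, organic matter and sorption decreasing with depth).
#' These are stand-in values, not a transcription of any published table.
#'
#' @return a [vg_layers()] table covering 0 to -150 cm.
#' @export
hamburg_like_layers <- function() {
  vg_layers(tibble::tibble(
    z_top = c(0, -30, -60),
    z_bottom = c(-30, -60, -150),
    theta_r = c(0.06, 0.05, 0.04),
    theta_s = c(0.43, 0.39, 0.36),
    alpha = c(0.035, 0.035, 0.04),
    n = c(1.45, 1.70, 2.00),
    K_s = c(60, 120, 200),
    l = 0.5,
    rho_b = c(1.45, 1.55, 1.60),
    tau = 0.5
  ))
}

#' Synthetic growing-season forcing
#'
#' Daily net top flux, potential transpiration and bottom pressure head
#' with the qualitative structure of a summer cropping season: an early
#' dry spell with rising transpiration demand, one large rainfall event
#' around day 80, and a second dry period before harvest.
#'
#' @param days number of forcing days (default 139).
#' @param peak_T peak potential transpiration, cm^3/d per plant.
#' @param h_bottom bottom boundary head, cm.
#' @return forcing tibble for [scenario()].
#' @export
season_forcing <- function(days = 139, peak_T = 0.45, h_bottom = -80) {
  day <- seq_len(days) - 1
  # sinusoidal crop development between emergence and harvest
  dev <- sin(pmin(pmax(day / 120, 0), 1) * pi)^1.5
  T_pot <- peak_T * dev
  rain <- numeric(days)
  rain[day %% 7 == 3 & day < 45] <- 0.25 # light early showers
  rain[day == 80] <- 4.0 # the large mid-season event
  rain[day %in% c(81, 82)] <- 1.0
  rain[day %% 10 == 5 & day > 95] <- 0.15 # sparse late showers
  evap <- 0.08 + 0.07 * dev
  tibble::tibble(
    day = day,
    net_top_flux = rain - evap,
    T_pot = T_pot,
    h_bottom = h_bottom
  )
}

#' Single vertical root column scenario
#'
#' A 0.9 x 0.9 x 145 cm^3 column (0.1 x 0.1 x 1 cm^3 cells) with one
#' vertical root growing to 100 cm by day 89: root length density about
#' 1.2 cm cm^-3 at full development, hydraulically uniform root
#' (Lr = 2e-4 cm d^-1 cm^-1, Kx = 0.5 cm^4 d^-1 cm^-1, tuned for a
#' uniform standard uptake fraction), advective uptake fraction 0.5 by
#' default, and the readily degradable dummy compound applied to the top
#' 30 cm.
#'
#' @param epsilon advective uptake fraction (default 0.5).
#' @param P root permeability, cm/d or `"from_logkow"` (default 0).
#' @param days forcing length (default 139).
#' @param nz number of 1-cm cells (default 145; smaller values truncate
#'   the column for quick tests and move the bottom boundary up).
#' @param dose_kg_ha applied mass expressed as a field rate, kg/ha,
#'   mixed uniformly into the top 30 cm of water (default 1).
#' @return a [scenario()].
#' @export
make_single_root_scenario <- function(epsilon = 0.5, P = 0, days = 139,
                                      nz = 145, dose_kg_ha = 1) {
  compound <- dummy_substance_b()
  layers <- hamburg_like_layers()
  # dose: kg/ha -> g/cm^2, dissolved in the top-30-cm water at theta ~ 0.25
  C0 <- rep(0, nz)
  top <- seq_len(min(30, nz))
  C0[top] <- dose_kg_ha * 1e-5 / (30 * 0.25)
  scenario(
    domain = list(nx = 9, ny = 9, nz = nz, dx = 0.1, dy = 0.1, dz = 1),
    layers = layers,
    compound = compound,
    uptake = uptake_parameters(epsilon = epsilon, P = P, compound = compound),
    hydraulics = constant_hydraulics(2e-4, 0.5),
    root = list(
      type = "single", final_depth = min(100, nz - 5), days_to_final = 89,
      radius = 0.003, segment_length = 1
    ),
    forcing = season_forcing(days, peak_T = 0.45),
    initial = list(h = "hydrostatic", C = C0, C_bottom = 1e-10),
    numerics = list(dt_max = if (is.numeric(P) && P == 0) 0.1 else 0.01),
    name = "single_root"
  )
}

#' Complex stochastic root architecture scenario
#'
#' A 75 x 15 x 145 cm^3 periodic domain with 1 cm^3 cells and a
#' stochastic maize-like root system (orders 0-2, root length density
#' about 0.1 cm cm^-3 at full development) with age- and order-dependent
#' hydraulics.
#'
#' @param seed generator seed.
#' @param epsilon advective uptake fraction.
#' @param P root permeability, cm/d.
#' @param days forcing length.
#' @param dose_kg_ha applied field rate, kg/ha, in the top 30 cm.
#' @return a [scenario()].
#' @export
make_complex_rsa_scenario <- function(seed, epsilon = 0.5, P = 0,
                                      days = 139, dose_kg_ha = 1) {
  compound <- dummy_substance_b()
  C0 <- rep(0, 145)
  C0[1:30] <- dose_kg_ha * 1e-5 / (30 * 0.25)
  scenario(
    domain = list(nx = 75, ny = 15, nz = 145, dx = 1, dy = 1, dz = 1),
    layers = hamburg_like_layers(),
    compound = compound,
    uptake = uptake_parameters(epsilon = epsilon, P = P, compound = compound),
    hydraulics = maize_hydraulics(),
    root = list(type = "stochastic", params = maize_root_params(), seed = seed),
    forcing = season_forcing(days, peak_T = 500),
    initial = list(h = "hydrostatic", C = C0, C_bottom = 1e-10),
    numerics = list(dt_max = if (P == 0) 0.1 else 0.01),
    name = sprintf("complex_rsa_seed%d", seed)
  )
}

#' Small uniform-concentration property-test scenario
#'
#' A single-cell-column toy domain (1 x 1 x 30 cells of 3 x 3 x 1 cm)
#' with uniform initial concentration, steady transpiration through a
#' 20-cm hydraulically well-supplied root, no degradation and no
#' sorption: the test bed on which purely advective uptake must give a
#' steady daily TSCF equal to the advective fraction, and high-P
#' diffusive uptake must approach the fully advective run.
#'
#' @param epsilon advective uptake fraction.
#' @param P root permeability, cm/d.
#' @param days forcing days (default 6).
#' @param T_steady steady potential transpiration, cm^3/d (default 0.3).
#' @param C0 uniform initial dissolved concentration, g/cm^3.
#' @return a [scenario()].
#' @export
make_toy_uniform_scenario <- function(epsilon, P, days = 6, T_steady = 0.3,
                                      C0 = 1e-6) {
  compound <- compound_properties(logKow = 1.41, D = 0.43, K_D = 0,
                                  half_life = Inf)
  layers <- vg_layers(tibble::tibble(
    z_top = 0, z_bottom = -40, theta_r = 0.05, theta_s = 0.40,
    alpha = 0.02, n = 1.8, K_s = 50, l = 0.5, rho_b = 1.5, tau = 0.5
  ))
  scenario(
    domain = list(nx = 1, ny = 1, nz = 30, dx = 3, dy = 3, dz = 1),
    layers = layers,
    compound = compound,
    uptake = uptake_parameters(epsilon = epsilon, P = P, compound = compound),
    hydraulics = constant_hydraulics(5e-3, 0.5),
    root = list(type = "single", final_depth = 20, days_to_final = 1e-6,
                radius = 0.05, segment_length = 1,
                collar = c(1.5, 1.5, 0)),
    forcing = tibble::tibble(
      day = seq_len(days) - 1, net_top_flux = 0,
      T_pot = T_steady, h_bottom = -25
    ),
    initial = list(h = "hydrostatic", C = C0, C_bottom = C0),
    numerics = list(dt_max = if (P == 0) 0.05 else 0.01),
    name = sprintf("toy_uniform_eps%g_P%g", epsilon, P)
  )
}

#' Top-heavy concentration / deep water uptake toy scenario
#'
#' A 60-cm toy column whose solute sits in the top 15 cm while the top
#' soil is dry and the subsoil wet, so that water uptake happens at
#' depth: with a high membrane permeability, solute diffuses into the
#' root near the surface and is flushed to the collar by deep water,
#' producing daily TSCF values above 1.
#'
#' @param P root permeability, cm/d (default the lipophilicity-derived
#'   13.4 of the dummy compound).
#' @param epsilon advective fraction (default 0, purely diffusive).
#' @param days forcing days (default 4).
#' @return a [scenario()].
#' @export
make_top_heavy_scenario <- function(P = NULL, epsilon = 0, days = 4) {
  compound <- dummy_substance_b(half_life = Inf, K_D = 0)
  if (is.null(P)) P <- permeability_from_logkow(compound$logKow)
  layers <- vg_layers(tibble::tibble(
    z_top = 0, z_bottom = -70, theta_r = 0.05, theta_s = 0.40,
    alpha = 0.02, n = 1.8, K_s = 30, l = 0.5, rho_b = 1.5, tau = 0.5
  ))
  h0 <- c(rep(-3000, 20), rep(-300, 10), rep(-60, 30)) # dry top, wet subsoil
  C0 <- c(rep(2e-6, 15), rep(1e-9, 45))
  scenario(
    domain = list(nx = 1, ny = 1, nz = 60, dx = 3, dy = 3, dz = 1),
    layers = layers,
    compound = compound,
    uptake = uptake_parameters(epsilon = epsilon, P = P, compound = compound),
    hydraulics = constant_hydraulics(5e-3, 0.5),
    root = list(type = "single", final_depth = 50, days_to_final = 1e-6,
                radius = 0.05, segment_length = 1,
                collar = c(1.5, 1.5, 0)),
    forcing = tibble::tibble(
      day = seq_len(days) - 1, net_top_flux = 0,
      T_pot = 0.3, h_bottom = -50
    ),
    initial = list(h = h0, C = C0, C_bottom = 1e-9),
    numerics = list(dt_max = 0.01),
    name = "top_heavy"
  )
}
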