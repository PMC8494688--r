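#' Van Genuchten-Mualem soil hydraulic layers
#'
#' Constructs a validated table of layered van Genuchten-Mualem parameters.
#' Layers must tile the soil column contiguously from the surface (z = 0,
#' elevations negative downward) to the domain bottom.
#'
#' @param layers a data frame with one row per layer and columns
#'   `z_top`, `z_bottom` (cm, z_top > z_bottom, both <= 0), `theta_r`,
#'   `theta_s` (-), `alpha` (1/cm), `n` (-), `K_s` (cm/d) and optionally
#'   `l` (Mualem tortuosity exponent, default 0.5), `rho_b` (dry bulk
#'   density, g/cm^3, default 1.5) and `tau` (solute diffusion impedance
#'   factor, default 0.5).
#' @return a tibble of class `vg_layers`.
#' @export
vg_layers <- function(layers) {
  layers <- tibble::as_tibble(layers)
  need <- c("z_top", "z_bottom", "theta_r", "theta_s", "alpha", "n", "K_s")
  miss <- setdiff(need, names(layers))
  if (length(miss) > 0) {
    stop("vg_layers(): missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"l" %in% names(layers)) layers$l <- 0.5
  if (!"rho_b" %in% names(layers)) layers$rho_b <- 1.5
  if (!"tau" %in% names(layers)) layers$tau <- 0.5
  layers <- dplyr::arrange(layers, dplyr::desc(.data$z_top))
  with(layers, {
    if (any(theta_r < 0 | theta_r >= theta_s | theta_s > 1)) {
      stop("vg_layers(): need 0 <= theta_r < theta_s <= 1")
    }
    if (any(alpha <= 0) || any(n <= 1) || any(K_s <= 0)) {
      stop("vg_layers(): need alpha > 0, n > 1, K_s > 0")
    }
  })
  if (layers$z_top[1] != 0) stop("vg_layers(): first layer must start at z = 0")
  if (nrow(layers) > 1 &&
      any(abs(layers$z_bottom[-nrow(layers)] - layers$z_top[-1]) > 1e-9)) {
    stop("vg_layers(): layers must tile the column without gaps or overlap")
  }
  layers$m <- 1 - 1 / layers$n
  class(layers) <- c("vg_layers", class(layers))
  layers
}

#' Read a layer table from CSV
#'
#' @param path path to a CSV with the columns documented in [vg_layers()].
#' @return a `vg_layers` tibble.
#' @export
read_vg_layers <- function(path) {
  vg_layers(utils::read.csv(path))
}

#' Water retention and unsaturated conductivity
#'
#' Standard van Genuchten retention theta(h) and Mualem conductivity K(h).
#' For h >= 0 the soil is saturated: theta = theta_s and K = K_s.
#'
#' @param h pressure head, cm (negative = unsaturated); vectorised.
#' @param layer one row of a [vg_layers()] table (or a list with the same
#'   fields).
#' @return water content (-) for `vg_theta`, conductivity (cm/d) for `vg_K`,
#'   specific moisture capacity d(theta)/dh (1/cm) for `vg_capacity`,
#'   effective saturation (-) for `vg_se`.
#' @export
vg_theta <- function(h, layer) {
  layer$theta_r + (layer$theta_s - layer$theta_r) * vg_se(h, layer)
}

#' @rdname vg_theta
#' @export
vg_se <- function(h, layer) {
  se <- (1 + abs(layer$alpha * h)^layer$n)^(-layer$m)
  se[h >= 0] <- 1
  se
}

#' @rdname vg_theta
#' @export
vg_K <- function(h, layer) {
  se <- vg_se(h, layer)
  K <- layer$K_s * se^layer$l * (1 - (1 - se^(1 / layer$m))^layer$m)^2
  K[h >= 0] <- layer$K_s
  pmax(K, 1e-12)
}

#' @rdname vg_theta
#' @export
vg_capacity <- function(h, layer) {
  a <- layer$alpha
  n <- layer$n
  m <- layer$m
  ah <- abs(a * h)
  cap <- (layer$theta_s - layer$theta_r) * a * m * n * ah^(n - 1) *
    (1 + ah^n)^(-m - 1)
  cap[h >= 0] <- 0
  cap
}

#' Invert the retention curve
#'
#' Pressure head at a given effective saturation; used to set initial states.
#'
#' @param se effective saturation in (0, 1].
#' @param layer a layer row as in [vg_theta()].
#' @return pressure head, cm (0 at se = 1).
#' @export
vg_head <- function(se, layer) {
  stopifnot(all(se > 0), all(se <= 1))
  h <- -(se^(-1 / layer$m) - 1)^(1 / layer$n) / layer$alpha
  h[se >= 1] <- 0
  h
}
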