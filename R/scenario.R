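#' Simulation scenario
#'
#' Bundles domain, soil, compound, uptake, root source, forcing and
#' numerics into a validated scenario object. Units are cm-day-gram
#' throughout.
#'
#' @param domain list: `nx, ny, nz, dx, dy, dz` (cells and edges, cm).
#' @param layers a [vg_layers()] table (or data frame).
#' @param compound a [compound_properties()].
#' @param uptake an [uptake_parameters()] (or a list of arguments for it;
#'   `P = "from_logkow"` is resolved against `compound`).
#' @param hydraulics a [hydraulic_table()].
#' @param root a [root_system()], or a list describing the source:
#'   `list(type = "single", final_depth, radius, ...)`,
#'   `list(type = "stochastic", params, seed)` or
#'   `list(type = "rsml", path, ...)`.
#' @param forcing tibble with columns `day` (0-based, contiguous),
#'   `net_top_flux` (cm/d, positive = infiltration), `T_pot` (cm^3/d per
#'   plant) and `h_bottom` (cm); values are piecewise-constant per day.
#' @param initial list: `h` (`"hydrostatic"`, per-depth vector or scalar),
#'   `C` (per-depth vector or scalar, g/cm^3), `C_bottom` (g/cm^3).
#' @param numerics list: `dt_max` (days; default 0.1 for purely advective
#'   uptake, 0.01 when P > 0), `h_crit` (collar limit, cm, default
#'   -15000), `richards` control list (see [richards_step()]),
#'   `max_segment_length` (cm; default: vertical cell edge).
#' @param temperature list for the [soil_temperature()] forcing:
#'   `mean_T`, `amplitude`, `damping_depth`, `peak_day`, `planting_doy`
#'   (day of year of planting, default 124).
#' @param name scenario label.
#' @return an object of class `scenario`.
#' @export
scenario <- function(domain, layers, compound, uptake, hydraulics, root,
                     forcing, initial = list(), numerics = list(),
                     temperature = list(), name = "scenario") {
  need <- c("nx", "ny", "nz", "dx", "dy", "dz")
  if (!all(need %in% names(domain))) {
    stop("scenario(): domain needs ", paste(need, collapse = ", "))
  }
  layers <- if (inherits(layers, "vg_layers")) layers else vg_layers(layers)
  if (!inherits(compound, "compound_properties")) {
    stop("scenario(): compound must be compound_properties()")
  }
  if (!inherits(uptake, "uptake_parameters")) {
    uptake <- do.call(uptake_parameters, c(uptake, list(compound = compound)))
  }
  if (!inherits(hydraulics, "hydraulic_table")) {
    stop("scenario(): hydraulics must be a hydraulic_table()")
  }
  forcing <- tibble::as_tibble(forcing)
  fneed <- c("day", "net_top_flux", "T_pot", "h_bottom")
  miss <- setdiff(fneed, names(forcing))
  if (length(miss) > 0) {
    stop("scenario(): forcing misses columns ", paste(miss, collapse = ", "))
  }
  if (any(diff(forcing$day) != 1)) {
    stop("scenario(): forcing days must be contiguous")
  }
  numerics <- utils::modifyList(
    list(
      dt_max = if (uptake$P > 0) 0.01 else 0.1,
      h_crit = -15000, richards = list(), max_segment_length = domain$dz
    ),
    numerics
  )
  if (numerics$dt_max <= 0) stop("scenario(): dt_max must be positive")
  temperature <- utils::modifyList(
    list(mean_T = 10, amplitude = 9, damping_depth = 180, peak_day = 200,
         planting_doy = 124),
    temperature
  )
  initial <- utils::modifyList(
    list(h = "hydrostatic", C = 0, C_bottom = 0), initial
  )
  structure(
    list(
      name = name, domain = domain, layers = layers, compound = compound,
      uptake = uptake, hydraulics = hydraulics, root = root,
      forcing = forcing, initial = initial, numerics = numerics,
      temperature = temperature
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %s: %dx%dx%d cells, %d forcing days, eps = %g, P = %g cm/d\n",
    x$name, x$domain$nx, x$domain$ny, x$domain$nz, nrow(x$forcing),
    x$uptake$epsilon, x$uptake$P
  ))
  invisible(x)
}

#' Build the grid of a scenario
#' @param sc a [scenario()].
#' @return a [soil_grid()].
#' @export
scenario_grid <- function(sc) {
  d <- sc$domain
  soil_grid(d$nx, d$ny, d$nz, d$dx, d$dy, d$dz, sc$layers)
}

#' Resolve the root system of a scenario
#'
#' Materialises the root source (explicit system, single-root generator,
#' stochastic generator or RSML file) and subdivides segments to the
#' scenario's maximum segment length.
#'
#' @param sc a [scenario()].
#' @return a [root_system()].
#' @export
scenario_root <- function(sc) {
  r <- sc$root
  rs <- if (inherits(r, "root_system")) {
    r
  } else if (identical(r$type, "single")) {
    generate_single_root(
      final_depth = r$final_depth %||% 100,
      days_to_final = r$days_to_final %||% 89,
      radius = r$radius %||% 0.003,
      segment_length = r$segment_length %||% sc$numerics$max_segment_length,
      collar = r$collar %||% c(sc$domain$nx * sc$domain$dx / 2,
                               sc$domain$ny * sc$domain$dy / 2, 0)
    )
  } else if (identical(r$type, "stochastic")) {
    generate_stochastic_root_system(
      params = r$params %||% maize_root_params(),
      seed = r$seed %||% 1,
      collar = r$collar %||% c(sc$domain$nx * sc$domain$dx / 2,
                               sc$domain$ny * sc$domain$dy / 2, 0)
    )
  } else if (identical(r$type, "rsml")) {
    read_rsml(r$path,
      max_segment_length = sc$numerics$max_segment_length,
      time_unit = r$time_unit %||% "days"
    )
  } else {
    stop("scenario_root(): unknown root source type")
  }
  subdivide_segments(rs, sc$numerics$max_segment_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a scenario configuration file
#'
#' Reads a YAML configuration, applies defaults (advective uptake
#' fraction 0.5, P = 0), normalises units to cm-day-gram and returns a
#' fully resolved [scenario()]. Errors list every problem found.
#'
#' @param path YAML file. Top-level keys: `name`, `domain`, `layers`
#'   (inline table or `csv` path), `compound`, `uptake`, `hydraulics`
#'   (`"constant"` with `Lr`/`Kx`, or `"maize"`), `root`, `forcing`
#'   (`csv` path or inline columns), `initial`, `numerics`,
#'   `temperature`.
#' @return a validated [scenario()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("validate_config(): no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("name", "domain", "layers", "compound", "uptake", "hydraulics",
             "root", "forcing", "initial", "numerics", "temperature")
  errs <- character()
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  for (k in c("domain", "layers", "compound", "forcing", "root")) {
    if (is.null(cfg[[k]])) errs <- c(errs, paste0("missing section: ", k))
  }
  up <- cfg$uptake %||% list()
  if (identical(up$P, "from_logkow") && is.null(cfg$compound$logKow)) {
    errs <- c(errs, "uptake P = \"from_logkow\" requires compound logKow")
  }
  if (!is.null(cfg$numerics$dt_max) && cfg$numerics$dt_max <= 0) {
    errs <- c(errs, "numerics dt_max must be > 0")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  forcing <- cfg$forcing
  if (!is.null(forcing$csv)) {
    fp <- resolve(forcing$csv)
    if (!file.exists(fp)) {
      errs <- c(errs, paste0("forcing csv not found: ", forcing$csv))
    } else {
      forcing <- utils::read.csv(fp)
    }
  } else {
    forcing <- tibble::as_tibble(lapply(forcing, unlist))
  }
  layers <- cfg$layers
  if (!is.null(layers$csv)) {
    lp <- resolve(layers$csv)
    if (!file.exists(lp)) {
      errs <- c(errs, paste0("layers csv not found: ", layers$csv))
    } else {
      layers <- utils::read.csv(lp)
    }
  } else {
    layers <- as.data.frame(lapply(
      as.data.frame(do.call(rbind, layers)), unlist
    ))
  }
  if (length(errs) > 0) {
    stop("validate_config(): invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  compound <- do.call(compound_properties, cfg$compound)
  uptake <- do.call(
    uptake_parameters,
    c(utils::modifyList(list(epsilon = 0.5, P = 0), up),
      list(compound = compound))
  )
  hyd <- cfg$hydraulics %||% list(type = "maize")
  hydraulics <- if (identical(hyd$type, "constant")) {
    constant_hydraulics(hyd$Lr, hyd$Kx, n_orders = hyd$n_orders %||% 3)
  } else if (identical(hyd$type, "maize") || is.null(hyd$type)) {
    maize_hydraulics()
  } else {
    stop("validate_config(): unknown hydraulics type: ", hyd$type)
  }
  root <- cfg$root
  if (identical(root$type, "rsml") && !is.null(root$path)) {
    root$path <- resolve(root$path)
  }
  scenario(
    domain = cfg$domain, layers = layers, compound = compound,
    uptake = uptake, hydraulics = hydraulics, root = root,
    forcing = forcing, initial = cfg$initial %||% list(),
    numerics = cfg$numerics %||% list(),
    temperature = cfg$temperature %||% list(),
    name = cfg$name %||% tools::file_path_sans_ext(basename(path))
  )
}

#' Write a scenario to a config + CSV bundle
#'
#' Serialises a scenario to `scenario.yaml` plus `forcing.csv` and
#' `layers.csv` in `dir`, the on-disk form read by [validate_config()].
#' Explicit root systems are written as RSML and referenced.
#'
#' @param sc a [scenario()].
#' @param dir destination directory (created if needed).
#' @return the path to the YAML file, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sc$forcing, file.path(dir, "forcing.csv"), row.names = FALSE)
  utils::write.csv(
    as.data.frame(sc$layers)[, c("z_top", "z_bottom", "theta_r", "theta_s",
                                 "alpha", "n", "K_s", "l", "rho_b", "tau")],
    file.path(dir, "layers.csv"), row.names = FALSE
  )
  root <- sc$root
  if (inherits(root, "root_system")) {
    write_rsml(root, file.path(dir, "root.rsml"))
    root <- list(type = "rsml", path = "root.rsml")
  }
  cp <- sc$compound
  cfg <- list(
    name = sc$name,
    domain = sc$domain,
    layers = list(csv = "layers.csv"),
    compound = list(
      logKow = cp$logKow, D = cp$D, K_D = cp$K_D,
      half_life = if (is.finite(log(2) / cp$k_ref)) log(2) / cp$k_ref else 1e9,
      theta_ref = cp$theta_ref
    ),
    uptake = sc$uptake[c("epsilon", "P", "theta_R", "rho_R", "K_D_R", "k_R")],
    hydraulics = list(type = "maize"),
    root = root,
    forcing = list(csv = "forcing.csv"),
    initial = sc$initial,
    numerics = sc$numerics[c("dt_max", "h_crit", "max_segment_length")],
    temperature = sc$temperature
  )
  out <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(cfg, out)
  invisible(out)
}
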