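#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run
#'
#' One row per simulated day with transpiration, uptake and collar
#' masses, mean concentrations and the TSCF/PUF diagnostics.
#'
#' @param x an `uptake_run`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy uptake_run
#' @export
tidy.uptake_run <- function(x, ...) x$metrics

#' One-row summary of a simulation run
#'
#' @param x an `uptake_run`.
#' @param ... unused.
#' @return a tibble with cumulative transpiration (cm^3), cumulative
#'   collar and net uptake mass (g), degraded mass, final soil and root
#'   mass, the overall solute closure error and the mean of the defined
#'   daily TSCF values.
#' @method glance uptake_run
#' @export
glance.uptake_run <- function(x, ...) {
  led <- x$solute_ledger
  rep <- mass_balance_report(x)
  tibble::tibble(
    days = nrow(x$metrics),
    transpiration = sum(x$metrics$T_act),
    m_collar = x$root_solute$m_collar,
    m_uptake = x$root_solute$uptake,
    degraded = sum(led$degraded_soil) + sum(led$degraded_root),
    soil_mass = led$soil_mass_end[nrow(led)],
    root_mass = led$root_mass_end[nrow(led)],
    closure_error = attr(rep, "closure"),
    mean_tscf = mean(x$metrics$TSCF, na.rm = TRUE)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the SUF depth profile
#'
#' Standard uptake fraction summed per depth bin, the architecture-only
#' fingerprint of where the root system would take up water under
#' uniform soil water potential.
#'
#' @param object a [compute_suf()] result.
#' @param bin depth bin, cm.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot suf
#' @export
autoplot.suf <- function(object, bin = 5, ...) {
  df <- tibble::as_tibble(object)
  df$zbin <- -(floor(-df$z / bin) + 0.5) * bin
  agg <- dplyr::summarise(dplyr::group_by(df, .data$zbin),
                          suf = sum(.data$suf), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$suf, y = .data$zbin)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standard uptake fraction per bin (-)",
                  y = "depth (cm)") +
    ggplot2::theme_minimal()
}

#' Plot daily uptake diagnostics of a run
#'
#' @param object an `uptake_run`.
#' @param what `"tscf"` (daily TSCF and PUF), `"concentration"`
#'   (per-layer mean dissolved concentration) or `"water"` (daily actual
#'   vs potential transpiration).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot uptake_run
#' @export
autoplot.uptake_run <- function(object, what = c("tscf", "concentration", "water"),
                                ...) {
  what <- match.arg(what)
  m <- object$metrics
  if (what == "tscf") {
    df <- tidyr::pivot_longer(
      m[, c("day", "TSCF", "PUF")], -"day",
      names_to = "metric", values_to = "value"
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 3) +
      ggplot2::labs(x = "days after planting", y = "daily factor (-)") +
      ggplot2::theme_minimal()
  } else if (what == "concentration") {
    lc <- object$layer_concentrations
    lc$layer <- sprintf("%g to %g cm", lc$z_top, lc$z_bottom)
    ggplot2::ggplot(lc, ggplot2::aes(.data$day, .data$C_mean,
                                     colour = .data$layer)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "days after planting",
                    y = "mean dissolved concentration (g cm^-3)") +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(
      m[, c("day", "T_act", "T_pot")], -"day",
      names_to = "flux", values_to = "value"
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$value,
                                     linetype = .data$flux)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "days after planting", y = "transpiration (cm^3/d)") +
      ggplot2::theme_minimal()
  }
}
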