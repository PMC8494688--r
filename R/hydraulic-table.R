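#' Age- and order-dependent root hydraulic properties
#'
#' Piecewise-linear breakpoints of radial conductivity `Lr` (cm d^-1 cm^-1,
#' per unit membrane surface and head) and axial conductance `Kx`
#' (cm^4 d^-1 cm^-1) as functions of segment age, one set per branching
#' order. Evaluation clamps outside the breakpoint range.
#'
#' @param ... one list per order (order 0 first), each with numeric vectors
#'   `age`, `Lr`, `Kx` of equal length (age strictly increasing).
#' @return an object of class `hydraulic_table`.
#' @export
hydraulic_table <- function(...) {
  orders <- list(...)
  if (length(orders) == 1 && is.null(orders[[1]]$age)) orders <- orders[[1]]
  for (k in seq_along(orders)) {
    o <- orders[[k]]
    stopifnot(
      length(o$age) == length(o$Lr), length(o$age) == length(o$Kx),
      !is.unsorted(o$age, strictly = length(o$age) > 1)
    )
    if (any(o$Lr <= 0) || any(o$Kx <= 0)) {
      stop("hydraulic_table(): Lr and Kx must be positive everywhere")
    }
  }
  structure(orders, class = "hydraulic_table")
}

#' Constant hydraulic properties
#'
#' Convenience constructor for a single-order table with age-independent
#' values, as used for a hydraulically uniform single root.
#'
#' @param Lr radial conductivity, cm d^-1 cm^-1.
#' @param Kx axial conductance, cm^4 d^-1 cm^-1.
#' @param n_orders replicate the same values for this many orders.
#' @return a [hydraulic_table()].
#' @export
constant_hydraulics <- function(Lr, Kx, n_orders = 1) {
  hydraulic_table(lapply(seq_len(n_orders), function(i) {
    list(age = 0, Lr = Lr, Kx = Kx)
  }))
}

#' Fig.-2-shaped maize hydraulic table
#'
#' Qualitative age/order parameterisation for the complex-architecture
#' scenario: young segments have high radial conductivity that declines
#' with maturation (suberisation), while axial conductance rises steeply
#' as xylem vessels mature; laterals are radially leaky but axially weak.
#'
#' @return a [hydraulic_table()] with orders 0-2.
#' @export
maize_hydraulics <- function() {
  hydraulic_table(
    list( # order 0
      age = c(0, 10, 25, 40), Lr = c(1.8e-4, 1.8e-4, 5e-5, 2e-5),
      Kx = c(1e-3, 5e-2, 3e-1, 4.3e-1)
    ),
    list( # order 1
      age = c(0, 10, 20), Lr = c(1.8e-4, 1.0e-4, 6e-5),
      Kx = c(1e-4, 2e-3, 4e-3)
    ),
    list( # order 2
      age = c(0, 10), Lr = c(1.8e-4, 1.5e-4),
      Kx = c(1e-4, 5e-4)
    )
  )
}

#' Look up hydraulic properties by order and age
#'
#' Piecewise-linear interpolation between breakpoints, clamped to the end
#' values outside the tabulated age range.
#'
#' @param table a [hydraulic_table()].
#' @param order branching order (0-based), scalar or vector.
#' @param age segment age, days (>= 0), same length as `order` or scalar.
#' @return a list with numeric vectors `Lr` and `Kx`.
#' @export
lookup_hydraulics <- function(table, order, age) {
  stopifnot(inherits(table, "hydraulic_table"))
  if (any(age < 0)) stop("lookup_hydraulics(): age must be >= 0")
  n <- max(length(order), length(age))
  order <- rep_len(as.integer(order), n)
  age <- rep_len(age, n)
  if (any(order < 0) || any(order >= length(table))) {
    stop(
      "lookup_hydraulics(): no hydraulic parameters for order(s) ",
      paste(sort(unique(order[order < 0 | order >= length(table)])),
            collapse = ", ")
    )
  }
  Lr <- numeric(n)
  Kx <- numeric(n)
  for (k in unique(order)) {
    o <- table[[k + 1]]
    idx <- order == k
    if (length(o$age) == 1) {
      Lr[idx] <- o$Lr
      Kx[idx] <- o$Kx
    } else {
      Lr[idx] <- stats::approx(o$age, o$Lr, age[idx], rule = 2)$y
      Kx[idx] <- stats::approx(o$age, o$Kx, age[idx], rule = 2)$y
    }
  }
  list(Lr = Lr, Kx = Kx)
}
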