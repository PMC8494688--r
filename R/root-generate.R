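#' Generate a single vertical root
#'
#' One vertical axis under the collar whose rooting depth grows linearly
#' with time: depth(t) = min(final_depth, final_depth * t / days_to_final),
#' the depth schedule used by 1D crop scenarios with uniform relative root
#' length distribution. After `days_to_final` the depth stays constant.
#'
#' @param final_depth final rooting depth, cm (> 0).
#' @param days_to_final days after planting at which the final depth is
#'   reached (default 89).
#' @param radius root radius, cm.
#' @param segment_length segment discretisation, cm (default 1).
#' @param collar collar position, cm (default origin at the surface).
#' @return a [root_system()] whose alive depth follows the schedule.
#' @export
generate_single_root <- function(final_depth, days_to_final = 89,
                                 radius = 0.003, segment_length = 1,
                                 collar = c(0, 0, 0)) {
  stopifnot(final_depth > 0, days_to_final > 0, segment_length > 0)
  if (radius <= 0) stop("generate_single_root(): radius must be positive")
  n <- as.integer(ceiling(final_depth / segment_length - 1e-9))
  z <- collar[3] - seq(0, final_depth, length.out = n + 1)
  depth_tip <- -(z[-1] - collar[3])
  seg <- tibble::tibble(
    id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    x1 = collar[1], y1 = collar[2], z1 = z[-(n + 1)],
    x2 = collar[1], y2 = collar[2], z2 = z[-1],
    radius = radius,
    order = 0L,
    # segment k becomes alive when the schedule reaches its tip depth
    emergence_time = days_to_final * depth_tip / final_depth,
    branch_id = 1L
  )
  root_system(seg, collar)
}

#' Default parameters of the stochastic maize-like generator
#'
#' Per-order growth parameters: elongation rate (cm/d), maximum branch
#' length (cm, sampled uniformly in `max_length` +- `length_spread`),
#' inter-branch distance (cm), apical unbranched zone (cm), insertion angle
#' (degrees from the parent direction), gravitropism strength (-) and
#' directional noise (-). `n_axes` main axes emerge between time 0 and
#' `axis_emergence_span` days and grow to `final_depth` cm following the
#' linear depth schedule of [generate_single_root()].
#'
#' @return a named list of generator parameters.
#' @export
maize_root_params <- function() {
  list(
    n_axes = 10,
    axis_emergence_span = 8,
    final_depth = 100,
    days_to_final = 89,
    orders = list(
      list( # order 0: axes splay like crown roots before turning down
        elongation = 100 / 89 / 0.95, radius = 0.05,
        branch_distance = 0.7, apical_zone = 5,
        insertion_angle = 45, tropism = 2.5, noise = 0.15
      ),
      list( # order 1 laterals
        elongation = 0.8, radius = 0.02, max_length = 5, length_spread = 3,
        branch_distance = 1.5, apical_zone = 2,
        insertion_angle = 70, tropism = 0.15, noise = 0.4
      ),
      list( # order 2 laterals
        elongation = 0.5, radius = 0.01, max_length = 1.2, length_spread = 0.7,
        branch_distance = Inf, apical_zone = Inf,
        insertion_angle = 70, tropism = 0.05, noise = 0.5
      )
    )
  )
}

# one growth step direction update: gravitropism + noise, unit length
next_direction <- function(d, tropism, noise) {
  d <- d + tropism * c(0, 0, -1) * 0.1 + noise * 0.1 * stats::rnorm(3)
  d / sqrt(sum(d^2))
}

#' Generate a stochastic maize-like root system
#'
#' Grows `n_axes` gravitropic main axes with first- and second-order
#' laterals. Geometry and timing are generated with one seeded RNG stream
#' per axis (laterals drawing from their axis stream in along-axis order),
#' so the topology does not depend on iteration order. The depth schedule
#' of the deepest tip follows the linear single-root schedule; laterals
#' fill the profile to an approximately uniform root length density.
#'
#' @param params parameter list as from [maize_root_params()].
#' @param seed integer RNG seed; the same seed reproduces the same system.
#' @param collar collar position, cm.
#' @return a [root_system()] with orders 0-2.
#' @export
generate_stochastic_root_system <- function(params = maize_root_params(),
                                            seed = 1,
                                            collar = c(0, 0, 0)) {
  if (is.null(params$n_axes) || params$n_axes < 1) {
    stop("generate_stochastic_root_system(): params must give >= 1 axis")
  }
  axes <- vector("list", params$n_axes)
  id0 <- 0L
  br0 <- 0L
  for (a in seq_len(params$n_axes)) {
    axes[[a]] <- withr_seed(
      (as.integer(seed) * 7919L + a * 104729L) %% 2147483629L,
      grow_axis(params, a, collar, id_offset = id0, branch_offset = br0)
    )
    id0 <- id0 + nrow(axes[[a]])
    br0 <- br0 + length(unique(axes[[a]]$branch_id))
  }
  seg <- dplyr::bind_rows(axes)
  # virtual 0-length connectors are avoided: each axis base sits at the collar
  root_system(seg, collar)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# grow one axis and all of its laterals; returns a segment tibble whose
# first segment attaches to the collar
grow_axis <- function(params, axis_index, collar, id_offset, branch_offset) {
  p0 <- params$orders[[1]]
  t0 <- (axis_index - 1) / max(1, params$n_axes - 1) * params$axis_emergence_span
  # initial direction: small insertion angle from vertical, random azimuth
  phi <- stats::runif(1, 0, 2 * pi)
  ang <- p0$insertion_angle * pi / 180 * stats::runif(1, 0.3, 1)
  d <- c(sin(ang) * cos(phi), sin(ang) * sin(phi), -cos(ang))
  rows <- list()
  nid <- id_offset
  nbr <- branch_offset
  grow_branch <- function(base, dir, order, t_start, parent_seg_id, max_len) {
    po <- params$orders[[order + 1]]
    nbr <<- nbr + 1L
    my_branch <- nbr
    pos <- base
    t <- t_start
    s <- 0
    prev_id <- parent_seg_id
    step <- 1 # cm growth resolution
    branch_pts <- list() # (arc length, seg id, time, position, direction)
    while (s < max_len - 1e-9) {
      dl <- min(step, max_len - s)
      dir <- next_direction(dir, po$tropism, po$noise)
      if (order == 0) {
        # axes stop at the target depth rather than at a length cap
        if (pos[3] - dl * abs(dir[3]) < collar[3] - params$final_depth) break
      }
      newpos <- pos + dl * dir
      nid <<- nid + 1L
      t <- t + dl / po$elongation
      rows[[length(rows) + 1L]] <<- c(
        nid, if (is.na(prev_id)) NA_real_ else prev_id,
        pos, newpos, po$radius, order, t, my_branch
      )
      branch_pts[[length(branch_pts) + 1L]] <-
        list(s = s + dl, id = nid, t = t, pos = newpos, dir = dir)
      prev_id <- nid
      pos <- newpos
      s <- s + dl
    }
    # spawn child laterals behind the apical zone
    if (is.finite(po$branch_distance) &&
        order < length(params$orders) - 1 && length(branch_pts) > 0) {
      child_par <- params$orders[[order + 2]]
      s_end <- s
      s_br <- po$branch_distance * 0.5
      for (bp in branch_pts) {
        while (s_br <= bp$s && s_br <= s_end - po$apical_zone) {
          # child inserts at the tip of segment bp (nearest grown node)
          phi <- stats::runif(1, 0, 2 * pi)
          ia <- child_par$insertion_angle * pi / 180
          cd <- insertion_direction(bp$dir, ia, phi)
          clen <- child_par$max_length +
            child_par$length_spread * stats::runif(1, -1, 1)
          # lateral emerges a delay after the apex passed the insertion point
          t_child <- bp$t + po$apical_zone / po$elongation
          grow_branch(bp$pos, cd, order + 1L, t_child, bp$id, max(clen, 0.5))
          s_br <- s_br + po$branch_distance
        }
      }
    }
  }
  grow_branch(collar, d, 0L, t0, NA_integer_,
              max_len = params$final_depth * 1.25)
  m <- do.call(rbind, rows)
  tibble::tibble(
    id = as.integer(m[, 1]), parent_id = as.integer(m[, 2]),
    x1 = m[, 3], y1 = m[, 4], z1 = m[, 5],
    x2 = m[, 6], y2 = m[, 7], z2 = m[, 8],
    radius = m[, 9], order = as.integer(m[, 10]),
    emergence_time = m[, 11], branch_id = as.integer(m[, 12])
  )
}

# unit vector at angle `ang` from `d`, azimuth `phi` around it
insertion_direction <- function(d, ang, phi) {
  # orthonormal frame around d
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  cos(ang) * d + sin(ang) * (cos(phi) * u + sin(phi) * v)
}

#' Root length density profile
#'
#' Alive root length per depth bin divided by the bin soil volume.
#'
#' @param rs a [root_system()].
#' @param t evaluation time, days after planting (default all segments).
#' @param footprint_area lateral soil area per plant, cm^2.
#' @param bin depth bin, cm (default 10).
#' @param max_depth profile depth, cm (default rooted depth rounded up).
#' @return a tibble with `z_top`, `z_bottom`, `length` (cm) and
#'   `rld` (cm root per cm^3 soil).
#' @export
root_length_density <- function(rs, t = Inf, footprint_area, bin = 10,
                                max_depth = NULL) {
  al <- alive_segments(rs, t)
  if (is.null(max_depth)) max_depth <- ceiling(rooting_depth(rs, t) / bin) * bin
  edges <- seq(0, max_depth, by = bin)
  zm <- -(al$z1 + al$z2) / 2 # midpoint depth, positive
  idx <- pmin(findInterval(zm, edges, rightmost.closed = TRUE), length(edges) - 1)
  len <- vapply(seq_len(length(edges) - 1),
                function(k) sum(al$length[idx == k]), numeric(1))
  tibble::tibble(
    z_top = -edges[-length(edges)], z_bottom = -edges[-1],
    length = len, rld = len / (footprint_area * bin)
  )
}
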