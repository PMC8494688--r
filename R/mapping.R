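#' Map root segments to soil cells
#'
#' Assigns every alive segment to the grid cell(s) it traverses,
#' length-weighted, with periodic wrapping of the lateral coordinates.
#' A segment is split at every grid-plane crossing and each piece is
#' attributed to the cell containing its midpoint, so fractions per
#' segment sum to exactly 1 and mapping conserves root length.
#'
#' @param rs a [root_system()].
#' @param grid a [soil_grid()].
#' @param t time, days after planting; only segments alive at `t` are
#'   mapped (default: all).
#' @return a tibble of class `segment_mapping` with columns `id` (segment
#'   id), `cell` (linear cell index) and `fraction`.
#' @export
map_segments_to_grid <- function(rs, grid, t = Inf) {
  al <- alive_segments(rs, t)
  n <- nrow(al)
  if (n == 0) {
    return(structure(
      tibble::tibble(id = integer(), cell = integer(), fraction = numeric()),
      class = c("segment_mapping", class(tibble::tibble()))
    ))
  }
  a <- cbind(al$x1, al$y1, al$z1)
  b <- cbind(al$x2, al$y2, al$z2)
  d <- c(grid$dx, grid$dy, grid$dz)
  ids <- al$id
  out_id <- vector("list", n)
  out_cell <- vector("list", n)
  out_frac <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- c(0, 1)
    for (ax in 1:3) {
      lo <- min(a[i, ax], b[i, ax])
      hi <- max(a[i, ax], b[i, ax])
      ks <- seq.int(ceiling(lo / d[ax] - 1e-12), floor(hi / d[ax] + 1e-12))
      ks <- ks[ks * d[ax] > lo + 1e-12 & ks * d[ax] < hi - 1e-12]
      if (length(ks) > 0 && abs(b[i, ax] - a[i, ax]) > 0) {
        ts <- c(ts, (ks * d[ax] - a[i, ax]) / (b[i, ax] - a[i, ax]))
      }
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    mid <- outer(rep(1, length(ts) - 1), a[i, ]) +
      ((ts[-length(ts)] + ts[-1]) / 2) %o% (b[i, ] - a[i, ])
    cells <- locate_cells(grid, mid[, 1], mid[, 2], mid[, 3],
                          what = paste("segment", ids[i]))
    frac <- diff(ts)
    # merge duplicates (possible at degenerate crossings)
    agg <- rowsum(frac, cells)
    out_id[[i]] <- rep(ids[i], nrow(agg))
    out_cell[[i]] <- as.integer(rownames(agg))
    out_frac[[i]] <- as.numeric(agg)
  }
  structure(
    tibble::tibble(
      id = unlist(out_id), cell = unlist(out_cell),
      fraction = unlist(out_frac)
    ),
    class = c("segment_mapping", class(tibble::tibble()))
  )
}

# distribute a per-segment quantity onto grid cells: returns a vector over
# cells of sum(value_i * fraction); `value` named by or aligned with ids
distribute_to_cells <- function(mapping, ids, value, ncell) {
  v <- value[match(mapping$id, ids)] * mapping$fraction
  out <- numeric(ncell)
  agg <- rowsum(v, mapping$cell)
  out[as.integer(rownames(agg))] <- as.numeric(agg)
  out
}

# gather a per-cell field to segments: length-fraction-weighted mean
gather_from_cells <- function(mapping, ids, field) {
  w <- rowsum(cbind(mapping$fraction * field[mapping$cell], mapping$fraction),
              match(mapping$id, ids))
  out <- numeric(length(ids))
  out[as.integer(rownames(w))] <- w[, 1] / w[, 2]
  out
}
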