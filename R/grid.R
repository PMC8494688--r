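#' Structured 3D soil grid
#'
#' Regular rectilinear grid over a laterally periodic soil column. The
#' coordinate convention is z = 0 at the soil surface, negative downward;
#' x and y wrap periodically (field-plot repetition). Cells are indexed
#' (ix, iy, iz) with iz = 1 the surface layer; the linear index runs x
#' fastest, then y, then z.
#'
#' @param nx,ny,nz cell counts in x, y, z.
#' @param dx,dy,dz cell edges, cm.
#' @param layers a [vg_layers()] table covering depth `nz * dz`.
#' @return an object of class `soil_grid`.
#' @export
soil_grid <- function(nx, ny, nz, dx, dy, dz, layers) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, dz > 0)
  layers <- if (inherits(layers, "vg_layers")) layers else vg_layers(layers)
  Lz <- nz * dz
  if (min(layers$z_bottom) > -Lz + 1e-9) {
    stop("soil_grid(): layer table does not cover the domain depth ", Lz, " cm")
  }
  zc <- -(seq_len(nz) - 0.5) * dz # cell-centre elevations, negative
  layer_of_iz <- vapply(zc, function(z) {
    which(layers$z_top >= z - 1e-12 & layers$z_bottom <= z + 1e-12)[1]
  }, integer(1))
  if (anyNA(layer_of_iz)) stop("soil_grid(): cell centre outside all layers")
  g <- list(
    nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
    Lx = nx * dx, Ly = ny * dy, Lz = Lz, z_bottom = -Lz,
    zc = zc, V = dx * dy * dz, ncell = nx * ny * nz,
    layers = layers, layer_of_iz = layer_of_iz
  )
  g$cache <- new.env(parent = emptyenv())
  class(g) <- "soil_grid"
  g
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf(
    "<soil_grid> %d x %d x %d cells (%g x %g x %g cm), depth %g cm, %d layers\n",
    x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, x$Lz, nrow(x$layers)
  ))
  invisible(x)
}

# expand a per-iz vector to the full cell ordering (x fastest)
expand_iz <- function(grid, v_iz) {
  rep(v_iz, each = grid$nx * grid$ny)
}

# per-cell layer index in linear ordering
cell_layer <- function(grid) expand_iz(grid, grid$layer_of_iz)

# evaluate a vg_* function per cell given per-cell heads, respecting layers
grid_vg <- function(grid, h, fun) {
  out <- numeric(grid$ncell)
  lay <- cell_layer(grid)
  for (k in unique(grid$layer_of_iz)) {
    idx <- lay == k
    out[idx] <- fun(h[idx], grid$layers[k, ])
  }
  out
}

# linear cell index from integer coordinates (already wrapped / validated)
cell_index <- function(grid, ix, iy, iz) {
  ix + (iy - 1L) * grid$nx + (iz - 1L) * grid$nx * grid$ny
}

#' Locate points in the grid
#'
#' Maps (x, y, z) coordinates to linear cell indices with periodic lateral
#' wrapping. Points below the domain bottom raise an error.
#'
#' @param grid a [soil_grid()].
#' @param x,y,z coordinates, cm (z <= 0).
#' @param what label used in error messages.
#' @return integer vector of linear cell indices.
#' @export
locate_cells <- function(grid, x, y, z, what = "point") {
  ix <- (floor(x / grid$dx) %% grid$nx) + 1L
  iy <- (floor(y / grid$dy) %% grid$ny) + 1L
  depth <- -z
  iz <- floor(depth / grid$dz) + 1L
  iz[depth <= 0] <- 1L # at/above the surface maps into the top cell
  # points exactly on the bottom boundary belong to the lowest cell
  iz[abs(depth - grid$Lz) < 1e-9] <- grid$nz
  bad <- iz > grid$nz
  if (any(bad)) {
    stop(sprintf(
      "%s %s lies below the domain bottom (z = %.6g cm < %g cm)",
      what, paste(which(bad), collapse = ","), min(z[bad]), grid$z_bottom
    ))
  }
  cell_index(grid, as.integer(ix), as.integer(iy), as.integer(iz))
}
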