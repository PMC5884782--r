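# Shared fixture builders and independent brute-force oracles.

# Grid whose voxel centres sit at 0.5, 1.5, ... along each axis (1 mm).
unit_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5),
                      axes = c("L-R", "A-P", "I-S")) {
  grid3d(origin, spacing, dims, axes)
}

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}

# Independent scalar even-odd point-in-polygon (classic crossing count),
# used as the brute-force rasterization oracle.
pip_oracle <- function(px, py, poly) {
  inside <- FALSE
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- poly[i, 1] + (py - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Count voxel centres of a slice inside a polygon by brute force.
rasterize_oracle_count <- function(grid, poly) {
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  n <- 0L
  for (x in xs) for (y in ys) if (pip_oracle(x, y, poly)) n <- n + 1L
  n
}

# Random non-empty mask on a grid.
random_mask <- function(grid, fill = 0.3, name = "rand") {
  occ <- array(stats::runif(prod(grid$dims)) < fill, dim = grid$dims)
  if (!any(occ)) occ[1, 1, 1] <- TRUE
  structure_mask(grid, occ, name)
}

# Random dose grid with doses in [0, dmax) cGy.
random_dose <- function(grid, dmax = 6000) {
  dose_grid(grid, array(stats::runif(prod(grid$dims), 0, dmax),
                        dim = grid$dims))
}

# A slab mask occupying whole coronal slices `slices` (along axis 2).
slab_mask <- function(grid, slices, name = "slab") {
  occ <- array(FALSE, dim = grid$dims)
  occ[, slices, ] <- TRUE
  structure_mask(grid, occ, name)
}

# Small phantom configuration for fast end-to-end tests.
small_phantom <- function(...) {
  phantom_config(dims = c(40, 50, 40), spacing = c(3, 3, 3),
                 lateral_offset_mm = 18, source_point_mm = c(58, 45, 35),
                 ...)
}
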