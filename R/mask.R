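#' Binary voxel mask for one structure
#'
#' @param grid a [grid3d()].
#' @param occupancy logical array with dimensions equal to `grid$dims`.
#' @param structure_name character scalar.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(grid, occupancy, structure_name = "structure") {
  stopifnot(inherits(grid, "grid3d"), is.character(structure_name))
  occupancy <- as.array(occupancy)
  if (!is.logical(occupancy)) {
    storage.mode(occupancy) <- "logical"
  }
  if (!identical(dim(occupancy), as.integer(grid$dims))) {
    stop("occupancy dimensions must equal grid dims", call. = FALSE)
  }
  if (anyNA(occupancy)) stop("occupancy must not contain NA", call. = FALSE)
  structure(
    list(grid = grid, occupancy = occupancy,
         structure_name = structure_name),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("structure_mask '", x$structure_name, "': ", sum(x$occupancy),
      " of ", prod(x$grid$dims), " voxels occupied (",
      format(mask_volume(x), digits = 4), " cc)\n", sep = "")
  invisible(x)
}

#' Structure volume in cc
#'
#' Occupied-voxel count times voxel volume; this is the denominator of every
#' relative volume metric (V_d).
#'
#' @param mask a [structure_mask()].
#' @return Volume in cc (1 cc = 1000 mm^3).
#' @examples
#' g <- grid3d(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
#' mask_volume(structure_mask(g, array(TRUE, c(10, 10, 10)))) # 1 cc
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

#' Resample a mask onto another grid (nearest neighbour)
#'
#' Each target voxel takes the occupancy of the source voxel nearest to its
#' centre; target voxels whose centre falls outside the source lattice are
#' empty. Used to bring an MRI-resolution delineation onto the (coarser)
#' dose grid before any dose metric is computed. Volume is preserved to
#' within one source-voxel volume per boundary voxel.
#'
#' @param mask a [structure_mask()].
#' @param target a [grid3d()] with the same axis labels, spatially
#'   overlapping the source grid.
#' @return A [structure_mask()] on `target`. If the grids do not overlap the
#'   result is empty and a warning is raised.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "structure_mask"), inherits(target, "grid3d"))
  src <- mask$grid
  if (!identical(src$axes, target$axes)) {
    stop("source and target grids must share axis labels", call. = FALSE)
  }
  if (.same_grid(src, target)) {
    return(structure_mask(target, mask$occupancy, mask$structure_name))
  }
  idx <- vector("list", 3)
  valid <- vector("list", 3)
  for (a in 1:3) {
    i <- .nearest_index(src, a, axis_coords(target, a))
    valid[[a]] <- which(i >= 1L & i <= src$dims[a])
    idx[[a]] <- i
  }
  occ <- array(FALSE, dim = target$dims)
  if (any(lengths(valid) == 0)) {
    warning("grids do not overlap; returning an empty mask", call. = FALSE)
    return(structure_mask(target, occ, mask$structure_name))
  }
  occ[valid[[1]], valid[[2]], valid[[3]]] <-
    mask$occupancy[idx[[1]][valid[[1]]],
                   idx[[2]][valid[[2]]],
                   idx[[3]][valid[[3]]]]
  structure_mask(target, occ, mask$structure_name)
}
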