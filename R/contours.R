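#' Planar contour set for one delineated structure
#'
#' Stores a structure as a stack of closed planar polygons, the form in which
#' clinical delineations are exchanged: each plane has a position (mm) along
#' the grid's third index axis and one or more polygons with vertices in the
#' plane of the first two index axes. Nested polygons describe holes
#' (even-odd rule). Polygons may repeat their first vertex as the last one or
#' leave the closure implicit.
#'
#' @param structure_name character scalar, e.g. `"HC-L"`.
#' @param planes list of planes, each a list with elements `z_mm` (numeric
#'   plane position) and `polygons` (list of n x 2 numeric matrices of
#'   vertices in mm, n >= 3 distinct vertices).
#' @return An object of class `contour_set`.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' cs <- contour_set("ROI", list(list(z_mm = 0, polygons = list(sq))))
#' @export
contour_set <- function(structure_name, planes = list()) {
  stopifnot(is.character(structure_name), length(structure_name) == 1)
  planes <- lapply(planes, function(p) {
    if (is.null(p$z_mm) || !is.finite(p$z_mm)) {
      stop("each plane needs a finite z_mm", call. = FALSE)
    }
    polys <- lapply(p$polygons, .as_polygon)
    list(z_mm = as.numeric(p$z_mm), polygons = polys)
  })
  if (length(planes) > 1) {
    z <- vapply(planes, function(p) p$z_mm, numeric(1))
    if (any(diff(order(z)) < 0) || anyDuplicated(z)) {
      planes <- planes[order(z)]
      if (anyDuplicated(vapply(planes, function(p) p$z_mm, numeric(1)))) {
        stop("plane positions must be distinct", call. = FALSE)
      }
    }
  }
  structure(list(structure_name = structure_name, planes = planes),
            class = "contour_set")
}

# Validate one polygon: >= 3 distinct vertices; drop an explicit closing
# vertex so downstream code always sees an implicitly closed ring.
.as_polygon <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 2) stop("polygon vertices must be n x 2", call. = FALSE)
  storage.mode(v) <- "double"
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3) {
    stop("invalid contour: polygon has fewer than 3 vertices", call. = FALSE)
  }
  v
}

#' @export
print.contour_set <- function(x, ...) {
  np <- vapply(x$planes, function(p) length(p$polygons), integer(1))
  cat("contour_set '", x$structure_name, "': ", length(x$planes),
      " planes, ", sum(np), " polygons\n", sep = "")
  invisible(x)
}

# Even-odd point-in-polygon over a full slice lattice. xs, ys are the
# voxel-centre coordinates of the slice; returns an |xs| x |ys| logical
# matrix. Standard half-open crossing rule, so results are deterministic for
# points on edges.
.points_in_polygon <- function(xs, ys, poly) {
  n1 <- length(xs)
  n2 <- length(ys)
  inside <- matrix(FALSE, n1, n2)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    if (y1 != y2) {
      crosses <- (y1 > ys) != (y2 > ys)
      if (any(crosses)) {
        xint <- x1 + (ys - y1) * (x2 - x1) / (y2 - y1)
        flips <- outer(xs, xint, "<") &
          matrix(crosses, n1, n2, byrow = TRUE)
        inside <- xor(inside, flips)
      }
    }
    j <- i
  }
  inside
}

#' Rasterize planar contours onto a voxel grid
#'
#' A voxel becomes occupied if and only if its centre lies inside an odd
#' number of the polygons of its nearest contour plane (even-odd rule, so
#' nested polygons carve holes). No partial-volume handling: the
#' centre-inside rule matches common treatment-planning-system behaviour and
#' admits an exact brute-force oracle. Contour planes are mapped to the
#' nearest grid slice along the third index axis, ties toward the lower
#' index; slices with no contour stay empty.
#'
#' @param contours a [contour_set()].
#' @param grid a [grid3d()] whose third index axis is the contour-plane
#'   stacking direction.
#' @return A [structure_mask()] on `grid`.
#' @export
rasterize_contours <- function(contours, grid) {
  stopifnot(inherits(contours, "contour_set"), inherits(grid, "grid3d"))
  occ <- array(FALSE, dim = grid$dims)
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  half <- grid$spacing[3] / 2
  zmin <- grid$origin[3] - half
  zmax <- grid$origin[3] + (grid$dims[3] - 1) * grid$spacing[3] + half
  for (p in contours$planes) {
    if (p$z_mm < zmin || p$z_mm > zmax) {
      stop("contour plane at z = ", p$z_mm,
           " mm lies outside the grid extent", call. = FALSE)
    }
    k <- .nearest_index(grid, 3, p$z_mm)
    k <- min(max(k, 1L), grid$dims[3])
    slice <- matrix(FALSE, grid$dims[1], grid$dims[2])
    for (poly in p$polygons) {
      slice <- xor(slice, .points_in_polygon(xs, ys, poly))
    }
    occ[, , k] <- occ[, , k] | slice
  }
  structure_mask(grid, occ, contours$structure_name)
}
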