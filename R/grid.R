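#' @keywords internal
"_PACKAGE"

# Valid per-axis anatomical labels. "A-P" means the voxel index increases from
# anterior to posterior; "P-A" the reverse, and so on.
.axis_labels <- c("L-R", "R-L", "A-P", "P-A", "I-S", "S-I")

.axis_family <- function(label) {
  switch(label,
    "L-R" = , "R-L" = "lateral",
    "A-P" = , "P-A" = "ap",
    "I-S" = , "S-I" = "is",
    stop("unknown axis label: ", label, call. = FALSE)
  )
}

#' Regular 3-D voxel lattice in patient coordinates
#'
#' A `grid3d` describes the geometry shared by dose grids and structure
#' masks: the patient-space position (mm) of the centre of the first voxel,
#' the (strictly positive, possibly anisotropic) voxel spacing, the number of
#' voxels per axis, and anatomical labels saying which array index runs
#' left-right, anterior-posterior and inferior-superior. A voxel's position
#' is always its centre; indices are 1-based as usual in R.
#'
#' @param origin numeric(3), patient-space mm of the centre of voxel
#'   `[1, 1, 1]`.
#' @param spacing numeric(3), voxel spacing in mm, strictly positive.
#'   Anisotropic spacing (e.g. 3 mm CT slices vs 1.5 mm MRI slices) is
#'   supported.
#' @param dims integer(3), number of voxels per axis, each >= 1.
#' @param axes character(3), one label per index axis from
#'   `"L-R", "R-L", "A-P", "P-A", "I-S", "S-I"`; together they must cover the
#'   lateral, anterior-posterior and inferior-superior directions exactly
#'   once. The first letter is the side the low index is on.
#' @return An object of class `grid3d`.
#' @examples
#' grid3d(c(0, 0, 0), c(2, 2, 2), c(80, 80, 60))
#' @export
grid3d <- function(origin, spacing, dims, axes = c("L-R", "A-P", "I-S")) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  axes <- as.character(axes)
  if (length(origin) != 3 || length(spacing) != 3 || length(dims) != 3 ||
      length(axes) != 3) {
    stop("origin, spacing, dims and axes must each have length 3",
         call. = FALSE)
  }
  if (any(!is.finite(origin))) stop("origin must be finite", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be strictly positive", call. = FALSE)
  }
  if (any(is.na(dims)) || any(dims < 1)) {
    stop("dims must be positive integers", call. = FALSE)
  }
  if (!all(axes %in% .axis_labels)) {
    stop("axes must be labels from: ", paste(.axis_labels, collapse = ", "),
         call. = FALSE)
  }
  fams <- vapply(axes, .axis_family, character(1))
  if (!setequal(fams, c("lateral", "ap", "is"))) {
    stop("axes must cover lateral, anterior-posterior and ",
         "inferior-superior exactly once", call. = FALSE)
  }
  structure(
    list(origin = origin, spacing = spacing, dims = dims, axes = axes),
    class = "grid3d"
  )
}

#' @export
print.grid3d <- function(x, ...) {
  cat("grid3d:", paste(x$dims, collapse = " x "), "voxels,",
      paste(format(x$spacing), collapse = " x "), "mm spacing\n")
  cat("  origin (mm):", paste(format(x$origin), collapse = ", "), "\n")
  cat("  axes:", paste(x$axes, collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-centre coordinates along one grid axis
#'
#' @param grid a [grid3d()].
#' @param axis integer in 1..3, the array index axis.
#' @return Numeric vector of patient-space mm positions of voxel centres.
#' @export
axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "grid3d"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Volume of one voxel in mm^3
#' @param grid a [grid3d()].
#' @return Scalar voxel volume (product of the spacings), mm^3.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "grid3d"))
  prod(grid$spacing)
}

# Nearest voxel index along `axis` for coordinate(s) x, ties broken toward
# the lower index. Returns possibly out-of-range indices; callers clamp or
# reject.
.nearest_index <- function(grid, axis, x) {
  t <- (x - grid$origin[axis]) / grid$spacing[axis]
  as.integer(ceiling(t - 0.5)) + 1L
}

# Geometric equality of two grids (same lattice).
.same_grid <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) && identical(a$axes, b$axes) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}
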