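#' Dose grid: voxel lattice plus per-voxel dose in cGy
#'
#' All doses in this package are stored in cGy (100 cGy = 1 Gy), the unit in
#' which clinical plans are reported.
#'
#' @param grid a [grid3d()].
#' @param dose numeric array of non-negative doses (cGy), dimensions equal
#'   to `grid$dims`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose) {
  stopifnot(inherits(grid, "grid3d"))
  dose <- as.array(dose)
  storage.mode(dose) <- "double"
  if (!identical(dim(dose), as.integer(grid$dims))) {
    stop("dose dimensions must equal grid dims", call. = FALSE)
  }
  if (anyNA(dose) || any(dose < 0)) {
    stop("dose must be non-negative and finite", call. = FALSE)
  }
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("dose_grid:", paste(x$grid$dims, collapse = " x "), "voxels,",
      "dose range", paste(format(range(x$dose), digits = 5),
                          collapse = " - "), "cGy\n")
  invisible(x)
}

# Doses of the occupied voxels; errors on empty mask or grid mismatch.
.structure_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!.same_grid(dose$grid, mask$grid)) {
    stop("mask and dose are on different grids; resample the mask onto ",
         "the dose grid first", call. = FALSE)
  }
  d <- dose$dose[mask$occupancy]
  if (length(d) == 0) {
    stop("empty structure: no occupied voxels", call. = FALSE)
  }
  d
}

#' Cumulative dose-volume histogram
#'
#' For each dose bin edge d, the percentage of the structure's volume
#' receiving at least d: `v_ge(d) = 100 * #\{voxels with dose >= d\} / M`.
#' The curve starts at 100% at 0 cGy, is monotone non-increasing, and
#' reaches 0% one bin past the structure maximum. Binning is for curve
#' export and plotting only; the point metrics ([dose_at_volume()] etc.) use
#' exact voxel order statistics and are independent of `bin_width`.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @param bin_width bin width in cGy (default 10).
#' @return An object of class `cumulative_dvh`: list with `bin_edges` (cGy),
#'   `v_ge` (percent), `total_volume_cc` and `structure_name`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 10) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  d <- .structure_doses(dose, mask)
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width,
               by = bin_width)
  counts <- vapply(edges, function(e) sum(d >= e), numeric(1))
  structure(
    list(bin_edges = edges, v_ge = 100 * counts / length(d),
         total_volume_cc = mask_volume(mask),
         structure_name = mask$structure_name),
    class = "cumulative_dvh"
  )
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat("cumulative_dvh '", x$structure_name, "': ",
      length(x$bin_edges), " bins to ", max(x$bin_edges), " cGy, volume ",
      format(x$total_volume_cc, digits = 4), " cc\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cumulative_dvh <- function(x, ...) {
  data.frame(dose_cGy = x$bin_edges, percent_volume = x$v_ge)
}

#' Dose to the hottest x% of a structure (D_x%)
#'
#' The minimum dose received by the hottest x percent of the structure's
#' volume: with the M occupied voxel doses sorted in descending order,
#' `D_x% = dose at rank ceiling(x/100 * M)`. D_1% is the near-maximum dose,
#' D_99% the near-minimum, D_50% the median-volume dose. Computed from exact
#' voxel order statistics, never from the binned curve.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @param x percent volume in (0, 100].
#' @return Dose in cGy. Vectorised over `x`.
#' @export
dose_at_volume <- function(dose, mask, x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100)) {
    stop("x must lie in (0, 100]", call. = FALSE)
  }
  d <- sort(.structure_doses(dose, mask), decreasing = TRUE)
  m <- length(d)
  rank <- pmin(pmax(ceiling(x * m / 100 - 1e-9), 1L), m)
  d[rank]
}

#' Percent volume receiving at least a dose (V_d)
#'
#' `V_d = 100 * #\{voxels with dose >= d\} / M`. A voxel exactly at the
#' threshold counts as irradiated.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @param d threshold dose in cGy, >= 0.
#' @return Percent volume in \[0, 100\]. Vectorised over `d`.
#' @export
volume_at_dose <- function(dose, mask, d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("threshold dose must be non-negative", call. = FALSE)
  }
  doses <- .structure_doses(dose, mask)
  vapply(d, function(thr) 100 * sum(doses >= thr) / length(doses),
         numeric(1))
}

#' Mean structure dose (D_mean)
#'
#' Arithmetic mean of the occupied-voxel doses. With uniform voxel volume
#' this equals the volume-weighted mean dose.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @return Mean dose in cGy.
#' @export
mean_dose <- function(dose, mask) {
  mean(.structure_doses(dose, mask))
}

#' Bundle of the standard clinical dose metrics
#'
#' Computes D_x% for the requested percentiles (default 1, 50, 99), D_mean,
#' and V_d for the requested thresholds. Thresholds are given in Gy, the
#' unit in which V metrics are conventionally named (V_5 = volume receiving
#' at least 5 Gy = 500 cGy); doses are returned in cGy.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @param v_thresholds_gy numeric vector of V thresholds in Gy (default
#'   `c(5, 10, 15, 20, 30, 40, 50)`); may be empty.
#' @param d_percents numeric vector of D percentiles (default
#'   `c(1, 50, 99)`).
#' @return An object of class `dose_metrics`: list with `d` (named vector,
#'   cGy, names `"D1"`, `"D50"`, ...), `dmean` (cGy), `v_at` (named percent
#'   vector, names `"V5"`, ...), `volume_cc` and `structure_name`.
#' @export
metrics_bundle <- function(dose, mask,
                           v_thresholds_gy = c(5, 10, 15, 20, 30, 40, 50),
                           d_percents = c(1, 50, 99)) {
  dx <- if (length(d_percents)) {
    stats::setNames(dose_at_volume(dose, mask, d_percents),
                    paste0("D", d_percents))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  vx <- if (length(v_thresholds_gy)) {
    stats::setNames(volume_at_dose(dose, mask, 100 * v_thresholds_gy),
                    paste0("V", v_thresholds_gy))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(
    list(d = dx, dmean = mean_dose(dose, mask), v_at = vx,
         volume_cc = mask_volume(mask),
         structure_name = mask$structure_name),
    class = "dose_metrics"
  )
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat("dose_metrics '", x$structure_name, "' (",
      format(x$volume_cc, digits = 4), " cc)\n", sep = "")
  for (nm in names(x$d)) {
    cat(sprintf("  %-6s %9.1f cGy\n", paste0(nm, "%"), x$d[[nm]]))
  }
  cat(sprintf("  %-6s %9.1f cGy\n", "Dmean", x$dmean))
  for (nm in names(x$v_at)) {
    cat(sprintf("  %-6s %8.2f %%\n", nm, x$v_at[[nm]]))
  }
  invisible(x)
}
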