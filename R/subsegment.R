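#' Head/body/tail layer-ratio parameters
#'
#' Fractions of the anterior-to-posterior layer count assigned to the head,
#' body and tail of the structure. The default 0.35/0.45/0.20 is the
#' conventional hippocampal head/body/tail split.
#'
#' @param head,body,tail fractions in (0, 1) summing to 1 (tolerance 1e-9).
#' @return An object of class `subregion_ratios`.
#' @export
subregion_ratios <- function(head = 0.35, body = 0.45, tail = 0.20) {
  r <- c(head = head, body = body, tail = tail)
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1)) {
    stop("ratios must lie strictly between 0 and 1", call. = FALSE)
  }
  if (abs(sum(r) - 1) > 1e-9) {
    stop("ratios must sum to 1 (got ", format(sum(r)), ")", call. = FALSE)
  }
  structure(as.list(r), class = "subregion_ratios")
}

#' Locate the anterior-posterior axis of a grid
#'
#' Resolves which array index axis runs anterior-posterior and whether the
#' index increases from anterior to posterior, so layer counting and
#' splitting can be written front-to-back regardless of storage order.
#'
#' @param grid a [grid3d()].
#' @return List with `axis` (1, 2 or 3) and `flip` (`TRUE` when increasing
#'   index runs posterior to anterior).
#' @export
orient_axis <- function(grid) {
  stopifnot(inherits(grid, "grid3d"))
  k <- which(grid$axes %in% c("A-P", "P-A"))
  if (length(k) != 1) {
    stop("grid axes do not identify an anterior-posterior axis",
         call. = FALSE)
  }
  list(axis = k, flip = grid$axes[k] == "P-A")
}

# Round half away from zero for positive x; the 1e-9 nudge absorbs binary
# representation shortfall in products like 0.35 * 10.
.round_half_up <- function(x) floor(x + 0.5 + 1e-9)

# Logical vector: which slices along `axis` hold any occupied voxel.
.occupied_slices <- function(mask, axis) {
  apply(mask$occupancy, axis, any)
}

#' Count coronal layers spanned by a structure
#'
#' Number of slices along the anterior-posterior axis between the first and
#' last occupied slice, inclusive (the span). Interior gaps — slices inside
#' the span where the delineation happens to be empty — still count, so a
#' single missing layer does not shift the subregion boundaries.
#'
#' @param mask a non-empty [structure_mask()].
#' @param axis optional axis index; defaults to the grid's
#'   anterior-posterior axis from [orient_axis()].
#' @return Integer layer count N >= 1.
#' @export
count_layers <- function(mask, axis = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (is.null(axis)) axis <- orient_axis(mask$grid)$axis
  occ <- .occupied_slices(mask, axis)
  if (!any(occ)) stop("empty structure: no occupied voxels", call. = FALSE)
  rng <- range(which(occ))
  as.integer(rng[2] - rng[1] + 1L)
}

#' Split a structure into head, body and tail by layer ratios
#'
#' With N span layers ordered anterior to posterior, the head receives
#' layers `1..c1`, the body `c1+1..c2` and the tail the rest, where
#' `c1 = round_half_up(f_head * N)` and
#' `c2 = round_half_up((f_head + f_body) * N)`. Rounding the cumulative
#' boundaries guarantees the three counts sum to N exactly. Layers are
#' assigned whole — no layer is divided between subregions — and every
#' parent voxel on a layer goes to that layer's subregion, so the three
#' sub-masks partition the parent exactly.
#'
#' @param mask a [structure_mask()] spanning at least 3 layers.
#' @param ratios a [subregion_ratios()].
#' @param axis optional anterior-posterior axis override (1, 2 or 3, with
#'   orientation taken from the grid labels).
#' @return An object of class `subregion_split`: list with `head`, `body`,
#'   `tail` ([structure_mask()]s), `boundary_layers` (span-relative layer
#'   indices of the last head layer and last body layer), and `n_layers`.
#' @examples
#' # a 20-layer slab splits 7/9/4 layers = exactly 35/45/20 % by volume
#' @export
split_structure <- function(mask, ratios = subregion_ratios(), axis = NULL) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(ratios, "subregion_ratios"))
  ori <- orient_axis(mask$grid)
  if (is.null(axis)) axis <- ori$axis
  flip <- if (axis == ori$axis) ori$flip else FALSE
  occ <- .occupied_slices(mask, axis)
  if (!any(occ)) stop("empty structure: no occupied voxels", call. = FALSE)
  rng <- range(which(occ))
  n <- as.integer(rng[2] - rng[1] + 1L)
  if (n < 3) {
    stop("structure spans only ", n,
         " layer(s); at least 3 are needed for a head/body/tail split",
         call. = FALSE)
  }
  c1 <- .round_half_up(ratios$head * n)
  c2 <- .round_half_up((ratios$head + ratios$body) * n)
  if (c1 < 1 || c2 <= c1 || c2 >= n) {
    stop("ratios yield an empty subregion for N = ", n, " layers",
         call. = FALSE)
  }
  # span slice indices ordered anterior -> posterior
  span <- seq.int(rng[1], rng[2])
  if (flip) span <- rev(span)
  part <- list(head = span[seq_len(c1)],
               body = span[seq.int(c1 + 1L, c2)],
               tail = span[seq.int(c2 + 1L, n)])
  sub <- lapply(names(part), function(nm) {
    occ_sub <- array(FALSE, dim = mask$grid$dims)
    sel <- .slice_index(mask$grid$dims, axis, part[[nm]])
    occ_sub[sel] <- mask$occupancy[sel]
    structure_mask(mask$grid, occ_sub,
                   paste(mask$structure_name, nm, sep = "_"))
  })
  names(sub) <- names(part)
  structure(
    list(head = sub$head, body = sub$body, tail = sub$tail,
         boundary_layers = c(c1, c2), n_layers = n),
    class = "subregion_split"
  )
}

# Logical array selecting whole slices `which` along `axis`.
.slice_index <- function(dims, axis, which) {
  sel <- array(FALSE, dim = dims)
  if (axis == 1) sel[which, , ] <- TRUE
  else if (axis == 2) sel[, which, ] <- TRUE
  else sel[, , which] <- TRUE
  sel
}

#' @export
print.subregion_split <- function(x, ...) {
  v <- vapply(x[c("head", "body", "tail")], mask_volume, numeric(1))
  cat("subregion_split over", x$n_layers, "layers",
      "(boundaries after layers",
      paste(x$boundary_layers, collapse = " and "), ")\n")
  cat(sprintf("  %-5s %8.3f cc (%.1f%%)\n", names(v), v,
              100 * v / sum(v)), sep = "")
  invisible(x)
}
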