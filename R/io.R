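# Internal plain-text exchange formats: JSON for contours, masks and dose
# grids; CSV for cohort tables. All formats are self-describing and carry
# the grid geometry, so files can be moved between runs and machines.

.grid_to_list <- function(grid) {
  list(origin_mm = grid$origin, spacing_mm = grid$spacing,
       dims = grid$dims, axes = grid$axes)
}

.grid_from_list <- function(x) {
  grid3d(unlist(x$origin_mm), unlist(x$spacing_mm), unlist(x$dims),
         unlist(x$axes))
}

#' Read and write contour sets (internal JSON format)
#'
#' The format is
#' `{structure_name, planes: [{z_mm, polygons: [[[x, y], ...], ...]}]}` with
#' coordinates in patient mm; polygon stacking is along the grid's third
#' index axis.
#'
#' @param path file path.
#' @return `read_contours()` returns a [contour_set()].
#' @export
read_contours <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$structure_name) || is.null(x$planes)) {
    stop("not a contour file: missing structure_name or planes",
         call. = FALSE)
  }
  planes <- lapply(x$planes, function(p) {
    polys <- lapply(p$polygons, function(poly) {
      do.call(rbind, lapply(poly, function(v) as.numeric(unlist(v))))
    })
    list(z_mm = as.numeric(p$z_mm), polygons = polys)
  })
  contour_set(as.character(x$structure_name), planes)
}

#' @rdname read_contours
#' @param contours a [contour_set()].
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  planes <- lapply(contours$planes, function(p) {
    list(z_mm = p$z_mm,
         polygons = lapply(p$polygons, function(poly) {
           lapply(seq_len(nrow(poly)), function(i) as.numeric(poly[i, ]))
         }))
  })
  jsonlite::write_json(
    list(structure_name = contours$structure_name, planes = planes),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read and write structure masks (internal JSON format)
#'
#' Occupancy is stored as a flat 0/1 vector in column-major (R array)
#' order together with the grid geometry.
#'
#' @param path file path.
#' @return `read_mask()` returns a [structure_mask()].
#' @export
read_mask <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$grid) || is.null(x$occupancy)) {
    stop("not a mask file: missing grid or occupancy", call. = FALSE)
  }
  grid <- .grid_from_list(x$grid)
  structure_mask(grid, array(as.logical(x$occupancy), dim = grid$dims),
                 as.character(x$structure_name))
}

#' @rdname read_mask
#' @param mask a [structure_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  jsonlite::write_json(
    list(structure_name = mask$structure_name,
         grid = .grid_to_list(mask$grid),
         occupancy = as.integer(mask$occupancy)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read and write dose grids (internal JSON format)
#'
#' Dose is stored in cGy as a flat vector in column-major (R array) order
#' together with the grid geometry.
#'
#' @param path file path.
#' @return `read_dose_grid()` returns a [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$grid) || is.null(x$dose_cgy)) {
    stop("not a dose file: missing grid or dose_cgy", call. = FALSE)
  }
  grid <- .grid_from_list(x$grid)
  dose_grid(grid, array(as.numeric(x$dose_cgy), dim = grid$dims))
}

#' @rdname read_dose_grid
#' @param dose a [dose_grid()].
#' @export
write_dose_grid <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  jsonlite::write_json(
    list(grid = .grid_to_list(dose$grid), dose_cgy = as.numeric(dose$dose)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Writes per-patient dose and structure files in the internal JSON formats
#' plus a cohort manifest CSV (columns `id, dose, left, right, pre, post`)
#' that [load_cohort()] and `run_study(mode = "files")` consume.
#'
#' @param cohort list of `patient_phantom`s from [make_cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    fd <- file.path(dir, paste0(p$id, "_dose.json"))
    fl <- file.path(dir, paste0(p$id, "_hc_l.json"))
    fr <- file.path(dir, paste0(p$id, "_hc_r.json"))
    write_dose_grid(p$dose, fd)
    write_mask(p$left, fl)
    write_mask(p$right, fr)
    data.frame(id = p$id, dose = basename(fd), left = basename(fl),
               right = basename(fr),
               pre = if (is.null(p$scores)) NA else p$scores[["pre"]],
               post = if (is.null(p$scores)) NA else p$scores[["post"]],
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a cohort from a manifest CSV
#'
#' @param manifest path to a cohort manifest as written by [write_cohort()];
#'   structure entries may be mask JSON or contour JSON (contours are
#'   rasterized onto the patient's dose grid).
#' @return List of `patient_phantom` objects.
#' @export
load_cohort <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "dose", "left", "right")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    dose <- read_dose_grid(file.path(dir, tab$dose[i]))
    read_structure <- function(f) {
      x <- jsonlite::read_json(file.path(dir, f), simplifyVector = FALSE)
      if (!is.null(x$planes)) {
        rasterize_contours(read_contours(file.path(dir, f)), dose$grid)
      } else {
        read_mask(file.path(dir, f))
      }
    }
    scores <- NULL
    if (all(c("pre", "post") %in% names(tab)) &&
        !is.na(tab$pre[i]) && !is.na(tab$post[i])) {
      scores <- c(pre = tab$pre[i], post = tab$post[i])
    }
    structure(
      list(id = tab$id[i], left = read_structure(tab$left[i]),
           right = read_structure(tab$right[i]), dose = dose,
           scores = scores),
      class = "patient_phantom"
    )
  })
}
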