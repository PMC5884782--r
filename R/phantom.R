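#' Configuration of the synthetic phantom cohort
#'
#' Parameters of the synthetic study: a head-sized voxel lattice, bilateral
#' hippocampus-like curved tubes running anterior-inferior to
#' posterior-superior, and a dose field peaked at a nasopharynx-like point
#' anterior-inferior-medial to the structures, decaying exponentially with
#' distance. Because the source sits in front of and below the hippocampal
#' heads, mean dose falls from head to body to tail — the spatial
#' relationship the analysis is designed to quantify.
#'
#' @param dims grid size in voxels (default 80 x 80 x 60).
#' @param spacing voxel spacing mm (default 2 mm isotropic).
#' @param origin patient-space mm of the first voxel centre.
#' @param hc_length_mm hippocampus centreline length (default 35 mm).
#' @param hc_radius_mm tube radius (default 5 mm).
#' @param curvature_mm lateral bow of the centreline (default 4 mm).
#' @param lateral_offset_mm distance of each hippocampus from the
#'   mid-sagittal plane (default 25 mm).
#' @param source_point_mm nasopharynx-like dose maximum, anterior-inferior
#'   and medial to both structures.
#' @param d0_cgy peak dose in cGy (default 7040, a typical nasopharyngeal
#'   prescription of 7040 cGy in 32 fractions).
#' @param lambda_mm exponential falloff length (default 25 mm), chosen so
#'   hippocampal mean doses land in the 500-3000 cGy range reported for
#'   nasopharyngeal plans without hippocampal sparing.
#' @param jitter_sdlog per-patient multiplicative lognormal dose jitter
#'   (sdlog, default 0.2), emulating inter-patient anatomy and plan
#'   variation.
#' @param anat_sd relative SD of per-patient anatomical jitter applied to
#'   length, radius and lateral offset (default 0.06).
#' @param score_mu_pre,score_sd mean and SD of the pre-treatment digit-span
#'   score (defaults 8.6 and 1.34).
#' @param score_delta mean post-treatment score drop (default 0.6).
#' @param score_noise_sd SD of the per-patient drop (default 1.0).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(80, 80, 60),
                           spacing = c(2, 2, 2),
                           origin = c(0, 0, 0),
                           hc_length_mm = 35,
                           hc_radius_mm = 5,
                           curvature_mm = 4,
                           lateral_offset_mm = 25,
                           source_point_mm = c(79, 45, 35),
                           d0_cgy = 7040,
                           lambda_mm = 25,
                           jitter_sdlog = 0.2,
                           anat_sd = 0.06,
                           score_mu_pre = 8.6,
                           score_sd = 1.34,
                           score_delta = 0.6,
                           score_noise_sd = 1.0) {
  cfg <- list(
    grid = grid3d(origin, spacing, dims),
    hc_length_mm = hc_length_mm, hc_radius_mm = hc_radius_mm,
    curvature_mm = curvature_mm, lateral_offset_mm = lateral_offset_mm,
    source_point_mm = as.numeric(source_point_mm),
    d0_cgy = d0_cgy, lambda_mm = lambda_mm,
    jitter_sdlog = jitter_sdlog, anat_sd = anat_sd,
    score_mu_pre = score_mu_pre, score_sd = score_sd,
    score_delta = score_delta, score_noise_sd = score_noise_sd
  )
  pos <- c(cfg$hc_length_mm, cfg$hc_radius_mm, cfg$lateral_offset_mm,
           cfg$d0_cgy, cfg$lambda_mm)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("lengths, d0 and lambda must be strictly positive", call. = FALSE)
  }
  if (cfg$curvature_mm < 0 || cfg$jitter_sdlog < 0 || cfg$anat_sd < 0) {
    stop("curvature and jitter parameters must be non-negative",
         call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

# Hippocampus centreline for one side, in (lateral-from-midline, y, z)
# coordinates. Runs anterior-inferior -> posterior-superior at ~30 degrees
# elevation, with a sinusoidal lateral bow.
.hc_centreline <- function(config, n = 200, length_mm = NULL,
                           offset_mm = NULL) {
  if (is.null(length_mm)) length_mm <- config$hc_length_mm
  if (is.null(offset_mm)) offset_mm <- config$lateral_offset_mm
  t <- seq(0, 1, length.out = n)
  elev <- pi / 6
  list(
    u = offset_mm + config$curvature_mm * sin(pi * t),
    y = 60 + t * length_mm * cos(elev),
    z = 50 + t * length_mm * sin(elev)
  )
}

#' Generate one hippocampus-like structure mask
#'
#' A curved tube of the configured length and radius running
#' anterior-inferior to posterior-superior, mirrored across the mid-sagittal
#' plane between the two sides. A voxel is occupied when its centre lies
#' within the tube radius of the sampled centreline. Per-patient anatomical
#' jitter (length, radius, lateral offset) is drawn from `seed`; both sides
#' of a patient use the same seed, so left and right are mirror images.
#'
#' @param config a [phantom_config()].
#' @param side `"left"` or `"right"`.
#' @param seed integer seed for the anatomical jitter; `NULL` for the
#'   unjittered template anatomy.
#' @return A [structure_mask()] named `"HC-L"` or `"HC-R"`.
#' @export
make_hippocampus <- function(config, side = c("left", "right"),
                             seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  side <- match.arg(side)
  jit <- if (!is.null(seed) && config$anat_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    j <- exp(stats::rnorm(3, 0, config$anat_sd))
    .Random.seed_restore(old)
    j
  } else {
    c(1, 1, 1)
  }
  len <- config$hc_length_mm * jit[1]
  rad <- config$hc_radius_mm * jit[2]
  off <- config$lateral_offset_mm * jit[3]
  grid <- config$grid
  cl <- .hc_centreline(config, length_mm = len, offset_mm = off)
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  mid <- (xs[1] + xs[length(xs)]) / 2
  s <- if (side == "right") 1 else -1
  u <- s * (xs - mid)   # signed lateral distance, positive on this side
  # bounding box in index space to keep the distance scan small
  pad <- rad + max(grid$spacing)
  bi <- which(u >= min(cl$u) - pad & u <= max(cl$u) + pad)
  bj <- which(ys >= min(cl$y) - pad & ys <= max(cl$y) + pad)
  bk <- which(zs >= min(cl$z) - pad & zs <= max(cl$z) + pad)
  if (length(bi) == 0 || length(bj) == 0 || length(bk) == 0 ||
      min(cl$y) - rad < ys[1] - grid$spacing[2] ||
      max(cl$y) + rad > ys[length(ys)] + grid$spacing[2] ||
      min(cl$z) - rad < zs[1] - grid$spacing[3] ||
      max(cl$z) + rad > zs[length(zs)] + grid$spacing[3]) {
    stop("configured structure does not fit inside the grid", call. = FALSE)
  }
  nu <- length(bi); ny <- length(bj); nz <- length(bk)
  U <- array(rep(u[bi], times = ny * nz), dim = c(nu, ny, nz))
  Y <- array(rep(rep(ys[bj], each = nu), times = nz), dim = c(nu, ny, nz))
  Z <- array(rep(zs[bk], each = nu * ny), dim = c(nu, ny, nz))
  mind <- array(Inf, dim = c(nu, ny, nz))
  for (k in seq_along(cl$u)) {
    d2 <- (U - cl$u[k])^2 + (Y - cl$y[k])^2 + (Z - cl$z[k])^2
    mind <- pmin(mind, d2)
  }
  occ <- array(FALSE, dim = grid$dims)
  occ[bi, bj, bk] <- mind <= rad^2
  mask <- structure_mask(grid, occ,
                         if (side == "left") "HC-L" else "HC-R")
  if (count_layers(mask) < 3) {
    stop("configured structure spans fewer than 3 coronal layers",
         call. = FALSE)
  }
  mask
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a nasopharynx-centred dose field
#'
#' `dose(v) = d0 * j * exp(-||v - source|| / lambda)` with a per-patient
#' multiplicative lognormal jitter `j` (median 1). For fixed `j` the field
#' is strictly decreasing with distance from the source point, so any
#' structure farther from the source receives less dose everywhere.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for the jitter draw; `NULL` gives `j = 1`.
#' @return A [dose_grid()].
#' @export
make_dose_field <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  j <- 1
  if (!is.null(seed) && config$jitter_sdlog > 0) {
    old <- .Random.seed_save()
    set.seed(seed + 1L)
    j <- stats::rlnorm(1, meanlog = 0, sdlog = config$jitter_sdlog)
    .Random.seed_restore(old)
  }
  sp <- config$source_point_mm
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  n1 <- grid$dims[1]; n2 <- grid$dims[2]; n3 <- grid$dims[3]
  r2 <- rep((xs - sp[1])^2, times = n2 * n3) +
    rep(rep((ys - sp[2])^2, each = n1), times = n3) +
    rep((zs - sp[3])^2, each = n1 * n2)
  dose <- config$d0_cgy * j * exp(-sqrt(r2) / config$lambda_mm)
  dose_grid(grid, array(dose, dim = grid$dims))
}

#' Generate a cohort of patient phantoms
#'
#' Per-patient seeds are derived reproducibly from the master seed; each
#' patient gets bilateral hippocampus masks (shared anatomical jitter, so
#' left and right mirror), a jittered dose field, and optionally a paired
#' pre/post digit-span score. Scores are drawn as
#' `pre ~ round(N(mu_pre, sd^2))`, `post = round(pre - delta + noise)`, both
#' clipped to the digit-span range 0-17.
#'
#' @param n_patients number of patients, >= 1.
#' @param config a [phantom_config()].
#' @param seed master integer seed.
#' @param with_scores generate paired cognitive scores? (default `TRUE`)
#' @return List of `patient_phantom` objects: `id`, `left`, `right`
#'   ([structure_mask()]s), `dose` ([dose_grid()]), `scores` (named vector
#'   `pre`/`post`, or `NULL`).
#' @export
make_cohort <- function(n_patients, config = phantom_config(), seed = 1,
                        with_scores = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  patient_seeds <- sample.int(.Machine$integer.max - 2L, n_patients)
  lapply(seq_len(n_patients), function(i) {
    ps <- patient_seeds[i]
    left <- make_hippocampus(config, "left", seed = ps)
    right <- make_hippocampus(config, "right", seed = ps)
    dose <- make_dose_field(config, seed = ps)
    scores <- NULL
    if (with_scores) {
      set.seed(ps + 2L)
      pre <- round(stats::rnorm(1, config$score_mu_pre, config$score_sd))
      drop <- config$score_delta +
        if (config$score_noise_sd > 0) {
          stats::rnorm(1, 0, config$score_noise_sd)
        } else 0
      post <- round(pre - drop)
      scores <- c(pre = min(max(pre, 0), 17), post = min(max(post, 0), 17))
    }
    structure(
      list(id = sprintf("P%02d", i), left = left, right = right,
           dose = dose, scores = scores),
      class = "patient_phantom"
    )
  })
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat("patient_phantom", x$id, "- volumes",
      format(mask_volume(x$left), digits = 4), "/",
      format(mask_volume(x$right), digits = 4), "cc (L/R)\n")
  invisible(x)
}
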