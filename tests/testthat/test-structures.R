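test_that("grid3d validates geometry and axes", {
  g <- grid3d(c(0, 0, 0), c(2, 2, 3), c(10, 20, 30))
  expect_s3_class(g, "grid3d")
  expect_equal(axis_coords(g, 3), seq(0, by = 3, length.out = 30))
  expect_equal(voxel_volume_mm3(g), 12)
  expect_error(grid3d(c(0, 0, 0), c(0, 1, 1), c(5, 5, 5)), "positive")
  expect_error(grid3d(c(0, 0, 0), c(1, 1, 1), c(5, 0, 5)), "positive")
  expect_error(grid3d(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5),
                      axes = c("L-R", "L-R", "I-S")), "exactly once")
  expect_error(grid3d(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5),
                      axes = c("up", "down", "left")), "labels")
})

test_that("an axis-aligned square rasterizes to exactly its interior voxels", {
  g <- unit_grid(c(10, 10, 1), origin = c(0.5, 0.5, 0))
  cs <- contour_set("sq", list(
    list(z_mm = 0, polygons = list(square_poly(0, 0, 10)))
  ))
  m <- rasterize_contours(cs, g)
  expect_equal(sum(m$occupancy), 100)
  expect_equal(m$structure_name, "sq")
})

test_that("an empty contour set rasterizes to an all-false mask", {
  g <- unit_grid(c(5, 5, 3))
  m <- rasterize_contours(contour_set("empty"), g)
  expect_false(any(m$occupancy))
})

test_that("rasterization matches the brute-force point-in-polygon oracle", {
  g <- unit_grid(c(10, 10, 1), origin = c(0.5, 0.5, 0))
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cs <- contour_set("tri", list(list(z_mm = 0, polygons = list(tri))))
  m <- rasterize_contours(cs, g)
  expect_equal(sum(m$occupancy), rasterize_oracle_count(g, tri))

  set.seed(7)
  for (rep in 1:5) {
    k <- sample(4:8, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    r <- stats::runif(k, 2, 5)
    poly <- cbind(5 + r * cos(ang), 5 + r * sin(ang))
    cs <- contour_set("p", list(list(z_mm = 0, polygons = list(poly))))
    m <- rasterize_contours(cs, g)
    expect_equal(sum(m$occupancy), rasterize_oracle_count(g, poly))
  }
})

test_that("nested polygons carve holes by the even-odd rule", {
  g <- unit_grid(c(10, 10, 1), origin = c(0.5, 0.5, 0))
  cs <- contour_set("ring", list(list(
    z_mm = 0,
    polygons = list(square_poly(0, 0, 10), square_poly(3, 3, 4))
  )))
  m <- rasterize_contours(cs, g)
  expect_equal(sum(m$occupancy), 100 - 16)
  expect_false(m$occupancy[5, 5, 1])
  expect_true(m$occupancy[1, 1, 1])
})

test_that("rasterization rejects bad polygons and out-of-extent planes", {
  g <- unit_grid(c(5, 5, 2))
  expect_error(
    contour_set("bad", list(list(z_mm = 0.5,
                                 polygons = list(rbind(c(0, 0), c(1, 1)))))),
    "invalid contour"
  )
  cs <- contour_set("far", list(
    list(z_mm = 50, polygons = list(square_poly(0, 0, 2)))
  ))
  expect_error(rasterize_contours(cs, g), "outside the grid extent")
})

test_that("contour planes map to the nearest slice, ties toward lower index", {
  g <- unit_grid(c(5, 5, 4), origin = c(0.5, 0.5, 0))  # slices at z 0,1,2,3
  sq <- square_poly(0, 0, 5)
  m <- rasterize_contours(
    contour_set("s", list(list(z_mm = 1.4, polygons = list(sq)))), g)
  expect_equal(which(apply(m$occupancy, 3, any)), 2L)
  m <- rasterize_contours(
    contour_set("s", list(list(z_mm = 1.5, polygons = list(sq)))), g)
  expect_equal(which(apply(m$occupancy, 3, any)), 2L)  # tie -> lower slice
  m <- rasterize_contours(
    contour_set("s", list(list(z_mm = 1.6, polygons = list(sq)))), g)
  expect_equal(which(apply(m$occupancy, 3, any)), 3L)
})

test_that("rasterized area converges to polygon area as spacing shrinks", {
  poly <- rbind(c(1.3, 1.1), c(8.7, 2.2), c(7.9, 8.4), c(2.1, 7.3))
  shoelace <- function(p) {
    n <- nrow(p)
    j <- c(n, seq_len(n - 1))
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  area <- shoelace(poly)
  err <- vapply(c(0.5, 0.125), function(sp) {
    n <- as.integer(10 / sp)
    g <- grid3d(c(sp / 2, sp / 2, 0), c(sp, sp, 1), c(n, n, 1))
    m <- rasterize_contours(
      contour_set("p", list(list(z_mm = 0, polygons = list(poly)))), g)
    abs(sum(m$occupancy) * sp^2 - area) / area
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("rasterization is deterministic", {
  g <- unit_grid(c(8, 8, 2))
  poly <- rbind(c(1, 1), c(7, 2), c(6, 7), c(2, 6))
  cs <- contour_set("p", list(list(z_mm = 0.5, polygons = list(poly))))
  m1 <- rasterize_contours(cs, g)
  m2 <- rasterize_contours(cs, g)
  expect_identical(m1$occupancy, m2$occupancy)
})

test_that("mask_volume is occupied count times voxel volume, in cc", {
  g1 <- unit_grid(c(10, 10, 10))
  expect_equal(mask_volume(structure_mask(g1, array(TRUE, c(10, 10, 10)))), 1)
  expect_equal(mask_volume(structure_mask(g1, array(FALSE, c(10, 10, 10)))), 0)
  g2 <- grid3d(c(0, 0, 0), c(3, 1, 1.5), c(10, 10, 1))
  occ <- array(FALSE, c(10, 10, 1))
  occ[seq_len(100)] <- TRUE
  expect_equal(mask_volume(structure_mask(g2, occ)), 0.45)
})

test_that("resampling onto the identical grid is the identity", {
  g <- unit_grid(c(6, 7, 8))
  set.seed(3)
  m <- random_mask(g)
  expect_identical(resample_mask(m, g)$occupancy, m$occupancy)
})

test_that("a fully occupied mask resamples to a fully occupied sub-grid", {
  g <- unit_grid(c(10, 10, 10))
  m <- structure_mask(g, array(TRUE, c(10, 10, 10)))
  sub <- grid3d(c(2.5, 2.5, 2.5), c(1, 1, 1), c(5, 5, 5))
  expect_true(all(resample_mask(m, sub)$occupancy))
})

test_that("2x downsampling preserves cuboid volume within one coarse voxel", {
  g <- unit_grid(c(20, 20, 20))
  occ <- array(FALSE, c(20, 20, 20))
  occ[4:15, 5:16, 3:14] <- TRUE
  m <- structure_mask(g, occ)
  coarse <- grid3d(c(1, 1, 1), c(2, 2, 2), c(10, 10, 10))
  m2 <- resample_mask(m, coarse)
  expect_equal(mask_volume(m), 12 * 12 * 12 / 1000)  # direct count, fine grid
  # direct count on the coarse grid: a coarse voxel is occupied iff its
  # centre's nearest fine voxel is occupied, so the extent along each axis
  # can move by at most one coarse voxel
  expect_lt(abs(mask_volume(m2) - mask_volume(m)) / mask_volume(m), 0.2)
})

test_that("disjoint grids resample to an empty mask with a warning", {
  g <- unit_grid(c(5, 5, 5))
  m <- structure_mask(g, array(TRUE, c(5, 5, 5)))
  far <- grid3d(c(100, 100, 100), c(1, 1, 1), c(5, 5, 5))
  expect_warning(out <- resample_mask(m, far), "do not overlap")
  expect_false(any(out$occupancy))
})
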