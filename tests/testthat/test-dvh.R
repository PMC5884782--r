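# A grid + uniform-dose + full-mask trio for the closed-form cases.
uniform_case <- function(dose_cgy = 1000, dims = c(5, 5, 4)) {
  g <- unit_grid(dims)
  list(g = g,
       dose = dose_grid(g, array(dose_cgy, dims)),
       mask = structure_mask(g, array(TRUE, dims)))
}

# 100 voxels with doses 1..100 cGy on a single-slice grid.
ladder_case <- function() {
  g <- unit_grid(c(10, 10, 1))
  list(g = g,
       dose = dose_grid(g, array(1:100, c(10, 10, 1))),
       mask = structure_mask(g, array(TRUE, c(10, 10, 1))))
}

test_that("uniform dose gives a step-function DVH", {
  u <- uniform_case(1000)
  dvh <- compute_dvh(u$dose, u$mask, bin_width = 100)
  expect_equal(dvh$v_ge[dvh$bin_edges <= 1000], rep(100, 11))
  expect_equal(dvh$v_ge[dvh$bin_edges > 1000], 0)
  expect_equal(dvh$total_volume_cc, mask_volume(u$mask))
})

test_that("two equal-volume dose levels cross 50% between them", {
  g <- unit_grid(c(10, 10, 2))
  d <- array(500, c(10, 10, 2))
  d[, , 2] <- 1500
  dose <- dose_grid(g, d)
  mask <- structure_mask(g, array(TRUE, c(10, 10, 2)))
  expect_equal(volume_at_dose(dose, mask, 1000), 50)
  dvh <- compute_dvh(dose, mask, bin_width = 500)
  expect_equal(dvh$v_ge[dvh$bin_edges == 1000], 50)
})

test_that("the DVH curve equals brute-force threshold counting", {
  set.seed(21)
  g <- unit_grid(c(12, 12, 6))
  dose <- random_dose(g)
  mask <- random_mask(g, fill = 0.5)
  dvh <- compute_dvh(dose, mask, bin_width = 250)
  d <- dose$dose[mask$occupancy]
  for (i in seq_along(dvh$bin_edges)) {
    expect_identical(dvh$v_ge[i],
                     100 * sum(d >= dvh$bin_edges[i]) / length(d))
  }
  expect_true(all(diff(dvh$v_ge) <= 0))
  expect_equal(dvh$v_ge[1], 100)
})

test_that("DVH rejects bad inputs", {
  u <- uniform_case()
  empty <- structure_mask(u$g, array(FALSE, u$g$dims))
  expect_error(compute_dvh(u$dose, empty), "empty structure")
  expect_error(compute_dvh(u$dose, u$mask, bin_width = 0), "positive")
  other <- structure_mask(unit_grid(c(5, 5, 4), origin = c(9, 9, 9)),
                          array(TRUE, c(5, 5, 4)))
  expect_error(compute_dvh(u$dose, other), "different grids")
})

test_that("D_x% is the descending rank-ceil(x*M/100) order statistic", {
  u <- uniform_case(1000)
  expect_equal(dose_at_volume(u$dose, u$mask, c(1, 50, 99)),
               rep(1000, 3))
  l <- ladder_case()
  expect_equal(dose_at_volume(l$dose, l$mask, 50), 51)
  expect_equal(dose_at_volume(l$dose, l$mask, 100), 1)
  expect_equal(dose_at_volume(l$dose, l$mask, 1), 100)
  expect_equal(dose_at_volume(l$dose, l$mask, 99), 2)
  expect_error(dose_at_volume(l$dose, l$mask, 0), "\\(0, 100\\]")
  expect_error(dose_at_volume(l$dose, l$mask, 101), "\\(0, 100\\]")
})

test_that("V_d counts the threshold voxel as irradiated", {
  u <- uniform_case(1000)
  expect_equal(volume_at_dose(u$dose, u$mask, 500), 100)
  expect_equal(volume_at_dose(u$dose, u$mask, 1000), 100)  # >= at boundary
  expect_equal(volume_at_dose(u$dose, u$mask, 1500), 0)
  l <- ladder_case()
  expect_equal(volume_at_dose(l$dose, l$mask, 50.5), 50)
  expect_error(volume_at_dose(l$dose, l$mask, -1), "non-negative")
})

test_that("mean dose equals direct summation", {
  u <- uniform_case(1000)
  expect_equal(mean_dose(u$dose, u$mask), 1000)
  l <- ladder_case()
  expect_equal(mean_dose(l$dose, l$mask), 50.5)
  set.seed(5)
  g <- unit_grid(c(9, 9, 9))
  dose <- random_dose(g)
  mask <- random_mask(g)
  d <- dose$dose[mask$occupancy]
  expect_equal(mean_dose(dose, mask), sum(d) / length(d), tolerance = 1e-9)
})

test_that("all metrics match brute-force sort/count oracles on random fields", {
  set.seed(33)
  for (rep in 1:10) {
    g <- unit_grid(c(sample(5:15, 1), sample(5:15, 1), sample(3:8, 1)))
    dose <- random_dose(g)
    mask <- random_mask(g, fill = stats::runif(1, 0.2, 0.8))
    d <- sort(dose$dose[mask$occupancy], decreasing = TRUE)
    m <- length(d)
    for (x in c(1, 50, 99)) {
      expect_identical(dose_at_volume(dose, mask, x),
                       d[max(1, ceiling(x * m / 100))])
    }
    for (thr in c(500, 1000, 2000, 3000, 4000, 5000)) {
      expect_identical(volume_at_dose(dose, mask, thr),
                       100 * sum(d >= thr) / m)
    }
  }
})

test_that("metric bundle composes the dose metrics with Gy thresholds", {
  u <- uniform_case(1000)  # 10 Gy everywhere
  mb <- metrics_bundle(u$dose, u$mask)
  expect_equal(unname(mb$d), rep(1000, 3))
  expect_equal(mb$dmean, 1000)
  expect_equal(unname(mb$v_at[c("V5", "V10")]), c(100, 100))
  expect_equal(unname(mb$v_at[c("V15", "V20", "V30", "V40", "V50")]),
               rep(0, 5))
  mb0 <- metrics_bundle(u$dose, u$mask, v_thresholds_gy = numeric(0))
  expect_length(mb0$v_at, 0)
})

test_that("a front-to-back dose gradient orders the subregion means", {
  g <- unit_grid(c(6, 20, 6))
  d <- array(0, c(6, 20, 6))
  for (j in 1:20) d[, j, ] <- 2100 - 100 * j  # anterior hottest
  dose <- dose_grid(g, d)
  mask <- slab_mask(g, 1:20)
  sp <- split_structure(mask)
  m_head <- mean_dose(dose, sp$head)
  m_body <- mean_dose(dose, sp$body)
  m_tail <- mean_dose(dose, sp$tail)
  expect_gt(m_head, m_body)
  expect_gt(m_body, m_tail)
  # direct computation on the constructed gradient: head = slices 1..7
  expect_equal(m_head, mean(2100 - 100 * (1:7)))
  expect_equal(m_body, mean(2100 - 100 * (8:16)))
  expect_equal(m_tail, mean(2100 - 100 * (17:20)))
})

test_that("D metrics are monotone in x and bounded by the dose range", {
  set.seed(13)
  g <- unit_grid(c(10, 10, 5))
  dose <- random_dose(g)
  mask <- random_mask(g)
  xs <- c(1, 5, 25, 50, 75, 99, 100)
  dx <- dose_at_volume(dose, mask, xs)
  expect_true(all(diff(dx) <= 0))
  d <- dose$dose[mask$occupancy]
  expect_gte(mean_dose(dose, mask), min(d))
  expect_lte(mean_dose(dose, mask), max(d))
})

test_that("doses scale covariantly: D scales by k, V maps threshold by k", {
  set.seed(17)
  g <- unit_grid(c(8, 8, 4))
  dose <- random_dose(g)
  mask <- random_mask(g)
  k <- 2.5
  dose_k <- dose_grid(g, dose$dose * k)
  xs <- c(1, 50, 99)
  expect_equal(dose_at_volume(dose_k, mask, xs),
               k * dose_at_volume(dose, mask, xs))
  expect_equal(mean_dose(dose_k, mask), k * mean_dose(dose, mask))
  thr <- c(400, 1500, 3000)
  expect_equal(volume_at_dose(dose_k, mask, k * thr),
               volume_at_dose(dose, mask, thr))
})
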