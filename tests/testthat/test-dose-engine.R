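test_that("equiangular beam constructor produces the protocol geometry", {
  b9 <- make_equiangular_beams(9, start_deg = 0)
  expect_length(b9$gantry_angles_deg, 9L)
  # brute-force pairwise differencing: spacing uniformly 360/9 = 40 degrees
  expect_equal(unique(diff(b9$gantry_angles_deg)), 40)
  expect_equal(make_equiangular_beams(1, start_deg = 123)$gantry_angles_deg, 123)
  # angle multiset invariant under rotation by 360/n
  rot <- make_equiangular_beams(9, start_deg = 40)
  expect_equal(rot$gantry_angles_deg, b9$gantry_angles_deg)
  expect_error(make_equiangular_beams(0), class = "autoplan_argument_error")
})

test_that("central-axis dose decreases monotonically with depth in water", {
  p <- tiny_phantom(water_only = TRUE)
  infl <- compute_influence(p, make_equiangular_beams(1, start_deg = 0))
  dose <- compute_dose(infl, rep(1, infl$n_beamlets))
  # beam at 0 deg travels toward +y; walk the central axis at the isocenter
  iso_idx <- floor((infl$isocenter_mm - p$origin) / p$spacing) + 1
  axis_dose <- dose$values[iso_idx[1], , iso_idx[3]]
  inside <- which(p$masks$body[iso_idx[1], , iso_idx[3]])
  expect_true(all(diff(axis_dose[inside]) < 0))
})

test_that("zero fluence gives zero dose everywhere", {
  p <- tiny_phantom()
  infl <- compute_influence(p, make_equiangular_beams(2))
  dose <- compute_dose(infl, rep(0, infl$n_beamlets))
  expect_true(all(dose$values == 0))
})

test_that("single-beamlet columns match an independent dense ray-trace", {
  p <- tiny_phantom()
  params <- engine_params()
  infl <- compute_influence(p, make_equiangular_beams(1, start_deg = 30), params)
  shape <- dim(p$density); spacing <- p$spacing; origin <- p$origin
  iso <- infl$isocenter_mm
  th <- 30 * pi / 180
  uy <- cos(th); ux <- sin(th)
  vy <- -ux; vx <- uy
  extent <- sqrt((shape[2] * spacing[2])^2 + (shape[3] * spacing[3])^2)
  K <- ceiling(extent / params$step_mm)

  body_flat <- which(p$masks$body)
  ind <- arrayInd(body_flat, shape)
  # dense oracle: per-voxel scalar ray-trace, no lateral cutoff, no drop tol
  oracle_dose <- function(vi, lat_b, z_b) {
    zc <- origin[1] + (ind[vi, 1] - 0.5) * spacing[1] - iso[1]
    yc <- origin[2] + (ind[vi, 2] - 0.5) * spacing[2] - iso[2]
    xc <- origin[3] + (ind[vi, 3] - 0.5) * spacing[3] - iso[3]
    depth <- 0
    for (k in seq_len(K)) {
      s <- (k - 0.5) * params$step_mm
      py <- yc - s * uy + iso[2]
      px <- xc - s * ux + iso[3]
      iy <- floor((py - origin[2]) / spacing[2]) + 1
      ix <- floor((px - origin[3]) / spacing[3]) + 1
      if (iy >= 1 && iy <= shape[2] && ix >= 1 && ix <= shape[3]) {
        depth <- depth + p$density[ind[vi, 1], iy, ix]
      }
    }
    depth <- depth * params$step_mm
    r2 <- (yc * vy + xc * vx - lat_b)^2 + (zc - z_b)^2
    exp(-params$mu_mm * depth) * exp(-r2 / (2 * params$sigma_mm^2))
  }

  for (j in c(1L, infl$n_beamlets %/% 2L)) {
    col <- infl$A[, j]
    nz <- which(col != 0)
    expect_gt(length(nz), 0)
    expected <- vapply(nz, oracle_dose,
                       numeric(1),
                       lat_b = infl$beamlets[j, "lat_mm"],
                       z_b = infl$beamlets[j, "z_mm"]) * infl$scale
    expect_lt(max(abs(col[nz] - expected) / expected), 1e-6)
  }
})

test_that("every beamlet deposits dose inside the body and entries are nonnegative", {
  p <- tiny_phantom()
  infl <- compute_influence(p, make_equiangular_beams(3))
  expect_true(all(infl$A@x >= 0))
  col_nnz <- diff(infl$A@p)
  expect_true(all(col_nnz >= 1))
})

test_that("forward dose is linear and matches brute-force summation", {
  p <- tiny_phantom()
  infl <- compute_influence(p, make_equiangular_beams(2))
  set.seed(11)
  w1 <- runif(infl$n_beamlets, 0, 100)
  w2 <- runif(infl$n_beamlets, 0, 100)
  d1 <- compute_dose(infl, w1)$values
  d2 <- compute_dose(infl, w2)$values
  d12 <- compute_dose(infl, w1 + w2)$values
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
  expect_equal(compute_dose(infl, 2 * w1)$values, 2 * d1, tolerance = 1e-12)

  # dense summation oracle
  Ad <- as.matrix(infl$A)
  manual <- numeric(nrow(Ad))
  for (j in seq_len(ncol(Ad))) manual <- manual + Ad[, j] * w1[j]
  expect_equal(unname(d1[infl$voxel_index]), unname(manual), tolerance = 1e-10)
  expect_true(all(d1[-infl$voxel_index] == 0))

  expect_error(compute_dose(infl, rep(-1, infl$n_beamlets)),
               class = "autoplan_argument_error")
  expect_error(compute_dose(infl, w1[-1]), class = "autoplan_argument_error")
})

test_that("uniform unit fluence is normalized to mean PTV dose 1 Gy", {
  p <- tiny_phantom()
  infl <- compute_influence(p, make_equiangular_beams(5))
  d <- compute_dose(infl, rep(1, infl$n_beamlets))
  expect_equal(mean(d$values[p$masks$ptv]), 1, tolerance = 1e-12)
})
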