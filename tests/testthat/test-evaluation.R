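test_that("cumulative DVH matches brute-force counting and is monotone", {
  u <- toy_grid(rep(50, 9))
  curve <- compute_dvh(u, all_mask(u), bin_width_gy = 1)
  expect_equal(curve$volume_pct[curve$dose_gy <= 50], rep(100, 51))
  expect_equal(curve$volume_pct[curve$dose_gy > 50], 0)

  d <- toy_grid(c(10, 30))
  c2 <- compute_dvh(d, all_mask(d), bin_width_gy = 1)
  expect_equal(c2$volume_pct[c2$dose_gy == 20], 50)  # 1 of 2 voxels >= 20 Gy

  set.seed(14)
  r <- toy_grid(runif(200, 0, 60), c(10, 10, 2))
  cr <- compute_dvh(r, all_mask(r), bin_width_gy = 0.5)
  expect_true(all(diff(cr$volume_pct) <= 0))
  expect_equal(cr$volume_pct[1], 100)
})

test_that("DVH-derived D_X agrees with nearest-rank D_X at fine bins", {
  set.seed(15)
  dose <- toy_grid(runif(500, 20, 60), c(10, 10, 5))
  mask <- all_mask(dose)
  curve <- compute_dvh(dose, mask, bin_width_gy = 0.01)
  for (x in c(2, 5, 50, 95, 98)) {
    dvh_dx <- max(curve$dose_gy[curve$volume_pct >= x])
    expect_equal(dvh_dx, dose_at_volume(dose, mask, x), tolerance = 0.011)
  }
})

test_that("volume_at_dose counts threshold fractions correctly", {
  d <- toy_grid(c(10, 20, 30, 40))
  m <- all_mask(d)
  expect_equal(volume_at_dose(d, m, 25), 50)       # 2 of 4
  expect_equal(volume_at_dose(d, m, 5), 100)
  expect_equal(volume_at_dose(d, m, 0), 100)       # V_0 = 100 for positive dose
  expect_equal(volume_at_dose(d, m, 100), 0)
})

test_that("homogeneity index follows the rank rule and its invariances", {
  d <- toy_grid(c(40, 45, 50, 55, 60))
  m <- all_mask(d)
  # D5 -> rank 1 -> 60; D95 -> rank 5 -> 40; HI = 60/40
  expect_equal(homogeneity_index(d, m), 1.5)
  expect_equal(homogeneity_index(toy_grid(rep(33, 5)), m), 1)
  expect_equal(homogeneity_index(3 * d, m), homogeneity_index(d, m))
  set.seed(16)
  r <- toy_grid(runif(100, 10, 60), c(5, 5, 4))
  expect_gte(homogeneity_index(r, all_mask(r)), 1)
  z <- toy_grid(rep(0, 5))
  expect_true(is.infinite(homogeneity_index(z, m)))
})

test_that("conformity index matches hand evaluation and stays within [0, 1]", {
  dose <- array(c(55, 55, 55, 45, 55, 40, 40, 40), dim = c(2, 2, 2))
  ptv <- array(c(rep(TRUE, 4), rep(FALSE, 4)), dim = c(2, 2, 2))
  body <- array(TRUE, dim = c(2, 2, 2))
  expect_equal(conformity_index(dose, ptv, body, 50), 9 / 16)

  ideal <- array(10, dim = c(2, 2, 2)); ideal[ptv] <- 50
  expect_equal(conformity_index(ideal, ptv, body, 50), 1)

  set.seed(17)
  for (rep in 1:10) {
    d <- array(runif(64, 0, 70), dim = c(4, 4, 4))
    pm <- array(runif(64) < 0.3, dim = c(4, 4, 4)); pm[1] <- TRUE
    ci <- conformity_index(d, pm, array(TRUE, dim = c(4, 4, 4)), 50)
    expect_gte(ci, 0); expect_lte(ci, 1)
  }

  cold <- array(1, dim = c(2, 2, 2))
  flagged <- conformity_index(cold, ptv, body, 50)
  expect_equal(as.numeric(flagged), 0)
  expect_true(attr(flagged, "flagged"))
})

test_that("metrics report covers the full index battery with correct values", {
  p <- tiny_phantom()
  uniform <- dose_grid(array(50, dim = dim(p$density)) * (p$masks$body * 1 + 0),
                       p$spacing, p$origin)
  m <- metrics_report(uniform, p)
  expect_equal(m$HI, 1)
  for (st in names(m$structures)) expect_equal(m$structures[[st]]$Dmean, 50)
  expect_equal(m$global_max, 50)
  df <- as.data.frame(m)
  expect_setequal(
    df$metric[df$structure == "ptv"], c("Dmean", "D2", "D5", "D95", "D98"))
  expect_setequal(
    df$metric[df$structure == "bladder"], c("Dmean", "V15", "V25", "V35", "V50"))

  # exhaustive oracle on an 8-voxel toy phantom built by hand
  shape <- c(2L, 2L, 2L)
  masks <- list(body = array(TRUE, shape),
                ptv = array(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), shape),
                bladder = array(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), shape),
                femoral_head_l = array(c(rep(FALSE, 4), TRUE, TRUE, FALSE, FALSE), shape),
                femoral_head_r = array(c(rep(FALSE, 6), TRUE, TRUE), shape))
  toy <- phantom(array(1, shape), masks, c(5, 4, 4), c(0, 0, 0), "toy8")
  dvals <- array(c(52, 48, 30, 20, 16, 10, 40, 36), shape)
  tm <- metrics_report(dose_grid(dvals, c(5, 4, 4), c(0, 0, 0)), toy)
  expect_equal(tm$structures$ptv$Dmean, 50)
  expect_equal(tm$structures$ptv$D2, 52)      # rank ceil(.02*2)=1 of {52,48}
  expect_equal(tm$structures$ptv$D98, 48)
  expect_equal(tm$structures$bladder$V25, 50) # {30,20}: one >= 25
  expect_equal(tm$structures$femoral_head_l$V15, 50)
  expect_equal(tm$global_max, 52)

  # V_D ladder is non-increasing per structure on a real plan-scale dose
  set.seed(18)
  rd <- dose_grid(array(runif(length(p$density), 0, 60), dim(p$density)) *
                    (p$masks$body * 1), p$spacing, p$origin)
  rm <- metrics_report(rd, p)
  for (st in c("bladder", "femoral_head_l", "femoral_head_r")) {
    v <- unlist(rm$structures[[st]][c("V15", "V25", "V35", "V50")])
    expect_true(all(diff(v) <= 0))
  }
})

test_that("paired cohort comparison matches the textbook t-test", {
  identical_m <- lapply(c(1.1, 1.2, 1.3), function(h) list(HI = h))
  same <- compare_cohorts(identical_m, identical_m, "HI")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  # constant nonzero differences are degenerate and flagged
  a <- lapply(c(1, 2, 3), function(h) list(HI = h))
  b <- lapply(c(2, 3, 4), function(h) list(HI = h))
  deg <- compare_cohorts(a, b, "HI")
  expect_true(deg$flagged)
  expect_true(is.na(deg$p))

  set.seed(19)
  av <- rnorm(12, 1.2, 0.1); bv <- rnorm(12, 1.1, 0.1)
  am <- lapply(av, function(h) list(HI = h))
  bm <- lapply(bv, function(h) list(HI = h))
  got <- compare_cohorts(am, bm, "HI")
  want <- paired_t_oracle(av, bv)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$significant, want$p < 0.05)

  expect_error(compare_cohorts(am, bm[-1], "HI"),
               class = "autoplan_argument_error")
})
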