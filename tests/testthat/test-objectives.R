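# Central finite-difference gradient of a scalar objective in dose space.
fd_gradient <- function(fn, dose, h = 1e-6) {
  g <- array(0, dim = dim(dose))
  for (i in seq_along(dose)) {
    dp <- dose; dp[i] <- dp[i] + h
    dm <- dose; dm[i] <- dm[i] - h
    g[i] <- (fn(dp) - fn(dm)) / (2 * h)
  }
  g
}

test_that("voxel MSE objective matches hand values and is zero at identity", {
  d <- toy_grid(c(1, 3))
  z <- toy_grid(c(0, 0))
  m <- all_mask(d)
  res <- f_mse(d, z, m)                       # no normalization
  expect_equal(res$value, 10)                 # 1^2 + 3^2
  ident <- f_mse(d, d, m)
  expect_equal(ident$value, 0)
  expect_true(all(ident$gradient == 0))
  expect_error(f_mse(d, toy_grid(c(0, 0, 0)), m),
               class = "autoplan_argument_error")
})

test_that("MSE gradient matches central finite differences", {
  set.seed(21)
  dose <- array(runif(100, 40, 60), dim = c(5, 5, 4))
  pred <- array(runif(100, 40, 60), dim = c(5, 5, 4))
  mask <- array(runif(100) < 0.8, dim = c(5, 5, 4))
  mask[1] <- TRUE
  res <- f_mse(dose, pred, mask, prescription_gy = 50)
  fd <- fd_gradient(function(d) f_mse(d, pred, mask, prescription_gy = 50)$value,
                    dose)
  expect_lt(max(abs(res$gradient - fd)), 1e-5)
})

test_that("dose_at_volume follows the nearest-rank convention", {
  d <- toy_grid(c(10, 20, 30, 40, 50))
  m <- all_mask(d)
  # descending sort {50,40,30,20,10}; rank ceil(0.5 * 5) = 3 -> 30
  expect_equal(dose_at_volume(d, m, 50), 30)
  expect_equal(dose_at_volume(d, m, 2), 50)
  expect_equal(dose_at_volume(d, m, 100), 10)
  u <- toy_grid(rep(50, 7))
  for (x in c(2, 50, 95, 98)) expect_equal(dose_at_volume(u, all_mask(u), x), 50)
  # order-statistic monotonicity on random doses
  set.seed(5)
  for (rep in 1:5) {
    r <- toy_grid(runif(64, 0, 60), c(4, 4, 4))
    d2 <- dose_at_volume(r, all_mask(r), 2)
    d50 <- dose_at_volume(r, all_mask(r), 50)
    d98 <- dose_at_volume(r, all_mask(r), 98)
    expect_true(d2 >= d50 && d50 >= d98)
  }
  expect_error(dose_at_volume(d, array(FALSE, dim(d)), 50),
               class = "autoplan_geometry_error")
})

test_that("homogeneity objective matches the hand-computed rank rule", {
  d <- toy_grid(c(48, 50, 52, 50, 50))
  m <- all_mask(d)
  # descending {52,50,50,50,48}: D98 -> rank 5 -> 48; D50 -> rank 3 -> 50;
  # D2 -> rank 1 -> 52; value (48-50)^2 + (52-50)^2 = 8
  res <- f_hi(d, m, w_hi = 1)
  expect_equal(res$value, 8)
  expect_equal(unname(res$d_x), c(48, 50, 52))
  uni <- f_hi(toy_grid(rep(42, 6)), all_mask(toy_grid(rep(42, 6))), w_hi = 3)
  expect_equal(uni$value, 0)
})

test_that("HI subgradient matches finite differences away from rank ties", {
  set.seed(31)
  vals <- sample(seq(40, 60, length.out = 100))   # distinct, gaps >> h
  dose <- array(vals, dim = c(5, 5, 4))
  mask <- array(TRUE, dim = c(5, 5, 4))
  res <- f_hi(dose, mask, w_hi = 2, prescription_gy = 50)
  fd <- fd_gradient(function(d) f_hi(d, mask, w_hi = 2, prescription_gy = 50)$value,
                    dose, h = 1e-5)
  expect_lt(max(abs(res$gradient - fd)), 1e-5)
})

test_that("smoothed conformity objective matches hand evaluation and ideals", {
  # toy: |PTV| = 4 of 8 body voxels; isodose covers 3 PTV voxels + 1 outside
  dose <- array(c(55, 55, 55, 45, 55, 40, 40, 40), dim = c(2, 2, 2))
  ptv <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), dim = c(2, 2, 2))
  body <- array(TRUE, dim = c(2, 2, 2))
  res <- f_ci_smooth(dose, ptv, body, reference_isodose = 50, w_ci = 1, tau = 0.5)
  expect_equal(res$f_ci_hard, 9 / 16)            # 3^2 / (4 * 4)

  # perfect conformity: prescription isodose covers exactly the PTV
  ideal <- array(10, dim = c(2, 2, 2)); ideal[ptv] <- 51
  resi <- f_ci_smooth(ideal, ptv, body, reference_isodose = 50,
                      c_index = 1, w_ci = 5, tau = 0.01)
  expect_equal(resi$f_ci_hard, 1)
  expect_lt(abs(resi$value), 1e-6)   # W_CI * (F_CI - C_index)^2 -> 0
})

test_that("smoothed conformity gradient matches finite differences", {
  set.seed(41)
  dose <- array(runif(100, 45, 55), dim = c(5, 5, 4))
  body <- array(runif(100) < 0.9, dim = c(5, 5, 4)); body[1:4] <- TRUE
  ptv <- body & array(runif(100) < 0.4, dim = c(5, 5, 4)); ptv[1:2] <- TRUE
  fn <- function(d) f_ci_smooth(d, ptv, body, reference_isodose = 50,
                                w_ci = 3, tau = 1)$value
  res <- f_ci_smooth(dose, ptv, body, reference_isodose = 50, w_ci = 3, tau = 1)
  fd <- fd_gradient(fn, dose)
  expect_lt(max(abs(res$gradient - fd)), 1e-5)
})

test_that("objective terms are nonnegative and vanish exactly at their ideals", {
  set.seed(51)
  for (rep in 1:5) {
    dose <- array(runif(64, 0, 70), dim = c(4, 4, 4))
    pred <- array(runif(64, 0, 70), dim = c(4, 4, 4))
    mask <- array(TRUE, dim = c(4, 4, 4))
    expect_gte(f_mse(dose, pred, mask)$value, 0)
    expect_gte(f_hi(dose, mask)$value, 0)
    expect_gte(f_ci_smooth(dose, mask, mask, 50, w_ci = 1, tau = 0.5)$value, 0)
  }
})

test_that("total objective composes terms and maps gradients through A^T", {
  p <- tiny_phantom()
  infl <- compute_influence(p, make_equiangular_beams(2))
  masks <- list(ptv = p$masks$ptv, body = p$masks$body)
  wts <- objective_weights(alpha = 1, w_hi = 2, w_ci = 2, tau = 1)
  set.seed(61)
  w <- runif(infl$n_beamlets, 20, 80)
  d_pred <- geometric_predictor(p, 50)

  # mse_only value is zero when d_pred is the plan dose itself
  self <- total_objective(w, infl, compute_dose(infl, w), wts, "mse_only", masks)
  expect_equal(self$value, 0)

  # degenerate clinical weights reproduce mse_only exactly
  wts0 <- objective_weights(alpha = 1, w_hi = 0, w_ci = 0)
  a <- total_objective(w, infl, d_pred, wts0, "mse_only", masks)
  b <- total_objective(w, infl, d_pred, wts0, "mse_plus_clinical", masks)
  expect_identical(a$value, b$value)
  expect_identical(a$gradient, b$gradient)

  # full-chain fluence-space gradient vs central finite differences
  full <- total_objective(w, infl, d_pred, wts, "mse_plus_clinical", masks)
  h <- 1e-4
  fd <- vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (total_objective(wp, infl, d_pred, wts, "mse_plus_clinical", masks)$value -
       total_objective(wm, infl, d_pred, wts, "mse_plus_clinical", masks)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(full$gradient - fd)) / max(abs(fd)), 1e-4)
})
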