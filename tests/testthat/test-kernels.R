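test_that("thin-plate-spline kernels match their closed forms and limits", {
  expect_equal(tps_basis(1), 0)
  expect_equal(tps_basis(0), 0)
  expect_equal(tps_basis(2), 4 * log(2))
  expect_equal(tps_particular(1), -1 / 32)
  expect_equal(tps_particular(0), 0)
  expect_equal(tps_particular_dr(0), 0)
  expect_equal(tps_particular_dr(1), -1 / 16)
  expect_error(tps_basis(-0.1), "nonnegative")
  expect_error(tps_particular(-1), "nonnegative")
})

test_that("Laplace fundamental solution matches its closed form and is singular at r = 0", {
  expect_equal(laplace_fundamental(1), 0)
  expect_equal(laplace_fundamental(0.5), log(2) / (2 * pi))
  expect_error(laplace_fundamental(0), "singular")
})

test_that("particular kernel solves Lap(Phi) = phi (finite-difference check)", {
  set.seed(11)
  rs <- c(0.7, runif(10, 0.05, 2))
  for (r in rs) {
    lap <- fd_laplacian_radial(tps_particular, r)
    expect_equal(lap, tps_basis(r), tolerance = 1e-6)
  }
  # value quoted for the classic spot check
  expect_equal(fd_laplacian_radial(tps_particular, 0.7), 0.49 * log(0.7),
               tolerance = 1e-6)
})

test_that("fundamental solution is harmonic away from its source", {
  set.seed(12)
  # radii bounded away from the source so the h = 1e-4 stencil truncation
  # (~ h^2 / r^4) stays below the 1e-6 band
  for (r in c(0.3, runif(10, 0.3, 2))) {
    expect_lt(abs(fd_laplacian_radial(laplace_fundamental, r)), 1e-6)
  }
})

test_that("kernels are radially symmetric", {
  set.seed(13)
  r <- 0.83
  angles <- runif(6, 0, 2 * pi)
  pts <- cbind(r * cos(angles), r * sin(angles))
  vals_phi <- tps_basis(sqrt(rowSums(pts^2)))
  expect_true(all(abs(vals_phi - vals_phi[1]) < 1e-12))
  nd <- normal_derivative_tps_particular(pts, c(0, 0), pts / r)
  expect_true(all(abs(diag(nd) - nd[1, 1]) < 1e-12))
})

test_that("normal derivatives match finite-difference directional derivatives", {
  anchor <- c(0.2, -0.1)
  x <- c(0.2 + 0.4 * cos(0.7), -0.1 + 0.4 * sin(0.7))  # r = 0.4
  n <- c(cos(1.9), sin(1.9))
  h <- 1e-6
  fd_dir <- function(f) {
    (f(sqrt(sum((x + h * n - anchor)^2))) -
       f(sqrt(sum((x - h * n - anchor)^2)))) / (2 * h)
  }
  expect_equal(normal_derivative_fundamental(rbind(x), rbind(anchor), rbind(n))[1, 1],
               fd_dir(laplace_fundamental), tolerance = 1e-8)
  expect_equal(normal_derivative_tps_particular(rbind(x), rbind(anchor), rbind(n))[1, 1],
               fd_dir(tps_particular), tolerance = 1e-6)
})

test_that("normal derivatives respect radial geometry", {
  # orthogonal normal: radial fields have no tangential derivative
  x <- rbind(c(1, 0)); anchor <- rbind(c(0, 0)); n_orth <- rbind(c(0, 1))
  expect_equal(normal_derivative_tps_particular(x, anchor, n_orth)[1, 1], 0)
  expect_equal(normal_derivative_fundamental(x, anchor, n_orth)[1, 1], 0)
  # aligned normal at r = 1: dPhi/dr = (4 ln 1 - 1)/16, dG/dr = -1/(2 pi)
  n_par <- rbind(c(1, 0))
  expect_equal(normal_derivative_tps_particular(x, anchor, n_par)[1, 1], -1 / 16)
  expect_equal(normal_derivative_fundamental(x, anchor, n_par)[1, 1], -1 / (2 * pi))
  # coincident point: radial derivative vanishes in the limit
  expect_equal(normal_derivative_tps_particular(rbind(c(0, 0)), anchor, n_par)[1, 1], 0)
  expect_error(normal_derivative_fundamental(rbind(c(0, 0)), anchor, n_par), "singular")
  expect_error(normal_derivative_fundamental(x, anchor, rbind(c(2, 0))), "unit")
})
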