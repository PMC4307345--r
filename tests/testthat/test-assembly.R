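test_that("the default geometry assembles a 95 x 95 system", {
  cs <- build_collocation(domain_spec())
  props <- tissue_properties()
  lam2 <- helmholtz_lambda2(props, 1)
  prob <- helmholtz_problem(lam2, rep(0, 63), list(gamma1 = 0, gamma4 = 0), cs)
  sys <- assemble_system(prob)
  expect_equal(dim(sys$matrix), c(95, 95))
  expect_length(sys$rhs, 95)
})

test_that("interior rows carry -lambda2 * G in the source columns", {
  cs <- build_collocation(domain_spec())
  lam2 <- 1.7e5
  op <- helmholtz_operator(cs, lam2)
  M <- nrow(cs$interior)
  i <- 17; j <- 5
  r <- sqrt(sum((cs$interior[i, ] - cs$sources[j, ])^2))
  expect_equal(op$A[i, M + j], -lam2 * (-log(r) / (2 * pi)))
  # and phi - lambda2 * Phi in the RBF columns
  k <- 40
  rk <- sqrt(sum((cs$interior[i, ] - cs$interior[k, ])^2))
  expect_equal(op$A[i, k],
               rk^2 * log(rk) - lam2 * rk^4 * (2 * log(rk) - 1) / 32)
})

test_that("toy 5-point problem matches an independently built dense solve", {
  toy <- toy_collocation()
  lam2 <- 4
  prob <- helmholtz_problem(lam2, F = -2, bc_values = list(gamma1 = 1, gamma4 = 0.3),
                            colloc = toy)
  # hand-build the 5x5 system straight from the kernel definitions
  Phi_ <- function(r) r^4 * (2 * log(r) - 1) / 32
  phi_ <- function(r) r^2 * log(r)
  G_ <- function(r) -log(r) / (2 * pi)
  dPhi_ <- function(r) r^3 * (4 * log(r) - 1) / 16
  all_anchor <- rbind(toy$interior, toy$sources)
  rfun <- function(p, q) sqrt(sum((p - q)^2))
  A <- matrix(0, 5, 5)
  # PDE row at the interior point
  p0 <- toy$interior[1, ]
  A[1, 1] <- 0 - lam2 * 0  # r = 0 limits of phi and Phi
  for (j in 1:4) A[1, 1 + j] <- -lam2 * G_(rfun(p0, toy$sources[j, ]))
  for (i in 1:4) {
    p <- toy$boundary[i, ]
    n <- toy$normal[i, ]
    if (toy$segment[i] %in% c(1, 4)) {
      A[1 + i, 1] <- Phi_(rfun(p, p0))
      for (j in 1:4) A[1 + i, 1 + j] <- G_(rfun(p, toy$sources[j, ]))
    } else {
      d <- p - p0; r <- sqrt(sum(d^2))
      A[1 + i, 1] <- dPhi_(r) * sum(d * n) / r
      for (j in 1:4) {
        ds <- p - toy$sources[j, ]; rs2 <- sum(ds^2)
        A[1 + i, 1 + j] <- -sum(ds * n) / (2 * pi * rs2)
      }
    }
  }
  b <- c(-2, 1, 0, 0, 0.3)
  ref <- solve(A, b)
  cf <- solve_helmholtz(prob)
  expect_equal(as.numeric(cf), ref, tolerance = 1e-10)
  expect_lt(attr(cf, "residual"), 1e-8)
})

test_that("homogeneous problem yields the zero field", {
  cs <- build_collocation(domain_spec())
  prob <- helmholtz_problem(1e5, rep(0, 63), list(gamma1 = 0, gamma4 = 0), cs)
  cf <- solve_helmholtz(prob)
  pts <- cbind(seq(0.002, 0.028, length.out = 9), 0.006)
  expect_true(all(abs(evaluate_field(cf, cs, pts)) < 1e-10))
})

test_that("solved fields satisfy the collocation rows exactly", {
  cs <- build_collocation(domain_spec())
  props <- tissue_properties()
  lam2 <- helmholtz_lambda2(props, 1)
  set.seed(4)
  F <- rnorm(63, mean = -lam2 * 2, sd = lam2 / 10)
  bcv <- list(gamma1 = 0.4, gamma4 = -5.2)
  prob <- helmholtz_problem(lam2, F, bcv, cs)
  cf <- solve_helmholtz(prob)
  expect_lt(attr(cf, "residual"), 1e-8)
  # Dirichlet collocations reproduce their boundary values
  dirichlet <- cs$segment %in% c(1, 4)
  vals <- evaluate_field(cf, cs, cs$boundary[dirichlet, ])
  want <- ifelse(cs$segment[dirichlet] == 1, bcv$gamma1, bcv$gamma4)
  expect_equal(vals, want, tolerance = 1e-8)
  # insulated collocations have zero normal derivative
  neum <- !dirichlet
  Qrow <- cbind(
    normal_derivative_tps_particular(cs$boundary[neum, ], cs$interior, cs$normal[neum, ]),
    normal_derivative_fundamental(cs$boundary[neum, ], cs$sources, cs$normal[neum, ]))
  expect_true(all(abs(Qrow %*% as.numeric(cf)) < 1e-6))
})

test_that("manufactured sinh solution is reproduced and improves with refinement", {
  # theta*(x, y) = sinh(lam x)/sinh(lam Lx) solves Lap u - lam^2 u = 0 with
  # u = 0 at x = 0, u = 1 at x = Lx and zero flux through y edges
  err_for <- function(nx, ny, n_edge) {
    dom <- domain_spec(1, 0.5)
    cs <- build_collocation(dom, nx, ny, n_edge = n_edge)
    lam <- 5
    prob <- helmholtz_problem(lam^2, rep(0, nrow(cs$interior)),
                              list(gamma1 = 1, gamma4 = 0), cs)
    cf <- solve_helmholtz(prob, cond_warn = Inf)
    qx <- cbind(seq(0.05, 0.95, length.out = 17), 0.23)  # off-collocation
    max(abs(evaluate_field(cf, cs, qx) - sinh(lam * qx[, 1]) / sinh(lam)))
  }
  e_coarse <- err_for(9, 7, c(9, 7, 7, 9))
  e_fine <- err_for(13, 9, c(13, 9, 9, 13))
  expect_lt(e_coarse, 0.02)
  expect_lt(e_fine, e_coarse / 2)
})

test_that("problem construction validates its inputs", {
  cs <- build_collocation(domain_spec())
  expect_error(helmholtz_problem(-1, rep(0, 63), list(gamma1 = 0, gamma4 = 0), cs),
               "lambda2")
  expect_error(helmholtz_problem(1, rep(0, 10), list(gamma1 = 0, gamma4 = 0), cs),
               "interior")
  expect_error(helmholtz_problem(1, rep(0, 63), list(gamma1 = 0), cs), "gamma4")
  expect_error(evaluate_field(rep(0, 95), cs, cs$sources[1, , drop = FALSE]),
               "source")
})
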