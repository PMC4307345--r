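make_state <- function(theta_n, theta_nm1, layout) {
  field_state(theta_n, theta_nm1, t = 1, step_index = 1L, layout = layout)
}

test_that("helmholtz right-hand side matches its defining combination", {
  props <- tissue_properties()
  params <- step_parameters(dt = 1)
  lam2 <- helmholtz_lambda2(props, 1)
  cs <- build_collocation(domain_spec())
  layout <- list(M = 63, N = 32, P = 0, segment = cs$segment)
  n <- 95

  # source-free limit: F = -lambda2 * theta0 uniformly
  pm0 <- perfusion_model("constant", 0)
  props0 <- tissue_properties(Q_r = 0, Q_m = 0)
  st <- make_state(rep(3, n), rep(3, n), layout)
  expect_equal(helmholtz_rhs(st, params, props0, pm0),
               rep(-helmholtz_lambda2(props0, 1) * 3, 63))

  # theta = 0 history: the 3/2 - 1/2 weights collapse onto f(0)
  st0 <- make_state(rep(0, n), rep(0, n), layout)
  f0 <- 34200 / 4.2e6
  expect_equal(helmholtz_rhs(st0, params, props, perfusion_model("linear", 5e-4, 1e-4)),
               rep(-(4.2e6 / 0.5) * f0, 63))
  expect_equal(helmholtz_rhs(st0, params, props, perfusion_model("linear", 5e-4, 1e-4))[1],
               -68400)
})

test_that("half-step boundary values average the boundary data with the current field", {
  props <- tissue_properties()
  cs <- build_collocation(domain_spec())
  layout <- list(M = 63, N = 32, P = 0, segment = cs$segment)
  bc <- boundary_conditions(T_s = 25, T_c = 37)
  # boundary already at the Dirichlet values -> theta* equals them
  th <- c(rep(0, 63), ifelse(cs$segment %in% c(2, 3), 0,
                             ifelse(cs$segment == 1, 0, -12)))
  st <- make_state(th, th, layout)
  bv <- step_boundary_values(st, bc, props)
  expect_equal(bv$gamma1, rep(0, sum(cs$segment == 1)))
  expect_equal(bv$gamma4, rep(-12, sum(cs$segment == 4)))
  # zero current field: the average halves the boundary data
  st0 <- make_state(rep(0, 95), rep(0, 95), layout)
  expect_equal(step_boundary_values(st0, bc, props)$gamma4,
               rep(-6, sum(cs$segment == 4)))
})

test_that("bootstrap uses half the marching Helmholtz parameter", {
  props <- tissue_properties()
  eng <- bioheatmfs:::march_engine(build_collocation(domain_spec()), props,
                                   step_parameters(dt = 1))
  expect_equal(eng$op$lambda2, 2 * props$rho * props$c / props$k)
  expect_equal(eng$op0$lambda2, props$rho * props$c / props$k)
})

test_that("a harmonic steady state compatible with the data is a bootstrap fixed point", {
  props <- tissue_properties(Q_r = 0, Q_m = 0)
  pm <- perfusion_model("constant", 0)
  cs <- build_collocation(domain_spec())
  pts <- rbind(cs$interior, cs$boundary)
  th0 <- -12 + 12 * pts[, 1] / 0.03   # linear in x: harmonic, matches 25/37 BCs
  st <- bootstrap_first_step(th0, step_parameters(), props, pm, cs,
                             boundary_conditions())
  expect_lt(max(abs(st$theta_n - th0)), 1e-5)
})

test_that("advance preserves a steady state (fixed-point property)", {
  cfg <- bioheat_config()
  rec <- march(cfg)
  expect_true(rec$steady)
  st <- rec$final_state
  cs <- do.call(build_collocation, c(list(domain = cfg$domain), cfg$collocation))
  st2 <- advance(st, cfg$stepping, cfg$properties, cfg$perfusion, cs, cfg$bc,
                 probes = bioheatmfs:::config_probes(cfg))
  expect_lt(max(abs(st2$theta_n - st$theta_n)), 2e-5)
})

test_that("time stepping is second-order accurate in the heat-equation limit", {
  sol_at <- function(dt) {
    rec <- march(heat_limit_config(dt = dt, t_end = 64))
    rec$snapshots[nrow(rec$snapshots), ]
  }
  ref <- sol_at(1)
  e_coarse <- max(abs(sol_at(8) - ref))
  e_half <- max(abs(sol_at(4) - ref))
  # AB2 + trapezoidal diffusion: halving dt should shrink the temporal
  # error ~4x (4.2x expected with the dt = 1 reference)
  expect_gt(e_coarse / e_half, 3)
  expect_lt(e_coarse / e_half, 5.5)
})

test_that("solution stays y-invariant and bounded", {
  # x-only boundary data, uniform start: no y-dependence at the level of
  # the spatial discretisation error of the 63/32 collocation
  rec <- march(quick_config(t_end = 50))
  expect_lt(column_y_spread(rec), 0.1)

  # with no heating, temperatures stay inside the data range (up to a
  # small collocation overshoot)
  cfg <- bioheat_config(properties = tissue_properties(Q_r = 0, Q_m = 0),
                        stepping = step_parameters(t_end = 300))
  rec2 <- march(cfg)
  expect_gt(min(rec2$snapshots), 25 - 0.02)
  expect_lt(max(rec2$snapshots), 37 + 0.02)
})

test_that("march honours t_end = 0 and records snapshots at requested times", {
  rec0 <- march(quick_config(t_end = 0))
  expect_equal(rec0$times, 0)
  expect_equal(nrow(rec0$snapshots), 1)
  expect_false(rec0$steady)

  rec <- march(quick_config(t_end = 20, snapshot_times = c(5, 10)))
  expect_equal(rec$times, c(0, 5, 10, 20))
})

test_that("march rejects invalid stepping parameters", {
  expect_error(step_parameters(dt = 0), "dt")
  expect_error(step_parameters(t_end = -5), "t_end")
})
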