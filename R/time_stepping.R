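#' Time-stepping controls of the operator-splitting march
#'
#' The nonlinear perfusion source is advanced with the explicit two-step
#' Adams-Bashforth scheme and diffusion with the implicit Adams-Moulton
#' (trapezoidal) scheme; both are second order. Combining the two turns each
#' step into a modified Helmholtz problem for the half-step average field
#' theta* = (theta^(n+1) + theta^n)/2 with parameter
#' lambda2 = 2 rho c / (k dt).
#'
#' @param dt time-step length (s)
#' @param t_end final time (s); the march stops earlier if it reaches a
#'   steady state
#' @param steady_tol stopping tolerance: the march halts once the maximum
#'   per-step temperature change stays below this value (degC per step) for
#'   `steady_hold` consecutive steps
#' @param steady_hold number of consecutive quiet steps required to stop
#' @return an object of class `step_parameters`
#' @export
step_parameters <- function(dt = 1, t_end = 20000, steady_tol = 1e-5,
                            steady_hold = 5L) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end < 0) {
    stop("t_end must be a single nonnegative number", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, steady_tol = steady_tol,
                 steady_hold = as.integer(steady_hold)),
            class = "step_parameters")
}

#' Helmholtz parameter of the marching scheme
#'
#' lambda2 = 2 rho c / (k dt), the coefficient that the trapezoidal
#' treatment of diffusion attaches to theta* in the per-step modified
#' Helmholtz equation. The bootstrap (backward-Euler) first step uses half
#' this value, rho c / (k dt).
#'
#' @param props a [tissue_properties()]
#' @param dt time-step length (s)
#' @return lambda^2 (1/m^2)
#' @export
helmholtz_lambda2 <- function(props, dt) {
  2 * props$rho * props$c / (props$k * dt)
}

#' Two-level field state of the march
#'
#' Holds the shifted temperature field theta = T - T_b at the current and
#' previous step on the tracked point set (interior collocations, boundary
#' collocations, then any extra probe points).
#'
#' @param theta_n,theta_nm1 shifted temperatures at steps n and n-1 (degC)
#' @param t current time (s)
#' @param step_index integer step counter
#' @param layout list with counts `M` (interior), `N` (boundary), `P`
#'   (probes) and the boundary `segment` labels
#' @return an object of class `field_state`
#' @export
field_state <- function(theta_n, theta_nm1, t, step_index, layout) {
  n_pts <- layout$M + layout$N + layout$P
  if (length(theta_n) != n_pts || length(theta_nm1) != n_pts) {
    stop("field arrays must match the tracked point layout", call. = FALSE)
  }
  if (any(!is.finite(theta_n)) || any(!is.finite(theta_nm1))) {
    stop("field state contains non-finite temperatures", call. = FALSE)
  }
  structure(list(theta_n = theta_n, theta_nm1 = theta_nm1, t = t,
                 step_index = step_index, layout = layout),
            class = "field_state")
}

state_interior <- function(state) state$theta_n[seq_len(state$layout$M)]
state_boundary <- function(state) {
  state$theta_n[state$layout$M + seq_len(state$layout$N)]
}

#' Right-hand side of the per-step modified Helmholtz problem
#'
#' F = -(rho c / k) * (3/2 f(theta^n) - 1/2 f(theta^(n-1)))
#'     - lambda2 * theta^n
#' evaluated at the interior collocation points, with f the nonlinear
#' perfusion source of [source_term()].
#'
#' @param state a [field_state()]
#' @param params a [step_parameters()]
#' @param props a [tissue_properties()]
#' @param perfusion a [perfusion_model()]
#' @return F values at the M interior points (degC/m^2)
#' @export
helmholtz_rhs <- function(state, params, props, perfusion) {
  M <- state$layout$M
  th_n <- state$theta_n[seq_len(M)]
  th_nm1 <- state$theta_nm1[seq_len(M)]
  rck <- props$rho * props$c / props$k
  lambda2 <- helmholtz_lambda2(props, params$dt)
  f_ab <- 1.5 * source_term(props, perfusion, th_n) -
    0.5 * source_term(props, perfusion, th_nm1)
  -rck * f_ab - lambda2 * th_n
}

#' Dirichlet boundary data for the half-step field
#'
#' Because theta* is the average of theta^(n+1) and theta^n, its Dirichlet
#' values are the averages of the prescribed boundary temperature and the
#' current boundary field: theta* = (theta_c + theta^n)/2 on gamma1 and
#' (theta_s + theta^n)/2 on gamma4. Insulated segments keep homogeneous
#' Neumann rows and carry no value.
#'
#' @param state a [field_state()]
#' @param bc a [boundary_conditions()]
#' @param props a [tissue_properties()] (provides T_b for the shift)
#' @return list with per-collocation theta* values on `gamma1` and `gamma4`
#' @export
step_boundary_values <- function(state, bc, props) {
  seg <- state$layout$segment
  th_b <- state_boundary(state)
  theta_c <- bc$T_c - props$T_b
  theta_s <- bc$T_s - props$T_b
  list(gamma1 = (theta_c + th_b[seg == 1L]) / 2,
       gamma4 = (theta_s + th_b[seg == 4L]) / 2)
}

# Precomputed machinery shared by all steps: collocation set, tracked point
# list, evaluation matrix, and the factored operators for the marching
# (lambda2) and bootstrap (lambda2/2) steps.
march_engine <- function(colloc, props, params, probes = NULL) {
  M <- nrow(colloc$interior)
  N <- nrow(colloc$boundary)
  probes <- if (is.null(probes)) {
    matrix(numeric(0), 0, 2)
  } else {
    rbind(probes)
  }
  pts <- rbind(colloc$interior, colloc$boundary, probes)
  lambda2 <- helmholtz_lambda2(props, params$dt)
  list(
    colloc = colloc,
    points = pts,
    layout = list(M = M, N = N, P = nrow(probes), segment = colloc$segment),
    E = evaluation_matrix(colloc, pts),
    op = helmholtz_operator(colloc, lambda2),
    op0 = helmholtz_operator(colloc, lambda2 / 2),
    lambda2 = lambda2
  )
}

#' Bootstrap first step of the two-step march
#'
#' The Adams-Bashforth/Adams-Moulton pair needs two history levels and
#' cannot start itself. The first step uses an extrapolated forward-Euler
#' treatment of the source with backward-Euler diffusion:
#' Lap(theta^1) - (rho c/(k dt)) theta^1
#'   = -(rho c/k) f(theta^0) - (rho c/(k dt)) theta^0,
#' solved with the original (un-averaged) boundary values. Note the
#' Helmholtz parameter here is half the marching lambda2.
#'
#' @param theta0 initial shifted temperature: a scalar or one value per
#'   tracked point
#' @param params a [step_parameters()]
#' @param props a [tissue_properties()]
#' @param perfusion a [perfusion_model()]
#' @param colloc a [build_collocation()] set
#' @param bc a [boundary_conditions()]
#' @param probes optional extra evaluation points tracked by the state
#' @param engine internal precomputed engine (built if missing)
#' @return a [field_state()] holding theta^1 and theta^0, ready for
#'   [advance()]
#' @export
bootstrap_first_step <- function(theta0, params, props, perfusion, colloc, bc,
                                 probes = NULL, engine = NULL) {
  if (is.null(engine)) engine <- march_engine(colloc, props, params, probes)
  n_pts <- nrow(engine$points)
  th0 <- if (length(theta0) == 1L) rep(theta0, n_pts) else theta0
  if (length(th0) != n_pts) {
    stop("theta0 must be a scalar or one value per tracked point", call. = FALSE)
  }
  M <- engine$layout$M
  lam0 <- engine$lambda2 / 2
  rck <- props$rho * props$c / props$k
  F0 <- -rck * source_term(props, perfusion, th0[seq_len(M)]) - lam0 * th0[seq_len(M)]
  bc0 <- list(gamma1 = bc$T_c - props$T_b, gamma4 = bc$T_s - props$T_b)
  prob <- helmholtz_problem(lam0, F0, bc0, engine$colloc)
  cf <- solve_helmholtz(prob, operator = engine$op0, cond_warn = Inf)
  th1 <- as.numeric(engine$E %*% cf)
  field_state(th1, th0, t = params$dt, step_index = 1L, layout = engine$layout)
}

#' Advance the field by one operator-splitting step
#'
#' Solves the modified Helmholtz problem for the half-step field theta*,
#' evaluates it at every tracked point and recovers
#' theta^(n+1) = 2 theta* - theta^n.
#'
#' @inheritParams bootstrap_first_step
#' @param state a [field_state()] holding theta^n and theta^(n-1)
#' @return the [field_state()] at step n+1
#' @export
advance <- function(state, params, props, perfusion, colloc, bc,
                    probes = NULL, engine = NULL) {
  if (is.null(engine)) engine <- march_engine(colloc, props, params, probes)
  F <- helmholtz_rhs(state, params, props, perfusion)
  bvals <- step_boundary_values(state, bc, props)
  prob <- helmholtz_problem(engine$lambda2, F, bvals, engine$colloc)
  cf <- tryCatch(
    solve_helmholtz(prob, operator = engine$op, cond_warn = Inf),
    error = function(e) {
      stop("solve failed at step ", state$step_index + 1L, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  tstar <- as.numeric(engine$E %*% cf)
  field_state(2 * tstar - state$theta_n, state$theta_n,
              t = state$t + params$dt,
              step_index = state$step_index + 1L,
              layout = engine$layout)
}

#' Run the full operator-splitting simulation
#'
#' Builds the collocation geometry, bootstraps the two-level history and
#' repeatedly applies [advance()] until `t_end` is reached or the field is
#' steady (maximum per-step change below `steady_tol` for `steady_hold`
#' consecutive steps). Temperatures are recorded at the requested snapshot
#' times (plus t = 0 and the final time) on the tracked point set, which is
#' the interior and boundary collocations plus the configured probe points
#' (by default a uniformly spaced centerline transect).
#'
#' @param config a [bioheat_config()]
#' @return an object of class `run_record`: snapshot `times` (s), a
#'   `snapshots` matrix (rows = times, columns = tracked points) of absolute
#'   temperatures (degC), the tracked `points` with roles, the per-step
#'   maximum `change` series and its `change_times`, `steady` flag,
#'   `steady_time`, and solver `diagnostics`
#' @export
#' @examples
#' \donttest{
#' cfg <- bioheat_config(stepping = step_parameters(t_end = 100),
#'                       output = list(snapshot_times = c(50, 80, 100)))
#' rec <- march(cfg)
#' head(centerline_profile(rec, 100))
#' }
march <- function(config) {
  stopifnot(inherits(config, "bioheat_config"))
  props <- config$properties
  perfusion <- config$perfusion
  bc <- config$bc
  params <- config$stepping
  colloc <- do.call(build_collocation, c(list(domain = config$domain), config$collocation))
  probes <- config_probes(config)
  engine <- march_engine(colloc, props, params, probes)
  if (engine$op$condition > config$cond_warn) {
    warning(sprintf("collocation system condition estimate %.3g exceeds %.3g",
                    engine$op$condition, config$cond_warn), call. = FALSE)
  }

  n_pts <- nrow(engine$points)
  theta0 <- config$initial$T0 - props$T_b
  th0 <- if (length(theta0) == 1L) rep(theta0, n_pts) else theta0

  dt <- params$dt
  n_steps <- floor(params$t_end / dt + 1e-9)
  snap_steps <- sort(unique(round(config$output$snapshot_times / dt)))
  snap_steps <- snap_steps[snap_steps >= 1 & snap_steps <= n_steps]

  roles <- rep(c("interior", "boundary", "probe"),
               c(engine$layout$M, engine$layout$N, engine$layout$P))
  points_df <- data.frame(role = roles, x = engine$points[, 1], y = engine$points[, 2])

  record <- function(times, snaps, change, steady, steady_time, final_state) {
    structure(
      list(times = times,
           snapshots = do.call(rbind, snaps),
           points = points_df,
           probe_idx = which(roles == "probe"),
           change = change,
           change_times = if (length(change)) dt * seq_along(change) else numeric(0),
           steady = steady, steady_time = steady_time,
           diagnostics = list(condition = engine$op$condition,
                              condition_bootstrap = engine$op0$condition,
                              lambda2 = engine$lambda2),
           final_state = final_state,
           config = config),
      class = "run_record"
    )
  }

  snaps <- list(props$T_b + th0)
  times <- 0
  if (n_steps == 0L) {
    return(record(times, snaps, numeric(0), FALSE, NA_real_, NULL))
  }

  state <- bootstrap_first_step(th0, params, props, perfusion, colloc, bc,
                                probes = probes, engine = engine)
  change <- numeric(n_steps)
  change[1] <- max(abs(state$theta_n - state$theta_nm1))
  if (1L %in% snap_steps) {
    snaps <- c(snaps, list(props$T_b + state$theta_n)); times <- c(times, state$t)
  }

  quiet <- as.integer(change[1] < params$steady_tol)
  steady <- FALSE
  k <- 1L
  while (k < n_steps) {
    state <- advance(state, params, props, perfusion, colloc, bc, engine = engine)
    k <- k + 1L
    change[k] <- max(abs(state$theta_n - state$theta_nm1))
    if (!is.finite(change[k]) || max(abs(state$theta_n)) > 1e4) {
      stop("march diverged at t = ", state$t, " s", call. = FALSE)
    }
    if (k %in% snap_steps) {
      snaps <- c(snaps, list(props$T_b + state$theta_n)); times <- c(times, state$t)
    }
    quiet <- if (change[k] < params$steady_tol) quiet + 1L else 0L
    if (quiet >= params$steady_hold) { steady <- TRUE; break }
  }
  change <- change[seq_len(k)]
  if (times[length(times)] != state$t) {
    snaps <- c(snaps, list(props$T_b + state$theta_n)); times <- c(times, state$t)
  }
  steady_time <- if (steady) first_quiet_time(change, dt, params$steady_tol) else NA_real_
  record(times, snaps, change, steady, steady_time, state)
}

# earliest time after which every per-step change stays below tol
first_quiet_time <- function(change, dt, tol) {
  above <- which(change >= tol)
  idx <- if (length(above)) max(above) + 1L else 1L
  if (idx > length(change)) return(NA_real_)
  dt * idx
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("Bioheat run: %d tracked points, %d snapshots, t up to %g s\n",
              nrow(x$points), length(x$times), max(x$times)))
  if (isTRUE(x$steady)) {
    cat(sprintf("  steady state (march tolerance) reached at t = %g s\n", x$steady_time))
  } else {
    cat("  steady state not reached within the simulated window\n")
  }
  if (!is.null(x$diagnostics$condition)) {
    cat(sprintf("  lambda2 = %g 1/m^2, condition estimate %.3g\n",
                x$diagnostics$lambda2, x$diagnostics$condition))
  }
  invisible(x)
}
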