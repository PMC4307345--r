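#' Extract a centerline temperature profile from a run
#'
#' Returns the temperature along the horizontal centerline y = Ly/2 (the
#' symmetry line of the rectangle; "along the x-axis" in the half-domain
#' view) at a recorded snapshot time.
#'
#' @param record a `run_record` from [march()] or [fd_march()]
#' @param t snapshot time (s); must be one of `record$times`. Defaults to
#'   the last recorded time.
#' @param label optional curve tag (e.g. the parameter value it belongs to)
#' @return a `profile_curve` data frame with columns `x` (m) and `T` (degC),
#'   attributes `t` and `label`
#' @export
centerline_profile <- function(record, t = NULL, label = NA) {
  stopifnot(inherits(record, "run_record"))
  if (is.null(t)) t <- record$times[length(record$times)]
  it <- which(abs(record$times - t) < 1e-9)
  if (length(it) != 1L) {
    stop("no snapshot recorded at t = ", t,
         " s (recorded: ", paste(record$times, collapse = ", "), ")", call. = FALSE)
  }
  idx <- record$probe_idx
  if (!length(idx)) stop("run record has no probe points", call. = FALSE)
  ord <- order(record$points$x[idx])
  idx <- idx[ord]
  out <- data.frame(x = record$points$x[idx], T = record$snapshots[it, idx])
  structure(out, class = c("profile_curve", "data.frame"), t = t, label = label)
}

#' Maximum relative error between two temperature profiles
#'
#' max over samples of |T_test - T_ref| / |T_ref| * 100, with temperatures
#' in degC as plotted. The two curves must share their sample positions;
#' mismatched grids are an error rather than being silently interpolated.
#'
#' @param test,ref `profile_curve` data frames (or any data frames with
#'   columns `x` and `T`) on identical `x` grids
#' @return maximum relative error in percent
#' @export
relative_error <- function(test, ref) {
  if (nrow(test) != nrow(ref) || any(abs(test$x - ref$x) > 1e-9)) {
    stop("profiles are sampled on different grids; no silent interpolation", call. = FALSE)
  }
  max(abs(test$T - ref$T) / abs(ref$T)) * 100
}

#' Time at which a run reaches steady state
#'
#' The first time after which the maximum per-step temperature change stays
#' below `tol` for the remainder of the record. The default tolerance is
#' 1e-4 degC per step; the resulting time depends on this choice, which is
#' a detection rule of this package, not a physical constant.
#'
#' @param record a `run_record` with a per-step `change` series
#' @param tol steady-state tolerance (degC per step)
#' @return time (s), or `NA` with a warning if the record never settles
#' @export
steady_state_time <- function(record, tol = 1e-4) {
  stopifnot(inherits(record, "run_record"))
  ch <- record$change
  if (!length(ch)) return(record$times[1])
  t <- first_quiet_time(ch, record$change_times[1], tol)
  if (is.na(t)) warning("steady state not reached within the record", call. = FALSE)
  t
}

#' Common intersection point of several profile curves
#'
#' Finds the x location where a family of temperature curves (sharing the
#' same sample grid) come closest to a common value: the x minimising the
#' maximum pairwise spread |T_i(x) - T_j(x)|. The discrete minimiser is
#' located over the interior samples (the Dirichlet end points, where all
#' curves coincide by construction, are excluded) and then refined by
#' piecewise-linear interpolation between the neighbouring samples.
#'
#' @param curves list of >= 2 `profile_curve` data frames on a common grid
#' @param refine number of interpolation samples used in the sub-grid
#'   refinement step
#' @return list with `x` (m), `T` (degC, mean of the curves at the
#'   intersection) and `spread` (degC, max pairwise gap there)
#' @export
#' @examples
#' xs <- seq(0, 2, by = 0.1)
#' a <- data.frame(x = xs, T = xs)
#' b <- data.frame(x = xs, T = 2 - xs)
#' find_intersection(list(a, b))  # x = 1, T = 1
find_intersection <- function(curves, refine = 201L) {
  if (length(curves) < 2L) stop("need at least two curves", call. = FALSE)
  xs <- curves[[1]]$x
  for (cv in curves[-1]) {
    if (nrow(cv) != length(xs) || any(abs(cv$x - xs) > 1e-9)) {
      stop("curves are sampled on different grids", call. = FALSE)
    }
  }
  Tm <- sapply(curves, function(cv) cv$T)   # samples x curves
  spread <- apply(Tm, 1, function(v) max(v) - min(v))
  if (max(spread) < 1e-12) {
    stop("degenerate: curves are identical everywhere, no unique intersection",
         call. = FALSE)
  }
  inner <- 2:(length(xs) - 1L)
  i0 <- inner[which.min(spread[inner])]
  lo <- xs[max(i0 - 1L, 1L)]
  hi <- xs[min(i0 + 1L, length(xs))]
  xf <- seq(lo, hi, length.out = refine)
  Tf <- sapply(seq_along(curves), function(j) approx(xs, Tm[, j], xout = xf)$y)
  spread_f <- apply(Tf, 1, function(v) max(v) - min(v))
  jb <- which.min(spread_f)
  list(x = xf[jb], T = mean(Tf[jb, ]), spread = spread_f[jb])
}

#' Run the solver and the finite-difference reference on one problem
#'
#' Marches both solvers on the identical configuration, extracts centerline
#' profiles at the requested snapshot times and reports the maximum
#' relative error of the meshless solution against the reference. The
#' meshless probe points are placed on the reference centerline nodes so
#' the curves share a grid.
#'
#' @param config a [bioheat_config()]; its `output$snapshot_times` are the
#'   comparison times
#' @param nx,ny reference grid resolution
#' @return list with `max_error` (percent), per-time `errors`, and the two
#'   run records `mfs` and `fd`
#' @export
verify_against_reference <- function(config, nx = 121, ny = 7) {
  stopifnot(inherits(config, "bioheat_config"))
  times <- config$output$snapshot_times
  if (!length(times)) stop("config has no snapshot times to compare at", call. = FALSE)
  xg <- seq(0, config$domain$Lx, length.out = nx)
  config$output$probes <- cbind(xg, config$domain$Ly / 2)
  mfs <- march(config)
  fd <- fd_march(config, nx = nx, ny = ny)
  errors <- vapply(times, function(t) {
    relative_error(centerline_profile(mfs, t), centerline_profile(fd, t))
  }, numeric(1))
  names(errors) <- paste0("t=", times, "s")
  list(max_error = max(errors), errors = errors, mfs = mfs, fd = fd)
}

#' Sensitivity sweep over a perfusion coefficient
#'
#' Re-runs the simulation to steady state for each value of `a1` or `a2`,
#' collects the steady centerline profiles and locates their common
#' intersection point. This reproduces the coefficient-sensitivity studies
#' of temperature-dependent perfusion: the curves of a sweep over `a1`
#' intersect near the point where the tissue sits at blood temperature,
#' where the perfusion term loses its sensitivity to the rate coefficient.
#'
#' @param config a [bioheat_config()]; its perfusion model supplies the
#'   non-swept coefficient
#' @param parameter `"a1"` or `"a2"`
#' @param values positive coefficient values to sweep
#' @return an object of class `sweep_result`: `curves` (list of steady
#'   `profile_curve`s labelled by value), `steady_times` (s, per run, under
#'   the 1e-4 degC/step detection rule), and `intersection` (list or the
#'   string `"n/a"` when fewer than two curves are available)
#' @export
sensitivity_sweep <- function(config, parameter = c("a1", "a2"), values) {
  stopifnot(inherits(config, "bioheat_config"))
  parameter <- match.arg(parameter)
  if (!length(values) || any(values <= 0)) {
    stop("sweep values must be positive", call. = FALSE)
  }
  curves <- list()
  steady_times <- numeric(0)
  for (v in values) {
    pm <- config$perfusion
    pm[[parameter]] <- v
    cfg_v <- config
    cfg_v$perfusion <- perfusion_model(pm$kind, pm$a1, pm$a2)
    rec <- tryCatch(march(cfg_v), error = function(e) {
      stop("sweep failed at ", parameter, " = ", v, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (!isTRUE(rec$steady)) {
      stop("sweep run at ", parameter, " = ", v,
           " did not reach steady state; increase t_end", call. = FALSE)
    }
    curves[[length(curves) + 1L]] <- centerline_profile(rec, label = v)
    steady_times <- c(steady_times, steady_state_time(rec))
  }
  intersection <- if (length(curves) >= 2L) {
    tryCatch(find_intersection(curves), error = function(e) "n/a")
  } else "n/a"
  structure(list(parameter = parameter, values = values, curves = curves,
                 steady_times = steady_times, intersection = intersection),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep over %s: %s\n", x$parameter,
              paste(x$values, collapse = ", ")))
  if (is.list(x$intersection)) {
    cat(sprintf("  intersection: x = %.3f mm, T = %.3f degC (spread %.3g degC)\n",
                1000 * x$intersection$x, x$intersection$T, x$intersection$spread))
  } else {
    cat("  intersection: n/a\n")
  }
  invisible(x)
}
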