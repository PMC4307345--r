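# Shared fixtures and independent oracles, all built in code.

# default skin-model configuration with a short horizon
quick_config <- function(t_end = 100, snapshot_times = numeric(0), ...) {
  bioheat_config(stepping = step_parameters(t_end = t_end),
                 output = list(snapshot_times = snapshot_times), ...)
}

# heat-equation limit: no perfusion, no heating
heat_limit_config <- function(dt = 1, t_end = 64, steady_tol = 0) {
  bioheat_config(
    properties = tissue_properties(Q_r = 0, Q_m = 0),
    perfusion = perfusion_model("constant", a1 = 0),
    stepping = step_parameters(dt = dt, t_end = t_end, steady_tol = steady_tol)
  )
}

# minimal hand-built collocation set: 1 interior point, 1 collocation per
# edge, sources inflated away from the unit square
toy_collocation <- function() {
  structure(list(
    interior = cbind(x = 0.5, y = 0.5),
    boundary = rbind(c(1, 0.5), c(0.5, 1), c(0.5, 0), c(0, 0.5)),
    normal = rbind(c(1, 0), c(0, 1), c(0, -1), c(-1, 0)),
    segment = 1:4,
    sources = rbind(c(1.75, 0.5), c(0.5, 1.75), c(0.5, -0.75), c(-0.75, 0.5)),
    counts = rep(1L, 4), domain = domain_spec(1, 1), source_offset = 1.5),
    class = "collocation_set")
}

# five-point finite-difference Laplacian of a radial kernel, centered at
# a point at distance r from the kernel anchor (independent of the
# package's analytic derivatives)
fd_laplacian_radial <- function(f, r, h = 1e-4) {
  p <- c(r, 0)  # anchor at origin, field point on the x-axis
  val <- function(q) f(sqrt(sum(q^2)))
  (val(p + c(h, 0)) + val(p - c(h, 0)) +
     val(p + c(0, h)) + val(p - c(0, h)) - 4 * val(p)) / h^2
}

# truncated Fourier-series solution of the 1D heat equation on [0, L]:
# theta(0) = theta_s, theta(L) = 0, theta(x, 0) = 0
heat_slab_series <- function(x, t, L, alpha, theta_s, n_terms = 50) {
  s <- theta_s * (1 - x / L)
  for (n in seq_len(n_terms)) {
    s <- s - (2 * theta_s / (n * pi)) * sin(n * pi * x / L) *
      exp(-alpha * (n * pi / L)^2 * t)
  }
  s
}

# independent steady 1D Pennes solve: second-order tridiagonal finite
# differences at high resolution (oracle for the closed-form profile)
steady_1d_fd_oracle <- function(props, omega_b, L, T_s, T_c, n = 4001) {
  x <- seq(0, L, length.out = n)
  h <- x[2] - x[1]
  ni <- n - 2
  pb <- props$rho_b * props$c_b * omega_b
  # k (T[i-1] - 2 T[i] + T[i+1])/h^2 - pb T[i] = -pb T_b - Q_t
  A <- Matrix::bandSparse(ni, ni, k = -1:1,
    diagonals = list(rep(props$k / h^2, ni - 1),
                     rep(-2 * props$k / h^2 - pb, ni),
                     rep(props$k / h^2, ni - 1)))
  b <- rep(-pb * props$T_b - props$Q_t, ni)
  b[1] <- b[1] - props$k / h^2 * T_s
  b[ni] <- b[ni] - props$k / h^2 * T_c
  list(x = x, T = c(T_s, as.numeric(Matrix::solve(A, b)), T_c))
}

# largest temperature spread across y within columns of equal x
column_y_spread <- function(record, roles = "interior") {
  pts <- record$points
  fin <- record$snapshots[nrow(record$snapshots), ]
  sel <- pts$role %in% roles
  max(tapply(fin[sel], round(pts$x[sel], 9), function(v) max(v) - min(v)))
}
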