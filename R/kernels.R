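#' Thin-plate-spline basis and its Laplacian particular solution
#'
#' The first-order thin plate spline phi(r) = r^2 log(r) is the radial basis
#' used for dual-reciprocity interpolation of the nonhomogeneous term. Its
#' particular-solution kernel Phi(r) = r^4 (2 log(r) - 1) / 32 satisfies
#' Lap(Phi) = phi in 2D; both have removable singularities at r = 0 where
#' the limit value 0 is returned. The radial derivative of Phi is
#' dPhi/dr = r^3 (4 log(r) - 1) / 16, also 0 in the limit r -> 0.
#'
#' @param r Euclidean distance(s), >= 0
#' @return kernel value(s)
#' @export
#' @examples
#' tps_basis(2)        # 4*log(2)
#' tps_particular(1)   # -1/32
tps_basis <- function(r) {
  if (any(r < 0)) stop("distance r must be nonnegative", call. = FALSE)
  out <- r; out[] <- 0   # zero limit at r = 0, shape preserved
  p <- r > 0
  out[p] <- r[p]^2 * log(r[p])
  out
}

#' @rdname tps_basis
#' @export
tps_particular <- function(r) {
  if (any(r < 0)) stop("distance r must be nonnegative", call. = FALSE)
  out <- r; out[] <- 0
  p <- r > 0
  out[p] <- r[p]^4 * (2 * log(r[p]) - 1) / 32
  out
}

#' @rdname tps_basis
#' @export
tps_particular_dr <- function(r) {
  if (any(r < 0)) stop("distance r must be nonnegative", call. = FALSE)
  out <- r; out[] <- 0
  p <- r > 0
  out[p] <- r[p]^3 * (4 * log(r[p]) - 1) / 16
  out
}

#' Fundamental solution of the 2D Laplace operator
#'
#' G(x, s) = -log(|x - s|) / (2 pi), harmonic everywhere away from the
#' source point s. Used as the basis of the method of fundamental solutions;
#' sources always lie outside the domain so the singularity is never hit.
#'
#' @param r distance(s) between field and source point, > 0
#' @return kernel value(s)
#' @export
laplace_fundamental <- function(r) {
  if (any(r <= 0)) stop("fundamental solution is singular at r = 0", call. = FALSE)
  -log(r) / (2 * pi)
}

# pairwise Euclidean distances between the rows of two 2-column matrices
pairwise_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Normal derivatives of the meshless kernels
#'
#' Directional derivatives grad(Phi) . n and grad(G) . n of the
#' thin-plate-spline particular kernel and the Laplace fundamental solution,
#' for boundary collocation rows of insulated (Neumann) segments. `x` holds
#' field points (rows), `centers`/`sources` the kernel anchor points (rows),
#' and `n` one unit normal per field point; the result is a matrix with one
#' row per field point and one column per anchor.
#'
#' For the radial kernels the derivative is f'(r) * ((x - anchor) . n) / r;
#' it vanishes when n is orthogonal to the radial direction, and the
#' thin-plate-spline derivative tends to 0 as r -> 0.
#'
#' @param x field points, matrix with 2 columns
#' @param centers,sources kernel anchor points, matrix with 2 columns
#' @param n outward unit normals, one row per row of `x`
#' @return matrix of directional derivative values
#' @export
normal_derivative_tps_particular <- function(x, centers, n) {
  x <- rbind(x); centers <- rbind(centers); n <- rbind(n)
  check_unit_normals(n)
  dx <- outer(x[, 1], centers[, 1], "-")
  dy <- outer(x[, 2], centers[, 2], "-")
  r <- sqrt(dx * dx + dy * dy)
  rn <- dx * n[, 1] + dy * n[, 2]   # (x - c) . n, recycled per row
  out <- matrix(0, nrow(x), nrow(centers))
  p <- r > 0
  out[p] <- tps_particular_dr(r[p]) * rn[p] / r[p]
  out
}

#' @rdname normal_derivative_tps_particular
#' @export
normal_derivative_fundamental <- function(x, sources, n) {
  x <- rbind(x); sources <- rbind(sources); n <- rbind(n)
  check_unit_normals(n)
  dx <- outer(x[, 1], sources[, 1], "-")
  dy <- outer(x[, 2], sources[, 2], "-")
  r2 <- dx * dx + dy * dy
  if (any(r2 == 0)) stop("fundamental solution is singular at r = 0", call. = FALSE)
  rn <- dx * n[, 1] + dy * n[, 2]
  -rn / (2 * pi * r2)
}

check_unit_normals <- function(n) {
  if (any(abs(sqrt(rowSums(n^2)) - 1) > 1e-10)) {
    stop("normals must be unit length", call. = FALSE)
  }
  invisible(n)
}
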