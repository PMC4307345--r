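#' Modified Helmholtz collocation problem
#'
#' One time step of the operator-splitting march requires the solution of
#' Lap(theta*) - lambda2 * theta* = F on the interior collocation points,
#' with Dirichlet data on the vertical edges (gamma1, gamma4) and insulation
#' (homogeneous Neumann) on the horizontal edges (gamma2, gamma3). The
#' unknown field is represented as
#' theta*(x) = sum_i alpha_i Phi_i(x) + sum_j beta_j G_j(x),
#' thin-plate-spline particular kernels centered at the M interior points
#' plus Laplace fundamental solutions anchored at the N exterior sources.
#'
#' @param lambda2 Helmholtz parameter lambda^2 (1/m^2), > 0
#' @param F right-hand-side values at the M interior points (degC/m^2)
#' @param bc_values list with elements `gamma1` and `gamma4`: Dirichlet
#'   theta* values (scalar, or one value per collocation on that segment)
#' @param colloc a [build_collocation()] set
#' @return an object of class `helmholtz_problem`
#' @export
helmholtz_problem <- function(lambda2, F, bc_values, colloc) {
  stopifnot(inherits(colloc, "collocation_set"))
  if (!is.numeric(lambda2) || length(lambda2) != 1L || lambda2 <= 0) {
    stop("lambda2 must be a single positive number", call. = FALSE)
  }
  M <- nrow(colloc$interior)
  if (length(F) != M) stop("F must have one value per interior point", call. = FALSE)
  for (seg in c("gamma1", "gamma4")) {
    v <- bc_values[[seg]]
    nseg <- sum(colloc$segment == switch(seg, gamma1 = 1L, gamma4 = 4L))
    if (is.null(v) || !(length(v) %in% c(1L, nseg)) || any(!is.finite(v))) {
      stop("bc_values$", seg, " must hold 1 or ", nseg, " finite values", call. = FALSE)
    }
  }
  structure(list(lambda2 = lambda2, F = F, bc_values = bc_values, colloc = colloc),
            class = "helmholtz_problem")
}

#' Assemble (and pre-factor) the collocation operator
#'
#' Builds the square (M+N) x (M+N) collocation matrix for a given geometry
#' and Helmholtz parameter. The first M rows enforce the PDE at the interior
#' points: thin-plate-spline columns carry phi_i(x) - lambda2 * Phi_i(x) and
#' source columns carry -lambda2 * G_j(x) (the fundamental solutions are
#' harmonic, so their Laplacian contributes nothing). The remaining N rows
#' enforce theta* = g on the Dirichlet segments through the field
#' representation, and d(theta*)/dn = 0 on the insulated segments through
#' its normal derivative.
#'
#' The matrix depends only on geometry and lambda2, so the marching scheme
#' factors it once and reuses it every step. Collocation matrices of the
#' method of fundamental solutions are severely ill-conditioned; the
#' operator stores a row/column equilibrated copy and its LAPACK QR
#' factorisation, together with a condition estimate of the equilibrated
#' system.
#'
#' @param colloc a [build_collocation()] set
#' @param lambda2 Helmholtz parameter (1/m^2)
#' @return an object of class `helmholtz_operator` with elements `A` (the
#'   raw matrix), `qr` (factorisation of the equilibrated matrix), `rscale`,
#'   `cscale`, and `condition`
#' @export
helmholtz_operator <- function(colloc, lambda2) {
  stopifnot(inherits(colloc, "collocation_set"))
  M <- nrow(colloc$interior)
  N <- nrow(colloc$boundary)

  r_im <- pairwise_dist(colloc$interior, colloc$interior)
  r_is <- pairwise_dist(colloc$interior, colloc$sources)
  pde_rows <- cbind(tps_basis(r_im) - lambda2 * tps_particular(r_im),
                    -lambda2 * laplace_fundamental(r_is))

  r_bm <- pairwise_dist(colloc$boundary, colloc$interior)
  r_bs <- pairwise_dist(colloc$boundary, colloc$sources)
  U <- cbind(tps_particular(r_bm), laplace_fundamental(r_bs))
  Q <- cbind(normal_derivative_tps_particular(colloc$boundary, colloc$interior, colloc$normal),
             normal_derivative_fundamental(colloc$boundary, colloc$sources, colloc$normal))

  dirichlet <- colloc$segment %in% c(1L, 4L)
  bc_rows <- Q
  bc_rows[dirichlet, ] <- U[dirichlet, ]

  A <- rbind(pde_rows, bc_rows)

  # equilibrate: raw MFS matrices can have rcond ~ 1e-20 yet solve accurately
  rscale <- 1 / apply(abs(A), 1, max)
  As <- A * rscale
  cscale <- 1 / apply(abs(As), 2, max)
  As <- sweep(As, 2, cscale, "*")
  qrA <- qr(As, LAPACK = TRUE)
  cond <- tryCatch(kappa(qrA, exact = FALSE), error = function(e) Inf)

  structure(
    list(A = A, qr = qrA, rscale = rscale, cscale = cscale,
         condition = cond, lambda2 = lambda2, colloc = colloc,
         dirichlet = dirichlet),
    class = "helmholtz_operator"
  )
}

#' @export
print.helmholtz_operator <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf("Modified Helmholtz collocation operator: %d x %d, lambda2 = %g 1/m^2\n",
              n, n, x$lambda2))
  cat(sprintf("  condition estimate (equilibrated): %.3g\n", x$condition))
  invisible(x)
}

#' Assemble the full linear system of a Helmholtz problem
#'
#' @param problem a [helmholtz_problem()]
#' @return list with the dense square `matrix` and the `rhs` vector
#' @export
assemble_system <- function(problem) {
  stopifnot(inherits(problem, "helmholtz_problem"))
  op <- helmholtz_operator(problem$colloc, problem$lambda2)
  list(matrix = op$A, rhs = helmholtz_rhs_vector(problem, op))
}

helmholtz_rhs_vector <- function(problem, op) {
  colloc <- problem$colloc
  N <- nrow(colloc$boundary)
  bc <- numeric(N)
  for (seg in c(1L, 4L)) {
    v <- problem$bc_values[[paste0("gamma", seg)]]
    bc[colloc$segment == seg] <- v
  }
  c(problem$F, bc)
}

#' Solve a modified Helmholtz collocation problem
#'
#' Solves the assembled square system for the coefficient vector
#' c = (alpha_1..alpha_M, beta_1..beta_N). A warning is raised when the
#' condition estimate of the (equilibrated) system exceeds `cond_warn`. The
#' infinity-norm relative residual of the raw system is attached to the
#' result and checked against 1e-8.
#'
#' @param problem a [helmholtz_problem()]
#' @param operator optionally a pre-built [helmholtz_operator()] for the
#'   same geometry and lambda2 (reused across time steps)
#' @param cond_warn condition-estimate warning threshold
#' @return numeric coefficient vector of class `coefficient_vector`, with
#'   attributes `residual` and `condition`
#' @export
solve_helmholtz <- function(problem, operator = NULL, cond_warn = 1e12) {
  stopifnot(inherits(problem, "helmholtz_problem"))
  if (is.null(operator)) {
    operator <- helmholtz_operator(problem$colloc, problem$lambda2)
  } else {
    stopifnot(inherits(operator, "helmholtz_operator"))
    if (operator$lambda2 != problem$lambda2) {
      stop("operator lambda2 does not match the problem", call. = FALSE)
    }
  }
  if (is.finite(cond_warn) && operator$condition > cond_warn) {
    warning(sprintf("collocation system condition estimate %.3g exceeds %.3g",
                    operator$condition, cond_warn), call. = FALSE)
  }
  b <- helmholtz_rhs_vector(problem, operator)
  cf <- operator_solve(operator, b)
  res <- max(abs(operator$A %*% cf - b))
  den <- max(abs(b))
  rel <- if (den > 0) res / den else res
  if (!is.finite(rel)) stop("collocation solve failed (singular system)", call. = FALSE)
  structure(cf, class = "coefficient_vector",
            residual = rel, condition = operator$condition)
}

operator_solve <- function(op, b) {
  z <- qr.coef(op$qr, op$rscale * b)
  as.numeric(op$cscale * z)
}

#' Evaluate the meshless field
#'
#' theta*(x) = sum_i alpha_i Phi_i(x) + sum_j beta_j G_j(x) at arbitrary
#' query points. Querying at a fictitious source point is an error (the
#' fundamental solution is singular there); this cannot happen for points
#' inside the closed domain.
#'
#' @param coef coefficient vector from [solve_helmholtz()]
#' @param colloc the collocation set the coefficients belong to
#' @param points query points, matrix-like with 2 columns (m)
#' @return theta* values at the query points (degC)
#' @export
evaluate_field <- function(coef, colloc, points) {
  as.numeric(evaluation_matrix(colloc, points) %*% as.numeric(coef))
}

#' @rdname evaluate_field
#' @export
evaluation_matrix <- function(colloc, points) {
  stopifnot(inherits(colloc, "collocation_set"))
  points <- rbind(points)
  r_pm <- pairwise_dist(points, colloc$interior)
  r_ps <- pairwise_dist(points, colloc$sources)
  if (any(r_ps == 0)) {
    stop("cannot evaluate the field at a fictitious source point", call. = FALSE)
  }
  cbind(tps_particular(r_pm), laplace_fundamental(r_ps))
}
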