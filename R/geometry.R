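#' Rectangular skin-tissue domain
#'
#' The solution domain is the rectangle \[0, Lx\] x \[0, Ly\] with x measured
#' from the skin surface. Its boundary is split into four segments:
#' gamma1 = right edge (body core, Dirichlet), gamma2 = top edge (insulated),
#' gamma3 = bottom edge (insulated), gamma4 = left edge (skin surface,
#' Dirichlet). Default dimensions are 30 mm x 15 mm, consistent with probe
#' locations up to 26.25 mm from the surface; with insulated top/bottom
#' edges and x-only boundary data the solution is independent of Ly.
#'
#' @param Lx domain length along x (m)
#' @param Ly domain height along y (m)
#' @return an object of class `domain_spec`
#' @export
domain_spec <- function(Lx = 0.03, Ly = 0.015) {
  if (!is.numeric(Lx) || length(Lx) != 1L || !is.finite(Lx) || Lx <= 0 ||
      !is.numeric(Ly) || length(Ly) != 1L || !is.finite(Ly) || Ly <= 0) {
    stop("domain dimensions Lx, Ly must be single positive numbers", call. = FALSE)
  }
  structure(list(Lx = Lx, Ly = Ly), class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("Rectangular domain: %g mm (x, from skin surface) x %g mm (y)\n",
              1000 * x$Lx, 1000 * x$Ly))
  invisible(x)
}

#' Build the collocation geometry
#'
#' Places the three point families the meshless solver needs:
#' \itemize{
#'   \item `interior`: a uniform `nx_int` x `ny_int` grid strictly inside the
#'     rectangle (inset by one grid spacing from every edge). These are both
#'     the PDE collocation points and the centers of the thin-plate-spline
#'     interpolation.
#'   \item `boundary`: uniformly spaced collocations on each edge with
#'     outward unit normals and segment labels. Corners are owned by the
#'     vertical (Dirichlet) edges, so the counts `n_edge = c(n1, n2, n3, n4)`
#'     place `n1`/`n4` points on the right/left edges including both corners
#'     and `n2`/`n3` points strictly inside the top/bottom edges. The default
#'     `c(9, 7, 7, 9)` gives the standard 32 boundary collocations.
#'   \item `sources`: the fictitious sources of the fundamental-solution
#'     basis, obtained by inflating each boundary point radially about the
#'     rectangle centroid by the factor `1 + source_offset`. They always lie
#'     strictly outside the closed domain, so the Laplace kernel is never
#'     singular.
#' }
#'
#' @param domain a [domain_spec()]
#' @param nx_int,ny_int interior grid counts (default 9 x 7 = 63 points)
#' @param n_edge integer vector `c(n1, n2, n3, n4)` of boundary collocation
#'   counts on segments gamma1 (right), gamma2 (top), gamma3 (bottom),
#'   gamma4 (left)
#' @param source_offset dimensionless radial inflation ratio (> 0) for the
#'   fictitious source circle; larger offsets improve accuracy but worsen
#'   the conditioning of the collocation matrix
#' @return an object of class `collocation_set` with elements `interior`
#'   (M x 2), `boundary` (N x 2), `normal` (N x 2), `segment` (integer 1..4),
#'   `sources` (N x 2), `counts`, and the originating `domain`
#' @export
#' @examples
#' cs <- build_collocation(domain_spec())
#' nrow(cs$interior)  # 63
#' nrow(cs$boundary)  # 32
build_collocation <- function(domain, nx_int = 9, ny_int = 7,
                              n_edge = c(9, 7, 7, 9), source_offset = 1.5) {
  stopifnot(inherits(domain, "domain_spec"))
  if (nx_int < 1 || ny_int < 1) stop("interior grid counts must be >= 1", call. = FALSE)
  if (length(n_edge) != 4L || any(n_edge < 2)) {
    stop("n_edge must give four per-segment counts, each >= 2", call. = FALSE)
  }
  if (!is.numeric(source_offset) || source_offset <= 0) {
    stop("source_offset must be > 0", call. = FALSE)
  }
  Lx <- domain$Lx; Ly <- domain$Ly

  xi <- seq(0, Lx, length.out = nx_int + 2)[-c(1, nx_int + 2)]
  yi <- seq(0, Ly, length.out = ny_int + 2)[-c(1, ny_int + 2)]
  interior <- cbind(x = rep(xi, times = ny_int), y = rep(yi, each = nx_int))

  # gamma1 right edge (normal +x) and gamma4 left edge (normal -x) own the
  # corners; gamma2 top (+y) and gamma3 bottom (-y) are corner-free
  y1 <- seq(0, Ly, length.out = n_edge[1])
  x2 <- seq(0, Lx, length.out = n_edge[2] + 2)[-c(1, n_edge[2] + 2)]
  x3 <- seq(0, Lx, length.out = n_edge[3] + 2)[-c(1, n_edge[3] + 2)]
  y4 <- seq(0, Ly, length.out = n_edge[4])
  boundary <- rbind(
    cbind(Lx, y1),
    cbind(x2, Ly),
    cbind(x3, 0),
    cbind(0, y4)
  )
  colnames(boundary) <- c("x", "y")
  normal <- rbind(
    matrix(c(1, 0), n_edge[1], 2, byrow = TRUE),
    matrix(c(0, 1), n_edge[2], 2, byrow = TRUE),
    matrix(c(0, -1), n_edge[3], 2, byrow = TRUE),
    matrix(c(-1, 0), n_edge[4], 2, byrow = TRUE)
  )
  segment <- rep.int(1:4, n_edge)

  centroid <- c(Lx / 2, Ly / 2)
  sources <- sweep(sweep(boundary, 2, centroid) * (1 + source_offset), 2, centroid, "+")

  cs <- structure(
    list(interior = interior, boundary = boundary, normal = normal,
         segment = segment, sources = sources, counts = as.integer(n_edge),
         domain = domain, source_offset = source_offset),
    class = "collocation_set"
  )
  validate_collocation(cs)
  cs
}

validate_collocation <- function(cs) {
  all_pts <- rbind(cs$interior, cs$boundary, cs$sources)
  d <- as.matrix(stats::dist(all_pts))
  diag(d) <- Inf
  if (min(d) <= 0) stop("collocation set contains duplicate points", call. = FALSE)
  nrm <- sqrt(rowSums(cs$normal^2))
  if (any(abs(nrm - 1) > 1e-12)) stop("boundary normals must be unit length", call. = FALSE)
  Lx <- cs$domain$Lx; Ly <- cs$domain$Ly
  s <- cs$sources
  inside <- s[, 1] >= 0 & s[, 1] <= Lx & s[, 2] >= 0 & s[, 2] <= Ly
  if (any(inside)) stop("fictitious source points must lie outside the domain", call. = FALSE)
  invisible(cs)
}

#' @export
print.collocation_set <- function(x, ...) {
  cat(sprintf("Collocation set: %d interior points, %d boundary collocations (%s), %d sources\n",
              nrow(x$interior), nrow(x$boundary),
              paste(x$counts, collapse = "+"), nrow(x$sources)))
  invisible(x)
}

#' @export
as.data.frame.collocation_set <- function(x, ...) {
  rbind(
    data.frame(role = "interior", x = x$interior[, 1], y = x$interior[, 2],
               nx = NA_real_, ny = NA_real_, segment = NA_integer_),
    data.frame(role = "boundary", x = x$boundary[, 1], y = x$boundary[, 2],
               nx = x$normal[, 1], ny = x$normal[, 2], segment = x$segment),
    data.frame(role = "source", x = x$sources[, 1], y = x$sources[, 2],
               nx = NA_real_, ny = NA_real_, segment = NA_integer_)
  )
}
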