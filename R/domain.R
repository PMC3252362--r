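#' Doubly periodic square domain
#'
#' Cells live on the square `[0, L) x [0, L)` with periodic (torus) boundary
#' conditions in both directions.  All lengths in the package are measured in
#' units of the cell radius.
#'
#' @param L Side length of the domain (cell radii), positive.
#' @return An object of class `periodic_domain` with element `L`.
#' @examples
#' dom <- periodic_domain(120)
#' min_image_dist(c(0, 0), c(119, 0), dom$L)  # 1, through the boundary
#' @export
periodic_domain <- function(L) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  structure(list(L = L), class = "periodic_domain")
}

#' @export
print.periodic_domain <- function(x, ...) {
  cat(sprintf("Periodic square domain [0, %g) x [0, %g)\n", x$L, x$L))
  invisible(x)
}

#' Wrap coordinates into the periodic domain
#'
#' @param xy Numeric vector, matrix or data frame of coordinates.
#' @param L Domain side length.
#' @return Coordinates mapped into `[0, L)`.
#' @export
wrap_coords <- function(xy, L) {
  w <- xy %% L
  w[w >= L] <- 0  # guard against rounding at the seam
  w
}

#' Minimum-image distance on the torus
#'
#' Each coordinate difference is mapped into `(-L/2, L/2]` before taking the
#' Euclidean norm, so distances are measured through the nearest periodic
#' image.  The result lies in `[0, L/sqrt(2)]`.
#'
#' @param p,q Points: length-2 vectors, or n x 2 matrices (recycled
#'   row-wise against each other).
#' @param L Domain side length.
#' @return Numeric vector of torus distances.
#' @export
min_image_dist <- function(p, q, L) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  d <- sweep_delta(p[, 1] - q[, 1], L)
  e <- sweep_delta(p[, 2] - q[, 2], L)
  sqrt(d * d + e * e)
}

# map coordinate differences into (-L/2, L/2]
sweep_delta <- function(d, L) {
  d <- d %% L
  d[d > L / 2] <- d[d > L / 2] - L
  d
}
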