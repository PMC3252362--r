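# Synthetic marked point patterns with known structure, so every statistic
# can be exercised (and calibrated) without running the simulator.

#' Poisson pattern with independent random labels
#'
#' Uniform positions with i.i.d. coin-flip marks: the random-differentiation
#' null, under which `g_S(r) = g(r)` and quadrat proportions follow the
#' binomial/truncated-normal null.
#'
#' @param N Number of points.
#' @param L Domain side length.
#' @param p Probability of mark `R`.
#' @return A [mark_pattern()] object.
#' @export
poisson_random_labels <- function(N, L, p = 0.5) {
  stopifnot(p >= 0, p <= 1, N >= 1)
  x <- runif(N, 0, L); y <- runif(N, 0, L)
  mark_pattern(x, y, ifelse(runif(N) < p, "R", "G"), L)
}

#' Alternating stripe pattern
#'
#' Uniform positions; mark `R` where `floor(x / w)` is even, giving
#' alternating vertical stripes of width `w` - a pattern with an exactly
#' known length-scale for validating the pattern-scale estimator.
#'
#' @param N Number of points.
#' @param L Domain side length.
#' @param w Stripe width; `L / (2 w)` must be an integer so the stripes
#'   tile the torus.
#' @return A [mark_pattern()] object.
#' @export
stripe_pattern <- function(N, L, w) {
  stopifnot(w > 0, w <= L / 2)
  if (abs(L / (2 * w) - round(L / (2 * w))) > 1e-9)
    stop("L / (2 w) must be an integer")
  x <- runif(N, 0, L); y <- runif(N, 0, L)
  mark_pattern(x, y, ifelse(floor(x / w) %% 2 == 0, "R", "G"), L)
}

#' Disc pattern
#'
#' Uniform positions; mark `R` inside any of the given discs (minimum-image
#' distance), `G` outside - a patchy fixture mimicking simulated patterns.
#'
#' @param N Number of points.
#' @param L Domain side length.
#' @param centres Matrix (or length-2 vector) of disc centres.
#' @param radius Disc radius, below `L / 4`.
#' @return A [mark_pattern()] object.
#' @export
disc_pattern <- function(N, L, centres, radius) {
  stopifnot(radius >= 0, radius < L / 4)
  centres <- matrix(as.numeric(centres), ncol = 2)
  x <- runif(N, 0, L); y <- runif(N, 0, L)
  inside <- rep(FALSE, N)
  for (k in seq_len(nrow(centres))) {
    d <- min_image_dist(cbind(x, y),
                        matrix(centres[k, ], N, 2, byrow = TRUE), L)
    inside <- inside | (d <= radius)
  }
  mark_pattern(x, y, ifelse(inside, "R", "G"), L)
}
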