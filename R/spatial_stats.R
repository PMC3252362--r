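#' Marked point pattern on a periodic square
#'
#' Cell-centre coordinates on `[0, L) x [0, L)` with a binary type mark
#' (`R` or `G`).  This is the common input of all spatial statistics; both
#' simulation output and external centroid tables are converted to it.
#'
#' @param x,y Coordinates in `[0, L)`.
#' @param type Marks: factor or character vector with values `"R"`/`"G"`.
#' @param L Domain side length.
#' @return An object of class `mpp` with elements `x`, `y`, `type`, `L`,
#'   counts `N`, `N_R`, `N_G` and densities `rho`, `rho_R`, `rho_G`.
#' @export
mark_pattern <- function(x, y, type, L) {
  stopifnot(length(x) == length(y), length(x) == length(type), L > 0,
            all(is.finite(x)), all(is.finite(y)),
            all(x >= 0), all(x < L), all(y >= 0), all(y < L))
  type <- factor(as.character(type), levels = c("R", "G"))
  if (anyNA(type)) stop("marks must be 'R' or 'G'")
  N <- length(x)
  N_R <- sum(type == "R"); N_G <- N - N_R
  structure(list(x = as.numeric(x), y = as.numeric(y), type = type, L = L,
                 N = N, N_R = N_R, N_G = N_G,
                 rho = N / L^2, rho_R = N_R / L^2, rho_G = N_G / L^2),
            class = "mpp")
}

#' @export
print.mpp <- function(x, ...) {
  cat(sprintf("Marked point pattern: %d cells (R = %d, G = %d) on [0, %g)^2\n",
              x$N, x$N_R, x$N_G, x$L))
  invisible(x)
}

#' @export
as.data.frame.mpp <- function(x, ...) {
  data.frame(id = seq_len(x$N) - 1L, x = x$x, y = x$y,
             type = as.character(x$type))
}

#' @export
plot.mpp <- function(x, cex = 0.4, ...) {
  graphics::plot(x$x, x$y, col = ifelse(x$type == "R", "red3", "green4"),
                 pch = 16, cex = cex, asp = 1, xlim = c(0, x$L),
                 ylim = c(0, x$L), xlab = "x (cell radii)",
                 ylab = "y (cell radii)", ...)
  invisible(x)
}

#' Read / write marked pattern CSV
#'
#' The table format is `id,x,y,type` with `type` in `{R, G}`; the domain
#' size `L` is supplied separately (it is not derivable from the points).
#'
#' @param file CSV path.
#' @param L Domain side length.
#' @return A [mark_pattern()] object.
#' @export
read_pattern <- function(file, L) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "type") %in% names(df)))
  mark_pattern(df$x, df$y, df$type, L)
}

#' @rdname read_pattern
#' @param pattern A [mark_pattern()] object.
#' @export
write_pattern <- function(pattern, file) {
  stopifnot(inherits(pattern, "mpp"))
  write.csv(as.data.frame(pattern), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

new_pcf_estimate <- function(values, M_g, L, label) {
  breaks <- seq(0, L, length.out = M_g + 1)
  centers <- (breaks[-1] + breaks[-(M_g + 1)]) / 2
  structure(list(values = as.numeric(values), centers = centers,
                 breaks = breaks, M_g = as.integer(M_g), L = L,
                 label = label),
            class = "pcf_estimate")
}

same_geometry <- function(a, b) {
  a$M_g == b$M_g && isTRUE(all.equal(a$L, b$L))
}

#' @export
print.pcf_estimate <- function(x, ...) {
  cat(sprintf("PCF estimate '%s': %d bins of width %g on (0, %g]\n",
              x$label, x$M_g, x$L / x$M_g, x$L))
  invisible(x)
}

#' @export
plot.pcf_estimate <- function(x, ..., xlim = c(0, x$L / 2)) {
  graphics::plot(x$centers, x$values, type = "l", xlim = xlim,
                 xlab = "r (cell radii)", ylab = x$label, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

# annulus normalisation pi (r_{k+1}^2 - r_k^2) for each bin
annulus_areas <- function(breaks) {
  pi * diff(breaks^2)
}

#' Pair correlation function of a marked point pattern
#'
#' Piecewise-constant estimate over `M_g` equal distance intervals
#' `(r_k, r_{k+1}]` spanning `0 < r <= L`: the ordered-pair count in each
#' interval (minimum-image distances, no edge correction needed on the
#' torus) normalised by `N^2 pi (r_{k+1}^2 - r_k^2) / L^2`.  Values are
#' attached to bin centres for plotting/interpolation.  The annulus
#' normalisation is exact only up to `r = L/2` on the torus; larger bins are
#' computed as defined but flagged (`biased` attribute) and excluded from
#' pattern-scale searches.
#'
#' @param pattern A [mark_pattern()] object with at least 2 points.
#' @param M_g Number of distance intervals.
#' @return A `pcf_estimate` object.
#' @export
pcf <- function(pattern, M_g = 60) {
  stopifnot(inherits(pattern, "mpp"))
  if (pattern$N < 2) stop("need at least two points to estimate a PCF")
  counts <- pair_count_bins_cpp(pattern$x, pattern$y, pattern$x, pattern$y,
                                pattern$L, M_g, TRUE)
  est <- new_pcf_estimate(NA, M_g, pattern$L, "g")
  est$values <- pattern$L^2 * counts / (pattern$N^2 * annulus_areas(est$breaks))
  est
}

#' Cross-type pair correlation function
#'
#' As [pcf()] but the ordered pairs run over cells of type `X` and `Y`
#' respectively, with normalisation `N_X N_Y pi (r_{k+1}^2 - r_k^2) / L^2`.
#' Self-pairs are excluded when `X == Y`.
#'
#' @param pattern A [mark_pattern()] object.
#' @param X,Y Types, `"R"` or `"G"`.
#' @param M_g Number of distance intervals.
#' @return A `pcf_estimate` object.
#' @export
cross_pcf <- function(pattern, X, Y, M_g = 60) {
  stopifnot(inherits(pattern, "mpp"))
  X <- match.arg(X, c("R", "G")); Y <- match.arg(Y, c("R", "G"))
  ix <- which(pattern$type == X); iy <- which(pattern$type == Y)
  if (length(ix) == 0) stop(sprintf("no cells of type %s", X))
  if (length(iy) == 0) stop(sprintf("no cells of type %s", Y))
  if (X == Y && length(ix) < 2)
    stop(sprintf("need at least two cells of type %s", X))
  counts <- if (X == Y) {
    pair_count_bins_cpp(pattern$x[ix], pattern$y[ix],
                        pattern$x[ix], pattern$y[ix], pattern$L, M_g, TRUE)
  } else {
    pair_count_bins_cpp(pattern$x[ix], pattern$y[ix],
                        pattern$x[iy], pattern$y[iy], pattern$L, M_g, FALSE)
  }
  est <- new_pcf_estimate(NA, M_g, pattern$L, sprintf("g_%s%s", X, Y))
  est$values <- pattern$L^2 * counts /
    (length(ix) * length(iy) * annulus_areas(est$breaks))
  est
}

#' Same-type pair correlation function
#'
#' Bin-wise combination of the two within-type cross-PCFs with weights
#' proportional to the squared type densities,
#' \deqn{g_S = \frac{\rho_R^2 g_{RR} + \rho_G^2 g_{GG}}{\rho_R^2 + \rho_G^2},}
#' so that `g_S / g` is the conditional probability that two cells a
#' distance `r` apart share a type, relative to two cells chosen at random.
#'
#' @param g_RR,g_GG `pcf_estimate` objects on identical bins.
#' @param rho_R,rho_G Type densities (at least one positive).
#' @return A `pcf_estimate` object.
#' @export
same_type_pcf <- function(g_RR, g_GG, rho_R, rho_G) {
  stopifnot(rho_R >= 0, rho_G >= 0, rho_R^2 + rho_G^2 > 0)
  if (!same_geometry(g_RR, g_GG)) stop("incompatible bin geometry")
  wR <- rho_R^2 / (rho_R^2 + rho_G^2)
  est <- new_pcf_estimate(wR * g_RR$values + (1 - wR) * g_GG$values,
                          g_RR$M_g, g_RR$L, "g_S")
  est
}

#' All pattern PCFs in one call
#'
#' Computes `g`, `g_RR`, `g_GG` and `g_S` for a pattern.  When one type is
#' absent (a fixated realisation) the same-type PCF equals the remaining
#' within-type PCF, which coincides with `g`; the result is flagged with
#' `fixated = TRUE`.
#'
#' @param pattern A [mark_pattern()] object.
#' @param M_g Number of distance intervals.
#' @return List with elements `g`, `g_S`, `g_RR`, `g_GG` (the latter two
#'   `NULL` when the type is absent) and `fixated`.
#' @export
pcf_summary <- function(pattern, M_g = 60) {
  g <- pcf(pattern, M_g)
  g_RR <- if (pattern$N_R >= 2) cross_pcf(pattern, "R", "R", M_g) else NULL
  g_GG <- if (pattern$N_G >= 2) cross_pcf(pattern, "G", "G", M_g) else NULL
  fixated <- pattern$N_R == 0 || pattern$N_G == 0
  g_S <- if (!is.null(g_RR) && !is.null(g_GG)) {
    same_type_pcf(g_RR, g_GG, pattern$rho_R, pattern$rho_G)
  } else if (!is.null(g_RR)) {
    est <- g_RR; est$label <- "g_S"; est
  } else if (!is.null(g_GG)) {
    est <- g_GG; est$label <- "g_S"; est
  } else {
    stop("pattern has fewer than two cells of each type")
  }
  list(g = g, g_S = g_S, g_RR = g_RR, g_GG = g_GG, fixated = fixated)
}

#' Bin-wise arithmetic mean of PCF estimates
#'
#' Used to average PCFs over simulation realisations with identical
#' parameters.
#'
#' @param estimates List of `pcf_estimate` objects on identical bins.
#' @return A `pcf_estimate` object.
#' @export
mean_pcf <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "pcf_estimate")))
  first <- estimates[[1]]
  for (e in estimates)
    if (!same_geometry(e, first)) stop("mismatched bin geometry")
  vals <- rowMeans(vapply(estimates, `[[`, numeric(first$M_g), "values"))
  new_pcf_estimate(vals, first$M_g, first$L, first$label)
}

#' Pattern-scale estimate from the PCF intersection
#'
#' The patch size `r_p` is the separation at which the same-type PCF drops
#' back to the all-pairs PCF.  Restricting to bins with centre `<= L/2`
#' (exact annulus normalisation), the difference `g_S - g` must exceed
#' `threshold` somewhere, otherwise no pattern is reported; from the
#' arg-max of the difference the search walks right to the first zero
#' crossing and linearly interpolates between the adjacent bin centres.
#'
#' @param g,g_S `pcf_estimate` objects on identical bins.
#' @param threshold Minimum excursion of `g_S - g` (default 0.02).
#' @return List with `r_p` (numeric, `NA` if absent), `max_diff`, `found`
#'   (logical) and `reason` (`"ok"`, `"below_threshold"` or
#'   `"no_intersection"`).
#' @export
pattern_scale <- function(g, g_S, threshold = 0.02) {
  if (!same_geometry(g, g_S)) stop("incompatible bin geometry")
  keep <- g$centers <= g$L / 2
  r <- g$centers[keep]
  diff <- g_S$values[keep] - g$values[keep]
  md <- max(diff)
  if (md <= threshold)
    return(list(r_p = NA_real_, max_diff = md, found = FALSE,
                reason = "below_threshold"))
  i0 <- which.max(diff)
  for (i in seq_len(length(diff) - i0) + i0) {
    if (diff[i] <= 0) {
      r_p <- if (diff[i] == 0) r[i] else {
        r[i - 1] + (r[i] - r[i - 1]) * diff[i - 1] / (diff[i - 1] - diff[i])
      }
      return(list(r_p = r_p, max_diff = md, found = TRUE, reason = "ok"))
    }
  }
  list(r_p = NA_real_, max_diff = md, found = FALSE, reason = "no_intersection")
}

#' Quadrat histogram of type-R proportions
#'
#' Partitions the domain into `M_q x M_q` square quadrats, computes the
#' proportion `p_R` of type-R cells in each non-empty quadrat (empty
#' quadrats are ignored), pools the values over all supplied patterns, and
#' bins them into `n_bins` equal half-open bins on `[0, 1]` (`p_R = 1` falls
#' in the last bin).  Densities are normalised so the histogram has unit
#' area.
#'
#' @param patterns A [mark_pattern()] object or list of them (shared `L`).
#' @param M_q Quadrats per side.
#' @param n_bins Number of histogram bins (default 50, giving extreme bins
#'   `p_R < 0.02` and `p_R > 0.98`).
#' @return An object of class `quadrat_histogram` with bin `breaks`,
#'   `counts`, `density`, the pooled `p_values`, the number of non-empty
#'   quadrats `n_quadrats` and the expected occupancy `N_q`.
#' @export
quadrat_histogram <- function(patterns, M_q = 12, n_bins = 50) {
  if (inherits(patterns, "mpp")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1, M_q >= 1,
            all(vapply(patterns, inherits, TRUE, "mpp")))
  L <- patterns[[1]]$L
  for (p in patterns) if (!isTRUE(all.equal(p$L, L))) stop("patterns must share L")
  w <- L / M_q
  p_values <- numeric(0)
  for (p in patterns) {
    qx <- pmin(floor(p$x / w), M_q - 1)
    qy <- pmin(floor(p$y / w), M_q - 1)
    quad <- qx * M_q + qy
    tot <- tabulate(quad + 1L, nbins = M_q^2)
    nr <- tabulate((quad + 1L)[p$type == "R"], nbins = M_q^2)
    nonempty <- tot > 0
    p_values <- c(p_values, nr[nonempty] / tot[nonempty])
  }
  if (length(p_values) == 0) stop("all quadrats are empty")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(floor(p_values * n_bins), n_bins - 1) + 1  # lower-closed bins
  counts <- tabulate(bin, nbins = n_bins)
  bw <- 1 / n_bins
  structure(list(breaks = breaks, counts = counts,
                 density = counts / (length(p_values) * bw),
                 p_values = p_values, n_quadrats = length(p_values),
                 M_q = as.integer(M_q), n_bins = as.integer(n_bins),
                 N_q = mean(vapply(patterns, `[[`, numeric(1), "N")) / M_q^2),
            class = "quadrat_histogram")
}

#' @export
print.quadrat_histogram <- function(x, ...) {
  extreme <- (x$counts[1] + x$counts[x$n_bins]) / x$n_quadrats
  cat(sprintf(
    "Quadrat histogram: %d x %d quadrats, %d non-empty (pooled), N_q = %.1f\n",
    x$M_q, x$M_q, x$n_quadrats, x$N_q))
  cat(sprintf("  extreme-bin fraction = %.3f\n", extreme))
  invisible(x)
}

#' @export
plot.quadrat_histogram <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, max(x$density)),
                 xlab = expression(p[R]), ylab = "density", ...)
  graphics::rect(x$breaks[-(x$n_bins + 1)], 0, x$breaks[-1], x$density,
                 col = "grey80")
  invisible(x)
}

#' Pattern-presence criterion from a quadrat histogram
#'
#' Reports a pattern when strictly more than `threshold` (default 10%) of
#' the pooled non-empty quadrats lie in either extreme bin (`p_R < 0.02` or
#' `p_R > 0.98` with the default 50 bins) - a conservative criterion, since
#' under random differentiation even one extreme quadrat is very unlikely.
#'
#' @param qh A [quadrat_histogram()] object.
#' @param threshold Extreme-bin fraction that must be exceeded.
#' @return Logical.
#' @export
pattern_criterion <- function(qh, threshold = 0.10) {
  stopifnot(inherits(qh, "quadrat_histogram"))
  (qh$counts[1] + qh$counts[qh$n_bins]) / qh$n_quadrats > threshold
}

#' Truncated-normal null density for quadrat proportions
#'
#' Under random independent differentiation the number of type-R cells in a
#' quadrat of occupancy `N_q` is Binomial(`N_q`, 1/2), so `p_R` is
#' approximately normal with mean 1/2 and variance `1/(4 N_q)`; truncating
#' to `[0, 1]` and renormalising gives the null density plotted against
#' quadrat histograms.
#'
#' @param p Proportion value(s) in `[0, 1]`.
#' @param N_q Expected quadrat occupancy, positive.
#' @return Density value(s).
#' @export
binomial_null_density <- function(p, N_q) {
  stopifnot(N_q > 0)
  sdv <- sqrt(1 / (4 * N_q))
  dnorm(p, 0.5, sdv) / (pnorm(1, 0.5, sdv) - pnorm(0, 0.5, sdv))
}

#' Write a PCF table
#'
#' CSV with header `r_center,g,g_S,g_RR,g_GG` (missing components are
#' written as empty fields).
#'
#' @param file Output path.
#' @param g,g_S Required `pcf_estimate` objects.
#' @param g_RR,g_GG Optional within-type estimates.
#' @export
write_pcf_table <- function(file, g, g_S, g_RR = NULL, g_GG = NULL) {
  df <- data.frame(r_center = g$centers, g = g$values, g_S = g_S$values,
                   g_RR = if (is.null(g_RR)) NA else g_RR$values,
                   g_GG = if (is.null(g_GG)) NA else g_GG$values)
  write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Write a quadrat-histogram table
#'
#' CSV with header `bin_low,bin_high,density,count`.
#'
#' @param qh A [quadrat_histogram()] object.
#' @param file Output path.
#' @export
write_qh_table <- function(qh, file) {
  df <- data.frame(bin_low = qh$breaks[-(qh$n_bins + 1)],
                   bin_high = qh$breaks[-1],
                   density = qh$density, count = qh$counts)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Summary statistics of one analysed pattern
#'
#' Combines the pattern-scale estimate and the quadrat criterion into the
#' summary reported by the command-line tools:
#' `r_p`, `max_gS_minus_g` and `pattern_present`.
#'
#' @param pattern A [mark_pattern()] object.
#' @param M_g Number of PCF distance intervals.
#' @param M_q Quadrats per side.
#' @param threshold Pattern-scale excursion threshold.
#' @return Named list suitable for JSON serialisation.
#' @export
pattern_summary <- function(pattern, M_g = 60, M_q = 12, threshold = 0.02) {
  ps <- pcf_summary(pattern, M_g)
  sc <- pattern_scale(ps$g, ps$g_S, threshold)
  qh <- quadrat_histogram(pattern, M_q)
  list(r_p = sc$r_p, max_gS_minus_g = sc$max_diff,
       pattern_present = pattern_criterion(qh),
       fixated = ps$fixated)
}
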