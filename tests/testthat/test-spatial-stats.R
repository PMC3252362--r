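test_that("marked pattern construction validates and summarises", {
  p <- mark_pattern(c(1, 2, 3), c(1, 2, 3), c("R", "G", "R"), 10)
  expect_equal(p$N, 3); expect_equal(p$N_R, 2); expect_equal(p$N_G, 1)
  expect_equal(p$rho, 0.03)
  expect_error(mark_pattern(1, 11, "R", 10))       # outside the domain
  expect_error(mark_pattern(1, 1, "B", 10))        # bad mark
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_pattern(p, f)
  q <- read_pattern(f, 10)
  expect_equal(q$x, p$x); expect_equal(q$type, p$type)
})

test_that("binned PCF estimators equal all-pairs double-loop counting", {
  set.seed(61)
  pat <- fixture_pattern(150, 40, p = 0.4, seed = 61)
  # ordered-pair counts agree bit-for-bit with the double loop
  counts <- stempatterns:::pair_count_bins_cpp(pat$x, pat$y, pat$x, pat$y,
                                               40, 20, TRUE)
  expect_identical(counts, oracle_pair_counts(pat$x, pat$y, 40, 20))
  g <- pcf(pat, 20)
  expect_equal(g$values, oracle_pcf(pat$x, pat$y, 40, 20), tolerance = 1e-14)
  for (ty in list(c("R", "R"), c("G", "G"), c("R", "G"))) {
    got <- cross_pcf(pat, ty[1], ty[2], 20)
    want <- oracle_cross_pcf(pat$x, pat$y, pat$type, ty[1], ty[2], 40, 20)
    expect_equal(got$values, want, tolerance = 1e-14)
  }
})

test_that("a two-point pattern reproduces the direct formula", {
  p <- mark_pattern(c(0, 5), c(0, 0), c("R", "R"), 120)
  g <- pcf(p, 60)
  # separation 5 lies in (4, 6]: value = L^2 * 2 / (N^2 pi (36 - 16))
  expect_equal(g$values[3], 120^2 * 2 / (4 * pi * 20))
  expect_equal(g$values[3], 114.59, tolerance = 1e-4)
  expect_equal(sum(g$values != 0), 1)
  expect_error(pcf(mark_pattern(1, 1, "R", 120), 60))     # N < 2
})

test_that("a large Poisson pattern has g close to 1", {
  set.seed(62)
  pat <- fixture_pattern(10000, 120, seed = 62)
  g <- pcf(pat, 60)
  keep <- g$centers > 2 & g$centers <= 60
  expect_lt(max(abs(g$values[keep] - 1)), 0.05)
})

test_that("cross-PCF restrictions behave in degenerate and null cases", {
  set.seed(63)
  allR <- mark_pattern(runif(300, 0, 40), runif(300, 0, 40),
                       rep("R", 300), 40)
  expect_equal(cross_pcf(allR, "R", "R", 20)$values, pcf(allR, 20)$values)
  expect_error(cross_pcf(allR, "G", "G", 20), "type G")
  # independent fair-coin marks: g_S tracks g
  pat <- fixture_pattern(3000, 60, seed = 64)
  ps <- pcf_summary(pat, 30)
  keep <- ps$g$centers <= 30
  expect_lt(max(abs(ps$g_S$values[keep] - ps$g$values[keep])), 0.1)
})

test_that("the same-type PCF is the squared-density weighted average", {
  gRR <- stempatterns:::new_pcf_estimate(rep(1, 10), 10, 20, "g_RR")
  gGG <- stempatterns:::new_pcf_estimate(rep(0, 10), 10, 20, "g_GG")
  expect_equal(same_type_pcf(gRR, gGG, 1, 1)$values, rep(0.5, 10))
  expect_equal(same_type_pcf(gRR, gGG, 1, 0)$values, rep(1, 10))
  expect_equal(same_type_pcf(gRR, gGG, 2, 1)$values, rep(0.8, 10))
  # identity on random inputs
  set.seed(65)
  a <- stempatterns:::new_pcf_estimate(runif(10), 10, 20, "g_RR")
  b <- stempatterns:::new_pcf_estimate(runif(10), 10, 20, "g_GG")
  gs <- same_type_pcf(a, b, 0.3, 0.7)
  expect_equal(gs$values * (0.3^2 + 0.7^2),
               0.3^2 * a$values + 0.7^2 * b$values)
  bad <- stempatterns:::new_pcf_estimate(runif(5), 5, 20, "g_GG")
  expect_error(same_type_pcf(a, bad, 1, 1), "geometry")
})

test_that("mean PCFs average bin-wise and reduce variance", {
  a <- stempatterns:::new_pcf_estimate(rep(0, 8), 8, 16, "g")
  b <- stempatterns:::new_pcf_estimate(rep(2, 8), 8, 16, "g")
  expect_equal(mean_pcf(list(a, b))$values, rep(1, 8))
  expect_equal(mean_pcf(list(a, a, a))$values, a$values)
  set.seed(66)
  gs <- lapply(1:40, function(i) pcf(fixture_pattern(300, 30, seed = i), 15))
  vals <- vapply(gs, `[[`, numeric(15), "values")
  vm <- apply(vals, 1, var)               # single-estimate bin variance
  gm <- mean_pcf(gs)
  # the mean's deviation from its expectation (N - 1)/N is far below a
  # single estimate's sd; bins wholly inside r <= L/2 (the last bin
  # straddles the torus cut-off and is biased by construction)
  keep <- gm$breaks[-1] <= 15
  expect_lt(mean(abs(gm$values[keep] - 299 / 300)),
            mean(sqrt(vm[keep])) / 2)
})

test_that("the pattern scale is the interpolated crossing right of the peak", {
  mk <- function(v) stempatterns:::new_pcf_estimate(v, 60, 120, "x")
  g <- mk(rep(1, 60))
  # g_S == g: no pattern
  expect_false(pattern_scale(g, g)$found)
  expect_equal(pattern_scale(g, g)$reason, "below_threshold")
  # constructed step: +0.5 below r = 20, -0.1 beyond
  centers <- g$centers
  gS <- mk(1 + ifelse(centers < 20, 0.5, -0.1))
  res <- pattern_scale(g, gS)
  # brute-force interpolation oracle between the bracketing bin centres
  i <- max(which(centers < 20)); d1 <- 0.5; d2 <- -0.1
  want <- centers[i] + (centers[i + 1] - centers[i]) * d1 / (d1 - d2)
  expect_equal(res$r_p, want)
  expect_lt(abs(res$r_p - 20), 2 * 2)     # within one bin width of the step
  # positive difference that never crosses: flagged, not invented
  gS2 <- mk(1 + 0.5 * exp(-centers / 50))
  expect_equal(pattern_scale(g, gS2)$reason, "no_intersection")
  # bins beyond L/2 are ignored in the search
  gS3 <- mk(1 + ifelse(centers < 20, 0.5, ifelse(centers > 80, -5, -0.1)))
  expect_equal(pattern_scale(g, gS3)$r_p, want)
})

test_that("quadrat histograms pool non-empty quadrats with half-open bins", {
  # all cells R: everything in the last bin
  set.seed(67)
  pat <- mark_pattern(runif(400, 0, 12), runif(400, 0, 12),
                      rep("R", 400), 12)
  qh <- quadrat_histogram(pat, 3)
  expect_equal(qh$counts[50], qh$n_quadrats)
  expect_true(pattern_criterion(qh))
  # a single occupied quadrat with 3 R of 4 cells: p = 0.75 in bin 38,
  # which covers [0.74, 0.76)
  pat2 <- mark_pattern(c(1, 1.2, 1.4, 1.6), rep(1, 4),
                       c("R", "R", "R", "G"), 12)
  qh2 <- quadrat_histogram(pat2, 3)
  expect_equal(qh2$n_quadrats, 1)
  expect_equal(qh2$p_values, 0.75)
  expect_equal(which(qh2$counts == 1), 38)
  expect_equal(qh2$breaks[38], 0.74)
  # density normalised to unit area
  expect_equal(sum(qh2$density) * (1 / 50), 1)
})

test_that("fair-coin marks match the binomial null", {
  set.seed(68)
  pats <- lapply(1:4, function(i) fixture_pattern(3456, 120, seed = 200 + i))
  qh <- quadrat_histogram(pats, 12)
  expect_equal(qh$N_q, 24)
  expect_equal(mean(qh$p_values), 0.5, tolerance = 0.02)
  expect_equal(sd(qh$p_values), sqrt(1 / (4 * 24)), tolerance = 0.15)
  expect_false(pattern_criterion(qh))
})

test_that("the pattern criterion uses a strict 10% threshold", {
  mk_qh <- function(p_values) {
    pat <- mark_pattern(0.5, 0.5, "R", 10)    # placeholder geometry
    qh <- quadrat_histogram(pat, 1)
    qh$p_values <- p_values
    qh$n_quadrats <- length(p_values)
    bin <- pmin(floor(p_values * 50), 49) + 1
    qh$counts <- tabulate(bin, nbins = 50)
    qh$density <- qh$counts / (length(p_values) * 0.02)
    qh
  }
  expect_true(pattern_criterion(mk_qh(rep(c(0, 1), 50))))
  # uniform proportions: extreme fraction 2/50 = 0.04
  expect_false(pattern_criterion(mk_qh(seq(0.01, 0.99, length.out = 100))))
  # exactly 10% extreme fails the strict inequality
  expect_false(pattern_criterion(mk_qh(c(rep(0, 10), rep(0.5, 90)))))
  expect_true(pattern_criterion(mk_qh(c(rep(0, 11), rep(0.5, 89)))))
})

test_that("the truncated-normal null density is symmetric and normalised", {
  x <- seq(0, 1, length.out = 401)
  d <- binomial_null_density(x, 24.3)
  expect_equal(d, rev(d))                       # symmetry about 1/2
  expect_equal(sum(d) * (x[2] - x[1]), 1, tolerance = 1e-3)
  expect_equal(sqrt(1 / (4 * 24.3)), 0.1014, tolerance = 1e-3)
})

test_that("statistics are invariant under swapping the two mark labels", {
  set.seed(69)
  pat <- fixture_pattern(800, 40, p = 0.35, seed = 69)
  swapped <- mark_pattern(pat$x, pat$y,
                          ifelse(pat$type == "R", "G", "R"), 40)
  a <- pcf_summary(pat, 20); b <- pcf_summary(swapped, 20)
  expect_equal(a$g$values, b$g$values)
  expect_equal(a$g_S$values, b$g_S$values)
  qa <- quadrat_histogram(pat, 4); qb <- quadrat_histogram(swapped, 4)
  # the pooled proportions mirror about 1/2 (bin counts only mirror up to
  # values falling exactly on bin edges, so compare the raw proportions)
  expect_equal(sort(qa$p_values), sort(1 - qb$p_values))
  expect_equal(pattern_criterion(qa), pattern_criterion(qb))
})
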