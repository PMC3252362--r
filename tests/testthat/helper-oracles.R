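# Independent brute-force oracles, written against the definitions rather
# than the package internals.

# torus distance, scalar
oracle_torus_dist <- function(p, q, L) {
  dx <- (p[1] - q[1]) %% L; if (dx > L / 2) dx <- dx - L
  dy <- (p[2] - q[2]) %% L; if (dy > L / 2) dy <- dy - L
  sqrt(dx^2 + dy^2)
}

# ordered-pair bin counts by double loop
oracle_pair_counts <- function(x, y, L, M_g) {
  N <- length(x)
  w <- L / M_g
  counts <- numeric(M_g)
  for (m in seq_len(N)) for (n in seq_len(N)) {
    if (m == n) next
    d <- oracle_torus_dist(c(x[m], y[m]), c(x[n], y[n]), L)
    if (d <= 0) next
    k <- ceiling(d / w)
    if (k >= 1 && k <= M_g) counts[k] <- counts[k] + 1
  }
  counts
}

# all-pairs double-loop PCF estimator (ordered pairs, N^2 normalisation)
oracle_pcf <- function(x, y, L, M_g) {
  N <- length(x)
  w <- L / M_g
  counts <- numeric(M_g)
  for (m in seq_len(N)) for (n in seq_len(N)) {
    if (m == n) next
    d <- oracle_torus_dist(c(x[m], y[m]), c(x[n], y[n]), L)
    if (d <= 0) next
    k <- ceiling(d / w)
    if (k >= 1 && k <= M_g) counts[k] <- counts[k] + 1
  }
  edges <- (0:M_g) * w
  L^2 * counts / (N^2 * pi * diff(edges^2))
}

# all-pairs cross-PCF: ordered pairs (m of type X, n of type Y)
oracle_cross_pcf <- function(x, y, type, X, Y, L, M_g) {
  ix <- which(type == X); iy <- which(type == Y)
  w <- L / M_g
  counts <- numeric(M_g)
  for (m in ix) for (n in iy) {
    if (m == n) next
    d <- oracle_torus_dist(c(x[m], y[m]), c(x[n], y[n]), L)
    if (d <= 0) next
    k <- ceiling(d / w)
    if (k >= 1 && k <= M_g) counts[k] <- counts[k] + 1
  }
  edges <- (0:M_g) * w
  L^2 * counts / (length(ix) * length(iy) * pi * diff(edges^2))
}

# dense linear-algebra oracle for one Douglas ADI step on an M x M periodic
# grid (x index fastest), via explicit matrices and solve()
oracle_adi_step <- function(u, src, D, lambda, dt, h) {
  M <- nrow(u)
  lap1 <- matrix(0, M, M)
  for (j in 1:M) {
    lap1[j, j] <- -2
    lap1[j, if (j == 1) M else j - 1] <- 1
    lap1[j, if (j == M) 1 else j + 1] <- 1
  }
  I1 <- diag(M)
  A1 <- (D / h^2) * kronecker(I1, lap1) - (lambda / 2) * diag(M^2)  # x-direction
  A2 <- (D / h^2) * kronecker(lap1, I1) - (lambda / 2) * diag(M^2)  # y-direction
  un <- as.vector(u); f <- as.vector(src)
  rhs1 <- un + (dt / 2) * (A1 %*% un) + dt * (A2 %*% un) + dt * f
  ustar <- solve(diag(M^2) - (dt / 2) * A1, rhs1)
  rhs2 <- ustar - (dt / 2) * (A2 %*% un)
  unew <- solve(diag(M^2) - (dt / 2) * A2, rhs2)
  matrix(unew, M, M)
}

# 1-D two-body reduction of the relaxation dynamics: both cells move, so the
# separation obeys dr/dt = 2 v(r); explicit Euler
oracle_two_body_separation <- function(r0, A, rc, Rv, dt, nsteps) {
  r <- r0
  out <- numeric(nsteps)
  for (i in seq_len(nsteps)) {
    v <- if (r >= Rv) 0 else A * rc^2 * (2 * rc - r) / r^3
    r <- r + dt * 2 * v
    out[i] <- r
  }
  out
}

# expected stripe same-type PCF: for CSR positions, g_S(r) = 2 E_theta[
# P(same stripe parity at x-offset r cos(theta))], with the parity-match
# probability a triangle wave in the offset
stripe_same_parity_prob <- function(dx, w) {
  u <- abs(dx) %% (2 * w)
  1 - pmin(u, 2 * w - u) / w
}
oracle_stripe_gS_minus_g <- function(r, w, nquad = 2048) {
  theta <- (seq_len(nquad) - 0.5) * (2 * pi / nquad)
  vapply(r, function(ri) {
    ps <- mean(stripe_same_parity_prob(ri * cos(theta), w))
    2 * ps - 1
  }, numeric(1))
}

# small deterministic marked pattern laid out on a jittered lattice
fixture_pattern <- function(N, L, p = 0.5, seed = 1) {
  set.seed(seed)
  mark_pattern(runif(N, 0, L), runif(N, 0, L),
               ifelse(runif(N) < p, "R", "G"), L)
}
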