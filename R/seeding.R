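#' Parameters for the initial seeding and mechanical relaxation phase
#'
#' Freshly seeded cells are placed uniformly at random and then pushed apart
#' by short-range repulsion and pulled together by longer-range attraction
#' for a brief interval, producing aggregates with minimal overlap.  The
#' defaults are the dimensionless values used throughout: force magnitude
#' `A = 5000`, cell radius `r_c = 1`, interaction cut-off `R_v = 3 r_c` and
#' relaxation interval `t_init = 0.002` integrated with the explicit Euler
#' method.  The Euler step `dt_init = 2e-5` (100 steps) keeps displacements
#' per step well below a cell radius at moderate separations.
#'
#' @param N Number of cells (>= 1).
#' @param A Magnitude of the pairwise force term.
#' @param r_c Cell radius (the length unit; default 1).
#' @param R_v Interaction cut-off radius; must exceed `2 r_c`.
#' @param t_init Duration of the relaxation phase.
#' @param dt_init Euler step for the relaxation phase.
#' @return An object of class `seeding_params`.
#' @export
seeding_params <- function(N, A = 5000, r_c = 1, R_v = 3 * r_c,
                           t_init = 0.002, dt_init = 2e-5) {
  stopifnot(N >= 1, A > 0, r_c > 0, R_v > 2 * r_c,
            dt_init > 0, t_init >= dt_init)
  structure(list(N = as.integer(N), A = A, r_c = r_c, R_v = R_v,
                 t_init = t_init, dt_init = dt_init),
            class = "seeding_params")
}

#' Pairwise radial velocity for the relaxation phase
#'
#' The signed speed applied along the separation vector of a pair of cells a
#' distance `r` apart:
#' \deqn{v(r) = A r_c^2 (2 r_c - r) / r^3 \quad (0 < r < R_v), \qquad
#'       v(r) = 0 \quad (r \ge R_v).}
#' Positive values move the pair apart.  The form is singular-repulsive at
#' contact, vanishes at the equilibrium spacing `r = 2 r_c`, and is weakly
#' attractive (adhesive) on `(2 r_c, R_v)`.
#'
#' @param r Separation distance(s), strictly positive.
#' @param params A [seeding_params()] object.
#' @return Signed speed(s); positive means repulsion.
#' @export
pairwise_velocity <- function(r, params) {
  stopifnot(inherits(params, "seeding_params"))
  if (any(r <= 0)) stop("separation must be strictly positive (coincident cells?)")
  v <- ifelse(r >= params$R_v, 0,
              params$A * params$r_c^2 * (2 * params$r_c - r) / r^3)
  as.numeric(v)
}

#' Seed cell positions uniformly at random
#'
#' Places `N` independent uniform points on the periodic square.  Driven by
#' R's global random number generator; call `set.seed()` first for
#' reproducibility.
#'
#' @param N Number of cells (>= 1).
#' @param domain A [periodic_domain()] object.
#' @return An `N x 2` matrix of coordinates in `[0, L)`.
#' @export
seed_positions <- function(N, domain) {
  stopifnot(inherits(domain, "periodic_domain"))
  if (N < 1) stop("N must be at least 1")
  cbind(x = runif(N, 0, domain$L), y = runif(N, 0, domain$L))
}

#' Relax seeded positions under pairwise forces
#'
#' Advances the cell-centre equations of motion (sum of radial pairwise
#' velocities, [pairwise_velocity()]) with the explicit Euler method for
#' `t_init`, using minimum-image displacements on the torus.  Interactions
#' beyond `R_v` contribute nothing.  Pair search uses a spatial grid with
#' bins at least `R_v` wide (`method = "grid"`); the brute-force all-pairs
#' path is retained for validation.
#'
#' @param pos `N x 2` matrix of positions in `[0, L)`.
#' @param params A [seeding_params()] object.
#' @param domain A [periodic_domain()] object.
#' @param method `"grid"` (cell-list, O(N)) or `"brute"` (all pairs).
#' @return Relaxed positions, wrapped into `[0, L)`.
#' @export
relax_positions <- function(pos, params, domain, method = c("grid", "brute")) {
  stopifnot(inherits(params, "seeding_params"), inherits(domain, "periodic_domain"))
  method <- match.arg(method)
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 2, all(is.finite(pos)))
  nsteps <- as.integer(round(params$t_init / params$dt_init))
  out <- relax_positions_cpp(unname(pos), domain$L, params$A, params$r_c,
                             params$R_v, params$dt_init, nsteps,
                             method == "grid")
  colnames(out) <- c("x", "y")
  out
}

#' Seed and relax an initial configuration
#'
#' Convenience wrapper combining [seed_positions()] and [relax_positions()].
#'
#' @inheritParams relax_positions
#' @inheritParams seed_positions
#' @return Relaxed `N x 2` position matrix.
#' @export
initial_configuration <- function(params, domain, method = c("grid", "brute")) {
  pos <- seed_positions(params$N, domain)
  relax_positions(pos, params, domain, method)
}

#' Write a cell-position table
#'
#' CSV with header `id,x,y` (0-based ids, coordinates in cell radii).
#'
#' @param pos `N x 2` position matrix.
#' @param file Output path.
#' @export
write_positions <- function(pos, file) {
  df <- data.frame(id = seq_len(nrow(pos)) - 1L, x = pos[, 1], y = pos[, 2])
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
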