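#' Parameters of the stochastic cell-fate model
#'
#' Each cell carries a stemness variable `s` (from 1 down to 0) and a fate
#' variable `f`.  Stemness decays exponentially, `ds = -s dt`, while the fate
#' evolves by
#' \deqn{df = (B + \chi(1/2 - s) f - \nu f^3)\,dt + \sqrt{2\delta}\,dW,}
#' a supercritical pitchfork in `f` with bifurcation parameter `s`: one
#' stable state `f = 0` for `s > 1/2`, two stable branches
#' `f = \pm\sqrt{\chi(1/2 - s)/\nu}` for `s < 1/2`.  The signalling bias `B`
#' tilts the two wells.  Defaults are the dimensionless reference values:
#' `chi = 5`, `nu = 1`, `delta = 1e-4`, `dt = 4e-4`, `t_end = 4`.
#'
#' @param chi Feedback strength (bifurcation control), positive.
#' @param nu Quartic saturation coefficient (1 in dimensionless units).
#' @param delta Noise amplitude (>= 0).
#' @param dt Euler-Maruyama timestep.
#' @param t_end Duration of the differentiation phase.
#' @return An object of class `diff_params`.
#' @export
diff_params <- function(chi = 5, nu = 1, delta = 1e-4, dt = 4e-4, t_end = 4) {
  stopifnot(chi > 0, nu > 0, delta >= 0, dt > 0, t_end >= dt)
  structure(list(chi = chi, nu = nu, delta = delta, dt = dt, t_end = t_end),
            class = "diff_params")
}

#' One explicit Euler step of stemness decay
#'
#' `s' = (1 - dt) s`, the discretisation of `ds/dt = -s`.  All cells share
#' the same deterministic stemness trajectory `s(tau) = (1 - dt)^tau`.
#'
#' @param s Stemness value(s) in `[0, 1]`.
#' @param dt Timestep, `dt < 1`.
#' @return Updated stemness.
#' @export
step_stemness <- function(s, dt) {
  stopifnot(dt > 0, dt < 1, all(s >= 0), all(s <= 1))
  (1 - dt) * s
}

#' One Euler-Maruyama step of the fate equation
#'
#' `f' = f + (B + chi (1/2 - s) f - nu f^3) dt + sqrt(2 delta) dW`, with
#' `dW ~ N(0, dt)` supplied by the caller (deterministic given `dW`).
#'
#' @param f Fate value(s).
#' @param s Stemness value(s).
#' @param B Signalling bias.
#' @param params A [diff_params()] object.
#' @param dW Gaussian increment(s) with variance `dt`.
#' @return Updated fate value(s).
#' @export
step_fate <- function(f, s, B, params, dW) {
  stopifnot(inherits(params, "diff_params"))
  out <- f + (B + params$chi * (0.5 - s) * f - params$nu * f^3) * params$dt +
    sqrt(2 * params$delta) * dW
  if (any(!is.finite(out)))
    stop("non-finite fate value: the Euler-Maruyama step is unstable")
  out
}

#' Stable equilibria of the deterministic fate dynamics
#'
#' With `s` frozen and `B = delta = 0`, the drift `chi(1/2 - s) f - nu f^3`
#' has a single stable zero for `s >= 1/2` and two stable branches
#' `+/- sqrt(chi (1/2 - s) / nu)` (with 0 unstable) for `s < 1/2`.
#'
#' @param s Stemness value.
#' @param chi,nu Model coefficients, positive.
#' @return Numeric vector of stable equilibria.
#' @export
stable_fates <- function(s, chi = 5, nu = 1) {
  stopifnot(chi > 0, nu > 0, length(s) == 1L)
  if (s >= 0.5) return(0)
  b <- sqrt(chi * (0.5 - s) / nu)
  c(-b, b)
}

#' Classify terminal cell types from the fate variable
#'
#' Type `R` for `f > 0`, type `G` otherwise (cells at exactly `f = 0` are
#' counted as `G`, consistent with counting `f > 0` as `R`; the boundary has
#' probability zero under noise).
#'
#' @param f Fate value(s), finite.
#' @return Factor with levels `c("R", "G")`.
#' @export
classify_fate <- function(f) {
  stopifnot(all(is.finite(f)))
  factor(ifelse(f > 0, "R", "G"), levels = c("R", "G"))
}

snapshot_steps_from_times <- function(snapshot_times, dt, nsteps) {
  if (is.null(snapshot_times)) return(integer(0))
  st <- sort(unique(as.integer(round(snapshot_times / dt))))
  st[st >= 1 & st <= nsteps]
}

#' Simulate the differentiation phase
#'
#' Runs `ceiling(t_end / dt)` synchronous Euler-Maruyama steps for all cells
#' from the undifferentiated state (`s = 1`, `f = 0`).  Within each step the
#' signalling model is advanced/evaluated from the start-of-step cell states,
#' then every fate variable is updated with an independent `N(0, dt)`
#' increment, then stemness decays; all cell updates use start-of-step
#' values (Jacobi ordering), which preserves the model's `f -> -f` symmetry
#' and makes runs reproducible.
#'
#' @param positions `N x 2` matrix of (static) cell centres in `[0, L)`.
#' @param domain A [periodic_domain()] object.
#' @param params A [diff_params()] object.
#' @param signalling A signalling model: [diffusive_signalling()],
#'   [juxtacrine_signalling()] or [no_signalling()].
#' @param snapshot_times Optional times at which to record `(s, f)`
#'   snapshots.
#' @param noise Optional `nsteps x N` matrix of standard-normal draws
#'   (scaled by `sqrt(dt)` internally); mainly for testing.  When `NULL`,
#'   increments come from R's global RNG.
#' @param engine `"cpp"` (fast path) or `"r"` (pure-R reference
#'   implementation used for validation).
#' @return An object of class `cell_sim` with elements `positions`, `s`,
#'   `f`, `type`, `bias`, `pattern` (a [mark_pattern()]), `snapshots`, and
#'   for the diffusive mechanism the final morphogen fields `a`, `b` and the
#'   minimum field value seen (`min_field`).
#' @export
simulate_differentiation <- function(positions, domain, params, signalling,
                                     snapshot_times = NULL, noise = NULL,
                                     engine = c("cpp", "r")) {
  stopifnot(inherits(domain, "periodic_domain"), inherits(params, "diff_params"),
            inherits(signalling, "signalling_model"))
  engine <- match.arg(engine)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, all(is.finite(positions)),
            all(positions >= 0), all(positions < domain$L))
  nsteps <- as.integer(ceiling(params$t_end / params$dt))
  snap <- snapshot_steps_from_times(snapshot_times, params$dt, nsteps)
  if (!is.null(noise)) {
    noise <- as.matrix(noise)
    stopifnot(nrow(noise) == nsteps, ncol(noise) == nrow(positions))
  }
  raw <- if (engine == "cpp") {
    run_signalling(signalling, positions, domain, params, nsteps, snap, noise)
  } else {
    simulate_reference(signalling, positions, domain, params, nsteps, snap, noise)
  }
  res <- structure(list(
    positions = positions, domain = domain, params = params,
    signalling = signalling, nsteps = nsteps,
    s = raw$s, f = raw$f, bias = raw$bias,
    type = classify_fate(raw$f),
    snapshots = raw$snapshots,
    a = raw$a, b = raw$b, min_field = raw$min_field
  ), class = "cell_sim")
  res$pattern <- mark_pattern(positions[, 1], positions[, 2], res$type, domain$L)
  res
}

#' @export
print.cell_sim <- function(x, ...) {
  cat(sprintf("Differentiation simulation: %d cells on [0, %g)^2, %d steps (t_end = %g)\n",
              nrow(x$positions), x$domain$L, x$nsteps, x$params$t_end))
  cat(sprintf("  mechanism: %s\n", class(x$signalling)[1]))
  tab <- table(x$type)
  cat(sprintf("  terminal types: R = %d, G = %d\n", tab[["R"]], tab[["G"]]))
  invisible(x)
}

#' @export
summary.cell_sim <- function(object, ...) {
  out <- list(
    n = nrow(object$positions),
    type_counts = table(object$type),
    s_final = object$s[1],
    f_range = range(object$f),
    mean_abs_f = mean(abs(object$f))
  )
  class(out) <- "summary.cell_sim"
  out
}

#' @export
print.summary.cell_sim <- function(x, ...) {
  cat(sprintf("%d cells; final stemness %.4g\n", x$n, x$s_final))
  cat(sprintf("types: R = %d, G = %d\n", x$type_counts[["R"]], x$type_counts[["G"]]))
  cat(sprintf("fate range [%.3f, %.3f], mean |f| = %.3f\n",
              x$f_range[1], x$f_range[2], x$mean_abs_f))
  invisible(x)
}

#' Write the final simulation state
#'
#' CSV with header `id,x,y,s,f,type` (0-based ids).
#'
#' @param sim A `cell_sim` object.
#' @param file Output path.
#' @export
write_final_state <- function(sim, file) {
  stopifnot(inherits(sim, "cell_sim"))
  df <- data.frame(id = seq_along(sim$f) - 1L,
                   x = sim$positions[, 1], y = sim$positions[, 2],
                   s = sim$s, f = sim$f, type = as.character(sim$type))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Pure-R reference implementation of the simulation loop, kept deliberately
# close to the per-operation functions so the fast path can be validated
# against it on small problems.
simulate_reference <- function(signalling, positions, domain, params,
                               nsteps, snap, noise) {
  N <- nrow(positions)
  s <- rep(1, N); f <- rep(0, N); B <- rep(0, N)
  state <- signalling_init(signalling, positions, domain, params)
  snapshots <- vector("list", length(snap))
  for (step in seq_len(nsteps)) {
    dW <- if (is.null(noise)) rnorm(N) else noise[step, ]
    upd <- signalling_bias(signalling, state, s, f, params)
    B <- upd$bias; state <- upd$state
    f <- step_fate(f, s, B, params, sqrt(params$dt) * dW)
    s <- step_stemness(s, params$dt)
    hit <- match(step, snap)
    if (!is.na(hit))
      snapshots[[hit]] <- list(step = step, t = step * params$dt, s = s, f = f)
  }
  list(s = s, f = f, bias = B, snapshots = snapshots,
       a = state$a, b = state$b, min_field = state$min_field)
}
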