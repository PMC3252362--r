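#' Parameters for juxtacrine (contact) signalling
#'
#' Cells signal to neighbours whose centres are strictly closer than
#' `R_juxt`; the contribution of a neighbour is weighted by `2 r_c / d`,
#' a proxy for contact area, and by its ligand signal `beta (1 - s)` of the
#' sign of its fate.  Defaults: `S_juxt = 1e-3`, `R_juxt = 3 r_c`,
#' `beta = 1`, `r_c = 1` (dimensionless reference values).
#'
#' @param S_juxt Sensitivity to contact signalling.
#' @param R_juxt Contact radius; must exceed `2 r_c`.
#' @param beta Ligand scale (typical number of cell-surface ligands).
#' @param r_c Cell radius.
#' @return An object of class `juxtacrine_params`.
#' @export
juxtacrine_params <- function(S_juxt = 1e-3, R_juxt = 3, beta = 1, r_c = 1) {
  stopifnot(S_juxt >= 0, beta > 0, r_c > 0, R_juxt > 2 * r_c)
  structure(list(S_juxt = S_juxt, R_juxt = R_juxt, beta = beta, r_c = r_c),
            class = "juxtacrine_params")
}

#' Juxtacrine signalling model
#'
#' @param params A [juxtacrine_params()] object.
#' @return A signalling model usable with [simulate_differentiation()].
#' @export
juxtacrine_signalling <- function(params = juxtacrine_params()) {
  stopifnot(inherits(params, "juxtacrine_params"))
  structure(list(params = params),
            class = c("juxtacrine_signalling", "signalling_model"))
}

#' Build the static neighbour list
#'
#' All unordered pairs of cells with minimum-image distance strictly below
#' `R_juxt`.  Cells are static during differentiation, so the list is built
#' once per simulation.  The grid-accelerated search returns exactly the
#' same pair set as the brute-force all-pairs search.
#'
#' @param pos `N x 2` matrix of positions in `[0, L)`.
#' @param R_juxt Contact radius.
#' @param domain A [periodic_domain()] object.
#' @param method `"grid"` or `"brute"`.
#' @return An object of class `neighbour_list`: a list with integer vectors
#'   `i`, `j` (1-based, `i < j`) and distances `d`.
#' @export
build_neighbour_list <- function(pos, R_juxt, domain,
                                 method = c("grid", "brute")) {
  stopifnot(inherits(domain, "periodic_domain"))
  method <- match.arg(method)
  pos <- as.matrix(pos)
  out <- neighbour_pairs_cpp(unname(pos), domain$L, R_juxt, method == "grid")
  ord <- order(out$i, out$j)
  structure(list(i = out$i[ord], j = out$j[ord], d = out$d[ord],
                 n = nrow(pos), R_juxt = R_juxt),
            class = "neighbour_list")
}

#' @export
print.neighbour_list <- function(x, ...) {
  cat(sprintf("Neighbour list: %d cells, %d pairs within %g\n",
              x$n, length(x$i), x$R_juxt))
  invisible(x)
}

#' Ligand signal strengths of a cell
#'
#' `beta_a = beta (1 - s)` for type-R cells (`f > 0`), `beta_b = beta (1 -
#' s)` for type-G cells (`f < 0`), both zero for uncommitted cells.
#'
#' @param s Stemness in `[0, 1]`.
#' @param f Fate value(s).
#' @param beta Ligand scale.
#' @return A list with vectors `beta_a` and `beta_b`.
#' @export
signal_strengths <- function(s, f, beta = 1) {
  stopifnot(all(s >= 0), all(s <= 1))
  base <- beta * (1 - s)
  list(beta_a = ifelse(f > 0, base, 0), beta_b = ifelse(f < 0, base, 0))
}

#' Juxtacrine bias for every cell
#'
#' \deqn{B_n = S^{juxt} \sum_{m} \frac{2 r_c}{|x_m - x_n|}
#'       (\beta_a(s_m, f_m) - \beta_b(s_m, f_m)),}
#' summed over neighbours within the contact radius.  Antisymmetric under a
#' global fate flip `f -> -f`.
#'
#' @param s,f Per-cell stemness and fate vectors.
#' @param nbrs A [build_neighbour_list()] object.
#' @param params A [juxtacrine_params()] object.
#' @return Per-cell bias vector.
#' @export
juxtacrine_bias <- function(s, f, nbrs, params) {
  stopifnot(inherits(nbrs, "neighbour_list"), inherits(params, "juxtacrine_params"),
            length(s) == nbrs$n, length(f) == nbrs$n)
  sig <- with(signal_strengths(s, f, params$beta), beta_a - beta_b)
  w <- params$S_juxt * 2 * params$r_c / nbrs$d
  B <- rep(0, nbrs$n)
  contrib_i <- w * sig[nbrs$j]
  contrib_j <- w * sig[nbrs$i]
  for (p in seq_along(nbrs$i)) {
    B[nbrs$i[p]] <- B[nbrs$i[p]] + contrib_i[p]
    B[nbrs$j[p]] <- B[nbrs$j[p]] + contrib_j[p]
  }
  B
}

#' Order-of-magnitude bound on the juxtacrine bias
#'
#' A fully differentiated neighbour at the typical spacing `2 r_c`
#' contributes `S_juxt`; with at most six close-packed neighbours the bias
#' magnitude is bounded by about `6 S_juxt`.
#'
#' @param S_juxt Sensitivity.
#' @return The estimated maximum bias magnitude.
#' @export
estimate_max_juxtacrine_bias <- function(S_juxt) {
  6 * S_juxt
}

#' @export
run_signalling.juxtacrine_signalling <- function(signalling, positions, domain,
                                                 params, nsteps, snap, noise) {
  p <- signalling$params
  nbrs <- build_neighbour_list(positions, p$R_juxt, domain)
  simulate_juxtacrine_cpp(nrow(positions), nbrs$i, nbrs$j, nbrs$d,
                          p$S_juxt, p$r_c, p$beta,
                          params$chi, params$nu, params$delta, params$dt,
                          nsteps, snap, noise)
}

#' @export
signalling_init.juxtacrine_signalling <- function(signalling, positions,
                                                  domain, params) {
  list(nbrs = build_neighbour_list(positions, signalling$params$R_juxt, domain))
}

#' @export
signalling_bias.juxtacrine_signalling <- function(signalling, state, s, f,
                                                  params) {
  list(bias = juxtacrine_bias(s, f, state$nbrs, signalling$params),
       state = state)
}
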