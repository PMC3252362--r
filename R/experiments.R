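#' Simulation configuration with reference defaults
#'
#' Bundles every dimensionless parameter of the model with the reference
#' defaults used throughout: domain `L = 120`, `N_init = 3500` cells,
#' `t_end = 4`, `chi = 5`, `delta = 1e-4`, `dt = 4e-4`, diffusive
#' `S_diff = 10`, `D = 1000`, `lambda = 10` on an `M_s = 120` grid,
#' juxtacrine `S_juxt = 1e-3` with `R_juxt = 3`, and statistics settings
#' `M_q = 12`, `M_g = 60`, `M_sim = 100`.  The `"reduced"` profile
#' (`N = 1000`, `L = 64`, `M_s = 64`, `M_sim = 10`) runs the identical model
#' at a smaller problem size for quick surveys.
#'
#' @param mechanism Signalling mechanism: `"diffusive"`, `"juxtacrine"` or
#'   `"none"`.
#' @param master_seed Master seed; per-realisation seeds derive from it via
#'   [realisation_seed()].
#' @param profile `"full"` or `"reduced"`.
#' @param ... Named overrides of any configuration field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mechanism = c("diffusive", "juxtacrine", "none"),
                       master_seed = 1, profile = c("full", "reduced"), ...) {
  mechanism <- match.arg(mechanism)
  profile <- match.arg(profile)
  cfg <- list(
    mechanism = mechanism, master_seed = as.integer(master_seed),
    L = 120, N_init = 3500, r_c = 1, t_end = 4,
    chi = 5, nu = 1, delta = 1e-4, dt = 4e-4,
    A = 5000, t_init = 0.002, dt_init = 2e-5,
    S_diff = 10, lambda = 10, D = 1000, M_s = 120,
    S_juxt = 1e-3, R_juxt = 3, beta = 1,
    M_q = 12, M_sim = 100, M_g = 60
  )
  if (profile == "reduced") {
    cfg$L <- 64; cfg$N_init <- 1000; cfg$M_s <- 64; cfg$M_sim <- 10
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, dots)
  stopifnot(cfg$L > 0, cfg$N_init >= 1, cfg$t_end > 0, cfg$dt > 0,
            cfg$M_s >= 3, cfg$M_q >= 1, cfg$M_g >= 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %s signalling, L = %g, N = %d, t_end = %g, dt = %g\n",
              x$mechanism, x$L, x$N_init, x$t_end, x$dt))
  if (x$mechanism == "diffusive")
    cat(sprintf("  S_diff = %g, D = %g, lambda = %g, M_s = %d\n",
                x$S_diff, x$D, x$lambda, x$M_s))
  if (x$mechanism == "juxtacrine")
    cat(sprintf("  S_juxt = %g, R_juxt = %g\n", x$S_juxt, x$R_juxt))
  cat(sprintf("  master seed %d, M_sim = %d\n", x$master_seed, x$M_sim))
  invisible(x)
}

#' Read a configuration file
#'
#' YAML file whose keys mirror the [run_config()] field names.
#'
#' @param file Path to a YAML config file.
#' @return A `run_config` object.
#' @export
read_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(file)
  mech <- if (is.null(vals$mechanism)) "diffusive" else vals$mechanism
  seed <- if (is.null(vals$master_seed)) 1L else vals$master_seed
  prof <- if (is.null(vals$profile)) "full" else vals$profile
  vals$mechanism <- NULL; vals$master_seed <- NULL; vals$profile <- NULL
  do.call(run_config, c(list(mechanism = mech, master_seed = seed,
                             profile = prof), vals))
}

#' Dimensional model parameters
#'
#' Physical parameters with units: rates in 1/s, lengths in cm, diffusion in
#' cm^2/s.  Defaults correspond to the reference estimates: differentiation
#' rate `kappa` of one per day, cell radius 10 micrometres, morphogen
#' diffusivity 1e-8 cm^2/s.
#'
#' @param kappa Differentiation (stemness decay) rate, 1/s.
#' @param r_c Cell radius, cm.
#' @param D Morphogen diffusion coefficient, cm^2/s.
#' @param lambda Morphogen decay rate, 1/s.
#' @param chi Fate feedback strength, 1/s.
#' @param delta Fate noise amplitude (units of f^2/s).
#' @param nu Quartic coefficient (1/(f^2 s)).
#' @param alpha Morphogen production scale.
#' @param beta Ligand number scale.
#' @param S_diff,S_juxt Dimensional sensitivities.
#' @param L Domain side, cm.
#' @param t_end Duration, s.
#' @return An object of class `dimensional_params`.
#' @export
dimensional_params <- function(kappa = 1 / 86400, r_c = 10e-4, D = 1e-8,
                               lambda = 2.5e-4, chi = 5 / 86400,
                               delta = NULL, nu = 1, alpha = 1, beta = 1,
                               S_diff = NULL, S_juxt = NULL, L = NULL,
                               t_end = NULL) {
  stopifnot(kappa > 0, r_c > 0)
  structure(list(kappa = kappa, r_c = r_c, D = D, lambda = lambda, chi = chi,
                 delta = delta, nu = nu, alpha = alpha, beta = beta,
                 S_diff = S_diff, S_juxt = S_juxt, L = L, t_end = t_end),
            class = "dimensional_params")
}

#' Nondimensionalise physical parameters
#'
#' Rescales time on `1/kappa`, distances on `r_c` and the fate variable on
#' `sqrt(kappa/nu)`, giving the dimensionless groups used by the simulator:
#' `chi_hat = chi/kappa`, `delta_hat = delta nu / kappa^2`,
#' `D_hat = D/(kappa r_c^2)`, `lambda_hat = lambda/kappa`,
#' `S_diff_hat = S_diff alpha sqrt(nu) / (kappa^{5/2} r_c^2)`,
#' `S_juxt_hat = S_juxt beta sqrt(nu) / kappa^{3/2}`, `L_hat = L/r_c`,
#' `t_end_hat = kappa t_end`.  With `kappa = r_c = alpha = beta = nu = 1`
#' the map is the identity.
#'
#' @param p A [dimensional_params()] object.
#' @return Named list of dimensionless parameters (only those whose inputs
#'   were supplied).
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  if (p$kappa <= 0 || p$r_c <= 0) stop("kappa and r_c must be positive")
  out <- list()
  if (!is.null(p$chi)) out$chi <- p$chi / p$kappa
  if (!is.null(p$delta)) out$delta <- p$delta * p$nu / p$kappa^2
  if (!is.null(p$D)) out$D <- p$D / (p$kappa * p$r_c^2)
  if (!is.null(p$lambda)) out$lambda <- p$lambda / p$kappa
  if (!is.null(p$S_diff))
    out$S_diff <- p$S_diff * p$alpha * sqrt(p$nu) / (p$kappa^2.5 * p$r_c^2)
  if (!is.null(p$S_juxt))
    out$S_juxt <- p$S_juxt * p$beta * sqrt(p$nu) / p$kappa^1.5
  if (!is.null(p$L)) out$L <- p$L / p$r_c
  if (!is.null(p$t_end)) out$t_end <- p$kappa * p$t_end
  out
}

#' Deterministic per-realisation seed
#'
#' Realisation `index` of a run with master seed `m` uses the seed
#' `(m + 1000003 * index) mod 2147483647`, so any subset of a sweep can be
#' reproduced independently.
#'
#' @param master Master seed (integer).
#' @param index Realisation index (>= 1).
#' @return Integer seed below 2^31.
#' @export
realisation_seed <- function(master, index) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(index)) %% 2147483647)
}

config_signalling <- function(config) {
  switch(config$mechanism,
    diffusive = diffusive_signalling(diffusive_params(
      D_a = config$D, D_b = config$D, lambda_a = config$lambda,
      lambda_b = config$lambda, S_diff = config$S_diff, M_s = config$M_s)),
    juxtacrine = juxtacrine_signalling(juxtacrine_params(
      S_juxt = config$S_juxt, R_juxt = config$R_juxt, beta = config$beta,
      r_c = config$r_c)),
    none = no_signalling())
}

#' Run one simulation realisation
#'
#' Seeds the RNG deterministically from `(master_seed, index)`, generates
#' and relaxes the initial configuration, runs the differentiation phase
#' with the configured mechanism, and computes the pattern statistics.
#'
#' @param config A [run_config()] object.
#' @param index Realisation index (>= 1).
#' @param keep_sim Keep the full `cell_sim` object in the result.
#' @return An object of class `realisation`: the marked `pattern`, PCF
#'   estimates `g` and `g_S`, the pattern-scale result `scale`, flags and
#'   the seed used.
#' @export
run_realisation <- function(config, index = 1, keep_sim = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- realisation_seed(config$master_seed, index)
  set.seed(seed)
  dom <- periodic_domain(config$L)
  sp <- seeding_params(config$N_init, A = config$A, r_c = config$r_c,
                       t_init = config$t_init, dt_init = config$dt_init)
  pos <- initial_configuration(sp, dom)
  dp <- diff_params(chi = config$chi, nu = config$nu, delta = config$delta,
                    dt = config$dt, t_end = config$t_end)
  sim <- simulate_differentiation(pos, dom, dp, config_signalling(config))
  ps <- pcf_summary(sim$pattern, config$M_g)
  sc <- pattern_scale(ps$g, ps$g_S)
  structure(list(index = index, seed = seed, pattern = sim$pattern,
                 g = ps$g, g_S = ps$g_S, fixated = ps$fixated,
                 scale = sc, sim = if (keep_sim) sim else NULL),
            class = "realisation")
}

#' @export
print.realisation <- function(x, ...) {
  cat(sprintf("Realisation %d (seed %d): N_R = %d, N_G = %d\n",
              x$index, x$seed, x$pattern$N_R, x$pattern$N_G))
  cat(sprintf("  max(g_S - g) = %.4f, r_p = %s\n", x$scale$max_diff,
              if (x$scale$found) sprintf("%.2f", x$scale$r_p) else "absent"))
  invisible(x)
}

summarise_parameter_set <- function(reals, config, threshold = 0.02) {
  ok <- !vapply(reals, is.null, TRUE)
  reals <- reals[ok]
  g_mean <- mean_pcf(lapply(reals, `[[`, "g"))
  gS_mean <- mean_pcf(lapply(reals, `[[`, "g_S"))
  sc <- pattern_scale(g_mean, gS_mean, threshold)
  qh <- quadrat_histogram(lapply(reals, `[[`, "pattern"), config$M_q)
  fixated <- vapply(reals, `[[`, TRUE, "fixated")
  max_diffs <- vapply(reals, function(r) r$scale$max_diff, numeric(1))
  r_ps <- vapply(reals, function(r) r$scale$r_p, numeric(1))
  pass <- !fixated & max_diffs > threshold
  list(g_mean = g_mean, g_S_mean = gS_mean, scale = sc, qh = qh,
       n_pass = sum(pass), n_fixated = sum(fixated), n_run = length(reals),
       n_failed = sum(!ok),
       r_p_mean = if (any(pass & is.finite(r_ps))) mean(r_ps[pass], na.rm = TRUE) else NA_real_,
       r_p_sd = if (sum(pass & is.finite(r_ps)) > 1) sd(r_ps[pass], na.rm = TRUE) else NA_real_,
       pattern_present = pattern_criterion(qh))
}

#' Run a parameter sweep
#'
#' For every row of `grid` (named columns overriding configuration fields,
#' e.g. `S_diff` and `lambda`, or `S_juxt`), runs `M_sim` realisations,
#' averages their PCFs, pools their quadrat histograms and summarises:
#' the pattern scale of the mean PCFs, the per-realisation `r_p`
#' distribution over realisations whose `max(g_S - g)` exceeds the 0.02
#' threshold (fixated, single-type realisations excluded), the count
#' passing that threshold and the pattern-presence flag.  Failed
#' realisations are recorded and skipped.
#'
#' @param config A [run_config()] object.
#' @param grid Data frame of parameter overrides, one row per sweep point.
#' @param M_sim Realisations per point (default from `config`).
#' @param verbose Print progress lines.
#' @return An object of class `sweep_report`: `table` (one summary row per
#'   point) and `detail` (per-point mean PCFs and pooled histogram).
#' @export
run_sweep <- function(config, grid, M_sim = config$M_sim, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"), is.data.frame(grid), nrow(grid) >= 1)
  unknown <- setdiff(names(grid), names(config))
  if (length(unknown)) stop("unknown sweep fields: ", paste(unknown, collapse = ", "))
  detail <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg_k <- config
    for (nm in names(grid)) cfg_k[[nm]] <- grid[k, nm]
    reals <- vector("list", M_sim)
    for (i in seq_len(M_sim)) {
      idx <- (k - 1L) * M_sim + i
      reals[[i]] <- tryCatch(run_realisation(cfg_k, idx),
                             error = function(e) {
                               warning(sprintf("realisation %d failed: %s",
                                               idx, conditionMessage(e)))
                               NULL
                             })
    }
    s <- summarise_parameter_set(reals, cfg_k)
    detail[[k]] <- s
    rows[[k]] <- cbind(grid[k, , drop = FALSE],
                       data.frame(r_p = s$scale$r_p,
                                  max_diff = s$scale$max_diff,
                                  r_p_mean = s$r_p_mean, r_p_sd = s$r_p_sd,
                                  n_pass = s$n_pass, n_fixated = s$n_fixated,
                                  n_run = s$n_run, n_failed = s$n_failed,
                                  pattern_present = s$pattern_present))
    if (verbose)
      message(sprintf("sweep point %d/%d done: r_p = %s, n_pass = %d/%d",
                      k, nrow(grid),
                      if (s$scale$found) sprintf("%.1f", s$scale$r_p) else "NA",
                      s$n_pass, s$n_run))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, detail = detail, config = config,
                 M_sim = M_sim), class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("Sweep report: %d parameter sets x %d realisations\n",
              nrow(x$table), x$M_sim))
  print(x$table)
  invisible(x)
}

#' Write a sweep report
#'
#' The summary table as CSV and the full report (including mean PCF values)
#' as JSON.
#'
#' @param report A [run_sweep()] report.
#' @param csv_file,json_file Output paths (`NULL` to skip either).
#' @export
write_sweep_report <- function(report, csv_file = NULL, json_file = NULL) {
  stopifnot(inherits(report, "sweep_report"))
  if (!is.null(csv_file))
    write.csv(report$table, csv_file, row.names = FALSE, quote = FALSE)
  if (!is.null(json_file)) {
    detail <- lapply(report$detail, function(d) list(
      r_center = d$g_mean$centers, g = d$g_mean$values,
      g_S = d$g_S_mean$values, qh_density = d$qh$density,
      n_pass = d$n_pass, n_fixated = d$n_fixated,
      pattern_present = d$pattern_present))
    jsonlite::write_json(list(table = report$table, detail = detail),
                         json_file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}

#' Write a run manifest
#'
#' JSON record of the configuration and seeds of a run, for reproducibility.
#'
#' @param config A [run_config()] object.
#' @param file Output path.
#' @param indices Realisation indices included in the run.
#' @export
write_manifest <- function(config, file, indices = 1L) {
  rec <- unclass(config)
  rec$realisation_indices <- indices
  rec$realisation_seeds <- vapply(indices, realisation_seed,
                                  integer(1), master = config$master_seed)
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
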