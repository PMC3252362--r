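test_that("stemness decays geometrically and is absorbing at zero", {
  expect_equal(step_stemness(1, 4e-4), 0.9996)
  expect_equal(step_stemness(0, 4e-4), 0)
  s <- 1
  for (i in 1:10000) s <- step_stemness(s, 4e-4)
  expect_equal(s, (1 - 4e-4)^10000)    # closed-form power
  expect_equal(s, 0.01830, tolerance = 1e-3)
})

test_that("the fate step reproduces drift equilibria and direct evaluations", {
  dp <- diff_params(chi = 5, nu = 1, delta = 0, dt = 4e-4)
  expect_equal(step_fate(0, 1, 0, dp, 0), 0)           # symmetric fixed point
  fstar <- sqrt(5 * 0.5)                               # stable branch at s = 0
  expect_equal(step_fate(fstar, 0, 0, dp, 0), fstar)
  expect_equal(fstar, 1.5811, tolerance = 1e-4)
  expect_equal(step_fate(1, 1, 0, dp, 0), 1 + (5 * (-0.5) - 1) * 4e-4)
  expect_equal(step_fate(1, 1, 0, dp, 0), 0.9986)
  expect_error(step_fate(1e200, 0, 0, dp, 0), "unstable")
})

test_that("stable fate equilibria follow the supercritical pitchfork", {
  expect_equal(stable_fates(1), 0)
  expect_equal(stable_fates(0.5), 0)
  expect_equal(stable_fates(0, chi = 5, nu = 1), c(-1, 1) * sqrt(2.5))
  expect_equal(stable_fates(0, chi = 5, nu = 1)[2], 1.5811, tolerance = 1e-4)
  # branches shrink to zero at the bifurcation point
  expect_lt(max(abs(stable_fates(0.499))), 0.1)
})

test_that("classification is by the sign of the fate variable", {
  expect_equal(as.character(classify_fate(c(0.3, -2, 0))), c("R", "G", "G"))
  expect_equal(levels(classify_fate(1)), c("R", "G"))
  expect_error(classify_fate(NaN))
})

test_that("without noise or signalling the f = 0 manifold is invariant", {
  dom <- periodic_domain(20)
  set.seed(5)
  pos <- seed_positions(50, dom)
  dp <- diff_params(delta = 0, t_end = 0.5)
  sim <- simulate_differentiation(pos, dom, dp, no_signalling())
  expect_true(all(sim$f == 0))
  expect_true(all(sim$type == "G"))
})

test_that("stemness snapshots equal the closed-form power for every cell", {
  dom <- periodic_domain(20)
  set.seed(6)
  pos <- seed_positions(30, dom)
  dp <- diff_params(t_end = 0.4, dt = 4e-4)
  sim <- simulate_differentiation(pos, dom, dp, no_signalling(),
                                  snapshot_times = c(0.2, 0.4))
  tau1 <- round(0.2 / 4e-4); tau2 <- round(0.4 / 4e-4)
  expect_equal(sim$snapshots[[1]]$s, rep((1 - 4e-4)^tau1, 30))
  expect_equal(sim$snapshots[[2]]$s, rep((1 - 4e-4)^tau2, 30))
  expect_equal(sim$s, rep((1 - 4e-4)^tau2, 30))
})

test_that("compiled and reference engines agree given the same noise", {
  dom <- periodic_domain(24)
  set.seed(7)
  pos <- relax_positions(seed_positions(60, dom), seeding_params(60), dom)
  dp <- diff_params(t_end = 0.2, dt = 4e-4)
  nsteps <- ceiling(dp$t_end / dp$dt)
  noise <- matrix(rnorm(nsteps * 60), nsteps, 60)
  for (sig in list(no_signalling(),
                   juxtacrine_signalling(juxtacrine_params(S_juxt = 5e-2)),
                   diffusive_signalling(diffusive_params(S_diff = 40, M_s = 24)))) {
    a <- simulate_differentiation(pos, dom, dp, sig, noise = noise,
                                  engine = "cpp")
    b <- simulate_differentiation(pos, dom, dp, sig, noise = noise,
                                  engine = "r")
    expect_equal(a$f, b$f, tolerance = 1e-12)
    expect_equal(a$s, b$s, tolerance = 1e-14)
    expect_equal(a$bias, b$bias, tolerance = 1e-12)
    if (!is.null(a$a)) expect_equal(a$a, b$a, tolerance = 1e-12)
  }
})

test_that("negating the noise mirrors fates and swaps types", {
  dom <- periodic_domain(24)
  set.seed(8)
  pos <- relax_positions(seed_positions(80, dom), seeding_params(80), dom)
  dp <- diff_params(t_end = 0.6, dt = 4e-4)
  nsteps <- ceiling(dp$t_end / dp$dt)
  noise <- matrix(rnorm(nsteps * 80), nsteps, 80)
  for (sig in list(juxtacrine_signalling(juxtacrine_params(S_juxt = 5e-2)),
                   diffusive_signalling(diffusive_params(S_diff = 40, M_s = 24)))) {
    a <- simulate_differentiation(pos, dom, dp, sig, noise = noise)
    b <- simulate_differentiation(pos, dom, dp, sig, noise = -noise)
    expect_equal(a$f, -b$f)
    expect_equal(table(a$type)[["R"]], table(b$type)[["G"]])
    if (!is.null(a$a)) {
      # morphogen fields exchange exactly under the fate flip
      expect_equal(a$a, b$b)
      expect_equal(a$b, b$a)
    }
  }
})

test_that("terminal fates are bimodal near the deep-well equilibria", {
  dom <- periodic_domain(48)
  set.seed(9)
  pos <- relax_positions(seed_positions(560, dom), seeding_params(560), dom)
  sim <- simulate_differentiation(pos, dom, diff_params(),
                                  juxtacrine_signalling())
  s_end <- sim$s[1]
  f_eq <- sqrt(5 * (0.5 - s_end))          # stable branch at terminal stemness
  expect_gt(min(table(sim$type)), 50)       # both types well represented
  # bimodal: most cells well inside a well, few left near the ridge f = 0,
  # and the committed cells sit close to the equilibrium branch
  expect_gt(mean(abs(sim$f) > 1), 0.7)
  expect_lt(mean(abs(sim$f) < 0.1), 0.1)
  expect_lt(abs(mean(abs(sim$f[abs(sim$f) > 1])) - f_eq), 0.2)
  # trajectory snapshots show the progression from unimodal to bimodal
  sim2 <- simulate_differentiation(pos, dom, diff_params(),
                                   juxtacrine_signalling(),
                                   snapshot_times = c(1, 4))
  expect_lt(mean(abs(sim2$snapshots[[1]]$f)), 0.5)
  expect_gt(mean(abs(sim2$snapshots[[2]]$f)), 1)
})
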