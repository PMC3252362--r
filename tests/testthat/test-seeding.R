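test_that("pairwise velocity has the repulsion/adhesion structure", {
  sp <- seeding_params(N = 10)
  expect_equal(pairwise_velocity(2, sp), 0)              # equilibrium spacing
  expect_equal(pairwise_velocity(3.5, sp), 0)            # beyond cut-off
  expect_equal(pairwise_velocity(1, sp), 5000)           # A r_c^2 (2-1)/1
  expect_gt(pairwise_velocity(0.5, sp), 0)               # repulsive short range
  expect_lt(pairwise_velocity(2.5, sp), 0)               # adhesive mid range
  expect_error(pairwise_velocity(0, sp))                 # coincident pair
})

test_that("random seeding is uniform on the domain", {
  dom <- periodic_domain(120)
  expect_error(seed_positions(0, dom))
  set.seed(11)
  pos <- seed_positions(3500, dom)
  expect_equal(dim(pos), c(3500, 2))
  expect_true(all(pos >= 0 & pos < 120))
  expect_equal(colMeans(pos), c(x = 60, y = 60), tolerance = 2 / 60)
  # chi-square uniformity over a 12 x 12 partition at alpha = 0.001
  set.seed(12)
  pos <- seed_positions(10000, dom)
  cells <- floor(pos[, 1] / 10) * 12 + floor(pos[, 2] / 10)
  counts <- tabulate(cells + 1, nbins = 144)
  stat <- sum((counts - 10000 / 144)^2 / (10000 / 144))
  expect_lt(stat, qchisq(0.999, df = 143))
})

test_that("relaxation respects two-body dynamics", {
  dom <- periodic_domain(40)
  sp <- seeding_params(N = 2, dt_init = 2e-5)
  # single isolated cell does not move
  one <- relax_positions(matrix(c(5, 5), 1, 2), sp, dom)
  expect_equal(unname(one), matrix(c(5, 5), 1, 2))
  # a pair at the equilibrium spacing stays put
  pair <- matrix(c(10, 12, 10, 10), 2, 2)
  expect_equal(unname(relax_positions(pair, sp, dom)), pair)
  # a pair at 1.2 r_c separates monotonically toward 2 r_c (1-D reduction
  # integrated independently as the oracle)
  p0 <- matrix(c(10, 11.2, 10, 10), 2, 2)
  nst <- 100
  sep_oracle <- oracle_two_body_separation(1.2, 5000, 1, 3, 2e-5, nst)
  expect_true(all(diff(c(1.2, sep_oracle[sep_oracle < 2])) > 0))
  p1 <- relax_positions(p0, sp, dom)
  expect_equal(min_image_dist(p1[1, ], p1[2, ], 40), sep_oracle[nst],
               tolerance = 1e-10)
})

test_that("relaxation is translation-equivariant and conserves pair momentum", {
  dom <- periodic_domain(30)
  sp <- seeding_params(N = 40, dt_init = 2e-5, t_init = 2e-4)
  set.seed(21)
  pos <- seed_positions(40, dom)
  out <- relax_positions(pos, sp, dom)
  shift <- matrix(c(7.5, 13.25), 40, 2, byrow = TRUE)
  out_sh <- relax_positions(wrap_coords(pos + shift, 30), sp, dom)
  expect_equal(wrap_coords(out + shift, 30), out_sh, tolerance = 1e-9,
               ignore_attr = TRUE)
  # one Euler step: displacements sum to zero (equal and opposite per pair)
  one <- relax_positions(pos, seeding_params(N = 40, dt_init = 2e-5,
                                             t_init = 2e-5), dom)
  disp <- ((one - pos + 15) %% 30) - 15  # minimum-image unwrapped step
  expect_equal(colSums(disp), c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("grid-accelerated relaxation matches the all-pairs brute force", {
  # one Euler step: identical pair interactions (summation order aside);
  # over many steps the dynamics amplify last-ulp differences, so the
  # per-step comparison is the meaningful one
  dom <- periodic_domain(30)
  sp <- seeding_params(N = 300, dt_init = 2e-5, t_init = 2e-5)
  set.seed(31)
  pos <- seed_positions(300, dom)
  expect_equal(relax_positions(pos, sp, dom, method = "grid"),
               relax_positions(pos, sp, dom, method = "brute"),
               tolerance = 1e-12)
})

test_that("relaxed configurations have minimal overlap", {
  dom <- periodic_domain(120)
  # fraction of neighbouring pairs (within the interaction range) that are
  # overlapping (closer than 1.5 r_c) stays below 1%
  overlap <- vapply(1:2, function(seed) {
    set.seed(seed)
    sp <- seeding_params(3500)
    pos <- relax_positions(seed_positions(3500, dom), sp, dom)
    nb <- build_neighbour_list(pos, 3, dom)
    mean(nb$d < 1.5)
  }, numeric(1))
  expect_true(all(overlap < 0.01))
})

test_that("relaxation rejects coincident and non-finite input", {
  dom <- periodic_domain(20)
  sp <- seeding_params(N = 2)
  expect_error(relax_positions(matrix(c(5, 5, 5, 5), 2, 2), sp, dom),
               "coincident")
  expect_error(relax_positions(matrix(c(NA, 5, 5, 5), 2, 2), sp, dom))
})
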