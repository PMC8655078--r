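test_that("generators are pure functions of their seed", {
  a <- gen_uniform_emitters(5000, 1e-5, seed = 3)
  b <- gen_uniform_emitters(5000, 1e-5, seed = 3)
  expect_identical(a, b)
  s1 <- gen_drift_spline(2000, mean_nodes = 6, seed = 9)
  s2 <- gen_drift_spline(2000, mean_nodes = 6, seed = 9)
  expect_identical(s1, s2)
  t1 <- gen_blink_traces(200, 500, seed = 11)
  t2 <- gen_blink_traces(200, 500, seed = 11)
  expect_identical(t1, t2)
})

test_that("uniform field count follows its Poisson expectation", {
  ns <- vapply(1:60, function(s)
    nrow(gen_uniform_emitters(6400, 1e-4, seed = s)), numeric(1))
  mu <- 1e-4 * 6400^2
  expect_lt(abs(mean(ns) - mu), 3 * sqrt(mu / 60))
  expect_equal(nrow(gen_uniform_emitters(6400, 1e-12, seed = 1)), 0)
})

test_that("star field honors the wedge geometry at the requested density", {
  f <- gen_star_emitters(6400, 5e-4, n_wedges = 16, seed = 2)
  expect_true(all(in_star(f$x, f$y, 6400, 16)))
  # accepted-region density: wedges cover half the inscribed disk
  area_accepted <- pi * 3200^2 / 2
  expect_lt(abs(nrow(f) / area_accepted - 5e-4) / 5e-4, 0.05)
  # two wedges = half plane through the center
  h <- gen_star_emitters(4000, 5e-4, n_wedges = 2, seed = 3)
  th <- atan2(h$y - 2000, h$x - 2000) %% (2 * pi)
  expect_true(all(th < pi))
})

test_that("ring pairs sit exactly on their circles at two z levels", {
  f <- gen_ring_pair_3d(diameter_nm = 40, separation_nm = 80,
                        center = c(100, 200, 50), seed = 4)
  r <- sqrt((f$x - 100)^2 + (f$y - 200)^2)
  expect_lt(max(abs(r - 20)), 1e-9)
  zs <- sort(unique(f$z))
  expect_length(zs, 2L)
  expect_equal(diff(zs), 80)
  # Poisson count check: rho * circumference / pixel per ring
  ns <- vapply(1:40, function(s)
    nrow(gen_ring_pair_3d(seed = s)), numeric(1))
  mu <- 2 * 1000 * pi * 40 / 100
  expect_lt(abs(mean(ns) - mu), 3 * sqrt(mu / 40))
})

test_that("blink traces obey the renewal statistics of the on/off rates", {
  n_em <- 20000; n_fr <- 1000; kon <- 5e-4; koff <- 1
  tr <- gen_blink_traces(n_em, n_fr, kon, koff, seed = 6)
  expect_true(all(tr$t_on < tr$t_off))
  expect_true(all(tr$t_on >= 0 & tr$t_off <= n_fr))
  # intervals of one emitter are disjoint and ordered
  e1 <- tr[tr$emitter == tr$emitter[1], ]
  if (nrow(e1) > 1)
    expect_true(all(diff(as.vector(t(e1[, c("t_on", "t_off")]))) >= 0))

  # on-fraction ~ duty cycle K_on/(K_on+K_off); sigma from emitter groups
  on_frac_g <- vapply(split(tr$t_off - tr$t_on,
                            (tr$emitter - 1) %/% (n_em / 20)),
                      sum, numeric(1)) / (n_em / 20 * n_fr)
  duty <- kon / (kon + koff)
  se <- sd(on_frac_g) / sqrt(length(on_frac_g))
  expect_lt(abs(mean(on_frac_g) - duty), 3 * se + 1e-12)

  # events per emitter ~ n * kon * koff / (kon + koff)
  lam_hat <- nrow(tr) / n_em
  lam_th <- n_fr * kon * koff / (kon + koff)
  expect_lt(abs(lam_hat - lam_th), 3 * sqrt(lam_th / n_em))

  # vanishing K_on produces no events
  expect_equal(nrow(gen_blink_traces(100, 100, K_on = 1e-12, seed = 1)), 0)
})

test_that("expected pair count matches the Poisson closed form", {
  expect_equal(expected_pairs(2), 2)
  expect_equal(expected_pairs(0), 0)
  set.seed(7)
  k <- rpois(2e5, 0.7)
  mc <- mean(choose(k, 2))
  se <- sd(choose(k, 2)) / sqrt(length(k))
  expect_lt(abs(mc - expected_pairs(0.7)), 3 * se)
  expect_equal(expected_pairs(0.7), 0.245)
})

test_that("drift curve generators evaluate their stated forms", {
  cst <- gen_drift_constant(20, c(0.3, 0.4))
  expect_equal(cst$x[11], 3)   # frame 10
  expect_equal(cst$y[11], 4)
  expect_equal(cst$x, cumsum(c(0, rep(0.3, 19))))

  pol <- gen_drift_polynomial(1001, c(0.05, 0.02))
  expect_equal(pol$x[1001], 50)  # frame 1000
  expect_equal(pol$y[1001], 20)
  q <- gen_drift_polynomial(100, c(1, 2), c(0.1, -0.2))
  f <- q$frame
  expect_equal(q$x, 1 * f + 0.1 * f^2)
  expect_equal(q$y, 2 * f - 0.2 * f^2)
  expect_equal(q$x[1], 0)
})

test_that("spline drift interpolates its nodes and stays near-bounded", {
  cur <- gen_drift_spline(5000, mean_nodes = 10, amplitude_nm = 100,
                          ndim = 2, seed = 13)
  nd <- attr(cur, "nodes")$x
  at_nodes <- cur$x[round(nd$frame) + 1]
  # spline passes through nodes (grid evaluation at rounded node frames)
  expect_lt(max(abs(at_nodes - nd$value)), 2)
  worst <- vapply(1:100, function(s) {
    max(abs(as.matrix(gen_drift_spline(3000, 8, 100, ndim = 2,
                                       seed = s)[c("x", "y")])))
  }, numeric(1))
  expect_lt(max(worst), 1.5 * 100)
})

test_that("rendered localizations respect positions, drift and noise", {
  set.seed(15)
  field <- gen_uniform_emitters(2000, 5e-4)
  traces <- gen_blink_traces(nrow(field), 200, K_on = 0.01)
  # noiseless, undrifted: localizations sit exactly on their emitters
  sim0 <- render_localizations(field, traces, NULL, noise_sigma_nm = 0,
                               frames_per_dataset = 100)
  expect_equal(sim0$table$x * 100, sim0$truth$true_x, tolerance = 1e-12)

  # row count: one localization per covered frame per on-interval
  n_expected <- sum(pmax(pmin(ceiling(traces$t_off - 1e-12), 200) -
                           pmax(floor(traces$t_on), 0), 0))
  expect_equal(nrow(sim0$table), n_expected)

  # drift bookkeeping is exactly invertible
  curve <- gen_drift_constant(200, c(0.5, -0.3))
  simd <- render_localizations(field, traces, curve, noise_sigma_nm = 0,
                               frames_per_dataset = 100)
  undone <- simd$table$x * 100 - simd$truth$drift_x
  expect_equal(undone, simd$truth$true_x, tolerance = 1e-9)

  # localization scatter has the requested spread
  simn <- render_localizations(field, traces, NULL, noise_sigma_nm = 10,
                               frames_per_dataset = 100, seed = 16)
  resid <- simn$table$x * 100 - simn$truth$true_x
  n <- length(resid)
  expect_lt(abs(sd(resid) - 10), 3 * 10 / sqrt(2 * (n - 1)))
})

test_that("anisotropic scatter applies per-axis sigmas", {
  field <- gen_ring_pair_3d(density_per_px = 3000, seed = 17)
  traces <- gen_blink_traces(nrow(field), 500, K_on = 0.01, seed = 17)
  sim <- render_localizations(field, traces, NULL,
                              noise_sigma_nm = c(5, 5, 20),
                              frames_per_dataset = 500, seed = 18)
  rz <- sim$table$z * 100 - sim$truth$true_z
  rx <- sim$table$x * 100 - sim$truth$true_x
  expect_gt(sd(rz), 2.5 * sd(rx))
})

test_that("synthetic brightfield stacks carry exact ground truth", {
  st0 <- gen_brightfield_stack(shape = c(12, 12, 5), n_blobs = 100, seed = 19)
  sc <- attr(st0, "scene")
  again <- render_brightfield(sc)
  expect_equal(st0$voxels, again$voxels)
  # an integer-voxel shift equals an index-rolled copy inside the overlap
  sh <- render_brightfield(sc, offset_nm = c(100, 0, 0))  # +1 voxel in x
  expect_equal(sh$voxels[, 2:12, ], st0$voxels[, 1:11, ], tolerance = 1e-12)
})
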