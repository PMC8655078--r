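test_that("projection to t=0 inverts the polynomial motion model", {
  set.seed(2)
  pos <- matrix(runif(60, 0, 100), ncol = 2)
  fr <- sample(0:999, 30)
  expect_equal(project_to_t0(pos, fr, matrix(0, 1, 2)), pos)

  lin <- matrix(c(0.003, 0.004), 1, 2)
  at100 <- project_to_t0(matrix(c(10, 10), 1), 100, lin)
  expect_equal(as.vector(at100), c(10 - 0.3, 10 - 0.4))

  # quadratic coefficients against a direct polynomial evaluation oracle
  co <- matrix(c(1e-3, -2e-6, 2e-3, 1e-6), 2, 2)
  proj <- project_to_t0(pos, fr, co)
  oracle <- pos - cbind(co[1, 1] * fr + co[2, 1] * fr^2,
                        co[1, 2] * fr + co[2, 2] * fr^2)
  expect_equal(proj, oracle, tolerance = 1e-12)
})

test_that("intra cost vanishes at the true model for noiseless blinks", {
  d <- make_duplicated_emitters()
  c_true <- intra_cost(d$positions, d$frames, matrix(d$rate, 1, 2))
  c_zero <- intra_cost(d$positions, d$frames, matrix(0, 1, 2))
  expect_lt(c_true, 1e-9)
  expect_gt(c_zero, c_true)
})

test_that("single-blink emitters saturate the intra cost at n * l", {
  set.seed(5)
  # isolated emitters, one localization each, far apart
  pos <- 10 * matrix(seq_len(40), 20)
  fr <- sample(0:99, 20)
  expect_equal(intra_cost(pos, fr, matrix(0, 1, 2), l_intra = 1), 20)
})

test_that("intra fit recovers a linear drift rate from blinking data", {
  sim <- quick_sim(n_emitters = 2e4, lambda = 0.45, seed = 21)
  fit <- fit_intra(coords_of(sim$table), sim$table$frame)
  # 0.05 and 0.02 nm/frame at 100 nm/px
  expect_lt(abs(fit$coeffs[1, 1] - 5e-4), 1e-4)
  expect_lt(abs(fit$coeffs[1, 2] - 2e-4), 1e-4)
  expect_true(fit$converged)
  expect_lte(fit$cost, fit$init_cost)
})

test_that("intra fit on zero-drift data returns near-zero coefficients", {
  sim <- quick_sim(n_emitters = 1e4, lambda = 0.6, alpha = c(0, 0),
                   seed = 8)
  fit <- fit_intra(coords_of(sim$table), sim$table$frame)
  expect_lt(max(abs(fit$coeffs)), 1e-3)
})

test_that("quadratic fit reaches at least the true-coefficient cost", {
  set.seed(31)
  d <- make_duplicated_emitters(rate_px_frame = c(2e-3, -1e-3))
  beta <- c(2e-6, -1e-6)
  pos <- d$positions + outer(d$frames^2, beta)
  co_true <- rbind(d$rate, beta)
  fit <- fit_intra(pos, d$frames, degree = 2)
  c_true <- intra_cost(pos, d$frames, co_true)
  expect_lte(fit$cost, c_true + 1e-4)
})

test_that("degenerate datasets fall back to zero drift with a warning", {
  expect_warning(f <- fit_intra(matrix(c(1, 2), 1), 0L), "fewer than 2")
  expect_equal(f$coeffs, matrix(0, 1, 2), ignore_attr = TRUE)
})

test_that("inter fit recovers a constant displacement", {
  set.seed(13)
  ref <- matrix(runif(800, 0, 60), ncol = 2)
  s <- c(0.8, -0.35)
  target <- sweep(ref, 2, s, "+")
  idx <- nn_reference_index(ref, 2)
  expect_equal(inter_cost(idx, target, -s), 0, tolerance = 1e-12)
  expect_equal(inter_cost(idx, target + 100, c(0, 0)), nrow(target) * 2)

  fit <- fit_inter(idx, target)
  expect_lt(max(abs(fit$shift + s)), 1e-3)
  expect_lte(fit$cost, fit$init_cost)

  same <- fit_inter(idx, ref)
  expect_lt(max(abs(same$shift)), 1e-3)
})

test_that("an outlier beyond l_inter contributes exactly the threshold", {
  ref <- cbind(c(0, 1, 2, 3, 4), 0)
  target <- rbind(sweep(ref, 2, c(0.5, 0), "+"), c(100, 100))
  fit <- fit_inter(nn_reference_index(ref, 2), target,
                   init_shift = c(-0.5, 0))
  expect_equal(fit$cost, 2, tolerance = 1e-6)
})

test_that("inter cost equals the brute-force oracle on random sets", {
  for (seed in 1:3) {
    set.seed(seed)
    dim <- sample(2:3, 1)
    ref <- matrix(runif(90 * dim, 0, 15), ncol = dim)
    target <- matrix(runif(60 * dim, 0, 15), ncol = dim)
    s <- runif(dim, -1, 1)
    expect_equal(inter_cost(nn_reference_index(ref, 2), target, s),
                 brute_nnd_sum(sweep(target, 2, s, "+"), ref, 2),
                 tolerance = 1e-12)
  }
})

test_that("full correction removes an inter-dataset shift and is exactly
           consistent with its model", {
  set.seed(17)
  em <- matrix(runif(500, 0, 50), ncol = 2)
  s <- c(0.6, -0.4)
  frames <- sample(0:199, 250, TRUE)
  tab <- loc_table(
    x = c(em[, 1], em[, 1] + s[1]), y = c(em[, 2], em[, 2] + s[2]),
    frame = c(frames, frames), dataset = rep(0:1, each = 250),
    frames_per_dataset = 200L)
  fit <- drift_correct_knn(tab, registration_used = TRUE)
  expect_lt(max(abs(fit$model$inter[2, ] - s)), 1e-3)
  drift <- predict(fit$model, tab$dataset, tab$frame)
  expect_identical(coords_of(fit$table), coords_of(tab) - drift)
})

test_that("zero-drift data receives only optimizer-noise corrections", {
  sim <- quick_sim(n_emitters = 2e4, lambda = 1, alpha = c(0, 0), seed = 4)
  fit <- drift_correct_knn(sim$table)
  expect_lt(max(abs(coords_of(fit$table) - coords_of(sim$table))), 0.02)
})

test_that("fitted intra coefficients are invariant to a global translation", {
  sim <- quick_sim(n_emitters = 5e3, lambda = 1, seed = 19)
  fit1 <- drift_correct_knn(sim$table)
  moved <- sim$table
  moved$x <- moved$x + 7.25
  moved$y <- moved$y - 3.5
  fit2 <- drift_correct_knn(moved)
  expect_equal(fit1$model$intra[[1]], fit2$model$intra[[1]],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("re-segmentation override corrects and restores the original
           scheme", {
  sim <- quick_sim(n_emitters = 5e3, lambda = 1.5, n_frames = 1000,
                   frames_per_dataset = 1000, seed = 23)
  fit <- drift_correct_knn(sim$table, registration_used = FALSE,
                           frames_per_dataset = 250)
  expect_identical(fit$table$dataset, sim$table$dataset)
  expect_identical(fit$table$frame, sim$table$frame)
  expect_equal(length(fit$model$intra), 4L)
  # corrected coordinates still reflect the 4-chunk model
  est <- drift_curve_from_model(fit$model, units = "nm")
  tr <- sim$curve
  err <- (est$x - est$x[1]) - (tr$x - tr$x[1])
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("cost landscape is funnel-shaped with its minimum at the fitted
           parameters", {
  set.seed(29)
  ref <- matrix(runif(600, 0, 40), ncol = 2)
  s <- c(0.9, -0.6)
  tab <- loc_table(x = c(ref[, 1], ref[, 1] + s[1]),
                   y = c(ref[, 2], ref[, 2] + s[2]),
                   frame = rep(0:99, 6), dataset = rep(0:1, each = 300))
  g <- seq(-1.5, 1.5, by = 0.15)
  ls <- cost_landscape(tab, "inter", x_grid = g, y_grid = g, dataset = 1L)
  expect_true(all(ls$cost >= 0))
  expect_true(all(ls$cost <= ls$n_query * ls$l + 1e-9))
  mi <- arrayInd(which.min(ls$cost), dim(ls$cost))
  expect_lt(abs(g[mi[1]] - (-s[1])), 0.15 + 1e-9)
  expect_lt(abs(g[mi[2]] - (-s[2])), 0.15 + 1e-9)
})
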