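make_stack <- function(dims = c(8, 8, 5), seed = 1) {
  set.seed(seed)
  image_stack(array(runif(prod(dims), 0.5, 2), dims), z_step_nm = 50)
}

test_that("slice normalization makes every slice sum to one", {
  st <- image_stack(array(rep(c(2, 4, 8), each = 16), c(4, 4, 3)))
  ns <- normalize_slices(st)
  expect_equal(apply(ns$voxels, 3, sum), rep(1, 3))
  expect_equal(ns$voxels[1, 1, 1], 1 / 16)

  rs <- normalize_slices(make_stack(seed = 4))
  expect_equal(apply(rs$voxels, 3, sum), rep(1, 5), tolerance = 1e-12)

  bad <- image_stack(array(0, c(3, 3, 3)))
  expect_error(normalize_slices(bad), "zero")
})

test_that("whitening zeroes the mean and normalizes the autocorrelation
           peak to 1", {
  st <- make_stack(seed = 2)
  w <- whiten_stack(st)
  expect_lt(abs(mean(w$voxels)), 1e-12)
  # peak of the full zero-padded autocorrelation = sum of squares = 1
  auto <- scaled_xcorr3(w, w)
  ctr <- dim(st$voxels)
  expect_equal(auto$cc[ctr[1], ctr[2], ctr[3]], 1, tolerance = 1e-9)
  # identical to the alternative normalization by the autocorrelation max
  v <- st$voxels
  alt <- (v - mean(v)) / sqrt(sum((v - mean(v))^2))
  expect_equal(w$voxels, alt, tolerance = 1e-12)

  expect_error(whiten_stack(image_stack(array(1, c(3, 3, 3)))), "constant")
})

test_that("ones-overlap volume is the separable triangle count", {
  o <- ones_overlap(c(3, 1, 1))
  expect_equal(as.vector(o), c(1, 2, 3, 2, 1))
  o2 <- ones_overlap(c(4, 5, 3))
  expect_equal(max(o2), 4 * 5 * 3)
  # agrees with the FFT route: unscaled xcorr of ones with itself
  ones <- image_stack(array(1, c(4, 5, 3)))
  w <- scaled_xcorr3(ones, ones)   # scaling by max(o)/o undone below
  expect_equal(w$cc * o2 / max(o2), o2, tolerance = 1e-6)
})

test_that("scaled cross-correlation equals the brute-force sliding window", {
  a <- make_stack(c(8, 8, 5), seed = 5)
  b <- make_stack(c(8, 8, 5), seed = 6)
  fftv <- scaled_xcorr3(a, b)$cc
  brute <- brute_scaled_xcorr3(a$voxels, b$voxels)
  expect_lt(max(abs(fftv - brute)), 1e-9)
  expect_error(scaled_xcorr3(a, make_stack(c(6, 8, 5), seed = 7)), "shape")
})

test_that("self-correlation peaks at zero lag with value 1", {
  st <- whiten_stack(make_stack(c(10, 9, 5), seed = 8))
  v <- scaled_xcorr3(st, st)
  pk <- suppressWarnings(subpixel_peak(v))
  expect_equal(unname(pk$lag), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(pk$peak_value, 1, tolerance = 1e-6)
})

test_that("integer-voxel shifts move the correlation argmax accordingly", {
  set.seed(9)
  sc <- gen_brightfield_scene(shape = c(16, 16, 7), n_blobs = 300)
  ref <- whiten_stack(normalize_slices(render_brightfield(sc)))
  sh <- c(2, -1, 1) # voxels (dx, dy, dz)
  new <- render_brightfield(sc, offset_nm = sh * c(100, 100, 50))
  new <- whiten_stack(normalize_slices(new))
  pk <- subpixel_peak(scaled_xcorr3(ref, new))
  expect_equal(round(unname(pk$lag)), sh)
})

test_that("3-point parabola vertex follows its closed form", {
  cc <- array(0.01, c(5, 5, 5))
  cc[3, 3, 3] <- 1
  cc[2, 3, 3] <- 0.4; cc[4, 3, 3] <- 0.8   # y-line through the max
  cc[3, 2, 3] <- 0.5; cc[3, 4, 3] <- 0.5   # symmetric in x
  cc[3, 3, 2] <- 0.5; cc[3, 3, 4] <- 0.5   # symmetric in z
  vol <- structure(list(cc = cc, mask = array(TRUE, c(5, 5, 5)),
                        shape = c(3, 3, 3)), class = "xcorr_volume")
  pk <- subpixel_peak(vol)
  expect_equal(unname(pk$lag["dy"]), (0.8 - 0.4) / (2 * (2 - 0.4 - 0.8)))
  expect_equal(unname(pk$lag["dx"]), 0)
  expect_equal(unname(pk$lag["dz"]), 0)
})

test_that("single-pass registration recovers a known sub-voxel shift and is
           invariant to intensity rescaling", {
  sc <- gen_brightfield_scene(seed = 5)
  ref <- render_brightfield(sc)
  true_shift <- c(120, -80, 150)
  new <- render_brightfield(sc, offset_nm = true_shift)
  r <- register_once(ref, new)
  expect_lt(abs(r$shift_nm["dx"] - true_shift[1]), 10)
  expect_lt(abs(r$shift_nm["dy"] - true_shift[2]), 10)
  expect_lt(abs(r$shift_nm["dz"] - true_shift[3]), 25)

  bright <- new
  bright$voxels <- bright$voxels * 3
  expect_equal(register_once(ref, bright)$shift_nm, r$shift_nm)

  same <- register_once(ref, ref)
  expect_lt(max(abs(same$shift_nm)), 1)

  # antisymmetry of the measured shift
  rev <- register_once(new, ref)
  expect_lt(max(abs(r$shift_nm + rev$shift_nm)), 5)
})

test_that("median sub-voxel recovery error stays below 0.1 voxel laterally", {
  sc <- gen_brightfield_scene(seed = 12)
  ref <- render_brightfield(sc)
  errs <- vapply(1:40, function(i) {
    set.seed(3000 + i)
    tr <- c(runif(2, -50, 50), runif(1, -25, 25))
    r <- register_once(ref, render_brightfield(sc, offset_nm = tr))
    abs(r$shift_nm - tr) / c(100, 100, 50)
  }, numeric(3))
  expect_lt(median(errs[1, ]), 0.1)
  expect_lt(median(errs[2, ]), 0.1)
})

test_that("iterative registration converges below the stage tolerances", {
  sc <- gen_brightfield_scene(seed = 5)
  ref <- render_brightfield(sc)

  stage <- simulated_stage(sc, offset_nm = c(200, 150, 300))
  res <- register_iterative(ref, stage)
  expect_true(res$converged)
  expect_lt(max(abs(res$shift_nm[c("dx", "dy")])), 5)
  expect_lt(abs(res$shift_nm["dz"]), 50)

  # already aligned: one pass suffices
  res0 <- register_iterative(ref, simulated_stage(sc))
  expect_true(res0$converged)
  expect_length(res0$iterations, 1L)

  # 20% move error still converges by geometric residual decay
  stage_err <- simulated_stage(sc, offset_nm = c(200, 150, 300),
                               move_error = 0.2)
  res_err <- register_iterative(ref, stage_err)
  expect_true(res_err$converged)
})

test_that("TIFF + sidecar round trip reproduces the stack", {
  st <- make_stack(c(12, 10, 4), seed = 15)
  tmp <- tempfile(fileext = ".tif")
  write_image_stack(st, tmp)
  back <- read_image_stack(tmp)
  expect_equal(back$voxels, st$voxels, tolerance = 1e-6)
  expect_equal(back$z_positions, st$z_positions)
  expect_equal(back$pixel_size_nm, st$pixel_size_nm)
})

test_that("stack construction enforces geometry invariants", {
  expect_error(image_stack(array(1, c(4, 4, 2))), "3 slices")
  expect_error(image_stack(array(1, c(4, 4, 4)),
                           z_positions = c(0, 50, 90, 160)), "uniform")
  expect_error(image_stack(array(NA_real_, c(4, 4, 3))), "finite")
})
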