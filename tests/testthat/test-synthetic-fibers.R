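test_that("sine tortuosity: straight limit, small-amplitude expansion, dual oracle", {
  expect_equal(sine_tortuosity(0, 100, 200), 1)
  # second-order expansion tau - 1 -> pi^2 a^2 / lambda^2 as a -> 0
  a <- 2; lam <- 100
  tau <- sine_tortuosity(a, lam, 200)
  approx <- pi^2 * a^2 / lam^2
  expect_lt(abs((tau - 1) - approx) / approx, 0.05)
  # quadrature agrees with dense polyline summation to 1e-6
  a <- 10; lam <- 100; L <- 200
  x <- seq(0, L, length.out = 1e5)
  y <- a * sin(2 * pi * x / lam)
  poly <- sum(sqrt(diff(x)^2 + diff(y)^2)) / L
  expect_equal(sine_tortuosity(a, lam, L), poly, tolerance = 1e-6)
})

test_that("scene generation is deterministic and seed-sensitive", {
  spec <- fiber_scene_spec(image_size_px = c(96, 96), n_fibers = 4,
                           fiber_length_um = 120, seed = 7)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$fibers, s2$truth$fibers)
  spec2 <- fiber_scene_spec(image_size_px = c(96, 96), n_fibers = 4,
                            fiber_length_um = 120, seed = 8)
  s3 <- generate_scene(spec2)
  expect_false(identical(s1$image$pixels, s3$image$pixels))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_scene(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("degenerate and noise-free specs honour their construction", {
  empty <- generate_scene(fiber_scene_spec(image_size_px = c(64, 64),
                                           n_fibers = 0, noise_sd = 0, seed = 1))
  expect_equal(nrow(empty$truth$fibers), 0L)
  expect_true(all(empty$image$pixels == 0))
  # zero jitter, zero amplitude: all orientations at base angle, tau = 1
  s <- generate_scene(fiber_scene_spec(image_size_px = c(128, 128),
                                       n_fibers = 5, base_angle_rad = 0.8,
                                       angle_jitter_rad = 0, wave_amplitude_um = 0,
                                       fiber_length_um = 100, length_jitter = 0,
                                       noise_sd = 0, seed = 3))
  expect_true(all(abs(s$truth$fibers$orientation_rad - 0.8) < 1e-6))
  expect_true(all(abs(s$truth$fibers$tortuosity - 1) < 1e-9))
  expect_true(all(s$truth$fibers$tortuosity >= 1))
})

test_that("ground-truth tortuosity of wavy fibers matches the analytic oracle", {
  lam <- 120
  for (ratio in c(0.05, 0.1)) {
    s <- generate_scene(fiber_scene_spec(
      image_size_px = c(256, 256), pixel_size_um = 2, n_fibers = 4,
      base_angle_rad = 1.2, angle_jitter_rad = 0,
      wave_amplitude_um = ratio * lam, wave_length_um = lam,
      fiber_length_um = 2 * lam, length_jitter = 0, noise_sd = 0, seed = 11,
      centers = cbind(c(90, 90, 166, 166), c(90, 166, 90, 166))))
    tr <- s$truth$fibers
    full <- tr[!tr$clipped, ]
    expect_gt(nrow(full), 0)
    expect_equal(full$tortuosity,
                 rep(sine_tortuosity(ratio * lam, lam, 2 * lam), nrow(full)),
                 tolerance = 1e-4)
  }
})

test_that("cohort profiles order the ground-truth dispersion by construction", {
  ac <- make_group_cohort("acute_like", 3, seed = 5)
  ch <- make_group_cohort("chronic_like", 3, seed = 5)
  iqr_of <- function(sc) {
    th <- sc$truth$fibers$orientation_rad
    unname(diff(quantile(th, c(0.25, 0.75))))
  }
  expect_true(all(vapply(ac, iqr_of, 0) < vapply(ch, iqr_of, 0)))
  expect_equal(attr(ac, "profile"), "acute_like")
  expect_equal(vapply(ac, function(s) s$group, ""), rep("acute_like", 3))
  expect_error(make_group_cohort("acute_like", 0), "n_images")
  # different seeds give different images under the same parameters
  a1 <- make_group_cohort("acute_like", 1, seed = 1)[[1]]
  a2 <- make_group_cohort("acute_like", 1, seed = 2)[[1]]
  expect_false(identical(a1$image$pixels, a2$image$pixels))
})

test_that("well-separated straight fibers yield one surviving segment each", {
  n_fib <- 6
  centers <- cbind(rep(192, n_fib), seq(60, 324, length.out = n_fib))
  s <- generate_scene(fiber_scene_spec(
    image_size_px = c(384, 384), pixel_size_um = 2, n_fibers = n_fib,
    base_angle_rad = pi / 2, angle_jitter_rad = 0.02, wave_amplitude_um = 0,
    fiber_length_um = 400, length_jitter = 0.1, noise_sd = 0,
    seed = 21, centers = centers))
  res <- run_pipeline(s, pipeline_config(backend = "intensity"))
  expect_gte(res$biomarkers$n_segments, ceiling(n_fib * 0.9))
  expect_lte(res$biomarkers$n_segments, floor(n_fib * 1.1))
})

test_that("shadow occluders darken the scene without touching ground truth", {
  base_args <- list(image_size_px = c(128, 128), n_fibers = 4,
                    fiber_length_um = 150, noise_sd = 0, seed = 13)
  s0 <- generate_scene(do.call(fiber_scene_spec, c(base_args, shadow_count = 0)))
  s1 <- generate_scene(do.call(fiber_scene_spec, c(base_args, shadow_count = 3)))
  expect_identical(s0$truth$fibers, s1$truth$fibers)
  expect_lte(sum(s1$image$pixels), sum(s0$image$pixels))
})
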