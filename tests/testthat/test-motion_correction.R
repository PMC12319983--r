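test_that("rigid parameter algebra is consistent", {
  mu <- c(4, -2, 1, 10, -25, 40)
  T <- rigid_matrix(mu)
  expect_equal(det(T[1:3, 1:3]), 1, tolerance = 1e-12)
  expect_equal(rotation_to_euler(T[1:3, 1:3]), mu[4:6], tolerance = 1e-10)
  expect_equal(compose_rigid(mu, invert_rigid(mu)), rep(0, 6),
               tolerance = 1e-10)
  expect_equal(rigid_matrix(invert_rigid(mu)), solve(T), tolerance = 1e-10)
})

test_that("apply_rigid handles identity and integer shifts exactly", {
  v <- array(withr::with_seed(1, runif(6 * 5 * 4)), c(6, 5, 4))
  expect_identical(apply_rigid(v, rep(0, 6), interpolation = "nearest"), v)
  expect_identical(apply_rigid(v, rep(0, 6), interpolation = "trilinear"), v)

  # one-voxel translation along x with nearest neighbour = array shift
  sh <- apply_rigid(v, c(1, 0, 0, 0, 0, 0), voxel_size = 1,
                    interpolation = "nearest")
  expect_equal(sh[2:6, , ], v[1:5, , ])
  expect_true(all(sh[1, , ] == 0))
})

test_that("resampling round trips are accurate on smooth images", {
  # a smooth object (broad Gaussian blobs): forward-then-inverse
  # resampling must reproduce the interior to within 1% of the range
  d <- c(32, 32, 32)
  g <- function(c0, w) {
    x <- (slice.index(array(0, d), 1) - c0[1])
    y <- (slice.index(array(0, d), 2) - c0[2])
    z <- (slice.index(array(0, d), 3) - c0[3])
    exp(-(x^2 + y^2 + z^2) / (2 * w^2))
  }
  v <- 100 * g(c(16, 16, 16), 6) + 40 * g(c(20, 13, 17), 4)
  mu <- c(3, 2, -1, 5, -4, 2)
  for (interp in c("trilinear", "cubic")) {
    v2 <- apply_rigid(apply_rigid(v, mu, 2.5, interp), mu, 2.5, interp,
                      invert = TRUE)
    interior <- erode_mask(v > 0.02 * max(v), 2)
    rmse <- sqrt(mean((v2[interior] - v[interior])^2))
    expect_lt(rmse / diff(range(v)), 0.01)
  }
})

test_that("registration recovers known displacements", {
  ph <- default_phantom()
  v <- phantom_signal(ph, 0, c(0, 0, 1))

  # identical images: the optimum is the identity
  r0 <- rigid_register(v, v, 2.5)
  expect_lt(max(abs(r0$mu[1:3])), 0.1)
  expect_lt(max(abs(r0$mu[4:6])), 0.1)

  # 5 mm / 3 degree displacement recovered within 0.5 mm / 0.5 degree
  true <- c(5, -3, 2, 3, -2, 1)
  r <- rigid_register(apply_rigid(v, true, 2.5), v, 2.5)
  e <- attr(trace_error(matrix(true, 1), matrix(r$mu, 1)), "summary")
  expect_lt(e$median_translation_mm, 0.5)
  expect_lt(e$median_rotation_deg, 0.5)

  # graceful degradation under Rician noise (sigma = 5% of mean signal)
  sigma <- 0.05 * mean(v[ph$mask])
  noisy <- withr::with_seed(3, sqrt(
    (apply_rigid(v, true, 2.5) +
     array(rnorm(length(v), sd = sigma), dim(v)))^2 +
    array(rnorm(length(v), sd = sigma), dim(v))^2))
  rn <- rigid_register(noisy, v, 2.5)
  en <- attr(trace_error(matrix(true, 1), matrix(rn$mu, 1)), "summary")
  expect_lt(en$median_translation_mm, 1)
  expect_lt(en$median_rotation_deg, 1)

  expect_error(rigid_register(array(1, dim(v)), v, 2.5), "flat")
})

test_that("the engine is a fixed point on motion-free noiseless data", {
  # full 95-volume protocol: with both shells fully sampled the model
  # prediction is accurate enough that registration has nothing to correct
  ph <- default_phantom()
  sch <- order_incrementally(
    design_scheme(11, list(c(400, 28), c(900, 56)), seed = 3,
                  restarts = 2, max_iter = 60))
  sim <- simulate_series(ph, sch, corruption_spec(sigma = 0))
  res <- suppressMessages(
    correct_motion(sim$series, moco_config(n_epochs = 2), mask = ph$mask))

  expect_true(all(abs(res$trace[, 1:3]) < 0.2))
  expect_true(all(abs(res$trace[, 4:6]) < 0.2))
  # corrected data equals the input within interpolation tolerance
  interior <- erode_mask(ph$mask, 2)
  err <- vapply(seq_len(length(sch)), function(v)
    sqrt(mean((res$corrected$data[, , , v][interior] -
               sim$series$data[, , , v][interior])^2)), numeric(1))
  expect_lt(max(err) / diff(range(sim$series$data)), 0.02)
})

test_that("the engine recovers burst motion on a compact scheme", {
  ph <- default_phantom()
  sch <- small_scheme()
  tr <- burst_motion_trace(length(sch), n_bursts = 2, max_translation = 10,
                           max_rotation = 12, seed = 5)
  sim <- simulate_series(ph, sch, corruption_spec(trace = tr,
                                                  sigma = 5, seed = 9))
  res <- suppressMessages(
    correct_motion(sim$series, moco_config(n_epochs = 2), mask = ph$mask))

  # the compact scheme (16 directions against a 28-term angular model)
  # leaves the prediction underdetermined, so bounds are loose here; the
  # full-protocol accuracy bounds are asserted in the acceptance tests
  e <- attr(trace_error(sim$trace, res$trace), "summary")
  expect_lt(e$median_translation_mm, 4)
  expect_lt(e$median_rotation_deg, 7)

  # correcting actual motion shrinks the weighted prediction residual
  expect_lt(res$log$weighted_rmse[nrow(res$log)],
            res$log$weighted_rmse[1])

  # gradient rotation matches the realignment rotation, volume by volume
  inv <- t(apply(unclass(res$trace), 1, invert_rigid))
  for (v in which(!is_b0(sch))[1:5]) {
    R <- euler_to_rotation(inv[v, 4:6])
    expect_equal(res$rotated_scheme$directions[v, ],
                 drop(R %*% sch$directions[v, ]), tolerance = 1e-6)
  }

  # SSIM against the motion-free ground truth improves
  nv <- length(sch)
  sc <- vapply(seq_len(nv), function(v)
    ssim(res$corrected$data[, , , v], sim$clean$data[, , , v]), numeric(1))
  su <- vapply(seq_len(nv), function(v)
    ssim(sim$series$data[, , , v], sim$clean$data[, , , v]), numeric(1))
  expect_gt(mean(sc), mean(su))
})

test_that("divergence bounds flag volumes instead of aborting", {
  cfg <- moco_config(max_translation = 1e-6, max_rotation = 1e-6)
  expect_equal(cfg$max_translation, 1e-6)
  # a config with one epoch performs no registration and cannot flag
  ph <- default_phantom()
  sim <- simulate_series(ph, small_scheme(), corruption_spec(sigma = 0))
  res <- suppressMessages(
    correct_motion(sim$series, moco_config(n_epochs = 1), mask = ph$mask))
  expect_false(any(res$flagged))
  expect_true(all(res$trace == 0))
})
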