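test_that("phantom construction is deterministic and validated", {
  a <- make_phantom()
  b <- make_phantom()
  expect_identical(a$s0, b$s0)
  expect_identical(a$tensors, b$tensors)
  expect_error(make_phantom(phantom_spec(fiber_evals = c(-1e-3, 1e-3, 1e-3))),
               "positive")
  expect_true(all(abs(rowSums(matrix(a$fractions, ncol = 2)) - 1) < 1e-12))
})

test_that("an isotropic phantom gives direction-independent signals", {
  iso <- make_phantom(phantom_spec(fiber_evals = rep(1e-3, 3),
                                   iso_diffusivity = 1e-3,
                                   csf_diffusivity = 1e-3))
  s1 <- phantom_signal(iso, 900, c(1, 0, 0))
  s2 <- phantom_signal(iso, 900, c(0, 1, 0))
  s3 <- phantom_signal(iso, 900, c(1, 1, 1) / sqrt(3))
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
})

test_that("single-fiber voxels follow the tensor closed form", {
  ph <- sharp_phantom()  # no partial-volume smoothing
  # a voxel deep inside the x-fiber lobe
  i <- c(23, 16, 16)
  expect_equal(ph$fractions[i[1], i[2], i[3], ], c(1, 0))
  s_par <- phantom_signal(ph, 900, c(1, 0, 0))[i[1], i[2], i[3]]
  s0 <- ph$s0[i[1], i[2], i[3]]
  lambda1 <- ph$spec$fiber_evals[1]
  expect_equal(s_par, s0 * exp(-900 * lambda1), tolerance = 1e-12)
  # perpendicular encoding decays with the small eigenvalue
  s_perp <- phantom_signal(ph, 900, c(0, 1, 0))[i[1], i[2], i[3]]
  expect_equal(s_perp, s0 * exp(-900 * ph$spec$fiber_evals[2]),
               tolerance = 1e-12)
})

test_that("crossing regions show reduced fractional anisotropy", {
  # log-linear tensor-fit oracle on clean signals
  ph <- sharp_phantom()
  dirs <- withr::with_seed(14, {
    U <- matrix(rnorm(90), ncol = 3)
    U / sqrt(rowSums(U^2))
  })
  fit_fa <- function(vox) {
    s0 <- ph$s0[vox[1], vox[2], vox[3]]
    y <- vapply(seq_len(nrow(dirs)), function(k)
      phantom_signal(ph, 900, dirs[k, ])[vox[1], vox[2], vox[3]],
      numeric(1))
    X <- -900 * cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
                      2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
                      2 * dirs[, 2] * dirs[, 3])
    d <- solve(crossprod(X), crossprod(X, log(y / s0)))
    D <- matrix(d[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
    ev <- eigen(D, symmetric = TRUE)$values
    sqrt(3 / 2 * sum((ev - mean(ev))^2) / sum(ev^2))
  }
  fa_single <- fit_fa(c(23, 16, 16))   # x-fiber lobe
  fa_cross <- fit_fa(c(16, 16, 21))    # crossing band
  expect_gt(fa_single, 0.6)
  expect_lt(fa_cross, fa_single - 0.2)
})

test_that("the clean forward simulation is exact and reproducible", {
  ph <- default_phantom()
  sch <- small_scheme()
  sim <- simulate_series(ph, sch, corruption_spec(sigma = 0))
  for (v in c(1, 7, 20))
    expect_identical(sim$series$data[, , , v],
                     phantom_signal(ph, sch$bvals[v], sch$directions[v, ]))
  expect_identical(sim$series$data, sim$clean$data)

  sim2 <- simulate_series(ph, sch, corruption_spec(sigma = 3, seed = 4))
  sim3 <- simulate_series(ph, sch, corruption_spec(sigma = 3, seed = 4))
  expect_identical(sim2$series$data, sim3$series$data)
})

test_that("dropout slices attenuate exactly in the noiseless limit", {
  ph <- default_phantom()
  sch <- small_scheme()
  drops <- data.frame(volume = c(2, 5), slice = c(14, 18), factor = 0.2)
  sim <- simulate_series(ph, sch, corruption_spec(dropouts = drops))
  for (i in 1:2)
    expect_equal(mean(sim$series$data[, , drops$slice[i], drops$volume[i]]),
                 0.2 * mean(sim$clean$data[, , drops$slice[i], drops$volume[i]]))
  expect_error(corruption_spec(dropouts = data.frame(volume = 1, slice = 1,
                                                     factor = 1.2)),
               "attenuation")
  expect_error(corruption_spec(hyper = data.frame(volume = 1, slice = 1,
                                                  gain = 0.5)),
               "gain")
})

test_that("simulated noise has Rician statistics", {
  # voxels of the b = 0 volumes act as repeated draws: the observed mean
  # magnitude should match the analytic Rician mean voxel-wise
  ph <- default_phantom()
  sigma <- 5
  sch <- gradient_scheme(rep(0, 12), matrix(0, 12, 3))
  sim <- simulate_series(ph, sch, corruption_spec(sigma = sigma, seed = 2))
  eta <- ph$s0[ph$mask]
  observed <- apply(sim$series$data, 1:3, mean)[ph$mask]
  predicted <- sigma * dwimotion:::rician_mean_factor(eta / sigma)
  expect_lt(abs(mean(observed) - mean(predicted)) / mean(predicted), 0.01)
})

test_that("motion corrupts volumes by the specified rigid transforms", {
  ph <- default_phantom()
  sch <- small_scheme()
  tr <- motion_trace(matrix(0, length(sch), 6))
  tr[3, ] <- c(5, -2, 0, 0, 0, 10)
  sim <- simulate_series(ph, sch, corruption_spec(trace = tr))
  R <- euler_to_rotation(c(0, 0, 10))
  expected <- apply_rigid(
    phantom_signal(ph, sch$bvals[3], drop(crossprod(R, sch$directions[3, ]))),
    tr[3, ], ph$voxel_size)
  expect_identical(sim$series$data[, , , 3], expected)
  expect_identical(sim$series$data[, , , 1], sim$clean$data[, , , 1])
})

test_that("opposed-blip warps conserve mass and displace symmetrically", {
  ph <- default_phantom()
  v <- phantom_signal(ph, 0, c(0, 0, 1))
  d <- dim(v)

  zero <- array(0, d)
  pair0 <- simulate_blip_pair(v, zero, "y")
  expect_identical(pair0$plus, v)
  expect_identical(pair0$minus, v)

  x <- (slice.index(v, 1) - d[1] / 2) / d[1]
  fieldmap <- 60 * exp(-8 * x^2)  # smooth bump, Hz
  pair <- simulate_blip_pair(v, fieldmap, "y", readout_scaling = 0.04)
  expect_lt(abs(sum(pair$plus) - sum(v)) / sum(v), 1e-3)
  expect_lt(abs(sum(pair$minus) - sum(v)) / sum(v), 1e-3)

  # a delta feature lands symmetrically about its true position
  delta <- array(0, d)
  delta[16, 16, 16] <- 1
  fm <- array(50, d)
  pd <- simulate_blip_pair(delta, fm, "y", readout_scaling = 0.05)
  centroid <- function(img) sum(slice.index(img, 2) * img) / sum(img)
  expect_equal(centroid(pd$plus) - 16, 16 - centroid(pd$minus),
               tolerance = 1e-9)
  expect_equal(centroid(pd$plus), 16 + 50 * 0.05, tolerance = 1e-9)

  expect_error(simulate_blip_pair(v, array(1e4, d), "y"), "half the field")
})
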