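test_that("electrostatic energy matches closed forms", {
  expect_equal(electrostatic_energy(matrix(c(1, 0, 0), 1, 3)), 0)
  two <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(electrostatic_energy(list(two), global_weight = 1), sqrt(2))
  # coincident and antipodal pairs are degenerate
  expect_equal(electrostatic_energy(rbind(c(1, 0, 0), c(1, 0, 0))),
               .Machine$double.xmax)
  expect_equal(electrostatic_energy(rbind(c(1, 0, 0), c(-1, 0, 0))),
               .Machine$double.xmax)
})

test_that("energy is invariant under antipodal flips", {
  withr::with_seed(11, {
    U <- matrix(rnorm(24), ncol = 3)
    U <- U / sqrt(rowSums(U^2))
    e0 <- electrostatic_energy(U)
    for (i in c(1, 4, 8)) {
      V <- U
      V[i, ] <- -V[i, ]
      expect_equal(electrostatic_energy(V), e0)
    }
  })
})

test_that("optimized direction sets beat random ones", {
  opt <- design_scheme(0, list(c(1000, 6)), seed = 4, restarts = 5,
                       max_iter = 150)
  e_opt <- electrostatic_energy(opt$directions)
  rand_e <- withr::with_seed(21, vapply(1:1000, function(i) {
    U <- matrix(rnorm(18), ncol = 3)
    electrostatic_energy(U / sqrt(rowSums(U^2)))
  }, numeric(1)))
  expect_lte(e_opt, min(rand_e))
})

test_that("designed shells beat the median random shell", {
  sch <- small_scheme()
  d400 <- sch$directions[round(sch$bvals) == 400, ]
  e <- electrostatic_energy(d400)
  rand_e <- withr::with_seed(22, vapply(1:200, function(i) {
    U <- matrix(rnorm(3 * nrow(d400)), ncol = 3)
    electrostatic_energy(U / sqrt(rowSums(U^2)))
  }, numeric(1)))
  expect_lte(e, median(rand_e))
})

test_that("scheme design is reproducible and sized correctly", {
  a <- design_scheme(2, list(c(400, 5), c(900, 7)), seed = 8,
                     restarts = 3, max_iter = 50)
  b <- design_scheme(2, list(c(400, 5), c(900, 7)), seed = 8,
                     restarts = 3, max_iter = 50)
  expect_identical(a$directions, b$directions)
  expect_equal(length(a), 14)
  expect_error(design_scheme(0, list()), "at least one")

  one <- design_scheme(0, list(c(1000, 1)), seed = 1, restarts = 1,
                       max_iter = 5)
  expect_equal(length(one), 1)
  expect_equal(sum(one$directions^2), 1)
  expect_equal(electrostatic_energy(one$directions), 0)
})

test_that("incremental ordering balances shells in every prefix", {
  sch <- order_incrementally(
    design_scheme(11, list(c(400, 28), c(900, 56)), seed = 3,
                  restarts = 2, max_iter = 60))
  expect_equal(length(sch), 95)
  expect_true(all(sort(sch$temporal_order) == 1:95))

  dw <- which(!is_b0(sch))
  shell <- round(sch$bvals[dw])
  # first third of the DW volumes: counts within 1 of the 1:2 shell ratio
  pre <- shell[1:28]
  expect_lte(abs(sum(pre == 400) - 28 / 3), 1)
  expect_lte(abs(sum(pre == 900) - 56 / 3), 1)
  # every prefix stays within one volume of proportionality
  for (t in seq_along(shell)) {
    expect_lte(abs(sum(shell[1:t] == 400) - t / 3), 1 + 1e-9)
    expect_lte(abs(sum(shell[1:t] == 900) - 2 * t / 3), 1 + 1e-9)
  }
  # every contiguous window of 12 DW volumes contains both shells
  for (t in seq_len(length(shell) - 11))
    expect_equal(length(unique(shell[t:(t + 11)])), 2)
  # b = 0 volumes are spread out: gaps between consecutive b0 positions
  b0_pos <- which(is_b0(sch))
  gaps <- diff(b0_pos)
  expect_lte(max(gaps), 2 * ceiling(95 / 11))

  expect_identical(order_incrementally(design_scheme(1, list(), seed = 1))$temporal_order,
                   1L)
})

test_that("ordered same-shell prefixes stay angularly uniform", {
  sch <- order_incrementally(
    design_scheme(4, list(c(400, 12), c(900, 20)), seed = 5,
                  restarts = 3, max_iter = 80))
  for (b in c(400, 900)) {
    dirs <- sch$directions[round(sch$bvals) == b, , drop = FALSE]
    for (k in 6:nrow(dirs)) {
      e_prefix <- electrostatic_energy(dirs[1:k, , drop = FALSE])
      rand_e <- withr::with_seed(k, vapply(1:200, function(i) {
        electrostatic_energy(dirs[sample(nrow(dirs), k), , drop = FALSE])
      }, numeric(1)))
      expect_lte(e_prefix, mean(rand_e))
    }
  }
})

test_that("gradient tables rotate with the volume transforms", {
  sch <- small_scheme()
  n <- length(sch)
  expect_equal(rotate_gradient_table(sch, matrix(0, n, 6))$directions,
               sch$directions)

  tr <- matrix(0, n, 6)
  tr[, 6] <- 90  # 90 degrees about z
  rot <- rotate_gradient_table(sch, tr)
  i <- which(!is_b0(sch))[1]
  u <- sch$directions[i, ]
  expect_equal(rot$directions[i, ], c(-u[2], u[1], u[3]), tolerance = 1e-12)
  expect_identical(rot$bvals, sch$bvals)
  expect_identical(rot$temporal_order, sch$temporal_order)

  rnd <- withr::with_seed(2, matrix(rnorm(n * 6, sd = 20), n, 6))
  rot2 <- rotate_gradient_table(sch, rnd)
  expect_equal(sqrt(rowSums(rot2$directions[!is_b0(sch), ]^2)),
               rep(1, sum(!is_b0(sch))), tolerance = 1e-12)
})
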