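test_that("index set enumeration has the expected cardinalities", {
  counts <- vapply(c(0, 2, 4, 6), function(N) nrow(shore_index_set(N)),
                   numeric(1))
  # sum over even l <= N of (N - l + 1)(2l + 1)
  expect_equal(counts, c(1, 8, 29, 72))
  expect_equal(shore_index_set(0), data.frame(n = 0, l = 0, m = 0))
  idx <- shore_index_set(6)
  expect_true(all(idx$l %% 2 == 0))
  expect_true(all(idx$l <= idx$n & idx$n <= 6 & abs(idx$m) <= idx$l))
  expect_error(shore_index_set(3), "even")
  expect_error(shore_index_set(-2), "even")
})

test_that("basis columns vanish correctly at the q-space origin", {
  idx <- shore_index_set(4)
  B <- build_basis(idx, rbind(c(0, 0, 0), c(10, 5, -3)), zeta = 700)
  origin_row <- B$design[1, ]
  expect_true(all(origin_row[idx$l > 0] == 0))
  expect_true(all(origin_row[idx$l == 0] != 0))
  expect_error(build_basis(idx, matrix(1, 1, 3), zeta = 0), "positive")
})

test_that("the basis is antipodally symmetric (even degrees only)", {
  idx <- shore_index_set(6)
  q <- withr::with_seed(5, matrix(rnorm(30, sd = 15), ncol = 3))
  expect_equal(build_basis(idx, -q, 700)$design,
               build_basis(idx, q, 700)$design, tolerance = 1e-12)
})

test_that("the basis is orthonormal under its q-space measure", {
  # numerical quadrature oracle: Gauss-Legendre radially (weight q^2) and
  # in cos(theta), uniform in phi
  idx <- shore_index_set(4)
  zeta <- 700
  gl <- pracma::gaussLegendre(120, 0, 250)
  ct <- pracma::gaussLegendre(24, -1, 1)
  nphi <- 48
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  grid <- expand.grid(iq = seq_along(gl$x), ic = seq_along(ct$x),
                      ip = seq_len(nphi))
  q <- gl$x[grid$iq]
  cz <- ct$x[grid$ic]
  sz <- sqrt(1 - cz^2)
  pts <- cbind(q * sz * cos(phi[grid$ip]), q * sz * sin(phi[grid$ip]),
               q * cz)
  wt <- gl$w[grid$iq] * q^2 * ct$w[grid$ic] * (2 * pi / nphi)
  G <- crossprod(build_basis(idx, pts, zeta)$design * sqrt(wt))
  expect_equal(diag(G), rep(1, nrow(idx)), tolerance = 1e-6)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-3)
})

test_that("regularization operators follow l(l+1) and n(n+1)", {
  idx <- shore_index_set(6)
  reg <- regularization_operators(idx, 1e-8, 1e-8)
  expect_equal(reg$L_diag[idx$n == 0 & idx$l == 0], 0)
  expect_equal(reg$N_diag[idx$n == 0 & idx$l == 0], 0)
  expect_equal(unique(reg$L_diag[idx$l == 2]), 6)
  expect_equal(unique(reg$N_diag[idx$n == 2]), 6)
  expect_equal(unique(reg$L_diag[idx$l == 6]), 42)
  expect_equal(unique(reg$N_diag[idx$n == 6]), 42)
  expect_error(regularization_operators(idx, -1, 0), "non-negative")
})

test_that("noiseless signals refit exactly (forward-generation oracle)", {
  B <- build_basis(shore_index_set(6), q_points(dense_scheme()), 700)
  reg0 <- regularization_operators(shore_index_set(6), 0, 0)
  cstar <- withr::with_seed(7, rnorm(72))
  signal <- B$design %*% cstar
  fit <- fit_shore(signal, B, reg = reg0)
  expect_equal(drop(fit$coefficients), cstar, tolerance = 1e-8)

  # round trip through prediction reproduces the signal
  expect_equal(drop(predict_signal(fit)), drop(signal), tolerance = 1e-8)
  expect_equal(drop(predict_signal(fit, q_points(dense_scheme()))),
               drop(signal), tolerance = 1e-8)

  # zero signal gives zero coefficients, zero prediction
  z <- fit_shore(rep(0, nrow(B$design)), B, reg = reg0)
  expect_equal(drop(z$coefficients), rep(0, 72))
  expect_equal(drop(predict_signal(z)), rep(0, nrow(B$design)))
})

test_that("zero weights reproduce the clean-subset fit", {
  sch <- dense_scheme()
  B <- build_basis(shore_index_set(6), q_points(sch), 700)
  reg0 <- regularization_operators(shore_index_set(6), 0, 0)
  cstar <- withr::with_seed(8, rnorm(72))
  signal <- drop(B$design %*% cstar)
  bad <- withr::with_seed(9, sample(length(signal), 40))
  corrupted <- signal
  corrupted[bad] <- corrupted[bad] * 5 + 100
  w <- rep(1, length(signal))
  w[bad] <- 0

  fit_w <- fit_shore(corrupted, B, weights = w, reg = reg0)
  Bsub <- build_basis(shore_index_set(6), q_points(sch)[-bad, ], 700)
  fit_sub <- fit_shore(signal[-bad], Bsub, reg = reg0)
  expect_equal(fit_w$coefficients, fit_sub$coefficients, tolerance = 1e-10)
})

test_that("rank-deficient unregularized fits are rejected with advice", {
  # a 2-shell scheme has too few distinct radial magnitudes for order 6
  B <- build_basis(shore_index_set(6), q_points(small_scheme()), 700)
  reg0 <- regularization_operators(shore_index_set(6), 0, 0)
  expect_error(fit_shore(rep(1, nrow(B$design)), B, reg = reg0),
               "regularization")
})

test_that("l = 0 coefficients are rotation equivariant", {
  sch <- dense_scheme()
  qp <- q_points(sch)
  idx <- shore_index_set(6)
  reg <- regularization_operators(idx, 1e-8, 1e-8)
  cstar <- withr::with_seed(10, rnorm(72))
  signal <- drop(build_basis(idx, qp, 700)$design %*% cstar)

  R <- euler_to_rotation(c(20, -35, 50))
  fit_a <- fit_shore(signal, build_basis(idx, qp, 700), reg = reg)
  fit_b <- fit_shore(signal, build_basis(idx, qp %*% t(R), 700), reg = reg)
  l0 <- idx$l == 0
  expect_equal(fit_a$coefficients[l0, ], fit_b$coefficients[l0, ],
               tolerance = 1e-6)
})

test_that("stronger angular regularization shrinks the angular roughness", {
  sch <- dense_scheme()
  B <- build_basis(shore_index_set(6), q_points(sch), 700)
  idx <- shore_index_set(6)
  signal <- withr::with_seed(12,
    drop(B$design %*% rnorm(72)) + rnorm(nrow(B$design), sd = 0.1))
  roughness <- vapply(c(0, 1e-8, 1e-6, 1e-4, 1e-2), function(ll) {
    f <- fit_shore(signal, B,
                   reg = regularization_operators(idx, ll, 1e-8))
    sqrt(sum((idx$l * (idx$l + 1) * f$coefficients)^2))
  }, numeric(1))
  expect_true(all(diff(roughness) <= 1e-8))
})
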