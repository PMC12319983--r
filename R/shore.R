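# SHORE q-space signal basis: radial generalized-Laguerre functions times
# real even-degree spherical harmonics, orthonormal under q^2 dq dOmega.
# The radial truncation keeps all n = l..order_max, which gives 72 basis
# functions at order 6 (the alternative limit (order + l)/2 gives 50).

#' Enumerate the SHORE basis index set
#'
#' Indices `(n, l, m)` with even `l` from 0 to `order_max`,
#' `n = l, ..., order_max`, and `m = -l, ..., l`, in deterministic
#' lexicographic order (l, then n, then m). The count is
#' `sum over even l of (order_max - l + 1)(2l + 1)`: 1, 8, 29 and 72 for
#' orders 0, 2, 4 and 6.
#'
#' @param order_max even non-negative integer.
#' @return data.frame with columns `n`, `l`, `m`.
#' @export
shore_index_set <- function(order_max) {
  if (length(order_max) != 1 || order_max < 0 || order_max %% 2 != 0)
    stopf("order_max must be an even non-negative integer")
  rows <- list()
  for (l in seq(0, order_max, by = 2))
    for (n in l:order_max)
      rows[[length(rows) + 1]] <- data.frame(n = n, l = l, m = -l:l)
  do.call(rbind, rows)
}

# generalized Laguerre polynomials L_k^a(x) by the standard recurrence
genlaguerre <- function(k, a, x) {
  if (k == 0) return(rep(1, length(x)))
  Lm1 <- rep(1, length(x))
  L <- 1 + a - x
  if (k == 1) return(L)
  for (j in 2:k) {
    Lp <- ((2 * j - 1 + a - x) * L - (j - 1 + a) * Lm1) / j
    Lm1 <- L
    L <- Lp
  }
  L
}

# real spherical harmonics for all (l, m) up to lmax at unit directions U;
# returns a list sh[[l + 1]] = matrix [npts x (2l + 1)] with columns
# m = -l..l. Convention: m < 0 -> sqrt(2) * N * P_l^|m|(cos theta) *
# sin(|m| phi); m = 0 -> N * P_l^0; m > 0 -> sqrt(2) * N * P_l^m * cos(m phi)
# (Condon-Shortley phase included in the associated Legendre functions).
real_sh <- function(U, lmax) {
  z <- pmin(1, pmax(-1, U[, 3]))
  phi <- atan2(U[, 2], U[, 1])
  out <- vector("list", lmax + 1)
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, z)          # (l + 1) x npts, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    Y <- matrix(0, length(z), 2 * l + 1)
    for (m in 0:l) {
      N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        Y[, l + 1] <- N * P[1, ]
      } else {
        Y[, l + 1 + m] <- sqrt(2) * N * P[m + 1, ] * cos(m * phi)
        Y[, l + 1 - m] <- sqrt(2) * N * P[m + 1, ] * sin(m * phi)
      }
    }
    out[[l + 1]] <- Y
  }
  out
}

#' Build a SHORE basis design matrix
#'
#' Evaluates every basis function at the given q-space points:
#' entry (i, j) is `X_{n_j l_j}(|q_i|, zeta) * Y_{l_j m_j}(u_i)` with the
#' radial part
#' `X_nl(q) = kappa_nl (q^2/zeta)^{l/2} exp(-q^2/(2 zeta))
#'  L_{n-l}^{l+1/2}(q^2/zeta)`,
#' `kappa_nl = sqrt(2 (n-l)! / (zeta^{3/2} Gamma(n + 3/2)))`, and real
#' even-degree spherical harmonics `Y_lm`. At the q-space origin only the
#' `l = 0` columns are nonzero.
#'
#' @param index_set data.frame from [shore_index_set()] (or an even order
#'   to enumerate one).
#' @param qpts N x 3 matrix of q-space points (see [q_points()]).
#' @param zeta positive scale parameter (same units as q^2).
#' @return An object of class `shore_basis`: list with `index_set`, `zeta`,
#'   `order_max`, and the N x C `design` matrix.
#' @export
build_basis <- function(index_set, qpts, zeta = 700) {
  if (is.numeric(index_set) && length(index_set) == 1)
    index_set <- shore_index_set(index_set)
  if (zeta <= 0) stopf("zeta must be positive")
  qpts <- as.matrix(qpts)
  qmag <- sqrt(rowSums(qpts^2))
  U <- qpts
  nz <- qmag > 0
  U[nz, ] <- U[nz, , drop = FALSE] / qmag[nz]
  U[!nz, ] <- rep(c(0, 0, 1), each = sum(!nz))  # arbitrary; l > 0 vanish at q = 0

  lmax <- max(index_set$l)
  sh <- real_sh(U, lmax)
  x <- qmag^2 / zeta

  C <- nrow(index_set)
  design <- matrix(0, nrow(qpts), C)
  # radial part is shared by all m of one (n, l)
  nl <- unique(index_set[, c("n", "l")])
  rad <- list()
  for (r in seq_len(nrow(nl))) {
    n <- nl$n[r]; l <- nl$l[r]
    kappa <- sqrt(2 * exp(lgamma(n - l + 1) - lgamma(n + 1.5)) / zeta^1.5)
    xr <- if (l == 0) rep(1, length(x)) else x^(l / 2)
    rad[[paste(n, l)]] <- kappa * xr * exp(-x / 2) *
      genlaguerre(n - l, l + 0.5, x)
  }
  for (j in seq_len(C)) {
    n <- index_set$n[j]; l <- index_set$l[j]; m <- index_set$m[j]
    design[, j] <- rad[[paste(n, l)]] * sh[[l + 1]][, m + l + 1]
  }
  structure(list(index_set = index_set, zeta = zeta,
                 order_max = max(index_set$n), design = design),
            class = "shore_basis")
}

#' @export
print.shore_basis <- function(x, ...) {
  cat(sprintf("SHORE basis: order %d, zeta %g, %d functions, %d q-points\n",
              x$order_max, x$zeta, nrow(x$index_set), nrow(x$design)))
  invisible(x)
}

#' Radial/angular roughness penalty operators
#'
#' Diagonal operators with entries `l(l + 1)` (angular) and `n(n + 1)`
#' (radial) per basis function, penalizing high angular and radial
#' frequencies in the regularized fit.
#'
#' @param index_set data.frame from [shore_index_set()].
#' @param lambda_l,lambda_n non-negative regularization strengths.
#' @return list with `L_diag`, `N_diag`, `lambda_l`, `lambda_n`.
#' @export
regularization_operators <- function(index_set, lambda_l = 1e-8,
                                     lambda_n = 1e-8) {
  if (lambda_l < 0 || lambda_n < 0)
    stopf("regularization strengths must be non-negative")
  list(L_diag = index_set$l * (index_set$l + 1),
       N_diag = index_set$n * (index_set$n + 1),
       lambda_l = lambda_l, lambda_n = lambda_n)
}

#' Fit SHORE coefficients by weighted regularized least squares
#'
#' Solves, per signal column,
#' `argmin_c ||W (Phi c - E)||^2 + lambda_l ||L c||^2 + lambda_n ||N c||^2`
#' via the normal equations
#' `(Phi' W^2 Phi + lambda_l L^2 + lambda_n N^2) c = Phi' W^2 E`
#' with a Cholesky solve. Weights lie in `[0, 1]` and multiply rows
#' (q-space samples). Columns sharing a weight vector share one
#' factorization.
#'
#' @param signal numeric vector (one voxel, length Q) or Q x V matrix.
#' @param basis a [build_basis()] object whose design has Q rows.
#' @param weights `NULL` (all ones), a length-Q vector, or a Q x V matrix.
#' @param reg `NULL` (unregularized) or [regularization_operators()].
#' @return An object of class `shore_coefficients`: list with
#'   `coefficients` (C x V matrix) and `basis`.
#' @export
fit_shore <- function(signal, basis, weights = NULL, reg = NULL) {
  E <- as.matrix(signal)
  Phi <- basis$design
  Q <- nrow(Phi)
  if (nrow(E) != Q)
    stopf("signal has %d rows but the basis has %d q-points", nrow(E), Q)
  V <- ncol(E)
  if (is.null(weights)) weights <- rep(1, Q)
  W <- as.matrix(weights)
  if (nrow(W) != Q) stopf("weights must have one entry per q-point")
  if (ncol(W) == 1 && V > 1) W <- W[, rep(1, V), drop = FALSE]
  if (min(W) < 0 || max(W) > 1) stopf("weights must lie in [0, 1]")

  pen <- 0
  if (!is.null(reg))
    pen <- reg$lambda_l * reg$L_diag^2 + reg$lambda_n * reg$N_diag^2

  C <- ncol(Phi)
  coef <- matrix(0, C, V)
  # group columns that share a weight vector: one factorization per group
  key <- apply(W, 2, function(w) paste(signif(w, 12), collapse = ","))
  for (k in unique(key)) {
    cols <- which(key == k)
    w2 <- W[, cols[1]]^2
    A <- crossprod(Phi, w2 * Phi)
    diag(A) <- diag(A) + pen
    # Jacobi equilibration keeps the Cholesky factor well scaled
    s <- sqrt(diag(A))
    s[s == 0] <- 1
    As <- A / tcrossprod(s)
    ch <- tryCatch(chol(As), error = function(e) NULL)
    if (is.null(ch))
      stopf(paste("normal equations are rank deficient; add regularization",
                  "(nonzero lambda) or more sampling directions"))
    rhs <- crossprod(Phi, w2 * E[, cols, drop = FALSE])
    solve_eq <- function(b)
      backsolve(ch, forwardsolve(t(ch), b / s)) / s
    x <- solve_eq(rhs)
    for (it in 1:2)  # iterative refinement against the normal equations
      x <- x + solve_eq(rhs - A %*% x)
    coef[, cols] <- x
  }
  structure(list(coefficients = coef, basis = basis),
            class = "shore_coefficients")
}

#' @export
print.shore_coefficients <- function(x, ...) {
  cat(sprintf("SHORE coefficients: %d functions x %d voxel(s)\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Predict signal from SHORE coefficients
#'
#' Evaluates `Phi(q) c` at new q-space points with the basis (order, zeta,
#' index set) the coefficients were fitted in. With `qpts = NULL` the
#' fitting points are reused, returning the fitted values `Phi c` exactly.
#'
#' @param coefficients a [fit_shore()] result.
#' @param qpts N x 3 matrix of q-space points, or `NULL`.
#' @return numeric N x V matrix of predicted signals (a vector when a
#'   single voxel was fitted).
#' @export
predict_signal <- function(coefficients, qpts = NULL) {
  basis <- coefficients$basis
  Phi <- if (is.null(qpts)) basis$design else
    build_basis(basis$index_set, qpts, basis$zeta)$design
  out <- Phi %*% coefficients$coefficients
  if (ncol(out) == 1) drop(out) else out
}
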