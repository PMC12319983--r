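# Multi-shell direction design: antipodally symmetric Coulomb repulsion with
# a convex combination of the pooled (all-shell) energy and the mean
# per-shell energy, optimized by multi-start projected gradient descent.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# pairwise antipodal Coulomb terms; returns list(minus2, plus2) of squared
# distances ||ui-uj||^2 and ||ui+uj||^2
pair_dist2 <- function(U) {
  G <- tcrossprod(U)
  list(minus2 = pmax(2 - 2 * G, 0), plus2 = pmax(2 + 2 * G, 0))
}

#' Electrostatic repulsion energy of a multi-shell direction set
#'
#' Antipodally symmetric Coulomb energy
#' `E(S) = sum_{i<j} 1/||u_i - u_j|| + 1/||u_i + u_j||`, combined across
#' shells as `global_weight * E(all pooled) + (1 - global_weight) *
#' mean_shells E(shell)`. This balances the global angular distribution of
#' all directions against the angular distribution on each shell. A
#' coincident or antipodal pair makes the energy degenerate; the largest
#' finite double is returned so optimizers can escape.
#'
#' @param directions_by_shell a list of N_s x 3 unit-direction matrices
#'   (or a single matrix for one shell).
#' @param global_weight weight in `[0, 1]` of the pooled term.
#' @return non-negative scalar energy (`.Machine$double.xmax` when
#'   degenerate).
#' @export
electrostatic_energy <- function(directions_by_shell, global_weight = 0.5) {
  if (is.matrix(directions_by_shell))
    directions_by_shell <- list(directions_by_shell)
  if (global_weight < 0 || global_weight > 1)
    stopf("global_weight must lie in [0, 1]")
  shell_e <- vapply(directions_by_shell, pair_energy, numeric(1))
  pooled <- pair_energy(do.call(rbind, directions_by_shell))
  if (!is.finite(pooled) || any(!is.finite(shell_e)) ||
      pooled >= .Machine$double.xmax || any(shell_e >= .Machine$double.xmax))
    return(.Machine$double.xmax)
  global_weight * pooled + (1 - global_weight) * mean(shell_e)
}

pair_energy <- function(U) {
  n <- nrow(U)
  if (n < 2) return(0)
  d2 <- pair_dist2(U)
  up <- upper.tri(d2$minus2)
  dm <- sqrt(d2$minus2[up]); dp <- sqrt(d2$plus2[up])
  if (any(dm < 1e-9) || any(dp < 1e-9)) return(.Machine$double.xmax)
  sum(1 / dm) + sum(1 / dp)
}

# energy and Riemannian gradient under per-pair weights lambda (n x n,
# symmetric, zero diagonal)
weighted_energy_grad <- function(U, lambda) {
  d2 <- pair_dist2(U)
  dm <- sqrt(d2$minus2); dp <- sqrt(d2$plus2)
  diag(dm) <- Inf; diag(dp) <- Inf
  if (any(dm[lambda > 0] < 1e-9) || any(dp[lambda > 0] < 1e-9))
    return(list(value = .Machine$double.xmax, grad = matrix(0, nrow(U), 3)))
  up <- upper.tri(dm)
  value <- sum((lambda * (1 / dm + 1 / dp))[up])
  wm <- lambda / dm^3
  wp <- lambda / dp^3
  grad <- -(rowSums(wm) + rowSums(wp)) * U + wm %*% U - wp %*% U
  # project onto the tangent space of the sphere
  grad <- grad - rowSums(grad * U) * U
  list(value = value, grad = grad)
}

#' Design a multi-shell gradient sampling scheme
#'
#' Places `n_dirs` unit directions on each shell by minimizing
#' [electrostatic_energy()] with multi-start projected gradient descent on
#' the sphere. The result is deterministic for a fixed seed. b = 0 volumes
#' are prepended with zero directions; call [order_incrementally()] to
#' interleave them and set the acquisition order.
#'
#' @param n_b0 number of unweighted (b = 0) volumes.
#' @param shells list of `c(b, n_dirs)` pairs (b in s/mm^2).
#' @param global_weight pooled-energy weight in `[0, 1]`.
#' @param seed RNG seed for the restarts.
#' @param restarts number of random initializations.
#' @param max_iter gradient-descent iterations per restart.
#' @return a [gradient_scheme()] with `n_b0 + sum(n_dirs)` volumes.
#' @export
design_scheme <- function(n_b0, shells, global_weight = 0.5, seed = 1,
                          restarts = 20, max_iter = 300) {
  if (n_b0 < 0) stopf("n_b0 must be non-negative")
  if (length(shells) == 0 && n_b0 == 0)
    stopf("need at least one shell or one b = 0 volume")
  bs <- vapply(shells, `[`, numeric(1), 1)
  ns <- vapply(shells, function(s) as.integer(s[2]), integer(1))
  if (length(ns) && any(ns < 1)) stopf("each shell needs at least 1 direction")

  n_dw <- sum(ns)
  dirs <- matrix(0, 0, 3)
  if (n_dw > 0) {
    shell_of <- rep(seq_along(ns), ns)
    lambda <- global_weight +
      (1 - global_weight) / length(ns) * outer(shell_of, shell_of, "==")
    diag(lambda) <- 0
    dirs <- with_seed(seed, {
      best <- NULL; best_val <- Inf
      for (r in seq_len(restarts)) {
        U <- matrix(rnorm(3 * n_dw), ncol = 3)
        U <- U / sqrt(rowSums(U^2))
        fit <- descend_sphere(U, lambda, max_iter)
        if (fit$value < best_val) { best_val <- fit$value; best <- fit$U }
      }
      best
    })
  }
  bvals <- c(rep(0, n_b0), rep(bs, ns))
  directions <- rbind(matrix(0, n_b0, 3), dirs)
  gradient_scheme(bvals, directions)
}

descend_sphere <- function(U, lambda, max_iter) {
  eg <- weighted_energy_grad(U, lambda)
  step <- 1e-3
  for (it in seq_len(max_iter)) {
    cand <- U - step * eg$grad
    cand <- cand / sqrt(rowSums(cand^2))
    eg2 <- weighted_energy_grad(cand, lambda)
    if (eg2$value < eg$value) {
      U <- cand; eg <- eg2; step <- step * 1.2
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(U = U, value = eg$value)
}

#' Order a scheme incrementally
#'
#' Sets the acquisition order so that (a) b = 0 volumes are interleaved
#' approximately evenly across the series, (b) every temporal prefix of
#' diffusion-weighted volumes keeps per-shell counts within one of the
#' overall shell ratio, and (c) within each shell successive directions are
#' placed greedily to maximize the minimum (antipodal) angular distance to
#' their recent same-shell predecessors. The angular coverage of each shell
#' therefore grows uniformly, and neighbouring directions are separated in
#' time, so any temporal segment of the acquisition samples the sphere
#' nearly uniformly.
#'
#' @param scheme a [gradient_scheme()].
#' @param recent number of preceding same-shell placements considered in
#'   the greedy farthest-point step (default: all of them, which also
#'   keeps every prefix well spread; a small window separates only
#'   temporal neighbours).
#' @return the scheme with rows permuted into acquisition order;
#'   `temporal_order` records the permutation applied (new row t = old row
#'   `temporal_order[t]`).
#' @export
order_incrementally <- function(scheme, recent = Inf) {
  n <- length(scheme)
  if (n == 1) return(scheme)
  b0 <- is_b0(scheme)
  idx_b0 <- which(b0)
  sid <- shell_ids(scheme)
  shells <- sort(unique(sid[!b0]))

  slots_b0 <- integer(0)
  if (length(idx_b0)) {
    slots_b0 <- unique(round(seq(1, n, length.out = length(idx_b0))))
    while (length(slots_b0) < length(idx_b0))  # rounding collisions
      slots_b0 <- sort(c(slots_b0, setdiff(seq_len(n), slots_b0)[1]))
  }
  slots_dw <- setdiff(seq_len(n), slots_b0)

  # greedy shell-quota + farthest-point ordering of the DW volumes
  remaining <- lapply(shells, function(s) which(sid == s & !b0))
  totals <- lengths(remaining)
  p <- totals / sum(totals)
  placed_dirs <- lapply(shells, function(s) integer(0))
  counts <- rep(0, length(shells))
  dw_order <- integer(0)
  for (t in seq_len(sum(totals))) {
    deficit <- t * p - counts
    deficit[lengths(remaining) == 0] <- -Inf
    s <- which.max(deficit + 1e-9 * p)  # ties favour the larger shell
    cand <- remaining[[s]]
    prev <- placed_dirs[[s]]
    if (length(prev) == 0) {
      pick <- cand[1]
    } else {
      recent_idx <- utils::tail(prev, recent)
      Up <- scheme$directions[recent_idx, , drop = FALSE]
      Uc <- scheme$directions[cand, , drop = FALSE]
      ang <- acos(pmin(abs(Uc %*% t(Up)), 1))  # pmin keeps the matrix shape
      score <- apply(ang, 1, min)
      pick <- cand[which.max(score)]
    }
    remaining[[s]] <- setdiff(remaining[[s]], pick)
    placed_dirs[[s]] <- c(placed_dirs[[s]], pick)
    counts[s] <- counts[s] + 1
    dw_order <- c(dw_order, pick)
  }

  ord <- integer(n)
  ord[slots_b0] <- idx_b0
  ord[slots_dw] <- dw_order
  gradient_scheme(scheme$bvals[ord], scheme$directions[ord, , drop = FALSE],
                  temporal_order = ord, pe_axis = scheme$pe_axis)
}
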