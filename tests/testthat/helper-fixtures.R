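# Shared fixtures, built in code and cached for the duration of the run.

# a small two-shell scheme for plumbing tests (fast to optimize)
small_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- order_incrementally(
        design_scheme(4, list(c(400, 10), c(900, 16)),
                      seed = 3, restarts = 4, max_iter = 100))
    cache
  }
})

# densely sampled multi-shell scheme: ten b-values spread to b = 6000 keep
# the order-6 SHORE design matrix well conditioned (distinct radial
# magnitudes for every radial order)
dense_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      shells <- lapply(seq(300, 6000, length.out = 10),
                       function(b) c(b, 30))
      cache <<- design_scheme(4, shells, seed = 2, restarts = 2,
                              max_iter = 60)
    }
    cache
  }
})

default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom()
    cache
  }
})

# phantom without partial-volume smoothing: voxels deep inside a region
# carry exactly that region's tensor (closed-form signal checks)
sharp_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_phantom(phantom_spec(smoothing = 0))
    cache
  }
})

# a random series with reproducible contents
random_series <- function(dims = c(8, 8, 6), scheme = small_scheme(),
                          seed = 42) {
  withr::with_seed(seed, {
    data <- array(runif(prod(dims) * length(scheme), 10, 100),
                  c(dims, length(scheme)))
    dwi_series(data, scheme, voxel_size = c(2, 2, 2.5))
  })
}

# interior (eroded) region of a mask: voxels whose full neighbourhood is
# inside, where interpolation error statements apply
erode_mask <- function(mask, iterations = 2) {
  for (i in seq_len(iterations)) {
    m <- mask
    d <- dim(mask)
    m[-1, , ] <- m[-1, , ] & mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] & mask[-1, , ]
    m[, -1, ] <- m[, -1, ] & mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] & mask[, -1, ]
    m[, , -1] <- m[, , -1] & mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] & mask[, , -1]
    mask <- m
  }
  mask
}
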