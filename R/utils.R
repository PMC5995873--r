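# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; generator kinds pinned for cross-version reproducibility.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# draw n values from a {fixed, uniform, lognormal} distribution spec
drawDistribution <- function(n, kind, params) {
  switch(kind,
    fixed = rep(params[["value"]], n),
    uniform = stats::runif(n, params[["min"]], params[["max"]]),
    lognormal = stats::rlnorm(n, params[["meanlog"]], params[["sdlog"]]),
    stop("unknown distribution kind: ", kind)
  )
}

# normalized 1D Gaussian kernel, radius 3*sigma (at least 1)
gaussKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D derivative-of-Gaussian kernel, for use by correlation (as
# .convolveAxis applies it); normalized so a unit-slope ramp returns 1
gaussDerivKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- x * exp(-x^2 / (2 * sigma^2))
  k / sum(x * k)
}

# separable Gaussian smoothing of a 3D array (sigma in voxels)
gaussSmooth3D <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussKernel(sigma)
  d <- dim(arr)
  for (ax in 0:2) arr <- .convolveAxis(arr, d, k, ax)
  arr
}

# Gaussian-derivative gradient along one array axis (0=z, 1=y, 2=x)
gaussGradientAxis <- function(arr, sigma, axis) {
  d <- dim(arr)
  g <- gaussKernel(sigma)
  dg <- gaussDerivKernel(sigma)
  for (ax in 0:2) {
    arr <- .convolveAxis(arr, d, if (ax == axis) dg else g, ax)
  }
  arr
}

roundToOdd <- function(x) {
  w <- as.integer(round(x))
  if (w %% 2L == 0L) w <- w + 1L
  max(3L, w)
}

logProvenance <- function(entries, fmt, ...) c(entries, sprintf(fmt, ...))
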