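# Internal helpers shared across modules.

# Mirror (reflective, edge not repeated? -- edge repeated: "symmetric" padding)
# indices for positions 1-h .. n+h into 1..n. Uses symmetric reflection with
# edge duplication, the usual "mirror" boundary of image-processing toolkits.
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  # reflect into [1, 2n] then fold
  period <- 2L * n
  j <- ((idx - 1L) %% period + period) %% period # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

# Pad a matrix by h rows/cols on each side with mirror boundary.
mirror_pad <- function(m, h) {
  ri <- mirror_index(seq(1L - h, nrow(m) + h), nrow(m))
  ci <- mirror_index(seq(1L - h, ncol(m) + h), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with a point-symmetric kernel and mirror boundary handling.
# All kernels in this package (LoG, Gaussian derivative pairs, even Gabor)
# are point-symmetric, so FFT correlation equals convolution.
convolve_mirror <- function(img, kernel) {
  stopifnot(nrow(kernel) %% 2L == 1L, ncol(kernel) %% 2L == 1L)
  h <- max((nrow(kernel) - 1L) %/% 2L, (ncol(kernel) - 1L) %/% 2L)
  if (nrow(img) <= h || ncol(img) <= h) {
    stop("image (", nrow(img), "x", ncol(img),
         ") is smaller than the kernel support half-width ", h)
  }
  padded <- mirror_pad(img, h)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(h + 1L):(h + nrow(img)), (h + 1L):(h + ncol(img)), drop = FALSE]
}

# Evaluate a function with the RNG seeded locally; the caller's RNG state is
# untouched (single-seed determinism without global side effects).
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# Clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
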