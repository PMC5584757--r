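#' Non-maximum suppression configuration
#'
#' Two windows govern candidate clean-up: candidates are first relocated to
#' the brightest pixel in their `w1`-pixel local area, then deduplicated so
#' that only the brightest candidate survives within any `w2`-pixel area.
#' `w1` is the full side of the square relocation window (half-width
#' `floor(w1/2)`); `w2` is a Chebyshev suppression radius.
#'
#' @param w1 relocation window parameter in pixels (default 20).
#' @param w2 suppression window parameter in pixels (default 10).
#' @return A list of class `nms_config`.
#' @export
nms_config <- function(w1 = 20, w2 = 10) {
  stopifnot(w1 > 0, w2 > 0)
  structure(list(w1 = w1, w2 = w2), class = "nms_config")
}

# 3x3 max filter with -Inf padding (used for strict local-maximum tests).
max3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    out <- pmax(out, p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }
  out
}

# Same but excluding the centre cell.
max3x3_ring <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1L && dc == 1L) next
    out <- pmax(out, p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }
  out
}

# Scale-normalized determinant of the Hessian at scale sigma.
doh_layer <- function(image, sigma) {
  h <- max(ceiling(3 * sigma), 2L)
  g <- seq(-h, h)
  gauss <- exp(-g^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  d1 <- -g / sigma^2 * gauss
  d2 <- (g^2 - sigma^2) / sigma^4 * gauss
  # matrix[row = y, col = x]; outer(y-part, x-part)
  lxx <- convolve_mirror(image, outer(gauss, d2))
  lyy <- convolve_mirror(image, outer(d2, gauss))
  lxy <- convolve_mirror(image, outer(d1, d1))
  sigma^4 * (lxx * lyy - lxy^2)
}

#' Detect candidate bouton locations
#'
#' Dense determinant-of-Hessian detector: builds a scale-space of
#' scale-normalized Hessian determinants and returns strict local maxima over
#' position and scale whose response exceeds the threshold. This fulfils the
#' same contract as fast-Hessian (SURF-style) keypoint detectors while
#' guaranteeing availability without patented-era box-filter code.
#'
#' @param image numeric matrix, typically the LoG-[enhance()]d projection.
#' @param threshold response cutoff. With `threshold_relative = TRUE`
#'   (default) it is a fraction of the maximum response in the image, making
#'   the cutoff invariant to global intensity scaling; with `FALSE` it is an
#'   absolute determinant-of-Hessian value.
#' @param n_octaves,n_scales scale-space geometry: scales are
#'   `1.6 * 2^((i-1)/n_scales)` for `i = 1 .. n_octaves * n_scales`.
#' @param threshold_relative interpret `threshold` relative to the maximum
#'   response.
#' @return A data.frame with columns `row`, `col` (1-based pixel coordinates),
#'   `scale` (detector scale in pixels) and `response`, sorted by descending
#'   response.
#' @export
detect_interest_points <- function(image, threshold = 0.01,
                                   n_octaves = 3, n_scales = 4,
                                   threshold_relative = TRUE) {
  if (any(!is.finite(image))) stop("image contains non-finite values")
  empty <- data.frame(row = integer(), col = integer(),
                      scale = numeric(), response = numeric())
  rng <- diff(range(image))
  if (rng == 0) return(empty) # constant image: no structure, only FFT noise
  n_layers <- n_octaves * n_scales
  sigmas <- 1.6 * 2^((seq_len(n_layers) - 1) / n_scales)
  layers <- lapply(sigmas, function(s) doh_layer(image, s))
  maxr <- max(vapply(layers, max, 0))
  # floor keeps FFT roundoff (relative to the image dynamic range) out
  floor_resp <- 1e-10 * rng^2
  cutoff <- if (threshold_relative) {
    max(threshold * max(maxr, 0), floor_resp)
  } else {
    max(threshold, floor_resp)
  }
  kp <- list()
  for (l in seq_len(n_layers)) {
    m <- layers[[l]]
    is_max <- m > max3x3_ring(m) & m > 0 & m > cutoff
    if (l > 1L) is_max <- is_max & (m > max3x3(layers[[l - 1L]]))
    if (l < n_layers) is_max <- is_max & (m > max3x3(layers[[l + 1L]]))
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx)) {
      kp[[length(kp) + 1L]] <- data.frame(row = idx[, 1], col = idx[, 2],
                                          scale = sigmas[l],
                                          response = m[idx])
    }
  }
  out <- if (length(kp)) do.call(rbind, kp) else empty
  out[order(-out$response, out$row, out$col), , drop = FALSE]
}

#' Relocate candidates to their local intensity maximum
#'
#' Moves every candidate to the brightest pixel inside the `w1 x w1` window
#' centred on it (window clipped at image borders). Ties are broken toward
#' the smallest (row, col). The image intensity at an output point is never
#' below that at its input point.
#'
#' @param points data.frame with `row`, `col` columns (other columns are
#'   preserved).
#' @param image numeric matrix the intensities are read from (the enhanced
#'   image in the default pipeline).
#' @param cfg an [nms_config()].
#' @return `points` with updated `row`, `col`.
#' @export
relocate_to_local_max <- function(points, image, cfg = nms_config()) {
  h <- floor(cfg$w1 / 2)
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(nrow(points))) {
    r <- points$row[i]; cl <- points$col[i]
    stopifnot(r >= 1, r <= nr, cl >= 1, cl <= nc)
    r0 <- max(1L, r - h); r1 <- min(nr, r + h)
    c0 <- max(1L, cl - h); c1 <- min(nc, cl + h)
    w <- image[r0:r1, c0:c1, drop = FALSE]
    best <- which(w == max(w), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    points$row[i] <- r0 + best[1] - 1L
    points$col[i] <- c0 + best[2] - 1L
  }
  points
}

#' Remove duplicate candidates in a local area
#'
#' Greedy non-maximum suppression: candidates are visited in descending order
#' of image intensity at their location (ties broken by (row, col)); each kept
#' candidate suppresses all others within Chebyshev distance `w2`. Surviving
#' candidates are pairwise more than `w2` apart; the operation is idempotent.
#'
#' @inheritParams relocate_to_local_max
#' @return The surviving subset of `points`, in suppression (intensity) order.
#' @export
suppress_duplicates <- function(points, image, cfg = nms_config()) {
  n <- nrow(points)
  if (n == 0L) return(points)
  stopifnot(all(points$row >= 1), all(points$row <= nrow(image)),
            all(points$col >= 1), all(points$col <= ncol(image)))
  inten <- image[cbind(points$row, points$col)]
  ord <- order(-inten, points$row, points$col)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    cheb <- pmax(abs(points$row - points$row[i]), abs(points$col - points$col[i]))
    alive[cheb <= cfg$w2] <- FALSE
  }
  points[ord[keep[ord]], , drop = FALSE]
}
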