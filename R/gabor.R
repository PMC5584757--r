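#' Gabor descriptor configuration
#'
#' The descriptor correlates a square patch around each candidate with a bank
#' of even-symmetric Gabor filters at `n_angles` orientations. The envelope
#' standard deviations default to the bouton scale (4 px); the carrier
#' frequency `w` is the bank's main free parameter — the default
#' `1 / (4 * sigma_x)` cycles/pixel makes the carrier half-period span the
#' full blob diameter (about `2 * sigma`), so an entire bouton sits inside
#' the positive lobe with an inhibitory surround. Retune `frequency` first
#' when adapting the descriptor to other magnifications.
#'
#' @param sigma_x,sigma_y Gaussian envelope standard deviations in pixels.
#' @param frequency carrier spatial frequency magnitude in cycles/pixel.
#' @param n_angles number of orientations V; filters sit at angles
#'   `theta = n * pi / 6` for `n = 1 .. V` (default 12; even-symmetric
#'   filters repeat with period pi, so half of these duplicate, which is kept
#'   deliberately for a 12-element descriptor).
#' @param normalize_patch min-max normalize each patch to `[0, 1]` before
#'   description (constant patches map to all-zero).
#' @return A list of class `gabor_config`.
#' @export
gabor_config <- function(sigma_x = 4.0, sigma_y = 4.0,
                         frequency = 1 / (4 * sigma_x),
                         n_angles = 12L, normalize_patch = TRUE) {
  stopifnot(sigma_x > 0, sigma_y > 0, frequency >= 0, n_angles >= 1)
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y,
                 frequency = frequency, n_angles = as.integer(n_angles),
                 normalize_patch = isTRUE(normalize_patch)),
            class = "gabor_config")
}

#' Patch side length for an envelope scale
#'
#' The descriptor patch must capture an entire bouton: its half-width is three
#' envelope standard deviations, `(I - 1) / 2 = 3 * sigma`, so
#' `I = 2 * round(3 * sigma) + 1` (round-half-even, as in base R). At the
#' working scale `sigma = 4` this gives the canonical 25 x 25 patch.
#'
#' @param sigma envelope standard deviation in pixels.
#' @return Integer pair `(I, J)` (square).
#' @export
patch_size_from_sigma <- function(sigma) {
  stopifnot(sigma > 0)
  side <- as.integer(2 * round(3 * sigma) + 1)
  c(side, side)
}

#' Build the Gabor filter bank
#'
#' Filter `d` samples the even-symmetric 2D Gabor function
#' \deqn{g(x, y) = \frac{1}{2\pi\sigma_x\sigma_y}
#'   \exp\left[-\tfrac12\left(\frac{x^2}{\sigma_x^2} +
#'   \frac{y^2}{\sigma_y^2}\right)\right] \cos(2\pi w(x\cos\theta_d +
#'   y\sin\theta_d))}
#' on the patch grid, with the receptive-field centre at the patch centre and
#' `theta_d = d * pi / 6`. The rotation applies to the carrier only; the
#' envelope stays axis-aligned. Every filter is even-symmetric about the
#' patch centre and its centre value is `1 / (2 pi sigma_x sigma_y)`.
#'
#' @param cfg a [gabor_config()].
#' @param size patch shape `(I, J)`; defaults to
#'   [patch_size_from_sigma()] of `sigma_x`.
#' @return A list of class `gabor_bank` with fields `filters` (list of V
#'   matrices), `angles`, `config`.
#' @export
build_bank <- function(cfg = gabor_config(),
                       size = patch_size_from_sigma(cfg$sigma_x)) {
  stopifnot(size[1] %% 2 == 1, size[2] %% 2 == 1)
  hy <- (size[1] - 1L) %/% 2L
  hx <- (size[2] - 1L) %/% 2L
  y <- matrix(seq(-hy, hy), size[1], size[2])        # row offsets
  x <- matrix(seq(-hx, hx), size[1], size[2], byrow = TRUE)  # col offsets
  env <- exp(-0.5 * (x^2 / cfg$sigma_x^2 + y^2 / cfg$sigma_y^2)) /
    (2 * pi * cfg$sigma_x * cfg$sigma_y)
  angles <- seq_len(cfg$n_angles) * pi / 6
  filters <- lapply(angles, function(th) {
    env * cos(2 * pi * cfg$frequency * (cos(th) * x + sin(th) * y))
  })
  structure(list(filters = filters, angles = angles, config = cfg),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("gabor_bank: %d filters of %d x %d (sigma %.1f/%.1f, w %.3f)\n",
              length(x$filters), nrow(x$filters[[1]]), ncol(x$filters[[1]]),
              x$config$sigma_x, x$config$sigma_y, x$config$frequency))
  invisible(x)
}

#' Extract a descriptor patch around a point
#'
#' Crops the `I x J` window centred on the point, reflect-padding wherever the
#' window overruns the image border, and (by default) min-max normalizes the
#' patch to `[0, 1]`; a constant patch maps to all zeros.
#'
#' @param image numeric matrix.
#' @param point list/row with `row`, `col` (1-based) inside the image.
#' @param size integer pair `(I, J)`, both odd.
#' @param normalize min-max normalize the patch (default `TRUE`).
#' @return An `I x J` matrix.
#' @export
extract_patch <- function(image, point, size = patch_size_from_sigma(4),
                          normalize = TRUE) {
  r <- point$row; cl <- point$col
  stopifnot(r >= 1, r <= nrow(image), cl >= 1, cl <= ncol(image),
            size[1] %% 2 == 1, size[2] %% 2 == 1)
  hy <- (size[1] - 1L) %/% 2L
  hx <- (size[2] - 1L) %/% 2L
  ri <- mirror_index(seq(r - hy, r + hy), nrow(image))
  ci <- mirror_index(seq(cl - hx, cl + hx), ncol(image))
  p <- image[ri, ci, drop = FALSE]
  if (normalize) {
    rng <- range(p)
    p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else p * 0
  }
  p
}

#' Resize a patch by bilinear interpolation
#'
#' Training patches of other sizes are resampled to the canonical descriptor
#' size (25 x 25 at the default scale).
#'
#' @param patch numeric matrix.
#' @param size target `(I, J)`.
#' @return Resized matrix.
#' @export
resize_patch <- function(patch, size = c(25L, 25L)) {
  if (all(dim(patch) == size)) return(patch)
  as.matrix(EBImage::resize(patch, w = size[1], h = size[2],
                            filter = "bilinear"))
}

#' Describe a patch with the Gabor bank
#'
#' Element `d` of the descriptor is the inner product of the patch with filter
#' `d` (element-wise product, summed). With the default bank the descriptor
#' has 12 elements.
#'
#' @param patch `I x J` matrix, e.g. from [extract_patch()].
#' @param bank a [build_bank()] of matching shape.
#' @return Numeric vector of length `V = n_angles`.
#' @export
describe <- function(patch, bank = build_bank()) {
  if (!all(dim(patch) == dim(bank$filters[[1]]))) {
    stop("patch shape ", paste(dim(patch), collapse = "x"),
         " does not match filter shape ",
         paste(dim(bank$filters[[1]]), collapse = "x"))
  }
  vapply(bank$filters, function(g) sum(patch * g), 0.0)
}

#' Describe a set of candidate points on an image
#'
#' Convenience wrapper: extracts a patch at every point and stacks the
#' descriptors into a feature matrix.
#'
#' @param image numeric matrix.
#' @param points data.frame with `row`, `col`.
#' @param bank a [build_bank()].
#' @return Numeric matrix, one row per point, V columns.
#' @export
describe_points <- function(image, points, bank = build_bank()) {
  size <- dim(bank$filters[[1]])
  normalize <- bank$config$normalize_patch
  t(vapply(seq_len(nrow(points)), function(i) {
    describe(extract_patch(image, points[i, ], size, normalize), bank)
  }, numeric(length(bank$filters))))
}
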