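#' Enhancement configuration
#'
#' Parameters of the blob-enhancement stage. The Laplacian-of-Gaussian (LoG)
#' scale `sigma` should match the bouton radius r through `sigma = r / sqrt(2)`
#' (see [optimal_sigma_for_radius()]); the working default `sigma = 4` px
#' corresponds to the average bouton diameter at 0.147 um/px.
#'
#' @param sigma LoG scale in pixels (> 0).
#' @param support_halfwidth kernel half-extent in pixels; defaults to
#'   `ceiling(3 * sigma)`, giving a 25 x 25 kernel at `sigma = 4`.
#' @param zero_mean if `TRUE` (default) the discrete kernel is shifted to sum
#'   to zero, so constant background maps exactly to zero after enhancement.
#' @param nms_intensity_source which image the non-maximum-suppression stage
#'   reads intensities from: the `"enhanced"` image (default) or the raw
#'   `"projection"`.
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(sigma = 4.0,
                               support_halfwidth = ceiling(3 * sigma),
                               zero_mean = TRUE,
                               nms_intensity_source = c("enhanced", "projection")) {
  stopifnot(sigma > 0)
  if (support_halfwidth < ceiling(3 * sigma)) {
    stop("support_halfwidth must be at least ceiling(3*sigma)")
  }
  structure(list(sigma = sigma,
                 support_halfwidth = as.integer(support_halfwidth),
                 zero_mean = isTRUE(zero_mean),
                 nms_intensity_source = match.arg(nms_intensity_source)),
            class = "enhancement_config")
}

#' Laplacian-of-Gaussian kernel
#'
#' Samples the LoG
#' \deqn{LoG(x, y; \sigma) = \frac{x^2 + y^2 - 2\sigma^2}{2\pi\sigma^5}
#'       e^{-(x^2+y^2)/(2\sigma^2)}}
#' on the integer grid `[-h, h]^2`. The continuous kernel integrates to zero
#' but its truncated discrete sampling does not; with `zero_mean` set the mean
#' weight is subtracted so the discrete kernel sums to zero.
#'
#' @param config an [enhancement_config()].
#' @return A `(2h+1) x (2h+1)` matrix of kernel weights, centred at the
#'   origin. Weights are circularly symmetric and cross zero on the circle
#'   `x^2 + y^2 = 2 sigma^2`.
#' @export
log_kernel <- function(config = enhancement_config()) {
  s <- config$sigma
  h <- config$support_halfwidth
  g <- seq(-h, h)
  r2 <- outer(g^2, g^2, `+`)
  w <- (r2 - 2 * s^2) / (2 * pi * s^5) * exp(-r2 / (2 * s^2))
  if (config$zero_mean) w <- w - mean(w)
  w
}

#' Optimal LoG scale for a blob radius
#'
#' The negative-LoG response to a bright blob of radius `r` is maximal at
#' `sigma = r / sqrt(2)`; a bouton of radius `4 * sqrt(2)` px is best enhanced
#' at the working scale `sigma = 4`.
#'
#' @param r blob radius in pixels (> 0).
#' @return `r / sqrt(2)`.
#' @export
optimal_sigma_for_radius <- function(r) {
  if (any(r <= 0)) stop("blob radius must be positive")
  r / sqrt(2)
}

#' Enhance blob-like structure
#'
#' Convolves the image with the negated LoG kernel (reflective boundary
#' padding), accentuating bright blobs of radius about `sigma * sqrt(2)` while
#' suppressing structures significantly smaller than `sigma`.
#'
#' @param image numeric matrix (e.g. a [mean_projection()]).
#' @param config an [enhancement_config()].
#' @return A matrix of the same shape.
#' @export
enhance <- function(image, config = enhancement_config()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  convolve_mirror(image, -log_kernel(config))
}
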