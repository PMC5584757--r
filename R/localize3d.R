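#' Localize a 2D detection in depth
#'
#' For each slice k, sums the voxel intensities over the `N x N` window
#' centred on the point (clipped at frame borders; only in-frame pixels are
#' summed) and returns the slice with the largest sum. Ties break toward the
#' smallest slice index for determinism. With `normalize = TRUE` the window
#' sum is divided by its pixel count, which makes border and interior points
#' comparable; the default is the raw sum.
#'
#' @param stack an [image_stack()].
#' @param point list/row with `row`, `col` (1-based) inside the frame.
#' @param patch_side odd window side N (default 25, the canonical patch size).
#' @param normalize divide each window sum by its in-frame pixel count.
#' @return A list with `z` (1-based slice index) and `profile` (the per-slice
#'   window sums, a diagnostic for auditing multi-modal depth profiles, e.g.
#'   axons crossing in z).
#' @export
locate_z <- function(stack, point, patch_side = 25L, normalize = FALSE) {
  stopifnot(inherits(stack, "image_stack"), patch_side %% 2 == 1)
  d <- dim(stack$voxels)
  if (d[3] < 1L) stop("empty stack")
  r <- point$row; cl <- point$col
  stopifnot(r >= 1, r <= d[1], cl >= 1, cl <= d[2])
  h <- (patch_side - 1L) %/% 2L
  r0 <- max(1L, r - h); r1 <- min(d[1], r + h)
  c0 <- max(1L, cl - h); c1 <- min(d[2], cl + h)
  profile <- vapply(seq_len(d[3]), function(k) {
    sum(stack$voxels[r0:r1, c0:c1, k])
  }, 0.0)
  if (normalize) profile <- profile / ((r1 - r0 + 1) * (c1 - c0 + 1))
  list(z = which.max(profile), profile = profile)
}
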