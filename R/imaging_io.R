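#' Construct an image stack
#'
#' An `image_stack` holds a 3D grid of non-negative voxel intensities together
#' with the physical voxel size. Voxels are stored as an R array indexed
#' `[row, col, z]` (row = y, col = x); all exported CSV files use 0-based
#' `x = col - 1`, `y = row - 1`, `z = slice - 1` coordinates.
#'
#' @param voxels 3D numeric array `[row, col, z]` of non-negative intensities,
#'   or a matrix for a single-slice stack.
#' @param voxel_size numeric triple, physical size of a voxel in micrometres
#'   `(x, y, z)`. Defaults to the acquisition geometry of the target imaging
#'   protocol: 0.147 um laterally, 1 um axially.
#' @param bit_depth sample depth of the source file (8, 16, or NA for float).
#' @return An object of class `image_stack` with fields `voxels`,
#'   `voxel_size`, `bit_depth`.
#' @export
image_stack <- function(voxels, voxel_size = c(0.147, 0.147, 1.0),
                        bit_depth = NA_integer_) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    stop("voxel intensities must be finite and non-negative")
  }
  if (any(dim(voxels) < 1L)) stop("empty stack")
  structure(list(voxels = voxels,
                 voxel_size = as.numeric(voxel_size),
                 bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (%.3f x %.3f x %.1f um)\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Integer samples (8/16-bit) are promoted to double without rescaling, so raw
#' counts stay auditable; float samples are read as stored. Multi-channel
#' images are rejected.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @param voxel_size voxel size used when the file carries no metadata;
#'   see [image_stack()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size = c(0.147, 0.147, 1.0)) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  bps <- attr(first, "bits.per.sample")
  if (!is.null(bps) && bps >= 32) {
    # 32-bit samples are float; as.is would return raw bit patterns
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    first <- pages[[1]]
    bps <- NA_integer_
  }
  if (length(dim(first)) == 3L) {
    stop("unsupported format: image has ", dim(first)[3],
         " channels; a single-channel grayscale TIFF is required")
  }
  vox <- array(0, c(dim(first), length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
  image_stack(vox, voxel_size = voxel_size,
              bit_depth = if (is.null(bps)) NA_integer_ else as.integer(bps))
}

#' Write an image stack to a multi-page TIFF
#'
#' Stacks whose intensities are integers within 16-bit range are written as
#' 16-bit (lossless round-trip); float stacks are written as 32-bit float.
#' Because float storage outside `[0, 1]` is undefined in the TIFF writer,
#' float stacks with a peak above 1 are scaled by `1 / max` before writing;
#' the detection pipeline is invariant to this global scaling.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  int_like <- max(v) <= 65535 && all(v == round(v))
  if (int_like) {
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    if (max(v) > 1) v <- v / max(v)
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' Mean-intensity projection of a stack
#'
#' Collapses a stack to the 2D image the detection pipeline operates on: each
#' output pixel is the arithmetic mean over z of the voxel column at that
#' (row, col). A max-projection alternative is available but is never the
#' default.
#'
#' @param stack an [image_stack()].
#' @param type `"mean"` (default) or `"max"`.
#' @return A numeric matrix (rows x cols).
#' @export
mean_projection <- function(stack, type = c("mean", "max")) {
  stopifnot(inherits(stack, "image_stack"))
  type <- match.arg(type)
  v <- stack$voxels
  if (type == "mean") {
    out <- apply(v, c(1, 2), mean)
  } else {
    out <- apply(v, c(1, 2), max)
  }
  out
}

#' Construct a set of ground-truth boxes
#'
#' Boxes are axis-aligned rectangles in 1-based inclusive `[row, col]` pixel
#' coordinates (CSV interchange is 0-based x/y, see [read_boxes_csv()]).
#'
#' @param boxes data.frame or matrix with columns
#'   `row_min, col_min, row_max, col_max` (1-based, inclusive). May have zero
#'   rows.
#' @param frame_shape integer pair `(rows, cols)` of the labelled frame.
#' @return An object of class `box_set`.
#' @export
box_set <- function(boxes, frame_shape) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) == 0L) {
    boxes <- data.frame(row_min = integer(), col_min = integer(),
                        row_max = integer(), col_max = integer())
  }
  names(boxes)[1:4] <- c("row_min", "col_min", "row_max", "col_max")
  frame_shape <- as.integer(frame_shape)
  if (nrow(boxes) > 0L) {
    with(boxes, {
      if (any(row_min > row_max) || any(col_min > col_max))
        stop("degenerate box: min exceeds max")
      if (any(row_min < 1L) || any(col_min < 1L) ||
          any(row_max > frame_shape[1]) || any(col_max > frame_shape[2]))
        stop("box outside frame")
    })
  }
  structure(list(boxes = boxes, frame_shape = frame_shape), class = "box_set")
}

#' @export
print.box_set <- function(x, ...) {
  cat(sprintf("box_set: %d boxes in a %d x %d frame\n",
              nrow(x$boxes), x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}

#' @export
length.box_set <- function(x) nrow(x$boxes)

# 8-connected component labelling of a logical matrix by BFS.
# (Installed labellers only expose 4-connectivity in 2D.)
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  fg <- which(mask)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      nb_r <- r + offs[, 1]; nb_c <- cl + offs[, 2]
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Read ground-truth bouton labels
#'
#' Ground truth is interchange as a binary mask image in which each labelled
#' bouton is a filled box; each 8-connected component of positive pixels
#' becomes one box (its bounding rectangle). A plain CSV box list (see
#' [read_boxes_csv()]) is accepted as an alternative, keyed on the `.csv`
#' extension.
#'
#' @param path binary TIFF mask or CSV box list.
#' @param frame_shape expected `(rows, cols)`; checked against the mask,
#'   required for CSV input.
#' @return A [box_set()].
#' @export
read_groundtruth <- function(path, frame_shape = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(frame_shape)) stop("frame_shape is required for CSV ground truth")
    return(read_boxes_csv(path, frame_shape))
  }
  m <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(m)) == 3L) stop("ground-truth mask must be single-channel")
  vals <- unique(as.vector(m))
  if (length(vals) > 2L) {
    stop("ground-truth image is not binary: ", length(vals), " distinct values")
  }
  if (!is.null(frame_shape) && !all(dim(m) == frame_shape)) {
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match frame ", paste(frame_shape, collapse = "x"))
  }
  lab <- label_components_8(m > 0)
  n <- max(lab)
  boxes <- data.frame(row_min = integer(n), col_min = integer(n),
                      row_max = integer(n), col_max = integer(n))
  if (n > 0L) {
    for (k in seq_len(n)) {
      idx <- which(lab == k, arr.ind = TRUE)
      boxes[k, ] <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
    }
  }
  box_set(boxes, dim(m))
}

#' Rasterize a box set to a binary mask
#'
#' @param bs a [box_set()].
#' @return A 0/1 matrix of the box-set frame shape.
#' @export
rasterize_boxes <- function(bs) {
  stopifnot(inherits(bs, "box_set"))
  m <- matrix(0, bs$frame_shape[1], bs$frame_shape[2])
  b <- bs$boxes
  for (k in seq_len(nrow(b))) {
    m[b$row_min[k]:b$row_max[k], b$col_min[k]:b$col_max[k]] <- 1
  }
  m
}

#' Read / write a CSV box list
#'
#' The CSV interchange format has header `x_min,y_min,x_max,y_max` with
#' 0-based inclusive pixel coordinates (`x` = column, `y` = row).
#'
#' @param path CSV file path.
#' @param frame_shape integer pair `(rows, cols)`.
#' @return [read_boxes_csv()] returns a [box_set()]; [write_boxes_csv()]
#'   returns `path` invisibly.
#' @export
read_boxes_csv <- function(path, frame_shape) {
  d <- utils::read.csv(path)
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(d))) {
    stop("box CSV must have header x_min,y_min,x_max,y_max")
  }
  box_set(data.frame(row_min = d$y_min + 1L, col_min = d$x_min + 1L,
                     row_max = d$y_max + 1L, col_max = d$x_max + 1L),
          frame_shape)
}

#' @rdname read_boxes_csv
#' @param bs a [box_set()] to write.
#' @export
write_boxes_csv <- function(bs, path) {
  stopifnot(inherits(bs, "box_set"))
  b <- bs$boxes
  utils::write.csv(data.frame(x_min = b$col_min - 1L, y_min = b$row_min - 1L,
                              x_max = b$col_max - 1L, y_max = b$row_max - 1L),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
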