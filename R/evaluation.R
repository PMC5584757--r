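#' Match counts
#'
#' Container for the box-protocol confusion counts of one image.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A list of class `match_counts`.
#' @export
match_counts <- function(tp, fp, fn, tn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("match_counts: TP %d, FP %d, FN %d, TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Score detected points against ground-truth boxes
#'
#' A point counts as a true positive only if its coordinates lie within a
#' ground-truth box (edges inclusive), and only one TP is counted per box:
#' further points inside an already-matched box count as false positives, as
#' do points inside no box. Boxes containing no point count as false
#' negatives. Points are assigned in descending score order (then (row, col)
#' order) for determinism.
#'
#' True negatives are not point-like under this protocol; with
#' `tn_mode = "pixel"` the TN count is the number of frame pixels outside the
#' `exclusion_side`-square zones centred on every TP point, FP point and FN
#' box centre, which supports an FPR axis for ROC-style sweeps. The default
#' (`"none"`) leaves `tn = 0` and reports precision/recall metrics only.
#'
#' @param points data.frame with `row`, `col` (1-based, inside the frame) and
#'   optionally `score`.
#' @param boxes a [box_set()].
#' @param tn_mode `"none"` (default) or `"pixel"`.
#' @param exclusion_side side of the square TN exclusion zone (default 25).
#' @return A [match_counts()].
#' @export
match_detections <- function(points, boxes, tn_mode = c("none", "pixel"),
                             exclusion_side = 25L) {
  stopifnot(inherits(boxes, "box_set"))
  tn_mode <- match.arg(tn_mode)
  b <- boxes$boxes
  fs <- boxes$frame_shape
  n <- nrow(points)
  if (n > 0L) {
    if (any(points$row < 1) || any(points$row > fs[1]) ||
        any(points$col < 1) || any(points$col > fs[2])) {
      stop("detection coordinates outside the frame")
    }
  }
  score <- if ("score" %in% names(points)) points$score else rep(0, n)
  ord <- if (n > 0L) order(-score, points$row, points$col) else integer()
  claimed <- rep(FALSE, nrow(b))
  tp <- 0L; fp <- 0L
  tp_pts <- list(); fp_pts <- list()
  for (i in ord) {
    r <- points$row[i]; cl <- points$col[i]
    inside <- which(!claimed & b$row_min <= r & r <= b$row_max &
                      b$col_min <= cl & cl <= b$col_max)
    if (length(inside)) {
      claimed[inside[1]] <- TRUE
      tp <- tp + 1L
      tp_pts[[length(tp_pts) + 1L]] <- c(r, cl)
    } else {
      fp <- fp + 1L
      fp_pts[[length(fp_pts) + 1L]] <- c(r, cl)
    }
  }
  fn <- sum(!claimed)
  tn <- 0L
  if (tn_mode == "pixel") {
    excl <- matrix(FALSE, fs[1], fs[2])
    h <- (exclusion_side - 1L) %/% 2L
    stamp <- function(r, cl) {
      excl[max(1L, r - h):min(fs[1], r + h),
           max(1L, cl - h):min(fs[2], cl + h)] <<- TRUE
    }
    for (p in tp_pts) stamp(p[1], p[2])
    for (p in fp_pts) stamp(p[1], p[2])
    for (k in which(!claimed)) {
      stamp(as.integer(round((b$row_min[k] + b$row_max[k]) / 2)),
            as.integer(round((b$col_min[k] + b$col_max[k]) / 2)))
    }
    tn <- prod(fs) - sum(excl)
  }
  match_counts(tp, fp, fn, tn)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`, with the conventions
#' that an empty denominator yields 0.
#'
#' @param counts a [match_counts()].
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "match_counts"))
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Sweep the classifier threshold and build PR/ROC curves
#'
#' Re-matches the scored detections at `n_thresholds` evenly spaced
#' thresholds over `[-1, 1]`: at each threshold only points with scaled score
#' at or above it are kept. Emits precision/recall per threshold (and FPR
#' when `tn_mode = "pixel"`); the area under the precision-recall curve is
#' computed by the trapezoid rule over recall-ordered samples.
#'
#' @param points data.frame with `row`, `col`, `score` (scaled to `[-1, 1]`).
#' @param boxes a [box_set()].
#' @param n_thresholds number of thresholds (default 1000).
#' @inheritParams match_detections
#' @return A list with `samples` (data.frame `threshold`, `precision`,
#'   `recall`, `fpr`) and `auc` (PR area).
#' @export
threshold_sweep <- function(points, boxes, n_thresholds = 1000L,
                            tn_mode = c("none", "pixel"),
                            exclusion_side = 25L) {
  tn_mode <- match.arg(tn_mode)
  thr <- seq(-1, 1, length.out = n_thresholds)
  rows <- lapply(thr, function(t) {
    kept <- points[points$score >= t, , drop = FALSE]
    cnt <- match_detections(kept, boxes, tn_mode, exclusion_side)
    m <- metrics(cnt)
    fpr <- if (cnt$fp + cnt$tn > 0) cnt$fp / (cnt$fp + cnt$tn) else 0
    c(threshold = t, m["precision"], m["recall"], fpr = fpr)
  })
  samples <- as.data.frame(do.call(rbind, rows))
  names(samples) <- c("threshold", "precision", "recall", "fpr")
  ord <- order(samples$recall)
  rec <- samples$recall[ord]; prec <- samples$precision[ord]
  auc <- if (length(rec) > 1L) {
    sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  } else 0
  list(samples = samples, auc = auc)
}

#' Aggregate per-image counts into an evaluation report
#'
#' @param counts_list list of [match_counts()], one per image.
#' @param image_names optional labels.
#' @return A list of class `evaluation_report` with `per_image` (data.frame of
#'   counts and metrics) and `summary` (mean and sample standard deviation of
#'   precision/recall/F1 over images).
#' @export
evaluation_report <- function(counts_list, image_names = NULL) {
  stopifnot(length(counts_list) > 0)
  per <- do.call(rbind, lapply(counts_list, function(cnt) {
    m <- metrics(cnt)
    data.frame(tp = cnt$tp, fp = cnt$fp, fn = cnt$fn, tn = cnt$tn,
               n_boxes = cnt$tp + cnt$fn,
               precision = m["precision"], recall = m["recall"], f1 = m["f1"])
  }))
  rownames(per) <- if (is.null(image_names)) NULL else image_names
  cols <- c("precision", "recall", "f1")
  summary <- rbind(mean = colMeans(per[cols]),
                   sd = vapply(per[cols], stats::sd, 0.0))
  structure(list(per_image = per, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("evaluation_report over %d image(s): precision %.3f +/- %.3f, recall %.3f +/- %.3f, F1 %.3f +/- %.3f\n",
              nrow(x$per_image), s["mean", "precision"], s["sd", "precision"],
              s["mean", "recall"], s["sd", "recall"],
              s["mean", "f1"], s["sd", "f1"]))
  invisible(x)
}

#' Published per-image benchmark scores
#'
#' The published 20-image benchmark of the tracing-free detector against the
#' EPBscore baseline: per-image bouton counts and precision/recall/F1 for
#' both methods. Useful for metric-arithmetic checks and as context when
#' comparing runs.
#'
#' @return A data.frame with columns `image`, `n_boutons`, `precision`,
#'   `recall`, `f1`, `epb_precision`, `epb_recall`, `epb_f1`.
#' @export
reference_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "boutondetect"))
}
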