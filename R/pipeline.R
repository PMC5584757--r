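#' Pipeline configuration
#'
#' Bundles the per-stage configurations with run metadata. Defaults reproduce
#' the standard detector: LoG enhancement at sigma 4, determinant-of-Hessian
#' interest points, two-window NMS (20/10), 12-filter Gabor descriptor, SVM
#' threshold -0.0399, z-localization with a 25 x 25 patch.
#'
#' @param enhancement an [enhancement_config()].
#' @param detector list with `threshold`, `n_octaves`, `n_scales`,
#'   `threshold_relative` (see [detect_interest_points()]).
#' @param nms an [nms_config()].
#' @param gabor a [gabor_config()].
#' @param classifier a [classifier_params()].
#' @param localize list with `patch_side`, `normalize` (see [locate_z()]).
#' @param patch_source image patches are cut from the raw `"projection"`
#'   (default; axon context survives there) or the `"enhanced"` image; must
#'   match how the classifier was trained.
#' @param enhancement_enabled ablation switch; with `FALSE` the raw
#'   projection feeds the detector directly.
#' @param seed run seed (recorded in provenance).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(enhancement = enhancement_config(),
                            detector = list(threshold = 0.01, n_octaves = 3,
                                            n_scales = 4,
                                            threshold_relative = TRUE),
                            nms = nms_config(),
                            gabor = gabor_config(),
                            classifier = classifier_params(),
                            localize = list(patch_side = 25L, normalize = FALSE),
                            patch_source = c("projection", "enhanced"),
                            enhancement_enabled = TRUE,
                            seed = 1L) {
  structure(list(enhancement = enhancement, detector = detector, nms = nms,
                 gabor = gabor, classifier = classifier, localize = localize,
                 patch_source = match.arg(patch_source),
                 enhancement_enabled = isTRUE(enhancement_enabled),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train the full bouton model from labelled patches
#'
#' Describes every patch with the Gabor bank and fits the SVM; the returned
#' model carries the bank geometry so detection uses matching features.
#'
#' @param patches 25 x 25 x n array of labelled patches (see
#'   [generate_patches()]).
#' @param labels factor bouton/nonbouton of length n.
#' @param cfg a [pipeline_config()].
#' @return A [train_classifier()] result with the Gabor bank attached.
#' @export
train_bouton_model <- function(patches, labels, cfg = pipeline_config()) {
  bank <- build_bank(cfg$gabor)
  feats <- describe_patches(patches, bank)
  model <- train_classifier(feats, labels, cfg$classifier, seed = cfg$seed)
  model$bank <- bank
  model
}

#' Detect boutons in a stack
#'
#' Runs the full pipeline: mean projection, LoG enhancement, interest-point
#' detection, relocation to local maxima, duplicate suppression, Gabor
#' description, SVM classification, and per-detection z-localization.
#' Candidate counts at every stage are recorded in the result's `counts`
#' field.
#'
#' @param stack an [image_stack()].
#' @param model a [train_bouton_model()] result (or [train_classifier()] with
#'   a `bank`).
#' @param cfg a [pipeline_config()].
#' @return A list of class `detection_result` with `detections` (data.frame
#'   `row`, `col`, `z`, `score`, sorted by descending score), `candidates`
#'   (all scored candidates before thresholding, for curve construction),
#'   `counts` (per-stage candidate counts), and `config`.
#' @export
detect_boutons <- function(stack, model, cfg = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(model, "trained_classifier"))
  bank <- model$bank
  if (is.null(bank)) bank <- build_bank(cfg$gabor)

  proj <- mean_projection(stack)
  enh <- if (cfg$enhancement_enabled) enhance(proj, cfg$enhancement) else proj
  intensity_img <- switch(cfg$enhancement$nms_intensity_source,
                          enhanced = enh, projection = proj)
  patch_img <- switch(cfg$patch_source, enhanced = enh, projection = proj)

  kp <- detect_interest_points(enh,
                               threshold = cfg$detector$threshold,
                               n_octaves = cfg$detector$n_octaves,
                               n_scales = cfg$detector$n_scales,
                               threshold_relative = cfg$detector$threshold_relative)
  counts <- c(interest_points = nrow(kp))
  kp <- relocate_to_local_max(kp, intensity_img, cfg$nms)
  kp <- suppress_duplicates(kp, intensity_img, cfg$nms)
  counts["after_nms"] <- nrow(kp)

  empty <- data.frame(row = integer(), col = integer(), z = integer(),
                      score = numeric())
  if (nrow(kp) == 0L) {
    return(structure(list(detections = empty, candidates = empty,
                          counts = c(counts, accepted = 0L), config = cfg),
                     class = "detection_result"))
  }

  feats <- describe_points(patch_img, kp, bank)
  cls <- classify(model, feats, threshold = cfg$classifier$threshold)
  cand <- data.frame(row = kp$row, col = kp$col, score = cls$score)
  acc <- cand[cls$label == "bouton", , drop = FALSE]
  counts["accepted"] <- nrow(acc)

  zs <- vapply(seq_len(nrow(acc)), function(i) {
    locate_z(stack, acc[i, ], cfg$localize$patch_side,
             cfg$localize$normalize)$z
  }, integer(1))
  det <- data.frame(row = acc$row, col = acc$col,
                    z = if (nrow(acc)) zs else integer(), score = acc$score)
  det <- det[order(-det$score, det$row, det$col), , drop = FALSE]
  rownames(det) <- NULL
  structure(list(detections = det, candidates = cand, counts = counts,
                 config = cfg),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d interest points -> %d after NMS -> %d boutons\n",
              x$counts["interest_points"], x$counts["after_nms"],
              x$counts["accepted"]))
  invisible(x)
}

#' Evaluate a detection result against ground truth
#'
#' @param result a [detect_boutons()] result (or a data.frame of detections).
#' @param truth a [box_set()].
#' @param tn_mode see [match_detections()].
#' @return An [evaluation_report()] for the single image, with the
#'   [match_counts()] attached as attribute `"counts"`.
#' @export
run_evaluation <- function(result, truth, tn_mode = "none") {
  det <- if (inherits(result, "detection_result")) result$detections else result
  cnt <- match_detections(det, truth, tn_mode = tn_mode)
  rep <- evaluation_report(list(cnt))
  attr(rep, "counts") <- cnt
  rep
}

#' Write / read a detection CSV
#'
#' The interchange format is `x,y,z,score` with 0-based coordinates
#' (`x` = column, `y` = row, `z` = slice).
#'
#' @param detections data.frame with `row`, `col`, `z`, `score` (1-based).
#' @param path CSV path.
#' @return [read_detections_csv()] returns a 1-based data.frame;
#'   [write_detections_csv()] returns `path` invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(data.frame(x = detections$col - 1L,
                              y = detections$row - 1L,
                              z = if ("z" %in% names(detections)) detections$z - 1L else NA,
                              score = detections$score),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(row = d$y + 1L, col = d$x + 1L,
             z = if ("z" %in% names(d)) d$z + 1L else NA,
             score = d$score)
}
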