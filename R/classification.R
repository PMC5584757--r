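#' Classifier parameters
#'
#' The candidate classifier is a support vector machine with a polynomial
#' kernel of order 3 by default (the best-performing configuration for this
#' task); a Gaussian (radial) kernel is available as an alternative. The
#' operating point is a threshold on decision scores scaled to `[-1, 1]`;
#' the default `-0.0399` favours recall, the priority when boutons are scarce.
#'
#' @param kernel `"polynomial"` or `"gaussian"`.
#' @param degree polynomial order (ignored for gaussian).
#' @param C regularisation cost (> 0), penalising misclassification.
#' @param gamma kernel coefficient; `NULL` uses the library default
#'   (1 / n_features).
#' @param threshold operating threshold on the scaled score.
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(kernel = c("polynomial", "gaussian"),
                              degree = 3L, C = 1.0, gamma = NULL,
                              threshold = -0.0399) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  if (kernel == "polynomial") stopifnot(degree >= 1)
  if (kernel == "gaussian" && !is.null(gamma)) stopifnot(gamma > 0)
  structure(list(kernel = kernel, degree = as.integer(degree), C = C,
                 gamma = gamma, threshold = threshold),
            class = "classifier_params")
}

# Raw decision values oriented so that positive = bouton.
raw_scores <- function(fit, x, flip) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  as.numeric(dv) * flip
}

#' Train the bouton/non-bouton classifier
#'
#' Fits the SVM on a training partition of the labelled feature set (default
#' 80/20 train/validation, mirroring a 720/180 split of 900 patches) and
#' records a symmetric `[-1, 1]` scaling of the raw decision scores from the
#' training partition (half-range `max(abs(raw))`, so the SVM margin maps to
#' scaled 0 and the operating threshold stays interpretable). Class balance is enforced by down-sampling the majority
#' class (450/450 by design) unless `balance = FALSE`.
#'
#' @param features numeric matrix, one row per example (12 columns with the
#'   default descriptor).
#' @param labels factor or character vector with levels `bouton`,
#'   `nonbouton`; both classes must be present.
#' @param params a [classifier_params()].
#' @param split fraction of examples used for training (default 0.8).
#' @param seed integer seed controlling the split and down-sampling.
#' @param balance down-sample the majority class to balance (default `TRUE`).
#' @return A list of class `trained_classifier` with the fitted model, the
#'   score scaler `(min, max)`, the parameters, the validation index, and
#'   per-class training counts.
#' @export
train_classifier <- function(features, labels, params = classifier_params(),
                             split = 0.8, seed = 1L, balance = TRUE) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("bouton", "nonbouton"))
  stopifnot(nrow(features) == length(labels))
  if (any(is.na(labels))) stop("labels must be 'bouton' or 'nonbouton'")
  if (length(unique(labels)) < 2L) stop("training needs both classes")
  if (min(table(labels)) < 2L) stop("need at least 2 examples per class")

  sel <- with_seed(seed, function() {
    idx <- seq_along(labels)
    if (balance) {
      n_min <- min(table(labels))
      idx <- unlist(lapply(levels(labels), function(lv) {
        i <- which(labels == lv)
        if (length(i) > n_min) sort(sample(i, n_min)) else i
      }))
    }
    train <- sort(unlist(lapply(levels(labels), function(lv) {
      i <- idx[labels[idx] == lv]
      sample(i, max(1L, round(split * length(i))))
    })))
    list(train = train, valid = setdiff(idx, train))
  })

  xt <- features[sel$train, , drop = FALSE]
  yt <- droplevels(labels[sel$train])
  fit <- if (params$kernel == "polynomial") {
    e1071::svm(xt, yt, kernel = "polynomial", degree = params$degree,
               coef0 = 1, cost = params$C, scale = TRUE)
  } else {
    args <- list(xt, yt, kernel = "radial", cost = params$C, scale = TRUE)
    if (!is.null(params$gamma)) args$gamma <- params$gamma
    do.call(e1071::svm, args)
  }
  # libsvm's decision-value sign follows label encounter order; orient it so
  # that positive always means bouton.
  dv <- as.numeric(attr(stats::predict(fit, xt, decision.values = TRUE),
                        "decision.values"))
  flip <- if (mean(dv[yt == "bouton"]) >= mean(dv[yt == "nonbouton"])) 1 else -1
  raw <- dv * flip
  # symmetric scaling range: the SVM decision boundary (raw 0) maps to scaled
  # 0, so the operating threshold keeps its meaning of "just below the
  # margin" regardless of how asymmetric the raw score range is
  m_abs <- max(abs(raw))
  scaler <- c(min = -m_abs, max = m_abs)
  if (scaler["max"] <= scaler["min"]) stop("degenerate decision-score range")
  structure(list(model = fit, flip = flip, scaler = scaler, params = params,
                 valid_index = sel$valid, train_index = sel$train,
                 class_counts = table(yt), seed = seed, version = 1L),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("trained_classifier: %s SVM (C = %g), %d + %d training examples, threshold %.4f\n",
              x$params$kernel, x$params$C,
              x$class_counts[1], x$class_counts[2], x$params$threshold))
  invisible(x)
}

#' Scale raw decision scores to [-1, 1]
#'
#' Affine map sending the scaler minimum to -1 and maximum to +1; values
#' outside the range extrapolate linearly (no clipping), so the map is
#' invertible.
#'
#' @param raw numeric vector of raw decision values.
#' @param scaler numeric pair `(min, max)` with `max > min` (stored on the
#'   trained classifier).
#' @return Numeric vector of scaled scores.
#' @export
scale_scores <- function(raw, scaler) {
  lo <- scaler[[1]]; hi <- scaler[[2]]
  if (!(hi > lo)) stop("degenerate scaler: max must exceed min")
  2 * (raw - lo) / (hi - lo) - 1
}

#' Classify candidate feature vectors
#'
#' Scores each feature vector with the fitted SVM, scales the score to the
#' model's `[-1, 1]` range, and labels a candidate `bouton` iff its scaled
#' score is at or above the operating threshold.
#'
#' @param model a [train_classifier()] result.
#' @param features numeric matrix with one row per candidate and the feature
#'   length the model was trained on.
#' @param threshold override of the model's operating threshold.
#' @return A data.frame with columns `label` (factor bouton/nonbouton) and
#'   `score` (scaled).
#' @export
classify <- function(model, features, threshold = model$params$threshold) {
  stopifnot(inherits(model, "trained_classifier"))
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    return(data.frame(label = factor(character(),
                                     levels = c("bouton", "nonbouton")),
                      score = numeric()))
  }
  if (ncol(features) != ncol(model$model$SV)) {
    stop("feature length ", ncol(features), " does not match model (",
         ncol(model$model$SV), ")")
  }
  score <- scale_scores(raw_scores(model$model, features, model$flip),
                        model$scaler)
  data.frame(label = factor(ifelse(score >= threshold, "bouton", "nonbouton"),
                            levels = c("bouton", "nonbouton")),
             score = score)
}

#' Exhaustive hyperparameter search
#'
#' Trains one model per grid point and selects the setting with the highest
#' F1 on the validation partition; ties are broken toward smaller `C`, then
#' lower polynomial degree.
#'
#' @param features,labels as in [train_classifier()].
#' @param grid data.frame of candidate settings with any of the columns
#'   `kernel`, `degree`, `C`, `gamma` (missing columns take the defaults).
#' @param seed split seed shared by all evaluations.
#' @param split training fraction.
#' @return The selected [classifier_params()], with the grid results attached
#'   as attribute `"search"`.
#' @export
grid_search <- function(features, labels, grid, seed = 1L, split = 0.8) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  defaults <- classifier_params()
  score_one <- function(i) {
    p <- classifier_params(
      kernel = if ("kernel" %in% names(grid)) as.character(grid$kernel[i]) else defaults$kernel,
      degree = if ("degree" %in% names(grid)) grid$degree[i] else defaults$degree,
      C = if ("C" %in% names(grid)) grid$C[i] else defaults$C,
      gamma = if ("gamma" %in% names(grid)) grid$gamma[i] else defaults$gamma)
    m <- train_classifier(features, labels, p, split = split, seed = seed)
    vi <- m$valid_index
    pred <- classify(m, features[vi, , drop = FALSE], threshold = m$params$threshold)
    truth <- labels[vi] == "bouton"
    tp <- sum(pred$label == "bouton" & truth)
    fp <- sum(pred$label == "bouton" & !truth)
    fn <- sum(pred$label == "nonbouton" & truth)
    f1 <- metrics(match_counts(tp, fp, fn))["f1"]
    list(params = p, f1 = unname(f1))
  }
  res <- lapply(seq_len(nrow(grid)), score_one)
  f1s <- vapply(res, `[[`, 0.0, "f1")
  cs <- vapply(res, function(r) r$params$C, 0.0)
  degs <- vapply(res, function(r) r$params$degree, 0L)
  best <- order(-f1s, cs, degs)[1]
  out <- res[[best]]$params
  attr(out, "search") <- data.frame(grid, f1 = f1s)
  out
}

#' Save / load a trained classifier
#'
#' The model archive is a versioned RDS containing the fitted SVM, scaling
#' parameters and configuration; loading an archive with a different version
#' fails loudly.
#'
#' @param model a [train_classifier()] result.
#' @param path file path.
#' @return [load_classifier()] returns the model; [save_classifier()] returns
#'   `path` invisibly.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_classifier") ||
      !identical(model$version, 1L)) {
    stop("not a compatible classifier archive (expected version 1)")
  }
  model
}
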