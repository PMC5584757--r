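make_clusters <- function(n = 100, sep = 4, seed = 19) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(12 * n, mean = sep / 2), n),
             matrix(rnorm(12 * n, mean = -sep / 2), n))
  list(x = x, y = factor(rep(c("bouton", "nonbouton"), each = n),
                         levels = c("bouton", "nonbouton")))
}

test_that("training separates separable clusters and is deterministic", {
  d <- make_clusters()
  m <- train_classifier(d$x, d$y, seed = 2)
  pred <- classify(m, d$x[m$train_index, ])
  expect_equal(mean((pred$label == "bouton") ==
                      (d$y[m$train_index] == "bouton")), 1.0)

  # same data and seed twice: identical predictions on a held-out grid
  m2 <- train_classifier(d$x, d$y, seed = 2)
  grid <- matrix(rnorm(50 * 12), 50)
  expect_identical(classify(m, grid), classify(m2, grid))

  # single-class input errors
  expect_error(train_classifier(d$x[1:100, ], d$y[1:100]), "both classes")
})

test_that("score scaling is the affine [-1, 1] map with a linear inverse", {
  expect_equal(scale_scores(c(-2, 0, 6), c(-2, 6)), c(-1, -0.5, 1))
  expect_equal(scale_scores(-2, c(-2, 6)), -1)
  expect_error(scale_scores(1, c(3, 3)), "degenerate")

  set.seed(29)
  raw <- rnorm(200, sd = 5)
  sc <- scale_scores(raw, c(-4, 9))
  back <- (sc + 1) / 2 * (9 - -4) + -4
  expect_equal(back, raw, tolerance = 1e-12)
})

test_that("classification applies the operating threshold on scaled scores", {
  d <- make_clusters()
  m <- train_classifier(d$x, d$y, seed = 2)
  # scaled scores of the scaling set hit [-1, 1] at (at least) one endpoint
  raw <- boutondetect:::raw_scores(m$model, d$x[m$train_index, ], m$flip)
  sc <- scale_scores(raw, m$scaler)
  expect_gte(min(sc), -1)
  expect_lte(max(sc), 1)
  expect_equal(max(abs(sc)), 1)

  # threshold semantics at the default -0.0399
  fake <- m
  expect_equal(ifelse(-0.03 >= fake$params$threshold, "bouton", "nonbouton"),
               "bouton")
  expect_equal(ifelse(-0.05 >= fake$params$threshold, "bouton", "nonbouton"),
               "nonbouton")

  # positives never increase as the threshold rises
  grid <- matrix(rnorm(200 * 12), 200)
  n_pos <- vapply(seq(-1, 1, by = 0.1), function(th) {
    sum(classify(m, grid, threshold = th)$label == "bouton")
  }, 0L)
  expect_true(all(diff(n_pos) <= 0))
  # feature-length mismatch errors
  expect_error(classify(m, matrix(0, 3, 5)), "feature length")
})

test_that("grid search selects by validation F1 with the stated tie-breaks", {
  d <- make_clusters(n = 60)
  one <- grid_search(d$x, d$y, data.frame(C = 2.5), seed = 3)
  expect_equal(one$C, 2.5)

  # separable data: all settings tie at F1 = 1, smallest C wins
  sel <- grid_search(d$x, d$y, data.frame(C = c(10, 0.1, 1)), seed = 3)
  expect_equal(sel$C, 0.1)
  search <- attr(sel, "search")
  expect_true(all(search$f1 == 1))

  # selected setting's F1 is >= every grid point's (independent re-check)
  d2 <- make_clusters(n = 60, sep = 1.2, seed = 47) # overlapping classes
  grid <- expand.grid(degree = c(2, 3), C = c(0.1, 1, 10))
  sel2 <- grid_search(d2$x, d2$y, grid, seed = 5)
  f1s <- attr(sel2, "search")$f1
  re_eval <- vapply(seq_len(nrow(grid)), function(i) {
    p <- classifier_params(degree = grid$degree[i], C = grid$C[i])
    m <- train_classifier(d2$x, d2$y, p, seed = 5)
    vi <- m$valid_index
    pred <- classify(m, d2$x[vi, , drop = FALSE])
    truth <- d2$y[vi] == "bouton"
    tp <- sum(pred$label == "bouton" & truth)
    fp <- sum(pred$label == "bouton" & !truth)
    fn <- sum(pred$label == "nonbouton" & truth)
    unname(metrics(match_counts(tp, fp, fn))["f1"])
  }, 0.0)
  expect_equal(f1s, re_eval)
  sel_f1 <- f1s[grid$degree == sel2$degree & grid$C == sel2$C]
  expect_true(all(sel_f1 >= f1s))
  expect_error(grid_search(d$x, d$y, data.frame()), "empty")
})

test_that("model persistence round-trips and checks its version", {
  d <- make_clusters(n = 30)
  m <- train_classifier(d$x, d$y, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, tmp)
  back <- load_classifier(tmp)
  grid <- matrix(rnorm(20 * 12), 20)
  expect_identical(classify(back, grid), classify(m, grid))
  saveRDS(list(junk = 1), tmp)
  expect_error(load_classifier(tmp), "version")
})

test_that("synthetic patch features train an accurate classifier", {
  sh <- shared_model()
  m <- sh$model
  pats <- sh$patches
  feats <- describe_patches(pats$patches, m$bank)
  vi <- m$valid_index
  pred <- classify(m, feats[vi, ])
  truth <- pats$labels[vi] == "bouton"
  acc <- mean((pred$label == "bouton") == truth)
  expect_gte(acc, 0.9)
  # balanced-design recall and precision on held-out patches
  rec <- sum(pred$label == "bouton" & truth) / sum(truth)
  prec <- sum(pred$label == "bouton" & truth) / sum(pred$label == "bouton")
  expect_gt(rec, 0.85)
  expect_gt(prec, 0.85)
})
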