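test_that("point-in-box matching follows the one-TP-per-box protocol", {
  bs <- box_set(data.frame(row_min = 10, col_min = 10, row_max = 34,
                           col_max = 34), c(100, 100))
  # one point inside one box
  cnt <- match_detections(data.frame(row = 20, col = 20), bs)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(1L, 0L, 0L))

  # two points in the same box: one TP, one FP
  cnt <- match_detections(data.frame(row = c(20, 22), col = c(20, 25)), bs)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(1L, 1L, 0L))

  # no points, three boxes: three FNs
  bs3 <- box_set(data.frame(row_min = c(1, 40, 70), col_min = c(1, 40, 70),
                            row_max = c(25, 64, 94), col_max = c(25, 64, 94)),
                 c(100, 100))
  cnt <- match_detections(data.frame(row = numeric(), col = numeric()), bs3)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(0L, 0L, 3L))

  # box edges are inclusive; points outside any box are FPs
  cnt <- match_detections(data.frame(row = c(10, 34, 35), col = c(10, 34, 90)),
                          bs)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(1L, 2L, 0L))
  expect_error(match_detections(data.frame(row = 200, col = 5), bs),
               "outside the frame")
})

test_that("tp + fn always equals the number of boxes", {
  set.seed(43)
  for (trial in 1:25) {
    n_box <- sample(0:6, 1)
    origins <- data.frame(r = sample(seq(1, 70, by = 14), n_box),
                          cl = sample(seq(1, 70, by = 14), n_box))
    bs <- box_set(data.frame(row_min = origins$r, col_min = origins$cl,
                             row_max = origins$r + 9, col_max = origins$cl + 9),
                  c(90, 90))
    pts <- data.frame(row = sample(90, 15, TRUE), col = sample(90, 15, TRUE),
                      score = runif(15, -1, 1))
    cnt <- match_detections(pts, bs)
    expect_equal(cnt$tp + cnt$fn, n_box)
  }
})

test_that("metrics follow the printed formulas and conventions", {
  expect_equal(metrics(match_counts(10, 4, 0)),
               c(precision = 10 / 14, recall = 1, f1 = 2 * (10/14) / (10/14 + 1)))
  expect_equal(unname(metrics(match_counts(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(metrics(match_counts(0, 5, 3))), c(0, 0, 0))
  # f1 lies between precision and recall
  m <- metrics(match_counts(7, 3, 2))
  expect_gte(m["f1"], min(m[c("precision", "recall")]))
  expect_lte(m["f1"], max(m[c("precision", "recall")]))
})

test_that("the published benchmark table is arithmetically consistent", {
  ref <- reference_metrics()
  expect_equal(nrow(ref), 20L)
  # rows 1 and 17 reproduce exactly at 2 dp from printed precision/recall
  for (i in c(1, 17)) {
    f1 <- 2 * ref$precision[i] * ref$recall[i] /
      (ref$precision[i] + ref$recall[i])
    expect_equal(round(f1, 2), ref$f1[i])
  }
  # every row agrees within one unit in the printed last digit (the rounding
  # propagation bound for 2-dp inputs)
  f1_all <- 2 * ref$precision * ref$recall / (ref$precision + ref$recall)
  expect_true(all(abs(f1_all - ref$f1) <= 0.01 + 1e-12))
})

test_that("threshold sweeps rebuild PR samples consistent with an oracle", {
  # all points at score +1: recall stays at its maximum across the sweep
  bs <- box_set(data.frame(row_min = c(5, 40), col_min = c(5, 40),
                           row_max = c(29, 64), col_max = c(29, 64)),
                c(80, 80))
  pts <- data.frame(row = c(10, 50), col = c(10, 50), score = c(1, 1))
  sw <- threshold_sweep(pts, bs, n_thresholds = 21)
  expect_true(all(sw$samples$recall == 1))

  # no points at all
  sw0 <- threshold_sweep(data.frame(row = numeric(), col = numeric(),
                                    score = numeric()), bs, n_thresholds = 11)
  expect_true(all(sw0$samples$precision == 0))
  expect_true(all(sw0$samples$recall == 0))

  # brute-force oracle: re-match independently at every threshold
  set.seed(53)
  origins <- data.frame(r = seq(5, 61, by = 14), cl = seq(5, 61, by = 14))
  bs5 <- box_set(data.frame(row_min = origins$r, col_min = origins$cl,
                            row_max = origins$r + 9, col_max = origins$cl + 9),
                 c(80, 80))
  pts <- data.frame(row = sample(80, 30, TRUE), col = sample(80, 30, TRUE),
                    score = runif(30, -1, 1))
  sw <- threshold_sweep(pts, bs5, n_thresholds = 41)
  for (k in seq_len(41)) {
    th <- sw$samples$threshold[k]
    kept <- pts[pts$score >= th, , drop = FALSE]
    cnt <- match_detections(kept, bs5)
    m <- metrics(cnt)
    expect_equal(sw$samples$precision[k], unname(m["precision"]))
    expect_equal(sw$samples$recall[k], unname(m["recall"]))
  }
  # recall is monotonically non-increasing in the threshold
  expect_true(all(diff(sw$samples$recall) <= 1e-12))
})

test_that("pixel TN mode counts the frame outside exclusion zones", {
  bs <- box_set(data.frame(row_min = 10, col_min = 10, row_max = 34,
                           col_max = 34), c(100, 100))
  cnt <- match_detections(data.frame(row = 22, col = 22), bs,
                          tn_mode = "pixel")
  expect_equal(cnt$tn, 100 * 100 - 25 * 25) # one 25x25 zone around the TP
  # empty box contributes an exclusion zone at its centre
  cnt2 <- match_detections(data.frame(row = numeric(), col = numeric()), bs,
                           tn_mode = "pixel")
  expect_equal(cnt2$tn, 100 * 100 - 25 * 25)
})

test_that("evaluation reports aggregate with mean and sample sd", {
  counts <- list(match_counts(8, 2, 0), match_counts(5, 5, 5))
  rep <- evaluation_report(counts)
  expect_equal(rep$per_image$precision, c(0.8, 0.5))
  expect_equal(rep$summary["mean", "precision"], 0.65)
  expect_equal(rep$summary["sd", "precision"], stats::sd(c(0.8, 0.5)))
})
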