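test_that("stack write/read round-trips losslessly", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  set.seed(41)
  vox <- array(runif(4 * 4 * 3), c(4, 4, 3))
  write_stack(image_stack(vox), tmp)
  st <- read_stack(tmp)
  expect_s3_class(st, "image_stack")
  expect_equal(dim(st$voxels), c(4, 4, 3))
  expect_equal(st$voxels, vox, tolerance = 1e-6) # float32 storage

  # integer 16-bit path is exact
  vox_i <- array(sample(0:4095, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  write_stack(image_stack(vox_i), tmp)
  expect_identical(read_stack(tmp)$voxels + 0, vox_i + 0)

  # single-page file gives a degenerate 1-slice stack
  tiff::writeTIFF(matrix(runif(16), 4), tmp, bits.per.sample = 32)
  expect_equal(dim(read_stack(tmp)$voxels)[3], 1L)
})

test_that("stack reader rejects missing and multi-channel input", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "cannot read")
  tmp <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(4 * 4 * 3), c(4, 4, 3)), tmp) # RGB page
  expect_error(read_stack(tmp), "3 channels")
})

test_that("mean projection is the per-pixel arithmetic mean over z", {
  # two constant slices of 0 and 2 average to 1
  st <- image_stack(array(rep(c(0, 2), each = 16), c(4, 4, 2)))
  expect_equal(mean_projection(st), matrix(1, 4, 4))

  # k identical slices project to that slice
  sl <- matrix(runif(36), 6)
  st <- image_stack(array(rep(sl, 4), c(6, 6, 4)))
  expect_equal(mean_projection(st), sl)

  # brute-force oracle on a random stack
  set.seed(7)
  vox <- array(runif(8 * 8 * 5), c(8, 8, 5))
  got <- mean_projection(image_stack(vox))
  want <- matrix(0, 8, 8)
  for (r in 1:8) for (cl in 1:8) {
    acc <- 0
    for (k in 1:5) acc <- acc + vox[r, cl, k]
    want[r, cl] <- acc / 5
  }
  expect_equal(got, want)
  # bounded by stack min/max
  expect_gte(min(got), min(vox))
  expect_lte(max(got), max(vox))
})

test_that("ground-truth masks decompose into per-component boxes", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(0, 64, 80)
  m[11:35, 41:65] <- 1 # rows 11..35, cols 41..65 (1-based)
  tiff::writeTIFF(m, tmp)
  bs <- read_groundtruth(tmp)
  expect_equal(length(bs), 1L)
  expect_equal(unlist(bs$boxes[1, ]), c(row_min = 11, col_min = 41,
                                        row_max = 35, col_max = 65))

  # empty mask
  tiff::writeTIFF(matrix(0, 16, 16), tmp)
  expect_equal(length(read_groundtruth(tmp)), 0L)

  # non-binary mask is rejected
  tiff::writeTIFF(matrix(c(0, 0.5, 1, 1), 2), tmp)
  expect_error(read_groundtruth(tmp), "not binary")
})

test_that("mask component boxes match a flood-fill oracle and 8-connectivity", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  set.seed(11)
  m <- matrix(0, 48, 48)
  m[5:12, 5:12] <- 1
  m[30:40, 20:28] <- 1
  tiff::writeTIFF(m, tmp)
  bs <- read_groundtruth(tmp)
  # flood-fill oracle: recursive scan over foreground pixels
  seen <- matrix(FALSE, 48, 48)
  comps <- list()
  for (p in which(m > 0)) {
    if (seen[p]) next
    stack_ <- p; members <- integer()
    while (length(stack_)) {
      q <- stack_[1]; stack_ <- stack_[-1]
      if (seen[q]) next
      seen[q] <- TRUE; members <- c(members, q)
      r <- (q - 1) %% 48 + 1; cl <- (q - 1) %/% 48 + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= 48 && cc >= 1 && cc <= 48 &&
            m[rr, cc] > 0 && !seen[(cc - 1) * 48 + rr]) {
          stack_ <- c(stack_, (cc - 1) * 48 + rr)
        }
      }
    }
    rc <- cbind((members - 1) %% 48 + 1, (members - 1) %/% 48 + 1)
    comps[[length(comps) + 1]] <- c(min(rc[, 1]), min(rc[, 2]),
                                    max(rc[, 1]), max(rc[, 2]))
  }
  want <- do.call(rbind, comps)
  got <- as.matrix(bs$boxes)
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ],
               ignore_attr = TRUE)

  # diagonal touch merges into one component under 8-connectivity
  m2 <- matrix(0, 8, 8); m2[2, 2] <- 1; m2[3, 3] <- 1
  tiff::writeTIFF(m2, tmp)
  expect_equal(length(read_groundtruth(tmp)), 1L)
})

test_that("box-set reading is idempotent under rasterization", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  bs <- box_set(data.frame(row_min = c(3, 20), col_min = c(5, 30),
                           row_max = c(10, 27), col_max = c(12, 37)),
                c(48, 48))
  tiff::writeTIFF(rasterize_boxes(bs), tmp)
  again <- read_groundtruth(tmp)
  expect_equal(again$boxes[order(again$boxes$row_min), ], bs$boxes,
               ignore_attr = TRUE)
})

test_that("CSV box lists round-trip through the 0-based interchange format", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  bs <- box_set(data.frame(row_min = 11, col_min = 41, row_max = 35,
                           col_max = 65), c(512, 512))
  write_boxes_csv(bs, tmp)
  txt <- readLines(tmp)
  expect_equal(txt[1], "x_min,y_min,x_max,y_max")
  expect_equal(txt[2], "40,10,64,34") # 0-based x/y
  back <- read_groundtruth(tmp, c(512, 512))
  expect_equal(back$boxes, bs$boxes, ignore_attr = TRUE)
})

test_that("degenerate and out-of-frame boxes are rejected", {
  expect_error(box_set(data.frame(5, 5, 4, 9), c(10, 10)), "degenerate")
  expect_error(box_set(data.frame(5, 5, 11, 9), c(10, 10)), "outside")
  expect_error(image_stack(array(-1, c(2, 2, 2))), "non-negative")
})
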