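#' Synthetic scene parameters
#'
#' Describes a simulated two-photon field of view: bright curvilinear axons
#' rendered as Gaussian tubes spread over a few adjacent optical sections,
#' Gaussian-blob boutons riding on them, detached blob-like distractors,
#' smooth low-intensity gaps along axons, and background plus read/shot
#' noise. Defaults emulate the acquisition geometry the detector targets:
#' 512 x 512 frames, ~20 slices, bouton standard deviation 4 px (radius about
#' `4 * sqrt(2)` px at 0.147 um/px), bouton peak about 3x the local axon
#' intensity, and read noise at 1% of the axon intensity.
#'
#' @param rows,cols,depth frame dimensions in voxels (at least 64 x 64 x 3).
#' @param n_axons number of axons.
#' @param axon_intensity shaft peak intensity (arbitrary units).
#' @param axon_sd tube cross-section standard deviation in pixels.
#' @param boutons_per_axon boutons placed along each axon.
#' @param bouton_amplitude bouton peak / local axon intensity ratio (> 1).
#' @param bouton_sd bouton Gaussian standard deviation in pixels.
#' @param min_spacing minimum pairwise Euclidean distance between bouton
#'   centres in pixels.
#' @param background constant background level.
#' @param read_noise_sd Gaussian read-noise standard deviation (absolute
#'   intensity units; the default is 1% of `axon_intensity`).
#' @param shot_noise add Poisson shot noise at `photon_budget` photons per
#'   `axon_intensity` unit.
#' @param photon_budget photons corresponding to the axon shaft intensity.
#' @param n_distractors detached bouton-sized blobs (blob-like noise).
#' @param gap_modulation modulate axon intensity with a smooth random gain in
#'   `[0.3, 1]` (apparent gaps); the gain is held at 1 near boutons.
#' @param seed integer seed; all randomness in generation flows from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(rows = 512L, cols = 512L, depth = 20L,
                         n_axons = 3L, axon_intensity = 100,
                         axon_sd = 1.5, boutons_per_axon = 5L,
                         bouton_amplitude = 3, bouton_sd = 4,
                         min_spacing = 30, background = 10,
                         read_noise_sd = 1, shot_noise = FALSE,
                         photon_budget = 500, n_distractors = 5L,
                         gap_modulation = TRUE, seed = 1L) {
  stopifnot(rows >= 64, cols >= 64, depth >= 3,
            min_spacing > 0, bouton_amplitude > 1, bouton_sd > 0,
            axon_intensity > 0, n_axons >= 1)
  structure(as.list(environment()), class = "scene_params")
}

# Smooth random curve across the frame: endpoints on opposite borders,
# interior waypoints jittered, interpolated by natural splines; returns
# densely sampled (row, col) positions.
sample_axon_curve <- function(rows, cols) {
  horizontal <- stats::runif(1) < 0.5
  n_way <- 6L
  t <- seq(0, 1, length.out = n_way)
  if (horizontal) {
    x <- c(1, stats::runif(n_way - 2, 0.1 * cols, 0.9 * cols), cols)
    x <- sort(x)
    y <- stats::runif(n_way, 0.12 * rows, 0.88 * rows)
  } else {
    y <- c(1, stats::runif(n_way - 2, 0.1 * rows, 0.9 * rows), rows)
    y <- sort(y)
    x <- stats::runif(n_way, 0.12 * cols, 0.88 * cols)
  }
  tt <- seq(0, 1, length.out = 4L * max(rows, cols))
  rr <- stats::spline(t, y, xout = tt, method = "natural")$y
  cc <- stats::spline(t, x, xout = tt, method = "natural")$y
  ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
  cbind(row = rr[ok], col = cc[ok])
}

# Gaussian blur via the package's mirror-boundary convolution.
gauss_blur <- function(m, sd) {
  h <- max(ceiling(3 * sd), 2L)
  g <- seq(-h, h)
  k <- exp(-g^2 / (2 * sd^2))
  k2 <- outer(k, k); k2 <- k2 / sum(k2)
  convolve_mirror(m, k2)
}

# Add a 2D Gaussian blob of the given peak to a matrix, in place by value.
add_blob <- function(m, row, col, sd, peak) {
  h <- ceiling(4 * sd)
  r0 <- max(1L, round(row) - h); r1 <- min(nrow(m), round(row) + h)
  c0 <- max(1L, round(col) - h); c1 <- min(ncol(m), round(col) + h)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  m[rr, cc] <- m[rr, cc] + peak * exp(-d2 / (2 * sd^2))
  m
}

#' Generate a synthetic stack with known bouton ground truth
#'
#' Renders the scene described by `params` fully deterministically given the
#' seed. Each axon is a smooth random spline curve rendered as a Gaussian
#' tube and spread over 2-4 adjacent z-slices; each bouton is a 2D Gaussian
#' varicosity added on one slice, with its peak set to
#' `(bouton_amplitude - 1)` times the local z-summed axon intensity so that
#' the projected peak-to-shaft ratio equals `bouton_amplitude` by
#' construction. Ground-truth boxes are 25 x 25 squares centred on the bouton
#' centres.
#'
#' @param params a [scene_params()].
#' @return A list with `stack` ([image_stack()]), `boxes` ([box_set()]),
#'   `centres` (data.frame `row`, `col`, `z`, 1-based), and `scene`
#'   (centerline and distractor annotations used for patch sampling).
#' @export
generate_stack <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  with_seed(p$seed, function() {
    margin <- 14L  # keeps 25x25 boxes inside the frame
    axial <- array(0, c(p$rows, p$cols, p$depth))
    curves <- vector("list", p$n_axons)
    zinfo <- vector("list", p$n_axons)

    # --- bouton centres: arc positions with global min spacing -------------
    centres <- NULL
    curve_list <- lapply(seq_len(p$n_axons), function(a) sample_axon_curve(p$rows, p$cols))
    placed <- matrix(numeric(0), ncol = 2)
    bouton_arc <- vector("list", p$n_axons)
    for (a in seq_len(p$n_axons)) {
      crv <- curve_list[[a]]
      interior <- which(crv[, 1] > margin & crv[, 1] <= p$rows - margin &
                          crv[, 2] > margin & crv[, 2] <= p$cols - margin)
      picks <- integer(0)
      tries <- 0L
      while (length(picks) < p$boutons_per_axon) {
        tries <- tries + 1L
        if (tries > 4000L) {
          stop("infeasible bouton spacing: cannot place ", p$boutons_per_axon,
               " boutons at min_spacing ", p$min_spacing)
        }
        cand <- sample(interior, 1L)
        pt <- crv[cand, ]
        all_pts <- rbind(placed, crv[picks, , drop = FALSE])
        if (nrow(all_pts) == 0L ||
            min(sqrt(rowSums(sweep(all_pts, 2, pt)^2))) >= p$min_spacing) {
          picks <- c(picks, cand)
        }
      }
      placed <- rbind(placed, crv[picks, , drop = FALSE])
      bouton_arc[[a]] <- picks
      curves[[a]] <- crv
    }

    # --- render axon tubes over z ------------------------------------------
    for (a in seq_len(p$n_axons)) {
      crv <- curves[[a]]
      canvas <- matrix(0, p$rows, p$cols)
      gain <- rep(1, nrow(crv))
      if (p$gap_modulation) {
        nk <- 8L
        kt <- seq(0, 1, length.out = nk)
        kv <- stats::runif(nk, 0.3, 1)
        gain <- stats::spline(kt, kv, xout = seq(0, 1, length.out = nrow(crv)),
                              method = "natural")$y
        gain <- clamp(gain, 0.3, 1)
        # boutons are bright: hold the gain up near bouton arc positions
        for (b in bouton_arc[[a]]) {
          near <- abs(seq_len(nrow(crv)) - b) <= 40L
          gain[near] <- pmax(gain[near], 1)
        }
      }
      idx <- cbind(round(crv[, 1]), round(crv[, 2]))
      lin <- (idx[, 2] - 1L) * p$rows + idx[, 1]
      for (i in seq_along(lin)) canvas[lin[i]] <- max(canvas[lin[i]], gain[i])
      tube <- gauss_blur(canvas, p$axon_sd)
      shaft <- stats::quantile(tube[lin], 0.9, names = FALSE)
      if (shaft > 0) tube <- tube / shaft
      # z spread over 2-4 adjacent slices
      nz <- sample(2:4, 1L)
      zc <- sample(seq(2L, p$depth - 2L), 1L)
      zs <- zc + seq(0, nz - 1L) - (nz %/% 2L)
      zs <- zs[zs >= 1L & zs <= p$depth]
      w <- exp(-((zs - zc)^2) / 2); w <- w / sum(w)
      for (k in seq_along(zs)) {
        axial[, , zs[k]] <- axial[, , zs[k]] + p$axon_intensity * w[k] * tube
      }
      zinfo[[a]] <- list(zc = zc, zs = zs)
    }

    # --- distractor blobs (blob-like noise, detached from axons) -----------
    distractors <- NULL
    if (p$n_distractors > 0L) {
      all_curve_pts <- do.call(rbind, curves)
      got <- 0L; tries <- 0L
      while (got < p$n_distractors && tries < 2000L) {
        tries <- tries + 1L
        r <- stats::runif(1, margin + 1, p$rows - margin)
        cl <- stats::runif(1, margin + 1, p$cols - margin)
        d_axon <- min(sqrt((all_curve_pts[, 1] - r)^2 +
                             (all_curve_pts[, 2] - cl)^2))
        d_bout <- if (nrow(placed)) {
          min(sqrt((placed[, 1] - r)^2 + (placed[, 2] - cl)^2))
        } else Inf
        if (d_axon < 25 || d_bout < p$min_spacing) next
        got <- got + 1L
        z <- sample(seq_len(p$depth), 1L)
        axial[, , z] <- add_blob(axial[, , z], r, cl, p$bouton_sd,
                                 p$axon_intensity)
        distractors <- rbind(distractors, c(row = r, col = cl, z = z))
      }
    }

    # --- boutons -----------------------------------------------------------
    centres <- NULL
    for (a in seq_len(p$n_axons)) {
      crv <- curves[[a]]
      for (b in bouton_arc[[a]]) {
        r <- crv[b, 1]; cl <- crv[b, 2]
        ri <- round(r); ci <- round(cl)
        a_local <- sum(axial[ri, ci, ])  # z-summed axon intensity here
        zb <- zinfo[[a]]$zc
        axial[, , zb] <- add_blob(axial[, , zb], r, cl, p$bouton_sd,
                                  (p$bouton_amplitude - 1) * a_local)
        centres <- rbind(centres, data.frame(row = ri, col = ci, z = zb))
      }
    }

    # --- background and noise ---------------------------------------------
    vox <- axial + p$background
    if (p$shot_noise) {
      scale <- p$photon_budget / p$axon_intensity
      vox <- array(stats::rpois(length(vox), lambda = pmax(vox, 0) * scale),
                   dim(vox)) / scale
    }
    if (p$read_noise_sd > 0) {
      vox <- vox + stats::rnorm(length(vox), sd = p$read_noise_sd)
    }
    vox <- pmax(vox, 0)

    half <- 12L
    boxes <- box_set(data.frame(row_min = centres$row - half,
                                col_min = centres$col - half,
                                row_max = centres$row + half,
                                col_max = centres$col + half),
                     c(p$rows, p$cols))
    list(stack = image_stack(vox),
         boxes = boxes,
         centres = centres,
         scene = list(curves = curves, bouton_arc = bouton_arc,
                      distractors = distractors, zinfo = zinfo,
                      params = p))
  })
}

#' Generate labelled training patches
#'
#' Draws balanced bouton / non-bouton 25 x 25 patches from synthetic scenes
#' processed exactly as at detection time: by default patches are cut from
#' the raw mean projection (where the axon context that separates boutons
#' from detached blob-like noise is preserved); `patch_source = "enhanced"`
#' cuts from the LoG-enhanced projection instead.
#' Positive patches are centred on generated boutons. Negative patches are
#' centred on axon structure — shaft points away from any bouton, axon
#' crossings, or detached distractor blobs — never on blank background, so
#' every negative contains structure the classifier must reject.
#'
#' @param params a [scene_params()]; scenes are generated at these settings
#'   with seeds derived from `params$seed` until `n_per_class` positives are
#'   collected.
#' @param n_per_class patches per class (default 450, giving the canonical
#'   900-patch training set).
#' @param enh_config the [enhancement_config()] used when
#'   `patch_source = "enhanced"`.
#' @param patch_source extract patches from the raw `"projection"` (default,
#'   matching the detection pipeline) or the `"enhanced"` projection.
#' @return A list with `patches` (25 x 25 x 2*n_per_class array), `labels`
#'   (factor bouton/nonbouton), and `source` (data.frame of scene seed and
#'   centre coordinates per patch).
#' @export
generate_patches <- function(params = scene_params(rows = 256L, cols = 256L),
                             n_per_class = 450L,
                             enh_config = enhancement_config(),
                             patch_source = c("projection", "enhanced")) {
  stopifnot(n_per_class >= 1)
  patch_source <- match.arg(patch_source)
  size <- c(25L, 25L)
  pos <- list(); neg <- list()
  src <- list()
  scene_i <- 0L
  while (length(pos) < n_per_class || length(neg) < n_per_class) {
    scene_i <- scene_i + 1L
    if (scene_i > 500L) stop("could not collect enough patches")
    sp <- params
    sp$seed <- (params$seed * 1000L + scene_i) %% .Machine$integer.max
    # crowded waypoint draws can make the spacing constraint infeasible in
    # compact frames; skip such scene seeds
    gen <- tryCatch(generate_stack(sp), error = function(e) NULL)
    if (is.null(gen)) next
    img <- mean_projection(gen$stack)
    if (patch_source == "enhanced") img <- enhance(img, enh_config)

    grab <- function(r, cl) extract_patch(img, list(row = r, col = cl), size)

    # positives: bouton centres
    for (i in seq_len(nrow(gen$centres))) {
      if (length(pos) >= n_per_class) break
      pos[[length(pos) + 1L]] <- grab(gen$centres$row[i], gen$centres$col[i])
      src[[length(src) + 1L]] <- data.frame(seed = sp$seed, label = "bouton",
                                            row = gen$centres$row[i],
                                            col = gen$centres$col[i])
    }

    # negatives: crossings, distractors, then shaft points
    negs_here <- list()
    crvs <- gen$scene$curves
    if (length(crvs) > 1L) {
      for (a in seq_len(length(crvs) - 1L)) for (b in (a + 1L):length(crvs)) {
        ca <- crvs[[a]]; cb <- crvs[[b]]
        sub <- ca[seq(1, nrow(ca), by = 8L), , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
          d <- sqrt((cb[, 1] - sub[i, 1])^2 + (cb[, 2] - sub[i, 2])^2)
          if (min(d) < 1.5) {
            negs_here[[length(negs_here) + 1L]] <- sub[i, ]
            break
          }
        }
      }
    }
    if (!is.null(gen$scene$distractors)) {
      for (i in seq_len(nrow(gen$scene$distractors))) {
        negs_here[[length(negs_here) + 1L]] <- gen$scene$distractors[i, 1:2]
      }
    }
    # shaft points away from boutons
    margin <- 14L
    shaft_budget <- max(4L, length(negs_here))
    bc <- as.matrix(gen$centres[, c("row", "col")])
    for (a in seq_along(crvs)) {
      crv <- crvs[[a]]
      cand <- crv[seq(1, nrow(crv), length.out = 40L), , drop = FALSE]
      ok <- apply(cand, 1, function(pt) {
        pt[1] > margin && pt[1] <= params$rows - margin &&
          pt[2] > margin && pt[2] <= params$cols - margin &&
          min(sqrt((bc[, 1] - pt[1])^2 + (bc[, 2] - pt[2])^2)) > 20
      })
      cand <- cand[ok, , drop = FALSE]
      take <- utils::head(seq_len(nrow(cand)), shaft_budget)
      for (i in take) negs_here[[length(negs_here) + 1L]] <- cand[i, ]
    }
    for (pt in negs_here) {
      if (length(neg) >= n_per_class) break
      r <- as.integer(round(pt[[1]])); cl <- as.integer(round(pt[[2]]))
      neg[[length(neg) + 1L]] <- grab(r, cl)
      src[[length(src) + 1L]] <- data.frame(seed = sp$seed, label = "nonbouton",
                                            row = r, col = cl)
    }
  }
  patches <- array(0, c(size, 2L * n_per_class))
  labels <- character(2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    patches[, , i] <- pos[[i]]; labels[i] <- "bouton"
    patches[, , n_per_class + i] <- neg[[i]]
    labels[n_per_class + i] <- "nonbouton"
  }
  list(patches = patches,
       labels = factor(labels, levels = c("bouton", "nonbouton")),
       source = do.call(rbind, src))
}

#' Describe a patch array as a feature matrix
#'
#' @param patches 25 x 25 x n array (e.g. from [generate_patches()]).
#' @param bank a [build_bank()].
#' @return n x V feature matrix.
#' @export
describe_patches <- function(patches, bank = build_bank()) {
  n <- dim(patches)[3]
  t(vapply(seq_len(n), function(i) describe(patches[, , i], bank),
           numeric(length(bank$filters))))
}
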