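#' Synthetic ultrasound-phantom specification
#'
#' Describes one synthetic B-mode-like texture: a Rayleigh-distributed
#' speckle envelope, spatially smoothed to give the speckle a correlation
#' length, rescaled to 8-bit, with an optional lesion drawn on top. The
#' generator is a stand-in for homogeneous parenchymal speckle, not a
#' physics simulation: there is no beam model, attenuation, shadowing or
#' log-compression.
#'
#' Lesion types:
#' * `"none"` — plain speckle (normal parenchyma).
#' * `"microliths"` — small bright circular foci without shadowing
#'   (see [insert_microliths()]).
#' * `"cyst"` — a near-anechoic ellipse crossed by thin bright septa
#'   (see [insert_cyst()]).
#' * `"heterogeneous"` — a smooth multiplicative gain field emulating
#'   patchy, non-homogeneous parenchyma (see [apply_heterogeneity()]).
#'
#' @param shape Integer `c(height, width)` in pixels (default 128 x 128).
#' @param speckle_mean Target mean gray level of the speckle background
#'   after 8-bit rescaling (default 120).
#' @param speckle_scale Rayleigh scale (sigma) of the raw envelope
#'   (default 1; arbitrary units — the envelope is rescaled).
#' @param smoothing_radius Gaussian sigma in pixels applied to the
#'   envelope (speckle correlation length, default 1.2; 0 disables).
#' @param lesion Lesion type (see above).
#' @param lesion_args Named list of arguments forwarded to the lesion
#'   inserter (e.g. `count`, `radius_px`, `intensity_gain` for
#'   microliths).
#' @param seed Integer seed; identical spec + seed give identical images.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), speckle_mean = 120,
                         speckle_scale = 1, smoothing_radius = 1.2,
                         lesion = c("none", "microliths", "cyst",
                                    "heterogeneous"),
                         lesion_args = list(), seed = 1L) {
  lesion <- match.arg(lesion)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be c(height, width) with both >= 8", call. = FALSE)
  if (speckle_scale <= 0) stop("speckle_scale must be > 0", call. = FALSE)
  if (speckle_mean <= 0 || speckle_mean > 255)
    stop("speckle_mean must be in (0, 255]", call. = FALSE)
  if (smoothing_radius < 0) stop("smoothing_radius must be >= 0",
                                 call. = FALSE)
  structure(list(shape = shape, speckle_mean = speckle_mean,
                 speckle_scale = speckle_scale,
                 smoothing_radius = smoothing_radius, lesion = lesion,
                 lesion_args = lesion_args, seed = as.integer(seed)),
            class = "phantom_spec")
}

# raw Rayleigh envelope, one iid draw per pixel (before smoothing/rescale)
rayleigh_envelope <- function(h, w, scale, seed) {
  withr::with_seed(seed, {
    u <- stats::runif(h * w)
    matrix(scale * sqrt(-2 * log(u)), nrow = h, ncol = w)
  })
}

gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  # gblur's default brush is 2*ceiling(3*sigma)+1 wide; cap it so small
  # phantoms remain smoothable
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                2L * (min(dim(mat)) %/% 2L) - 1L)
  EBImage::gblur(mat, sigma = sigma, radius = radius)
}

#' Generate homogeneous speckle
#'
#' Draws an independent Rayleigh envelope per pixel, smooths it with a
#' Gaussian of the spec's `smoothing_radius`, and rescales so the
#' background mean lands at `speckle_mean` on the 8-bit scale (values
#' clipped to `[0, 255]`). Deterministic under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_image()] (256 levels).
#' @export
make_speckle <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec()")
  env <- rayleigh_envelope(spec$shape[1], spec$shape[2],
                           spec$speckle_scale, spec$seed)
  env <- gaussian_smooth(env, spec$smoothing_radius)
  px <- round_half_to_zero(pmin(pmax(env / mean(env) * spec$speckle_mean,
                                     0), 255))
  gray_image(px, levels = 256L)
}

#' Insert hyperechoic microlith foci
#'
#' Draws `count` bright circular foci of radius `radius_px` at
#' non-overlapping random positions, emulating pinpoint-to-small
#' well-defined hyperechoic foci; no acoustic shadow is drawn. The focus
#' gain is added to the underlying speckle and clipped to 255.
#'
#' @param image Background [gray_image()] (256 levels).
#' @param count Number of foci (>= 1).
#' @param radius_px Focus radius in pixels: a scalar, or a length-2 range
#'   from which an integer radius is drawn per focus (default `c(1, 3)`).
#' @param intensity_gain Gray levels added inside each focus (default 120).
#' @param seed Integer seed for focus placement.
#' @return List with `image` (modified [gray_image()]) and `foci`
#'   (tibble of ground-truth `x`, `y`, `radius`, 0-based center
#'   coordinates).
#' @export
insert_microliths <- function(image, count = 10L, radius_px = c(1L, 3L),
                              intensity_gain = 120, seed = 1L) {
  image <- as_gray_image(image)
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  rr <- range(as.integer(radius_px))
  h <- image$height; w <- image$width
  if (2L * rr[2] + 1L > min(h, w) / 4L)
    stop("radius too large relative to image for pinpoint foci",
         call. = FALSE)
  placed <- withr::with_seed(seed, {
    xs <- integer(0); ys <- integer(0); rs <- integer(0)
    tries <- 0L
    while (length(xs) < count && tries < 2000L) {
      tries <- tries + 1L
      r <- if (rr[1] == rr[2]) rr[1] else sample(rr[1]:rr[2], 1L)
      x <- sample((r + 1L):(w - r) - 1L, 1L)  # 0-based center
      y <- sample((r + 1L):(h - r) - 1L, 1L)
      if (length(xs) == 0L ||
          all((xs - x)^2 + (ys - y)^2 > (rs + r + 2L)^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      }
    }
    list(x = xs, y = ys, r = rs)
  })
  if (length(placed$x) < count)
    stop(sprintf(
      "cannot place %d non-overlapping foci in a %d x %d image; try fewer foci",
      count, h, w), call. = FALSE)
  px <- image$pixels
  for (k in seq_len(count)) {
    disk <- disk_mask(h, w, placed$x[k], placed$y[k], placed$r[k])
    px[disk] <- pmin(px[disk] + round(intensity_gain), 255L)
  }
  list(image = gray_image(px, levels = image$levels),
       foci = tibble::tibble(x = placed$x, y = placed$y,
                             radius = placed$r))
}

# logical mask of pixels within radius of a 0-based (cx, cy) center
disk_mask <- function(h, w, cx, cy, radius) {
  rowd <- (seq_len(h) - 1L) - cy
  cold <- (seq_len(w) - 1L) - cx
  outer(rowd^2, cold^2, `+`) <= radius^2
}

#' Insert a septated cystic lesion
#'
#' Replaces an elliptical region with near-anechoic content — a fresh
#' low-mean Rayleigh noise floor (`interior_mean`, well below the speckle
#' background) rather than a flat fill, since anechoic regions in B-mode
#' images still carry electronic noise and reverberation speckle — and
#' draws `septa_count` thin bright line segments across the interior with
#' per-pixel intensity jitter, emulating a septated cystic nodular lesion.
#'
#' @param image Background [gray_image()] (256 levels).
#' @param center 0-based `c(x, y)` ellipse center (default: image center).
#' @param axes `c(semi_x, semi_y)` ellipse semi-axes in pixels.
#' @param septa_count Number of septa (default 2; 0 gives a plain cyst).
#' @param septa_intensity Central gray level of the septa (default 180;
#'   drawn with +/- 35 uniform jitter, clipped to 255).
#' @param interior_mean Mean gray level of the interior noise floor
#'   (default 18, about 15% of the default speckle mean).
#' @param seed Integer seed for interior noise and septa orientation.
#' @return Modified [gray_image()].
#' @export
insert_cyst <- function(image, center = NULL, axes = NULL,
                        septa_count = 2L, septa_intensity = 180,
                        interior_mean = 18, seed = 1L) {
  image <- as_gray_image(image)
  h <- image$height; w <- image$width
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  if (is.null(axes)) axes <- c(floor(w / 4), floor(h / 5))
  if (any(axes < 2))
    stop("ellipse axes must be >= 2 pixels", call. = FALSE)
  if (center[1] - axes[1] < 0 || center[1] + axes[1] > w - 1 ||
      center[2] - axes[2] < 0 || center[2] + axes[2] > h - 1)
    stop(sprintf(
      "ellipse (center %g,%g axes %g,%g) out of bounds for %d x %d image",
      center[1], center[2], axes[1], axes[2], h, w), call. = FALSE)
  xs <- (seq_len(w) - 1L) - center[1]
  ys <- (seq_len(h) - 1L) - center[2]
  inside <- outer(ys^2 / axes[2]^2, xs^2 / axes[1]^2, `+`) <= 1
  px <- image$pixels
  septa_count <- as.integer(septa_count)
  withr::with_seed(seed, {
    # interior: Rayleigh noise floor scaled so its mean is interior_mean
    n_in <- sum(inside)
    floor_vals <- sqrt(-2 * log(stats::runif(n_in))) / sqrt(pi / 2) *
      interior_mean
    px[inside] <- as.integer(pmin(pmax(round(floor_vals), 0), 255))
    if (septa_count > 0L) {
      angles <- stats::runif(septa_count, 0, pi)
      for (a in angles) {
        # chord through the center at angle a, clipped to the ellipse
        tmax <- 1 / sqrt(cos(a)^2 / axes[1]^2 + sin(a)^2 / axes[2]^2)
        t <- seq(-tmax, tmax, by = 0.4)
        cxs <- as.integer(round(center[1] + t * cos(a)))
        cys <- as.integer(round(center[2] + t * sin(a)))
        ok <- cxs >= 0L & cxs < w & cys >= 0L & cys < h
        idx <- unique(cbind(cys[ok] + 1L, cxs[ok] + 1L))
        idx <- idx[inside[idx], , drop = FALSE]
        jitter <- stats::runif(nrow(idx), -35, 35)
        px[idx] <- as.integer(pmin(pmax(round(septa_intensity + jitter), 0),
                                   255))
      }
    }
  })
  gray_image(px, levels = image$levels)
}

#' Apply a heterogeneous parenchyma gain field
#'
#' Multiplies the image by a smooth random gain field (uniform noise
#' blurred at `patch_scale`, rescaled into `gain_range`), emulating areas
#' of non-homogeneous parenchyma.
#'
#' @param image Background [gray_image()] (256 levels).
#' @param patch_scale Gaussian sigma in pixels of the gain field
#'   (default 12; larger = coarser patches).
#' @param gain_range `c(low, high)` multiplicative gain bounds
#'   (default `c(0.55, 1.45)`).
#' @param seed Integer seed.
#' @return Modified [gray_image()].
#' @export
apply_heterogeneity <- function(image, patch_scale = 12,
                                gain_range = c(0.55, 1.45), seed = 1L) {
  image <- as_gray_image(image)
  if (gain_range[1] >= gain_range[2] || gain_range[1] < 0)
    stop("gain_range must be an increasing non-negative pair", call. = FALSE)
  h <- image$height; w <- image$width
  noise <- withr::with_seed(seed, matrix(stats::runif(h * w), h, w))
  field <- gaussian_smooth(noise, patch_scale)
  rng <- range(field)
  gain <- if (rng[1] == rng[2]) {
    matrix(mean(gain_range), h, w)
  } else {
    gain_range[1] + (field - rng[1]) / (rng[2] - rng[1]) *
      (gain_range[2] - gain_range[1])
  }
  px <- round_half_to_zero(pmin(pmax(image$pixels * gain, 0), 255))
  gray_image(px, levels = image$levels)
}

#' Generate one phantom image from its spec
#'
#' Builds the speckle background and applies the lesion named in the spec.
#' Lesion placement uses a seed derived deterministically from the spec
#' seed, so the whole phantom is a pure function of its spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_image()].
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec()")
  img <- make_speckle(spec)
  lesion_seed <- derive_seed(spec$seed, 104729L)
  switch(spec$lesion,
         none = img,
         microliths = do.call(insert_microliths,
                              c(list(image = img, seed = lesion_seed),
                                spec$lesion_args))$image,
         cyst = do.call(insert_cyst,
                        c(list(image = img, seed = lesion_seed),
                          spec$lesion_args)),
         heterogeneous = do.call(apply_heterogeneity,
                                 c(list(image = img, seed = lesion_seed),
                                   spec$lesion_args)))
}

# deterministic seed derivation, kept within the 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k)) %% 2147483647)
}

#' Cohort specification for phantom generation
#'
#' Describes a labeled cohort of phantom images: group sizes for normal,
#' microlith and "other" lesions, per-group phantom templates, and a
#' master seed. Defaults mirror a study-scale cohort of 280 images
#' (245 normal, 16 microlith, 19 other); `other` phantoms alternate
#' deterministically between septated cysts and heterogeneous parenchyma.
#'
#' @param n_normal,n_microlith,n_other Group sizes (defaults 245, 16, 19).
#' @param shape Image shape passed to each [phantom_spec()].
#' @param seed Master seed; per-image seeds are derived from it.
#' @param microlith_args,cyst_args,heterogeneous_args Named lists of
#'   lesion arguments overriding the inserter defaults.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 245L, n_microlith = 16L, n_other = 19L,
                        shape = c(128L, 128L), seed = 7L,
                        microlith_args = list(),
                        cyst_args = list(),
                        heterogeneous_args = list()) {
  sizes <- as.integer(c(n_normal, n_microlith, n_other))
  if (any(sizes < 0L) || sum(sizes) < 1L)
    stop("group sizes must be non-negative with at least one image",
         call. = FALSE)
  structure(list(n_normal = sizes[1], n_microlith = sizes[2],
                 n_other = sizes[3], shape = as.integer(shape),
                 seed = as.integer(seed),
                 microlith_args = microlith_args, cyst_args = cyst_args,
                 heterogeneous_args = heterogeneous_args),
            class = "cohort_spec")
}

#' Generate a labeled phantom cohort on disk
#'
#' Writes one 8-bit grayscale PNG per phantom plus a ROI/label CSV
#' (`rois.csv`) covering each full image as one ROI, directly consumable
#' by [extract_features()]. Plane and side tags cycle deterministically
#' (sagittal/transverse, left/right) to mimic a four-images-per-subject
#' acquisition. Fully deterministic under the master seed: rerunning with
#' the same spec yields byte-identical PNGs and CSV.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the ROI table written to `dir/rois.csv`.
#' @export
make_cohort <- function(spec, dir) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop(sprintf("output path '%s' is not writable", dir), call. = FALSE)
  labels <- c(rep("normal", spec$n_normal),
              rep("microlith", spec$n_microlith),
              rep("other", spec$n_other))
  n <- length(labels)
  planes <- rep(c("sagittal", "transverse"), length.out = n)
  sides <- rep(c("left", "left", "right", "right"), length.out = n)
  rows <- vector("list", n)
  other_idx <- 0L
  for (i in seq_len(n)) {
    seed_i <- derive_seed(spec$seed, i)
    lesion <- switch(labels[i],
                     normal = "none",
                     microlith = "microliths",
                     other = {
                       other_idx <- other_idx + 1L
                       if (other_idx %% 2L == 1L) "cyst" else "heterogeneous"
                     })
    args <- switch(lesion,
                   none = list(),
                   microliths = spec$microlith_args,
                   cyst = spec$cyst_args,
                   heterogeneous = spec$heterogeneous_args)
    img <- make_phantom(phantom_spec(shape = spec$shape, lesion = lesion,
                                     lesion_args = args, seed = seed_i))
    image_id <- sprintf("phantom_%04d.png", i)
    png::writePNG(img$pixels / 255, file.path(dir, image_id))
    rows[[i]] <- tibble::tibble(
      image_id = image_id, x0 = 0L, y0 = 0L,
      x1 = img$width, y1 = img$height,
      plane = planes[i], side = sides[i],
      mineralization = labels[i] == "microlith",
      nodule = labels[i] == "other",
      lesion_label = labels[i])
  }
  rois <- do.call(rbind, rows)
  readr::write_csv(rois, file.path(dir, "rois.csv"), progress = FALSE)
  invisible(rois)
}
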