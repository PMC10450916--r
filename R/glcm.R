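#' Gray-level image container
#'
#' Light-weight container for a single-channel image whose pixels are
#' integers in `[0, levels - 1]`. This is the unit of texture analysis:
#' every other operation in the package (cropping, GLCM construction,
#' phantom generation) consumes or produces a `gray_image`.
#'
#' @param pixels Integer matrix (rows = image rows, i.e. `y`; columns = `x`).
#'   Numeric input is accepted if it holds whole numbers.
#' @param levels Number of gray levels (default 256 for 8-bit data). All
#'   pixels must lie in `[0, levels - 1]`.
#'
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   (integer matrix), `height`, `width` and `levels`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2), levels = 4)
#' img$height
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (is.null(dim(pixels)) || length(pixels) == 0L)
    stop("empty image", call. = FALSE)
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers; use quantize_image() first",
         call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (any(pixels < 0L) || any(pixels > levels - 1L))
    stop("pixel exceeds gray-level range", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         levels = levels),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels, range [%d, %d]>\n",
              x$height, x$width, x$levels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_gray_image <- function(x, levels = 256L) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, levels = levels)
}

#' Quantize a numeric image to integer gray levels
#'
#' Linearly rescales the range `[min, max]` of the input onto the integer
#' range `[0, levels - 1]`. A constant input maps to all zeros. Values are
#' rounded half toward zero (so 1.5 becomes 1), which makes the operation
#' idempotent on inputs that are already integers in range.
#'
#' @param raw Numeric matrix.
#' @param levels Target number of gray levels (default 256).
#' @return A [gray_image()].
#' @examples
#' quantize_image(matrix(c(0, 0.5, 1), 1, 3), levels = 4)$pixels
#' @export
quantize_image <- function(raw, levels = 256L) {
  if (is.null(raw) || length(raw) == 0L) stop("empty image", call. = FALSE)
  raw <- as.matrix(raw)
  if (any(!is.finite(raw)))
    stop("image contains non-finite pixel values", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    q <- matrix(0L, nrow(raw), ncol(raw))
  } else {
    scaled <- (raw - rng[1]) / (rng[2] - rng[1]) * (levels - 1L)
    q <- round_half_to_zero(scaled)
  }
  gray_image(q, levels = levels)
}

# round half toward zero; scaled GLCM intensities are always >= 0 here but
# the negative branch keeps the rule total
round_half_to_zero <- function(x) {
  ifelse(x >= 0, ceiling(x - 0.5), floor(x + 0.5))
}

#' GLCM construction parameters
#'
#' Parameters controlling gray-level co-occurrence matrix construction.
#' Defaults mirror common ultrasound texture-analysis practice: paired
#' distance 5 pixels, 256 gray levels (8-bit), symmetric and normalized.
#'
#' The angle fixes the offset of the neighbor pixel relative to the
#' reference pixel: 0 degrees is `distance` pixels to the right, and
#' 45/90/135 degrees rotate counter-clockwise (up-right, up, up-left in
#' image coordinates). For a symmetric GLCM the opposite direction is
#' counted as well, so the matrix is direction-insensitive.
#'
#' @param distance Paired distance in pixels (positive integer, default 5).
#' @param angle One of 0, 45, 90, 135 (degrees, default 0).
#' @param levels Number of gray levels (default 256).
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @param normalized Divide counts by their total so entries sum to 1
#'   (default `TRUE`).
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(distance = 5L, angle = 0, levels = 256L,
                        symmetric = TRUE, normalized = TRUE) {
  distance <- as.integer(distance)
  levels <- as.integer(levels)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (!angle %in% c(0, 45, 90, 135))
    stop("angle must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  structure(
    list(distance = distance, angle = angle, levels = levels,
         symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
    class = "glcm_params")
}

# (row, col) offset of the neighbor pixel for an angle/distance pair
glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("angle must be one of 0, 45, 90, 135 degrees", call. = FALSE))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts, for every pixel whose offset neighbor lies inside the image, the
#' co-occurrence of the (reference, neighbor) gray-level pair. For an 8-bit
#' image with `levels = 256` the resulting matrix has 256 rows and 256
#' columns; cell `(i, j)` (1-based indices `i + 1`, `j + 1`) records how
#' often a reference value `i` has neighbor value `j`. With
#' `symmetric = TRUE` the transposed pairing is counted too; with
#' `normalized = TRUE` counts are divided by their total so the matrix is a
#' joint probability distribution.
#'
#' Pairs are counted only when both pixels lie inside the image; there is
#' no padding.
#'
#' @param image A [gray_image()] (or integer matrix, coerced with
#'   `params$levels` gray levels).
#' @param params A [glcm_params()] object.
#' @return An object of class `glcm`: list with `p` (levels x levels
#'   matrix), `params` and `n_pairs` (total pairs counted, including
#'   transposed pairs when symmetric).
#' @examples
#' strip <- gray_image(matrix(c(0L, 1L, 0L, 1L), 1, 4), levels = 2)
#' g <- compute_glcm(strip, glcm_params(distance = 1, levels = 2))
#' g$p
#' @export
compute_glcm <- function(image, params = glcm_params()) {
  if (!inherits(params, "glcm_params")) stop("params must be glcm_params()")
  image <- as_gray_image(image, levels = params$levels)
  if (max(image$pixels) >= params$levels)
    stop("pixel exceeds gray-level range", call. = FALSE)
  off <- glcm_offset(params$distance, params$angle)
  h <- image$height; w <- image$width
  rows <- max(1L, 1L - off[1]):min(h, h - off[1])
  cols <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (h - abs(off[1]) < 1L || w - abs(off[2]) < 1L ||
      length(rows) < 1L || length(cols) < 1L)
    stop("ROI too small for offset", call. = FALSE)
  px <- image$pixels
  i <- px[rows, cols, drop = FALSE]
  j <- px[rows + off[1], cols + off[2], drop = FALSE]
  L <- params$levels
  counts <- tabulate(as.vector(i) * L + as.vector(j) + 1L, nbins = L * L)
  # index i*L + j + 1 runs fastest over j -> fill by row
  p <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  if (params$symmetric) p <- p + t(p)
  n_pairs <- sum(p)
  if (n_pairs == 0L) stop("ROI too small for offset", call. = FALSE)
  if (params$normalized) p <- p / n_pairs
  structure(list(p = p, params = params, n_pairs = n_pairs), class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm %d x %d, distance %d, angle %g, %s, %s, %d pairs>\n",
    nrow(x$p), ncol(x$p), x$params$distance, x$params$angle,
    if (x$params$symmetric) "symmetric" else "asymmetric",
    if (x$params$normalized) "normalized" else "raw counts",
    x$n_pairs))
  invisible(x)
}

#' Texture features of a normalized GLCM
#'
#' Computes the seven classical Haralick-style texture features of a
#' normalized gray-level co-occurrence matrix `p(i, j)`:
#'
#' * contrast: sum of `p(i,j) * (i - j)^2`
#' * dissimilarity: sum of `p(i,j) * |i - j|`
#' * homogeneity: sum of `p(i,j) / (1 + (i - j)^2)`
#' * ASM (angular second moment): sum of `p(i,j)^2`
#' * energy: `sqrt(ASM)`
#' * entropy: `-sum(p * log(p))` over nonzero cells (natural log, with the
#'   `0 * log 0 = 0` convention)
#' * correlation: `sum(p * (i - mu_i) * (j - mu_j)) / (sigma_i * sigma_j)`,
#'   defined as 1 when either marginal standard deviation is zero (a
#'   constant image is perfectly self-similar)
#'
#' @param glcm A normalized [compute_glcm()] result.
#' @return Named numeric vector with elements `entropy`, `asm`, `energy`,
#'   `contrast`, `dissimilarity`, `homogeneity`, `correlation`.
#' @examples
#' strip <- gray_image(matrix(c(0L, 1L, 0L, 1L), 1, 4), levels = 2)
#' glcm_features(compute_glcm(strip, glcm_params(distance = 1, levels = 2)))
#' @export
glcm_features <- function(glcm) {
  if (!inherits(glcm, "glcm")) stop("glcm must be a compute_glcm() result")
  p <- glcm$p
  if (!isTRUE(glcm$params$normalized) || abs(sum(p) - 1) > 1e-8)
    stop("GLCM must be normalized", call. = FALSE)
  L <- nrow(p)
  i <- row(p) - 1L
  j <- col(p) - 1L
  d <- i - j
  contrast      <- sum(p * d^2)
  dissimilarity <- sum(p * abs(d))
  homogeneity   <- sum(p / (1 + d^2))
  asm           <- sum(p^2)
  energy        <- sqrt(asm)
  nz            <- p > 0
  entropy       <- -sum(p[nz] * log(p[nz]))
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum(p * (i - mu_i)^2); var_j <- sum(p * (j - mu_j)^2)
  sd_prod <- sqrt(var_i) * sqrt(var_j)
  correlation <- if (sd_prod < 1e-14) 1 else
    sum(p * (i - mu_i) * (j - mu_j)) / sd_prod
  c(entropy = entropy, asm = asm, energy = energy, contrast = contrast,
    dissimilarity = dissimilarity, homogeneity = homogeneity,
    correlation = correlation)
}

#' @rdname glcm_features
#' @param image A [gray_image()].
#' @param params A [glcm_params()] object; `normalized` is forced on.
#' @param average_angles If `TRUE`, compute features at all four angles
#'   (0, 45, 90, 135) and return their mean; the default uses the single
#'   angle in `params`.
#' @export
image_features <- function(image, params = glcm_params(),
                           average_angles = FALSE) {
  if (!average_angles) {
    params$normalized <- TRUE
    return(glcm_features(compute_glcm(image, params)))
  }
  feats <- vapply(c(0, 45, 90, 135), function(a) {
    pa <- params; pa$angle <- a; pa$normalized <- TRUE
    glcm_features(compute_glcm(image, pa))
  }, numeric(7))
  rowMeans(feats)
}

#' Canonical texture-feature names
#'
#' Order used throughout the package (feature tables, CSV schema, PCA).
#' @return Character vector of the seven feature names.
#' @export
feature_names <- function() {
  c("entropy", "asm", "energy", "contrast", "dissimilarity",
    "homogeneity", "correlation")
}
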