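#' Principal component analysis of a feature table
#'
#' Features are centered and scaled to unit variance (correlation-matrix
#' PCA) before decomposition; texture features span several orders of
#' magnitude (contrast vs. ASM), so covariance PCA would be dominated by
#' the widest-ranged feature. Components are ordered by decreasing
#' variance. A deterministic sign convention is applied: within each
#' loading column, the entry of largest magnitude is made positive (PC
#' signs are mathematically arbitrary; fixing them makes scores and plots
#' reproducible).
#'
#' @param table Feature table (e.g. from [extract_features()] or
#'   [read_feature_csv()]); the columns named in `features` are used.
#' @param k Number of components to keep (default: all).
#' @param features Feature column names (default [feature_names()]).
#' @return An object of class `glcm_pca`: list with `loadings`
#'   (features x k, orthonormal columns), `scores` (records x k),
#'   `variance_explained` (fractions of total variance, length k),
#'   `center`, `scale`, `k` and `feature_names`.
#' @export
run_pca <- function(table, k = NULL, features = feature_names()) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0L)
    stop(sprintf("feature columns not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  if (nrow(x) < 2L) stop("PCA needs at least 2 records", call. = FALSE)
  if (ncol(x) < 2L) stop("PCA needs at least 2 features", call. = FALSE)
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance feature cannot be scaled: %s",
                 paste(features[sds == 0], collapse = ", ")), call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(k)) k <- ncol(fit$rotation)
  k <- as.integer(k)
  if (k < 1L || k > ncol(fit$rotation))
    stop(sprintf("k must be between 1 and %d", ncol(fit$rotation)),
         call. = FALSE)
  loadings <- fit$rotation
  scores <- fit$x
  for (jj in seq_len(ncol(loadings))) {
    m <- which.max(abs(loadings[, jj]))
    if (loadings[m, jj] < 0) {
      loadings[, jj] <- -loadings[, jj]
      scores[, jj] <- -scores[, jj]
    }
  }
  structure(
    list(loadings = loadings[, seq_len(k), drop = FALSE],
         scores = scores[, seq_len(k), drop = FALSE],
         variance_explained = ve[seq_len(k)],
         center = fit$center, scale = fit$scale,
         k = k, feature_names = features),
    class = "glcm_pca")
}

#' @export
print.glcm_pca <- function(x, ...) {
  cat(sprintf("<glcm_pca: %d records, %d features, %d components>\n",
              nrow(x$scores), length(x$feature_names), x$k))
  pct <- round(100 * x$variance_explained, 1)
  cat("variance explained (%):", paste(pct, collapse = ", "), "\n")
  invisible(x)
}

#' Plot-ready biplot data (scores + loading arrows)
#'
#' Assembles per-record scores on two chosen components, grouped by a label
#' column, together with per-feature loading arrows. Arrow coordinates are
#' the loadings scaled by the square root of the component variance
#' (standard biplot display scaling); the raw unit-norm loadings are kept
#' alongside.
#'
#' @param result A [run_pca()] result.
#' @param table The feature table the PCA was run on (same row order).
#' @param label_column Name of the grouping column (e.g. `"lesion_label"`).
#' @param pcs Length-2 integer vector of component indices (default 1:2).
#' @param file Optional path (`.png`, `.svg` or `.pdf`); if given, a
#'   ggplot2 biplot is written there.
#' @return List of class `glcm_biplot` with `scores` (tibble: `score_x`,
#'   `score_y`, `label`), `loadings` (tibble: `feature`, `loading_x`,
#'   `loading_y`, `arrow_x`, `arrow_y`), `pcs` and `variance_pct`.
#' @export
biplot_data <- function(result, table, label_column = "lesion_label",
                        pcs = c(1L, 2L), file = NULL) {
  if (!inherits(result, "glcm_pca")) stop("result must be a run_pca() result")
  pcs <- as.integer(pcs)
  if (length(pcs) != 2L || any(pcs < 1L) || any(pcs > result$k))
    stop(sprintf("pcs must be two component indices in 1..%d", result$k),
         call. = FALSE)
  if (!label_column %in% names(table))
    stop(sprintf("label column '%s' not found; available columns: %s",
                 label_column, paste(names(table), collapse = ", ")),
         call. = FALSE)
  if (nrow(table) != nrow(result$scores))
    stop("table and PCA result have different numbers of records",
         call. = FALSE)
  scores <- tibble::tibble(
    score_x = result$scores[, pcs[1]],
    score_y = result$scores[, pcs[2]],
    label = as.character(table[[label_column]]))
  sd_x <- sqrt(result$variance_explained[pcs[1]] *
                 length(result$feature_names))
  sd_y <- sqrt(result$variance_explained[pcs[2]] *
                 length(result$feature_names))
  loadings <- tibble::tibble(
    feature = result$feature_names,
    loading_x = result$loadings[, pcs[1]],
    loading_y = result$loadings[, pcs[2]],
    arrow_x = result$loadings[, pcs[1]] * sd_x,
    arrow_y = result$loadings[, pcs[2]] * sd_y)
  out <- structure(
    list(scores = scores, loadings = loadings, pcs = pcs,
         variance_pct = 100 * result$variance_explained[pcs]),
    class = "glcm_biplot")
  if (!is.null(file)) save_biplot(out, file)
  out
}

#' Write a biplot figure
#'
#' @param bp A [biplot_data()] result.
#' @param file Output figure path (`.png`, `.svg`, `.pdf`).
#' @param width,height Figure size in inches.
#' @return `file`, invisibly.
#' @export
save_biplot <- function(bp, file, width = 7, height = 6) {
  if (!inherits(bp, "glcm_biplot")) stop("bp must be a biplot_data() result")
  arrow_scale <- max(abs(c(bp$scores$score_x, bp$scores$score_y))) /
    max(abs(c(bp$loadings$arrow_x, bp$loadings$arrow_y)), 1e-12) * 0.85
  ld <- bp$loadings
  ld$ax <- ld$arrow_x * arrow_scale
  ld$ay <- ld$arrow_y * arrow_scale
  p <- ggplot2::ggplot(bp$scores,
                       ggplot2::aes(x = score_x, y = score_y,
                                    colour = label, shape = label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = ax, yend = ay),
      arrow = grid::arrow(length = grid::unit(0.02, "npc")),
      colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = ax * 1.08, y = ay * 1.08, label = feature),
      colour = "red", size = 3, inherit.aes = FALSE) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", bp$pcs[1], bp$variance_pct[1]),
      y = sprintf("PC%d (%.1f%%)", bp$pcs[2], bp$variance_pct[2]),
      colour = "group", shape = "group") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(file)
}

#' Feature-to-feature correlation matrix
#'
#' Pearson correlations between the texture-feature columns of a feature
#' table. Zero-variance features yield `NA` rows/columns, reported with a
#' warning rather than silently set to zero.
#'
#' @param table Feature table.
#' @param features Feature column names (default [feature_names()]).
#' @return Symmetric features x features correlation matrix with unit
#'   diagonal (NA on degenerate rows).
#' @export
feature_correlations <- function(table, features = feature_names()) {
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  if (nrow(x) < 3L)
    stop("need at least 3 records to estimate correlations", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    bad <- features[sds == 0]
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
    diag(cm)[sds == 0] <- NA_real_
    warning(sprintf("correlation undefined for zero-variance feature(s): %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  cm
}
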