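# Per-pixel cell-boundary probability maps: a multiscale filter bank feeding
# either a trainable probabilistic pixel classifier (random forest) or a
# deterministic ridge-filter fallback that needs no training labels.

#' Construct a probability map object
#'
#' @param values Numeric matrix of probabilities in \[0, 1\], on the same
#'   grid as the source image.
#' @param source_id Identifier of the source image.
#' @param method `"trained_classifier"` or `"ridge_filter"`.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(values, source_id = "image",
                            method = c("trained_classifier", "ridge_filter")) {
  method <- match.arg(method)
  stopifnot(is.matrix(values))
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("probability map values must be finite and in [0, 1]")
  }
  structure(list(values = values, source_id = source_id, method = method),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("probability_map (", x$method, "): ", nrow(x$values), "x",
      ncol(x$values), " px, mean ", signif(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

# Shift an image by (dy, dx) with edge replication.
shift_img <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

#' Compute a multiscale per-pixel feature stack
#'
#' For each smoothing scale the stack contains the Gaussian-smoothed
#' intensity, the gradient magnitude, the Laplacian, and the largest Hessian
#' eigenvalue (all computed on the smoothed image with central differences,
#' border-replicated); the raw intensity comes first. Feature order is
#' stable: `raw`, then per scale in the given order
#' `smooth_s`, `gradmag_s`, `laplacian_s`, `hessmax_s` —
#' `4 * length(scales) + 1` features in total.
#'
#' @param image Numeric matrix with finite values.
#' @param scales Smoothing widths (Gaussian sigma, px); at least one.
#' @return A 3-D array `height x width x n_features` with feature names in
#'   `dimnames(...)[[3]]` and the scales in `attr(, "scales")`.
#' @export
compute_feature_stack <- function(image, scales = c(1, 2.5, 5)) {
  stopifnot(is.matrix(image), length(scales) >= 1)
  if (any(!is.finite(image))) stop("input image contains non-finite pixels")
  H <- nrow(image); W <- ncol(image)
  feats <- vector("list", 1L + 4L * length(scales))
  fnames <- character(length(feats))
  feats[[1]] <- image
  fnames[1] <- "raw"
  i <- 1L
  for (s in scales) {
    sm <- matrix(as.numeric(EBImage::gblur(image, sigma = s)), H, W)
    gy <- (shift_img(sm, -1, 0) - shift_img(sm, 1, 0)) / 2
    gx <- (shift_img(sm, 0, -1) - shift_img(sm, 0, 1)) / 2
    gyy <- shift_img(sm, -1, 0) - 2 * sm + shift_img(sm, 1, 0)
    gxx <- shift_img(sm, 0, -1) - 2 * sm + shift_img(sm, 0, 1)
    gxy <- (shift_img(sm, -1, -1) - shift_img(sm, -1, 1) -
            shift_img(sm, 1, -1) + shift_img(sm, 1, 1)) / 4
    disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    feats[[i + 1L]] <- sm
    feats[[i + 2L]] <- sqrt(gy^2 + gx^2)
    feats[[i + 3L]] <- gxx + gyy
    feats[[i + 4L]] <- ((gxx + gyy) + disc) / 2
    fnames[i + 1:4] <- paste0(c("smooth_", "gradmag_", "laplacian_",
                                "hessmax_"), s)
    i <- i + 4L
  }
  out <- array(unlist(feats, use.names = FALSE), dim = c(H, W, length(feats)),
               dimnames = list(NULL, NULL, fnames))
  attr(out, "scales") <- scales
  out
}

# Smallest Hessian eigenvalue per scale (used by the ridge filter).
hessian_min_eig <- function(image, s) {
  H <- nrow(image); W <- ncol(image)
  sm <- matrix(as.numeric(EBImage::gblur(image, sigma = s)), H, W)
  gyy <- shift_img(sm, -1, 0) - 2 * sm + shift_img(sm, 1, 0)
  gxx <- shift_img(sm, 0, -1) - 2 * sm + shift_img(sm, 0, 1)
  gxy <- (shift_img(sm, -1, -1) - shift_img(sm, -1, 1) -
          shift_img(sm, 1, -1) + shift_img(sm, 1, 1)) / 4
  disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
  ((gxx + gyy) - disc) / 2
}

#' Build a pixel training set from an image and a label mask
#'
#' Samples a balanced set of labelled pixels from the boundary mask
#' (positives) and from pixels at least `min_bg_distance_px` away from any
#' boundary pixel (negatives), and attaches their feature vectors. Keeping
#' the negatives away from the blurred boundary edge avoids training on
#' ambiguous pixels.
#'
#' @param image Numeric matrix (the boundary channel).
#' @param mask Logical matrix of true boundary pixels.
#' @param n_per_class Pixels sampled per class.
#' @param scales Feature scales, passed to [compute_feature_stack()].
#' @param min_bg_distance_px Minimal distance of negatives from the mask.
#' @param rng_seed Integer seed.
#' @return An object of class `pixel_training_set`: `feature_matrix`
#'   (rows = pixels), `labels` (factor `boundary`/`not_boundary`),
#'   `feature_names`, `scales`.
#' @export
make_pixel_training_set <- function(image, mask, n_per_class = 2000L,
                                    scales = c(1, 2.5, 5),
                                    min_bg_distance_px = 2, rng_seed = 1L) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  fs <- compute_feature_stack(image, scales)
  nF <- dim(fs)[3]
  fmat <- matrix(fs, ncol = nF)
  colnames(fmat) <- dimnames(fs)[[3]]
  pos_idx <- which(mask)
  dist_bg <- matrix(as.numeric(EBImage::distmap(1 - mask)),
                    nrow(mask), ncol(mask))
  neg_idx <- which(dist_bg >= min_bg_distance_px)
  if (length(pos_idx) == 0 || length(neg_idx) == 0) {
    stop("training mask must provide pixels of both classes")
  }
  with_seed(derive_seed(rng_seed, "training-pixels"), {
    pos <- sample(pos_idx, min(n_per_class, length(pos_idx)))
    neg <- sample(neg_idx, min(n_per_class, length(neg_idx)))
    pixel_training_set(
      feature_matrix = fmat[c(pos, neg), , drop = FALSE],
      labels = factor(rep(c("boundary", "not_boundary"),
                          c(length(pos), length(neg))),
                      levels = c("boundary", "not_boundary")),
      scales = scales)
  })
}

#' @rdname make_pixel_training_set
#' @param feature_matrix Numeric matrix of per-pixel feature vectors.
#' @param labels Factor with levels `boundary`, `not_boundary`.
#' @export
pixel_training_set <- function(feature_matrix, labels,
                               scales = c(1, 2.5, 5)) {
  labels <- factor(labels, levels = c("boundary", "not_boundary"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training set must contain at least one pixel of each class")
  }
  if (nrow(feature_matrix) != length(labels)) {
    stop("feature_matrix rows and labels differ in length")
  }
  structure(list(feature_matrix = feature_matrix, labels = labels,
                 feature_names = colnames(feature_matrix), scales = scales),
            class = "pixel_training_set")
}

#' Train a probabilistic pixel classifier
#'
#' Fits a probability random forest to the labelled pixels. The classifier
#' carries its feature configuration (names + scales) so prediction can
#' verify that the same filter bank is used, and is fully seeded.
#'
#' @param train A [pixel_training_set()].
#' @param num_trees Number of trees.
#' @param rng_seed Integer seed.
#' @return An object of class `pixel_classifier` implementing
#'   [predict_probability()].
#' @export
train_pixel_classifier <- function(train, num_trees = 60L, rng_seed = 1L) {
  stopifnot(inherits(train, "pixel_training_set"))
  if (nlevels(droplevels(train$labels)) < 2) {
    stop("training set must contain at least one pixel of each class")
  }
  df <- as.data.frame(train$feature_matrix)
  df$.label <- train$labels
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        probability = TRUE, num.trees = num_trees,
                        seed = derive_seed(rng_seed, "classifier"),
                        num.threads = 1L)
  structure(list(model = fit, feature_names = train$feature_names,
                 scales = train$scales, num_trees = num_trees,
                 rng_seed = rng_seed),
            class = "pixel_classifier")
}

#' Predict the boundary probability of feature vectors
#'
#' @param classifier A [train_pixel_classifier()] artifact.
#' @param features Numeric matrix whose columns match the classifier's
#'   feature configuration.
#' @return Numeric vector of boundary probabilities in \[0, 1\].
#' @export
predict_probability <- function(classifier, features) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  if (!identical(colnames(features), classifier$feature_names)) {
    stop("feature configuration mismatch: classifier was trained on [",
         paste(classifier$feature_names, collapse = ", "), "] but got [",
         paste(colnames(features), collapse = ", "), "]")
  }
  pr <- stats::predict(classifier$model, data = as.data.frame(features),
                       num.threads = 1L)$predictions
  as.numeric(pr[, "boundary"])
}

#' Predict a boundary probability map for an image
#'
#' Recomputes the classifier's filter bank on `image` and evaluates the
#' trained classifier at every pixel.
#'
#' @param image Numeric matrix.
#' @param classifier A trained [train_pixel_classifier()] artifact.
#' @param source_id Identifier stored in the resulting map.
#' @return A [probability_map()] with `method = "trained_classifier"`.
#' @export
predict_probability_map <- function(image, classifier, source_id = "image") {
  fs <- compute_feature_stack(image, classifier$scales)
  fmat <- matrix(fs, ncol = dim(fs)[3])
  colnames(fmat) <- dimnames(fs)[[3]]
  p <- predict_probability(classifier, fmat)
  probability_map(matrix(p, nrow(image), ncol(image)), source_id,
                  method = "trained_classifier")
}

#' Deterministic multiscale ridge probability map
#'
#' Training-free fallback boundary detector: bright ridges have a strongly
#' negative second derivative across the ridge, so per scale the strength is
#' `s^2 * max(0, -smallest Hessian eigenvalue)`; the pixelwise maximum over
#' scales is robustly rescaled to \[0, 1\] by clipping at the
#' `clip_quantiles` (default 1st–99th percentile) and linear rescaling. A
#' constant image yields an all-zero map (documented, not an error).
#'
#' @param image Numeric matrix.
#' @param scales Smoothing scales in px.
#' @param clip_quantiles Lower/upper quantiles for robust normalization.
#' @param source_id Identifier stored in the resulting map.
#' @return A [probability_map()] with `method = "ridge_filter"`.
#' @export
ridge_probability_map <- function(image, scales = c(1, 2.5, 5),
                                  clip_quantiles = c(0.01, 0.99),
                                  source_id = "image") {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("input image contains non-finite pixels")
  strength <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    strength <- pmax(strength, s^2 * pmax(-hessian_min_eig(image, s), 0))
  }
  lo <- quantile(strength, clip_quantiles[1], names = FALSE)
  hi <- quantile(strength, clip_quantiles[2], names = FALSE)
  vals <- if (hi <= lo) {
    matrix(0, nrow(image), ncol(image))
  } else {
    pmin(pmax((strength - lo) / (hi - lo), 0), 1)
  }
  probability_map(vals, source_id, method = "ridge_filter")
}

#' Ranking AUC of a probability map against a ground-truth mask
#'
#' Probability that a randomly chosen true boundary pixel outranks a randomly
#' chosen non-boundary pixel (Mann-Whitney statistic); a quality check for
#' boundary maps on synthetic scenes.
#'
#' @param map A [probability_map()].
#' @param mask Logical ground-truth boundary mask.
#' @return AUC in \[0, 1\].
#' @export
boundary_map_auc <- function(map, mask) {
  stopifnot(inherits(map, "probability_map"),
            all(dim(map$values) == dim(mask)))
  pos <- map$values[mask]
  neg <- map$values[!mask]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
}
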