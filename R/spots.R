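# Quantum-dot spot detection (scale-matched Laplacian-of-Gaussian blob
# response) and sub-pixel centroid refinement (background-subtracted
# intensity-weighted centroid).

#' Construct a spot set
#'
#' @param spots Data frame with columns `spot_id`, `y_px`, `x_px`,
#'   `integrated_intensity`, `detection_score`, `flag` (`""`, `"border"`,
#'   `"flat"` or `"outside"`). Coordinates are 1-based `(row, col)` with
#'   pixel centers at integers.
#' @param source_id Identifier of the source image.
#' @param detection_params Named list of every parameter that produced the
#'   set; together with the image it fully determines the result.
#' @param image_dim Integer `c(height, width)` of the source image.
#' @return An object of class `spot_set`.
#' @export
spot_set <- function(spots, source_id = "image", detection_params = list(),
                     image_dim = NULL) {
  required <- c("spot_id", "y_px", "x_px", "integrated_intensity",
                "detection_score", "flag")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols)) {
    stop("spots data frame lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(spots$spot_id)) stop("spot_ids must be distinct")
  if (!is.null(image_dim) && nrow(spots) > 0) {
    if (any(spots$y_px < 1 | spots$y_px > image_dim[1] |
            spots$x_px < 1 | spots$x_px > image_dim[2])) {
      stop("all centroids must lie inside the image frame")
    }
  }
  structure(list(spots = spots, source_id = source_id,
                 detection_params = detection_params,
                 image_dim = image_dim),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("spot_set:", nrow(x$spots), "spots from", x$source_id, "\n")
  invisible(x)
}

#' Detect diffraction-limited spots
#'
#' Candidates are strict local maxima of the scale-normalized
#' Laplacian-of-Gaussian blob response (`-sigma^2 * Laplacian` of the image
#' smoothed at `psf_sigma_px`; positive for bright blobs) that exceed
#' `median + detection_threshold * MAD` of the response (for noise-free
#' images, whose MAD is zero, a small fraction of the response range is used
#' as the noise scale instead), non-maximum
#' -suppressed so surviving spots are at least `min_separation_px` apart
#' (the stronger response wins). Spots are ordered by descending detection
#' score, ties broken by `(y, x)` lexicographic order. Zero detections is a
#' valid result, not an error.
#'
#' @param image Numeric matrix (quantum-dot channel).
#' @param psf_sigma_px Expected spot width (Gaussian sigma, px).
#' @param detection_threshold Threshold in robust noise units (multiples of
#'   the MAD of the LoG response above its median).
#' @param min_separation_px Minimal distance between reported spots.
#' @param source_id Identifier stored in the result.
#' @return A [spot_set()] with integer candidate positions;
#'   `integrated_intensity` is filled in by [refine_centroids()].
#' @export
detect_spots <- function(image, psf_sigma_px = 1.5, detection_threshold = 5,
                         min_separation_px = 5, source_id = "image") {
  stopifnot(is.matrix(image), psf_sigma_px > 0)
  if (any(!is.finite(image))) stop("input image contains non-finite pixels")
  H <- nrow(image); W <- ncol(image)
  s <- psf_sigma_px
  sm <- matrix(as.numeric(EBImage::gblur(image, sigma = s)), H, W)
  lap <- shift_img(sm, -1, 0) + shift_img(sm, 1, 0) +
         shift_img(sm, 0, -1) + shift_img(sm, 0, 1) - 4 * sm
  resp <- -s^2 * lap
  # robust noise scale; noise-free images have MAD 0, so fall back to a
  # small fraction of the response range to ignore convolution ripple
  noise <- mad(resp)
  if (noise == 0) noise <- 1e-6 * max(abs(resp - median(resp)))
  thr <- median(resp) + detection_threshold * noise

  is_max <- resp > thr
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    is_max <- is_max & (resp > shift_img(resp, d[1], d[2]))
    if (!any(is_max)) break
  }
  # exclude the replicated border where derivatives are unreliable
  is_max[c(1L, H), ] <- FALSE
  is_max[, c(1L, W)] <- FALSE

  idx <- which(is_max)
  ys <- (idx - 1L) %% H + 1L
  xs <- (idx - 1L) %/% H + 1L
  score <- resp[idx]
  ord <- order(-score, ys, xs)
  ys <- ys[ord]; xs <- xs[ord]; score <- score[ord]

  keep_y <- numeric(0); keep_x <- numeric(0); keep_s <- numeric(0)
  for (k in seq_along(ys)) {
    if (length(keep_y) == 0 ||
        min(sqrt((keep_y - ys[k])^2 + (keep_x - xs[k])^2)) >=
          min_separation_px) {
      keep_y <- c(keep_y, ys[k]); keep_x <- c(keep_x, xs[k])
      keep_s <- c(keep_s, score[k])
    }
  }

  spots <- data.frame(spot_id = seq_along(keep_y), y_px = keep_y,
                      x_px = keep_x,
                      integrated_intensity = rep(NA_real_, length(keep_y)),
                      detection_score = keep_s,
                      flag = rep("", length(keep_y)),
                      stringsAsFactors = FALSE)
  spot_set(spots, source_id = source_id,
           detection_params = list(psf_sigma_px = psf_sigma_px,
                                   detection_threshold = detection_threshold,
                                   min_separation_px = min_separation_px,
                                   response_threshold = thr),
           image_dim = c(H, W))
}

#' Refine spot centroids to sub-pixel precision
#'
#' For each candidate, the local background is estimated as the median of
#' the perimeter pixels of the `(2 * window_radius_px + 1)`-square window
#' and the centroid is the intensity-weighted mean of the background
#' -subtracted (non-negative) window. Spots whose window exits the frame
#' keep their integer position and are flagged `"border"`; windows with no
#' positive net intensity keep their integer position and are flagged
#' `"flat"`.
#'
#' @param image Numeric matrix the candidates came from.
#' @param spots A [spot_set()] (or a data frame with `y_px`, `x_px`).
#' @param window_radius_px Half-width of the refinement window.
#' @return A [spot_set()] with sub-pixel centroids, integrated intensities
#'   (background-subtracted positive mass) and flags.
#' @export
refine_centroids <- function(image, spots, window_radius_px = 4L) {
  stopifnot(is.matrix(image))
  ss <- if (inherits(spots, "spot_set")) spots$spots else spots
  H <- nrow(image); W <- ncol(image)
  w <- as.integer(window_radius_px)
  ys <- ss$y_px; xs <- ss$x_px
  out_y <- numeric(nrow(ss)); out_x <- numeric(nrow(ss))
  out_int <- numeric(nrow(ss))
  flag <- if ("flag" %in% names(ss)) ss$flag else rep("", nrow(ss))
  for (k in seq_len(nrow(ss))) {
    cy <- round(ys[k]); cx <- round(xs[k])
    if (cy - w < 1 || cy + w > H || cx - w < 1 || cx + w > W) {
      out_y[k] <- cy; out_x[k] <- cx
      flag[k] <- paste0(flag[k], ifelse(flag[k] == "", "", "+"), "border")
      patch <- image[max(1, cy - w):min(H, cy + w),
                     max(1, cx - w):min(W, cx + w), drop = FALSE]
      out_int[k] <- sum(pmax(patch - median(patch), 0))
      next
    }
    patch <- image[(cy - w):(cy + w), (cx - w):(cx + w), drop = FALSE]
    perim <- c(patch[1, ], patch[nrow(patch), ],
               patch[-c(1, nrow(patch)), 1], patch[-c(1, nrow(patch)),
                                                   ncol(patch)])
    bg <- median(perim)
    net <- pmax(patch - bg, 0)
    total <- sum(net)
    if (total <= 0) {
      out_y[k] <- cy; out_x[k] <- cx; out_int[k] <- 0
      flag[k] <- paste0(flag[k], ifelse(flag[k] == "", "", "+"), "flat")
      next
    }
    yy <- (cy - w):(cy + w); xx <- (cx - w):(cx + w)
    out_y[k] <- sum(rowSums(net) * yy) / total
    out_x[k] <- sum(colSums(net) * xx) / total
    out_int[k] <- total
  }
  res <- data.frame(spot_id = ss$spot_id, y_px = out_y, x_px = out_x,
                    integrated_intensity = out_int,
                    detection_score = ss$detection_score,
                    flag = flag, stringsAsFactors = FALSE)
  params <- if (inherits(spots, "spot_set")) spots$detection_params else list()
  params$window_radius_px <- w
  spot_set(res,
           source_id = if (inherits(spots, "spot_set")) spots$source_id
                       else "image",
           detection_params = params, image_dim = c(H, W))
}

#' Match detected spots to ground truth
#'
#' Greedy matching in order of detection score: each detection claims the
#' nearest unmatched truth spot within `radius_px`. Reports recall,
#' precision and per-match localization errors.
#'
#' @param detected A [spot_set()] (or data frame with `y_px`, `x_px`).
#' @param truth Data frame with `y_px`, `x_px` (e.g. `spots_truth` from
#'   [simulate_scene()]).
#' @param radius_px Match radius.
#' @return A list with `recall`, `precision`, `n_matched` and `errors_px`
#'   (Euclidean localization error per matched pair).
#' @export
match_spots <- function(detected, truth, radius_px = 2) {
  dd <- if (inherits(detected, "spot_set")) detected$spots else detected
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(dd) == 0) NA_real_ else 0,
                n_matched = 0L, errors_px = numeric(0)))
  }
  taken <- rep(FALSE, nrow(truth))
  errors <- numeric(0)
  for (k in seq_len(nrow(dd))) {
    d2 <- (truth$y_px - dd$y_px[k])^2 + (truth$x_px - dd$x_px[k])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius_px^2) {
      taken[j] <- TRUE
      errors <- c(errors, sqrt(d2[j]))
    }
  }
  n_matched <- sum(taken)
  list(recall = n_matched / nrow(truth),
       precision = if (nrow(dd) == 0) NA_real_ else n_matched / nrow(dd),
       n_matched = as.integer(n_matched), errors_px = errors)
}
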