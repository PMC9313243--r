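# The core colocalization statistic: boundary probability at each spot
# centroid, its histogram, the fraction of spots at or above a probability
# threshold, and a seeded permutation test between treatment groups.

#' Colocalization configuration
#'
#' @param probability_threshold Probability threshold defining a
#'   boundary-colocalized spot (default 0.2), strictly inside (0, 1).
#' @param interpolation `"nearest"` (default) or `"bilinear"` sampling of the
#'   probability map at sub-pixel centroids.
#' @param histogram_bins Number of uniform bins on \[0, 1\].
#' @param include_border_spots Keep spots flagged `border` by
#'   [refine_centroids()] (default TRUE).
#' @param strict Use a strict `>` comparison instead of the default
#'   inclusive `>=` at the threshold.
#' @return An object of class `coloc_config`.
#' @export
coloc_config <- function(probability_threshold = 0.2,
                         interpolation = c("nearest", "bilinear"),
                         histogram_bins = 20L,
                         include_border_spots = TRUE,
                         strict = FALSE) {
  interpolation <- match.arg(interpolation)
  if (probability_threshold <= 0 || probability_threshold >= 1) {
    stop("probability_threshold must be strictly inside (0, 1)")
  }
  if (histogram_bins < 1) stop("histogram_bins must be >= 1")
  structure(list(probability_threshold = probability_threshold,
                 interpolation = interpolation,
                 histogram_bins = as.integer(histogram_bins),
                 include_border_spots = include_border_spots,
                 strict = strict),
            class = "coloc_config")
}

#' Sample the boundary probability map at spot centroids
#'
#' Each spot is scored with the probability-map value at its (sub-pixel)
#' centroid, using nearest-pixel or bilinear interpolation. Spots outside
#' the map are clamped to the nearest edge pixel and flagged `"outside"`.
#'
#' @param spots A [spot_set()] (or data frame with `spot_id`, `y_px`,
#'   `x_px`).
#' @param map A [probability_map()] on the same grid as the spots' source
#'   image.
#' @param config A [coloc_config()].
#' @return A data frame with `spot_id`, `boundary_probability`, `flag`.
#' @export
score_spots <- function(spots, map, config = coloc_config()) {
  stopifnot(inherits(map, "probability_map"))
  ss <- if (inherits(spots, "spot_set")) spots$spots else spots
  if (inherits(spots, "spot_set") && !is.null(spots$image_dim) &&
      !all(spots$image_dim == dim(map$values))) {
    stop("grid mismatch: spots come from a ",
         paste(spots$image_dim, collapse = "x"), " image but the map is ",
         paste(dim(map$values), collapse = "x"))
  }
  if (!config$include_border_spots && "flag" %in% names(ss)) {
    ss <- ss[!grepl("border", ss$flag), , drop = FALSE]
  }
  H <- nrow(map$values); W <- ncol(map$values)
  y <- ss$y_px; x <- ss$x_px
  flag <- ifelse(y < 1 | y > H | x < 1 | x > W, "outside", "")
  y <- pmin(pmax(y, 1), H)
  x <- pmin(pmax(x, 1), W)
  p <- if (config$interpolation == "nearest") {
    map$values[cbind(pmin(pmax(round(y), 1), H), pmin(pmax(round(x), 1), W))]
  } else {
    y0 <- pmin(pmax(floor(y), 1), H - 1L); x0 <- pmin(pmax(floor(x), 1), W - 1L)
    fy <- pmin(pmax(y - y0, 0), 1);        fx <- pmin(pmax(x - x0, 0), 1)
    v00 <- map$values[cbind(y0, x0)];      v01 <- map$values[cbind(y0, x0 + 1L)]
    v10 <- map$values[cbind(y0 + 1L, x0)]; v11 <- map$values[cbind(y0 + 1L, x0 + 1L)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }
  data.frame(spot_id = ss$spot_id, boundary_probability = as.numeric(p),
             flag = flag, stringsAsFactors = FALSE)
}

#' Boundary-colocalized fraction and probability histogram
#'
#' The fraction of spots whose boundary probability meets the threshold
#' (inclusive `>=` by default), together with the histogram of per-spot
#' probabilities over \[0, 1\] (left-closed right-open uniform bins, last
#' bin closed). An empty spot list is an error — the statistic is undefined,
#' which is distinct from a fraction of 0.
#'
#' @param probabilities Numeric vector of per-spot boundary probabilities,
#'   or the data frame returned by [score_spots()].
#' @param threshold Probability threshold (default 0.2).
#' @param bins Number of histogram bins.
#' @param strict Use `>` instead of `>=`.
#' @return A list with `boundary_fraction`, `n_spots`, `threshold` and
#'   `histogram` (`breaks`, `counts`).
#' @export
#' @examples
#' boundary_fraction(c(0.1, 0.3, 0.9), threshold = 0.2)$boundary_fraction
boundary_fraction <- function(probabilities, threshold = 0.2, bins = 20L,
                              strict = FALSE) {
  p <- if (is.data.frame(probabilities)) {
    probabilities$boundary_probability
  } else probabilities
  if (length(p) == 0) {
    stop("boundary fraction is undefined for an empty spot list")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must be finite and in [0, 1]")
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- findInterval(p, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = bins)
  frac <- if (strict) mean(p > threshold) else mean(p >= threshold)
  list(boundary_fraction = frac, n_spots = length(p), threshold = threshold,
       histogram = list(breaks = breaks, counts = counts))
}

#' Full per-image colocalization result
#'
#' Runs [score_spots()] and [boundary_fraction()] and bundles the result
#' with its configuration and provenance.
#'
#' @inheritParams score_spots
#' @param source_id Image identifier recorded in the result.
#' @return An object of class `coloc_result`: `per_spot_probability`,
#'   `histogram`, `boundary_fraction`, `n_spots`, `config`, `source_id`.
#' @export
colocalize <- function(spots, map, config = coloc_config(),
                       source_id = map$source_id) {
  scored <- score_spots(spots, map, config)
  bf <- boundary_fraction(scored, threshold = config$probability_threshold,
                          bins = config$histogram_bins,
                          strict = config$strict)
  structure(list(per_spot_probability = scored,
                 histogram = bf$histogram,
                 boundary_fraction = bf$boundary_fraction,
                 n_spots = bf$n_spots,
                 config = config, source_id = source_id),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc_result (", x$source_id, "): ", x$n_spots,
      " spots, boundary fraction ", signif(x$boundary_fraction, 3),
      " at threshold ", x$config$probability_threshold, "\n", sep = "")
  invisible(x)
}

#' Permutation comparison of boundary fractions between two groups
#'
#' Two-sided permutation test of the difference in boundary colocalization
#' between two treatment groups. With `unit = "image"` (default) the
#' statistic is the difference in group means of per-image boundary
#' fractions and whole images are relabelled — the image (one seedling per
#' plate) is the independent experimental unit. With `unit = "spot"` the
#' per-spot colocalization indicators are pooled within each group and spot
#' labels are permuted; this gains power with few images per group but
#' treats spots as independent. Monte-Carlo p-values use the add-one rule
#' `(b + 1) / (m + 1)`; with `exhaustive = TRUE` (image unit only) all label
#' splits are enumerated and the p-value is exact.
#'
#' @param results_by_group Named list of length 2. For `unit = "image"` each
#'   element may be a numeric vector of per-image boundary fractions or a
#'   list of [colocalize()] results; for `unit = "spot"` each element must
#'   be a list of `coloc_result`s (the per-spot probabilities are needed).
#' @param n_permutations Number of Monte-Carlo permutations.
#' @param rng_seed Integer seed.
#' @param unit `"image"` or `"spot"` resampling unit.
#' @param exhaustive Enumerate all splits instead of sampling
#'   (`unit = "image"` only).
#' @return An object of class `group_comparison`: `group_labels`,
#'   `per_image_fractions`, `observed_difference` (first group minus
#'   second), `p_value`, `n_permutations`, `rng_seed`, `unit`.
#' @export
compare_groups <- function(results_by_group, n_permutations = 9999L,
                           rng_seed = 1L, unit = c("image", "spot"),
                           exhaustive = FALSE) {
  unit <- match.arg(unit)
  if (length(results_by_group) != 2 || is.null(names(results_by_group))) {
    stop("results_by_group must be a named list of exactly 2 groups")
  }
  labels <- names(results_by_group)
  as_fractions <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(r) r$boundary_fraction, numeric(1))
  }
  fr <- lapply(results_by_group, as_fractions)
  ns <- vapply(fr, length, integer(1))
  if (any(ns < 2)) {
    stop("each group needs at least 2 images (got ",
         paste(ns, collapse = " and "), ")")
  }

  if (unit == "image") {
    x <- fr[[1]]; y <- fr[[2]]
    obs <- mean(x) - mean(y)
    pool <- c(x, y); nx <- length(x); n <- length(pool)
    stat <- function(idx) mean(pool[idx]) - mean(pool[-idx])
    if (exhaustive) {
      splits <- combn(n, nx)
      d <- apply(splits, 2, stat)
      p <- mean(abs(d) >= abs(obs) - 1e-12)
      m <- ncol(splits)
    } else {
      d <- with_seed(derive_seed(rng_seed, "permutation"), {
        vapply(seq_len(n_permutations),
               function(i) stat(sample.int(n, nx)), numeric(1))
      })
      b <- sum(abs(d) >= abs(obs) - 1e-12)
      p <- (b + 1) / (n_permutations + 1)
      m <- n_permutations
    }
  } else {
    as_indicators <- function(g) {
      if (!is.list(g) || !all(vapply(g, inherits, logical(1), "coloc_result"))) {
        stop("unit = \"spot\" needs lists of coloc_result objects ",
             "(per-spot probabilities are required)")
      }
      unlist(lapply(g, function(r) {
        p <- r$per_spot_probability$boundary_probability
        thr <- r$config$probability_threshold
        if (r$config$strict) p > thr else p >= thr
      }))
    }
    ix <- as_indicators(results_by_group[[1]])
    iy <- as_indicators(results_by_group[[2]])
    obs <- mean(ix) - mean(iy)
    pool <- c(ix, iy); nx <- length(ix); n <- length(pool)
    d <- with_seed(derive_seed(rng_seed, "permutation"), {
      vapply(seq_len(n_permutations), function(i) {
        idx <- sample.int(n, nx)
        mean(pool[idx]) - mean(pool[-idx])
      }, numeric(1))
    })
    b <- sum(abs(d) >= abs(obs) - 1e-12)
    p <- (b + 1) / (n_permutations + 1)
    m <- n_permutations
  }

  structure(list(group_labels = labels,
                 per_image_fractions = fr,
                 observed_difference = obs,
                 p_value = p, n_permutations = m,
                 rng_seed = rng_seed, unit = unit,
                 exhaustive = exhaustive),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison: ", x$group_labels[1], " - ", x$group_labels[2],
      " = ", signif(x$observed_difference, 3), ", p = ",
      signif(x$p_value, 3), " (", x$unit, " permutation, m = ",
      x$n_permutations, ")\n", sep = "")
  invisible(x)
}
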