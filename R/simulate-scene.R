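# Synthetic root-tissue scenes: cell-boundary network, ground-truth spot
# placement, and camera-model rendering of the quantum-dot channel.

# Internal rendering constants for the boundary (brightfield-like) channel.
.boundary_render <- list(background = 200, amplitude = 600,
                         blur_sigma = 1, noise_sd = 15, max_count = 65535)

#' Generate a synthetic cell-boundary network
#'
#' Builds a space-filling tessellation of elongated cells from seed points on
#' a jittered anisotropic grid: each pixel is assigned to the nearest seed
#' under the elongation-weighted metric
#' `d^2 = (dy / spacing_y)^2 + (dx / spacing_x)^2`, which yields cell files
#' stretched along the root (row) axis. The 1-px edge set between cells is
#' dilated to `boundary_thickness_px` and rendered into a noisy intensity
#' channel (bright walls on a darker interior).
#'
#' @param spec A [cell_network_spec()].
#' @return A list with `boundary_mask` (logical matrix, dilated edge set),
#'   `boundary_channel` (numeric matrix, counts), `cell_labels` (integer
#'   matrix of cell ids) and `spec`.
#' @export
generate_cell_network <- function(spec) {
  stopifnot(inherits(spec, "cell_network_spec"))
  H <- spec$image_height; W <- spec$image_width
  ny <- max(1L, as.integer(round(H / spec$mean_cell_length)))
  nx <- max(1L, as.integer(round(W / spec$mean_cell_width)))
  if (ny * nx < 4) {
    stop("dimensions ", H, "x", W, " are too small to fit at least 4 cells ",
         "of mean size ", spec$mean_cell_length, "x", spec$mean_cell_width,
         " px; enlarge the image or shrink the cells")
  }
  sp_y <- H / ny; sp_x <- W / nx
  with_seed(derive_seed(spec$rng_seed, "network"), {
    # seed points on grid cell centers, jittered by < half a spacing so the
    # nearest seed of any pixel lies in the 3x3 neighbourhood of grid cells
    jit_y <- matrix(runif(ny * nx, -0.35, 0.35), ny, nx) * sp_y
    jit_x <- matrix(runif(ny * nx, -0.35, 0.35), ny, nx) * sp_x
    seed_y <- (row(jit_y) - 0.5) * sp_y + jit_y
    seed_x <- (col(jit_x) - 0.5) * sp_x + jit_x

    ycoord <- rep.int(seq_len(H), W)        # column-major over [H, W]
    xcoord <- rep(seq_len(W), each = H)
    gi <- pmin(pmax(ceiling(ycoord / sp_y), 1L), ny)
    gj <- pmin(pmax(ceiling(xcoord / sp_x), 1L), nx)
    best_d <- rep.int(Inf, H * W)
    best_k <- integer(H * W)
    for (di in -1:1) for (dj in -1:1) {
      ni <- pmin(pmax(gi + di, 1L), ny)
      nj <- pmin(pmax(gj + dj, 1L), nx)
      k <- (nj - 1L) * ny + ni
      d2 <- ((ycoord - seed_y[k]) / sp_y)^2 + ((xcoord - seed_x[k]) / sp_x)^2
      upd <- d2 < best_d
      best_d[upd] <- d2[upd]
      best_k[upd] <- k[upd]
    }
    labels <- matrix(best_k, H, W)

    edge <- matrix(FALSE, H, W)
    edge[-H, ] <- edge[-H, ] | (labels[-H, ] != labels[-1, ])
    edge[, -W] <- edge[, -W] | (labels[, -W] != labels[, -1])
    mask <- dilate_mask(edge, spec$boundary_thickness_px)

    rp <- .boundary_render
    smooth <- EBImage::gblur(mask * 1.0, sigma = rp$blur_sigma)
    channel <- rp$background + rp$amplitude * as.numeric(smooth) +
      rnorm(H * W, sd = rp$noise_sd)
    channel <- matrix(pmin(pmax(round(channel), 0), rp$max_count), H, W)

    list(boundary_mask = mask, boundary_channel = channel,
         cell_labels = labels, spec = spec)
  })
}

# Dilate a logical mask to about `thickness` px using an odd-diameter disc.
dilate_mask <- function(mask, thickness) {
  b <- as.integer(thickness) + as.integer(thickness %% 2 == 0)
  if (b <= 1) return(mask)
  out <- EBImage::dilate(mask * 1.0, EBImage::makeBrush(b, shape = "disc"))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

#' Place ground-truth spots relative to a boundary mask
#'
#' Places exactly `n_spots` emitters: `round half up(n_spots * f_boundary)`
#' are labelled `boundary` and lie within `boundary_jitter_px` of a boundary
#' pixel; the rest are labelled `interior` and lie strictly farther than
#' `2 * boundary_jitter_px` from any boundary pixel. All pairs are separated
#' by at least `min_separation_px`; placement retries are bounded and failure
#' raises an error naming the violated constraint.
#'
#' @param mask Logical boundary mask (from [generate_cell_network()]).
#' @param spec A [spot_placement_spec()].
#' @return A data frame `spots_truth` with columns `spot_id`, `y_px`, `x_px`
#'   (1-based, pixel centers at integers) and `label`
#'   (`"boundary"`/`"interior"`).
#' @export
place_spots <- function(mask, spec) {
  stopifnot(is.matrix(mask), inherits(spec, "spot_placement_spec"))
  if (!any(mask)) stop("boundary mask is empty")
  H <- nrow(mask); W <- ncol(mask)
  n <- spec$n_spots
  n_b <- round_half_up(n * spec$f_boundary)
  n_i <- n - n_b
  j <- spec$boundary_jitter_px
  m <- spec$margin_px
  in_margin <- function(y, x) y >= 1 + m & y <= H - m & x >= 1 + m & x <= W - m

  bidx <- which(mask)
  by <- (bidx - 1L) %% H + 1L
  bx <- (bidx - 1L) %/% H + 1L
  keep <- in_margin(by, bx)
  by <- by[keep]; bx <- bx[keep]
  if (n_b > 0 && length(by) == 0) stop("no boundary pixels inside the margin")

  # distance of every pixel to the nearest boundary pixel
  dist_to_boundary <- matrix(as.numeric(EBImage::distmap(1 - mask)), H, W)
  iidx <- which(dist_to_boundary > 2 * j + 1)
  iy <- (iidx - 1L) %% H + 1L
  ix <- (iidx - 1L) %/% H + 1L
  keep <- in_margin(iy, ix)
  iy <- iy[keep]; ix <- ix[keep]
  if (n_i > 0 && length(iy) == 0) {
    stop("no interior pixels farther than 2 * boundary_jitter_px (", 2 * j,
         " px) from the boundary inside the margin")
  }

  with_seed(derive_seed(spec$rng_seed, "spots"), {
    ys <- numeric(0); xs <- numeric(0); lab <- character(0)
    max_tries <- 500L * n
    tries <- 0L
    want <- c(rep("boundary", n_b), rep("interior", n_i))
    for (k in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not satisfy min_separation_px = ",
               spec$min_separation_px, " for ", n, " spots after ",
               max_tries, " retries; reduce n_spots or min_separation_px")
        }
        if (want[k] == "boundary") {
          p <- sample.int(length(by), 1L)
          r <- runif(1, 0, j); th <- runif(1, 0, 2 * pi)
          y <- by[p] + r * sin(th); x <- bx[p] + r * cos(th)
        } else {
          p <- sample.int(length(iy), 1L)
          y <- iy[p] + runif(1, -0.3, 0.3); x <- ix[p] + runif(1, -0.3, 0.3)
        }
        if (!in_margin(y, x)) next
        if (length(ys) > 0 &&
            min(sqrt((ys - y)^2 + (xs - x)^2)) < spec$min_separation_px) next
        break
      }
      ys <- c(ys, y); xs <- c(xs, x); lab <- c(lab, want[k])
    }
    data.frame(spot_id = seq_len(n), y_px = ys, x_px = xs, label = lab,
               stringsAsFactors = FALSE)
  })
}

# Round half away from zero (0.5 -> 1), documented placement rounding rule.
round_half_up <- function(x) floor(x + 0.5)

#' Render the quantum-dot channel from ground-truth spots
#'
#' Each spot contributes a pixel-integrated Gaussian (photon mass
#' `spot_photon_mean` spread with width `psf_sigma_px`) added to a constant
#' background; the configured shot/read noise is applied and intensities are
#' clipped to the bit-depth range and rounded.
#'
#' @param spots Data frame with `y_px`, `x_px` (spot centers, may be
#'   sub-pixel).
#' @param spec An [imaging_spec()].
#' @param dim Integer vector `c(height, width)` of the output image.
#' @param rng_seed Seed for the noise stream.
#' @return A numeric matrix of counts.
#' @export
render_qd_channel <- function(spots, spec, dim, rng_seed = 1L) {
  stopifnot(inherits(spec, "imaging_spec"), length(dim) == 2L)
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  if (nrow(spots) > 0 &&
      (any(spots$y_px < 1) || any(spots$y_px > H) ||
       any(spots$x_px < 1) || any(spots$x_px > W))) {
    stop("all spots must lie inside the image frame")
  }
  s <- spec$psf_sigma_px
  expected <- matrix(spec$background_level, H, W)
  w <- as.integer(ceiling(4 * s)) + 1L
  for (k in seq_len(nrow(spots))) {
    y <- spots$y_px[k]; x <- spots$x_px[k]
    ry <- max(1L, floor(y) - w):min(H, ceiling(y) + w)
    rx <- max(1L, floor(x) - w):min(W, ceiling(x) + w)
    gy <- pnorm((ry + 0.5 - y) / s) - pnorm((ry - 0.5 - y) / s)
    gx <- pnorm((rx + 0.5 - x) / s) - pnorm((rx - 0.5 - x) / s)
    expected[ry, rx] <- expected[ry, rx] + spec$spot_photon_mean * outer(gy, gx)
  }
  img <- with_seed(derive_seed(rng_seed, "render-noise"), {
    out <- switch(spec$noise_model,
      "none" = expected,
      "poisson" = matrix(rpois(H * W, expected), H, W),
      "gaussian" = expected + matrix(rnorm(H * W, sd = spec$gaussian_noise_sd),
                                     H, W),
      "poisson+gaussian" = matrix(rpois(H * W, expected), H, W) +
        matrix(rnorm(H * W, sd = spec$gaussian_noise_sd), H, W))
    out
  })
  maxv <- 2^spec$bit_depth - 1
  matrix(pmin(pmax(round(img), 0), maxv), H, W)
}

#' Simulate a complete synthetic scene
#'
#' Chains [generate_cell_network()], [place_spots()] and
#' [render_qd_channel()]. When `rng_seed` is given, the three per-operation
#' streams are derived from it with [derive_seed()] (labels `"network"`,
#' `"spots"`, `"render"`), overriding the seeds carried by the specs.
#'
#' @param network A [cell_network_spec()].
#' @param placement A [spot_placement_spec()].
#' @param imaging An [imaging_spec()].
#' @param rng_seed Optional top-level seed overriding the per-spec seeds.
#' @return An object of class `qd_scene`: a list with `boundary_mask`,
#'   `boundary_channel`, `qd_channel`, `spots_truth` and `specs`.
#' @export
#' @examples
#' sc <- simulate_scene(cell_network_spec(image_height = 128, image_width = 128),
#'                      spot_placement_spec(n_spots = 10), imaging_spec(),
#'                      rng_seed = 7)
#' table(sc$spots_truth$label)
simulate_scene <- function(network = cell_network_spec(),
                           placement = spot_placement_spec(),
                           imaging = imaging_spec(),
                           rng_seed = NULL) {
  render_seed <- if (is.null(rng_seed)) {
    derive_seed(placement$rng_seed, "render")
  } else {
    network$rng_seed <- derive_seed(rng_seed, "network")
    placement$rng_seed <- derive_seed(rng_seed, "spots")
    derive_seed(rng_seed, "render")
  }
  net <- generate_cell_network(network)
  spots <- place_spots(net$boundary_mask, placement)
  qd <- render_qd_channel(spots, imaging,
                          dim = c(network$image_height, network$image_width),
                          rng_seed = render_seed)
  structure(list(boundary_mask = net$boundary_mask,
                 boundary_channel = net$boundary_channel,
                 qd_channel = qd,
                 spots_truth = spots,
                 specs = list(network = network, placement = placement,
                              imaging = imaging, rng_seed = rng_seed)),
            class = "qd_scene")
}

#' @export
print.qd_scene <- function(x, ...) {
  cat("qd_scene:", nrow(x$boundary_mask), "x", ncol(x$boundary_mask),
      "px,", nrow(x$spots_truth), "spots (",
      sum(x$spots_truth$label == "boundary"), "boundary /",
      sum(x$spots_truth$label == "interior"), "interior ),",
      "boundary pixel fraction",
      signif(mean(x$boundary_mask), 3), "\n")
  invisible(x)
}
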