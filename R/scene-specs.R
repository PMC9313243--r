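#' Specification of a synthetic cell-boundary network
#'
#' Parameters of the anisotropic tessellation used to emulate files of
#' elongated root epidermal cells: large cell interiors separated by thin,
#' bright boundaries, imaged in a boundary (brightfield-like) channel.
#'
#' @param image_height,image_width Image dimensions in pixels (each >= 64).
#' @param mean_cell_width Mean cell width in pixels (across the root axis).
#' @param mean_cell_length Mean cell length in pixels (along the root axis,
#'   i.e. image rows). Defaults to `anisotropy * mean_cell_width`.
#' @param boundary_thickness_px Thickness the 1-px tessellation edges are
#'   dilated to (>= 1). Realized as the nearest odd disc diameter.
#' @param anisotropy Cell elongation ratio (>= 1). Used as the default
#'   length:width ratio when `mean_cell_length` is not given.
#' @param rng_seed Integer seed; identical spec + seed give bit-identical
#'   output.
#' @return An object of class `cell_network_spec`.
#' @export
cell_network_spec <- function(image_height = 512L, image_width = 512L,
                              mean_cell_width = 16, mean_cell_length = NULL,
                              boundary_thickness_px = 3, anisotropy = 3,
                              rng_seed = 1L) {
  if (image_height < 64 || image_width < 64) {
    stop("image dimensions must be at least 64 px each (got ",
         image_height, "x", image_width, ")")
  }
  if (boundary_thickness_px < 1) stop("boundary_thickness_px must be >= 1")
  if (anisotropy < 1) stop("anisotropy must be >= 1")
  if (is.null(mean_cell_length)) mean_cell_length <- anisotropy * mean_cell_width
  if (mean_cell_length < 2 || mean_cell_width < 2) {
    stop("mean cell dimensions must be at least 2 px")
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 mean_cell_length = mean_cell_length,
                 mean_cell_width = mean_cell_width,
                 boundary_thickness_px = boundary_thickness_px,
                 anisotropy = anisotropy,
                 rng_seed = as.integer(rng_seed)),
            class = "cell_network_spec")
}

#' Specification of ground-truth spot placement
#'
#' Controls how many emitters are placed and which fraction sits on cell
#' boundaries. The realized number of boundary-labelled spots is
#' `round half up(n_spots * f_boundary)`. Boundary spots are displaced from a
#' boundary pixel by at most `boundary_jitter_px` (uniform in a disc),
#' emulating emitters lining the apoplast rather than sitting on a 1-px
#' skeleton; interior spots are kept strictly farther than
#' `2 * boundary_jitter_px` from any boundary pixel.
#'
#' @param n_spots Number of spots (>= 1).
#' @param f_boundary Fraction in \[0, 1\] of spots placed on boundaries —
#'   the ground-truth analogue of the measured boundary-colocalized fraction.
#' @param boundary_jitter_px Maximal displacement of boundary spots off the
#'   boundary mask, in pixels.
#' @param min_separation_px Minimal pairwise spot separation, in pixels.
#' @param margin_px Spots are kept at least this far from the image edge so
#'   detection/refinement windows fit.
#' @param rng_seed Integer seed.
#' @return An object of class `spot_placement_spec`.
#' @export
spot_placement_spec <- function(n_spots = 50L, f_boundary = 0.8,
                                boundary_jitter_px = 1,
                                min_separation_px = 5,
                                margin_px = 8, rng_seed = 1L) {
  if (n_spots < 1) stop("n_spots must be >= 1")
  if (f_boundary < 0 || f_boundary > 1) stop("f_boundary must be in [0, 1]")
  if (boundary_jitter_px < 0) stop("boundary_jitter_px must be >= 0")
  structure(list(n_spots = as.integer(n_spots), f_boundary = f_boundary,
                 boundary_jitter_px = boundary_jitter_px,
                 min_separation_px = min_separation_px,
                 margin_px = margin_px, rng_seed = as.integer(rng_seed)),
            class = "spot_placement_spec")
}

#' Specification of the imaging model for the quantum-dot channel
#'
#' Emitters are rendered as pixel-integrated Gaussians (the diffraction
#' -limited point-spread function approximated by a Gaussian of width
#' `psf_sigma_px`) on a constant background, followed by shot noise and/or
#' Gaussian read noise, and quantization to the camera bit depth.
#'
#' @param psf_sigma_px Gaussian PSF width in pixels (> 0).
#' @param spot_photon_mean Expected integrated photon count per spot.
#' @param background_level Constant background, in counts.
#' @param noise_model One of `"none"`, `"poisson"`, `"gaussian"`,
#'   `"poisson+gaussian"`.
#' @param gaussian_noise_sd Read-noise standard deviation in counts (used by
#'   the Gaussian terms).
#' @param bit_depth 8 or 16; intensities are clipped to the representable
#'   range and rounded.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(psf_sigma_px = 1.5, spot_photon_mean = 2000,
                         background_level = 100,
                         noise_model = c("poisson", "gaussian",
                                         "poisson+gaussian", "none"),
                         gaussian_noise_sd = 2, bit_depth = 16) {
  noise_model <- match.arg(noise_model)
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (background_level < 0 || spot_photon_mean < 0) {
    stop("background_level and spot_photon_mean must be >= 0")
  }
  structure(list(psf_sigma_px = psf_sigma_px,
                 spot_photon_mean = spot_photon_mean,
                 background_level = background_level,
                 noise_model = noise_model,
                 gaussian_noise_sd = gaussian_noise_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "imaging_spec")
}
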