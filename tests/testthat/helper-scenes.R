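# Shared synthetic fixtures, generated once per test run and cached.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(f_boundary = 0.8, size = 256L, n_spots = 40L,
                         seed = 101L, noise = "poisson") {
  id <- paste("scene", f_boundary, size, n_spots, seed, noise, sep = "_")
  if (!exists(id, envir = .scene_cache)) {
    sc <- simulate_scene(
      cell_network_spec(size, size),
      spot_placement_spec(n_spots = n_spots, f_boundary = f_boundary),
      imaging_spec(noise_model = noise),
      rng_seed = seed)
    assign(id, sc, envir = .scene_cache)
  }
  get(id, envir = .scene_cache)
}

# A classifier trained on a dedicated scene, reused across tests.
cached_classifier <- function(size = 256L, seed = 901L) {
  id <- paste("clf", size, seed, sep = "_")
  if (!exists(id, envir = .scene_cache)) {
    tr <- cached_scene(f_boundary = 0.5, size = size, seed = seed)
    ts <- make_pixel_training_set(tr$boundary_channel, tr$boundary_mask,
                                  n_per_class = 1500L, rng_seed = seed)
    assign(id, train_pixel_classifier(ts, rng_seed = seed),
           envir = .scene_cache)
  }
  get(id, envir = .scene_cache)
}

# Render an image containing only the given spots, noise-free.
render_clean <- function(spots, dim = c(128L, 128L), photons = 2000,
                         sigma = 1.5, background = 100) {
  render_qd_channel(spots,
                    imaging_spec(psf_sigma_px = sigma,
                                 spot_photon_mean = photons,
                                 background_level = background,
                                 noise_model = "none"),
                    dim = dim)
}
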