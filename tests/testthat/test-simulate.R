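test_that("tessellation produces plausible boundary networks, deterministically", {
  spec <- cell_network_spec(256, 256, mean_cell_width = 32, anisotropy = 1,
                            boundary_thickness_px = 1, rng_seed = 1)
  for (s in 1:10) {
    spec$rng_seed <- s
    net <- generate_cell_network(spec)
    frac <- mean(net$boundary_mask)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.40)
  }
  spec$rng_seed <- 3L
  a <- generate_cell_network(spec)
  b <- generate_cell_network(spec)
  expect_identical(a$boundary_mask, b$boundary_mask)
  expect_identical(a$boundary_channel, b$boundary_channel)

  thick <- spec
  thick$boundary_thickness_px <- 2
  expect_gt(sum(generate_cell_network(thick)$boundary_mask),
            sum(generate_cell_network(spec)$boundary_mask))
})

test_that("images too small for four cells are rejected with explanation", {
  spec <- cell_network_spec(64, 64, mean_cell_width = 64, anisotropy = 1)
  expect_error(generate_cell_network(spec), "4 cells")
  expect_error(cell_network_spec(32, 512), "at least 64")
})

test_that("spot placement honours fraction, separation and distance geometry", {
  net <- generate_cell_network(cell_network_spec(256, 256, rng_seed = 7))
  mask <- net$boundary_mask

  all_b <- place_spots(mask, spot_placement_spec(n_spots = 50, f_boundary = 1,
                                                 rng_seed = 11))
  expect_identical(unique(all_b$label), "boundary")
  expect_equal(nrow(all_b), 50L)

  none_b <- place_spots(mask, spot_placement_spec(n_spots = 30, f_boundary = 0,
                                                  rng_seed = 12))
  expect_identical(unique(none_b$label), "interior")
  dist_map <- matrix(as.numeric(EBImage::distmap(1 - mask)),
                     nrow(mask), ncol(mask))
  d <- dist_map[cbind(round(none_b$y_px), round(none_b$x_px))]
  expect_true(all(d > 2 * 1)) # farther than 2 x jitter from any boundary px

  # rounding rule: half rounds up
  half <- place_spots(mask, spot_placement_spec(n_spots = 101,
                                                f_boundary = 0.5,
                                                rng_seed = 13,
                                                min_separation_px = 3))
  expect_equal(sum(half$label == "boundary"), 51L)

  pd <- as.matrix(dist(cbind(half$y_px, half$x_px)))
  diag(pd) <- Inf
  expect_gte(min(pd), 3)
  expect_true(all(half$y_px >= 1 & half$y_px <= 256 &
                  half$x_px >= 1 & half$x_px <= 256))

  # determinism under a fixed seed
  again <- place_spots(mask, spot_placement_spec(n_spots = 101,
                                                 f_boundary = 0.5,
                                                 rng_seed = 13,
                                                 min_separation_px = 3))
  expect_identical(half, again)
})

test_that("impossible separation constraints fail with a named constraint", {
  net <- generate_cell_network(cell_network_spec(128, 128, rng_seed = 2))
  expect_error(
    place_spots(net$boundary_mask,
                spot_placement_spec(n_spots = 500, min_separation_px = 40,
                                    rng_seed = 1)),
    "min_separation_px")
})

test_that("rendering follows the integrated-Gaussian camera model", {
  # no spots, noise off: exactly the background
  empty <- data.frame(y_px = numeric(0), x_px = numeric(0))
  img0 <- render_clean(empty, dim = c(64, 64))
  expect_true(all(img0 == 100))

  # no spots, Poisson noise: mean within 3 SE of the background level
  imgp <- render_qd_channel(empty,
                            imaging_spec(background_level = 100,
                                         noise_model = "poisson"),
                            dim = c(64, 64), rng_seed = 5)
  se <- sqrt(100 / length(imgp))
  expect_lt(abs(mean(imgp) - 100), 3 * se)

  # single spot at integer coordinates, noise off: intensity-weighted
  # centroid of the background-subtracted patch equals the true position
  one <- data.frame(y_px = 40, x_px = 25)
  img1 <- render_clean(one, dim = c(64, 64))
  patch <- img1[30:50, 15:35] - 100
  w <- sum(patch)
  cy <- sum(rowSums(patch) * 30:50) / w
  cx <- sum(colSums(patch) * 15:35) / w
  expect_lt(abs(cy - 40), 0.05)
  expect_lt(abs(cx - 25), 0.05)

  # doubling the photon mean doubles the background-subtracted mass
  img2 <- render_qd_channel(one, imaging_spec(spot_photon_mean = 4000,
                                              noise_model = "none"),
                            dim = c(64, 64))
  m1 <- sum(img1 - 100)
  m2 <- sum(img2 - 100)
  expect_lt(abs(m2 / m1 - 2), 0.01)
})

test_that("scene ground truth recovers the requested boundary fraction exactly", {
  for (f in c(0.2, 0.5, 0.8)) {
    sc <- cached_scene(f_boundary = f, n_spots = 40, seed = 300 + 100 * f)
    expect_equal(mean(sc$spots_truth$label == "boundary"),
                 floor(40 * f + 0.5) / 40)
  }
  sc <- cached_scene()
  expect_identical(dim(sc$qd_channel), dim(sc$boundary_channel))
})

test_that("segregation count simulation is multinomial and seeded", {
  t1 <- simulate_segregation_counts(10, c(1, 0, 0), rng_seed = 1)
  expect_equal(as.numeric(t1$counts), c(10, 0, 0))

  big <- simulate_segregation_counts(1e5, c(0.25, 0.5, 0.25), rng_seed = 2)
  p <- c(0.25, 0.5, 0.25)
  sds <- sqrt(1e5 * p * (1 - p))
  expect_true(all(abs(as.numeric(big$counts) - 1e5 * p) < 4 * sds))

  expect_identical(simulate_segregation_counts(500, rng_seed = 9)$counts,
                   simulate_segregation_counts(500, rng_seed = 9)$counts)
  expect_error(simulate_segregation_counts(10, c(-0.1, 0.6, 0.5)),
               "non-negative")
})

test_that("growth table simulation is seeded and honest about its effects", {
  flat <- simulate_growth_table(c(MSO = 0, MEL = 0), noise_sd = 0,
                                plate_sd = 0, baseline = 7, rng_seed = 1)
  expect_true(all(flat$value == 7))
  expect_equal(nrow(flat), 2 * 4 * 10)

  a <- simulate_growth_table(c(MSO = 0, MEL = -2), rng_seed = 4)
  b <- simulate_growth_table(c(MSO = 0, MEL = -2), rng_seed = 4)
  expect_identical(a, b)
  expect_error(simulate_growth_table(c(MSO = 0), plates_per_treatment = 1),
               "2 plates")
})
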