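test_that("probability sampling obeys the interpolation contracts", {
  ones <- probability_map(matrix(1, 32, 32))
  spots <- data.frame(spot_id = 1:3, y_px = c(2.3, 15.7, 31.2),
                      x_px = c(4.4, 8.1, 30.9))
  expect_true(all(score_spots(spots, ones)$boundary_probability == 1))

  set.seed(7)
  vals <- matrix(runif(32 * 32), 32, 32)
  map <- probability_map(vals)
  at_pixel <- data.frame(spot_id = 1, y_px = 10, x_px = 21)
  expect_identical(score_spots(at_pixel, map)$boundary_probability,
                   vals[10, 21])

  # bilinear at (y + 0.5, x + 0.5) equals the mean of the 4 neighbours
  cfg <- coloc_config(interpolation = "bilinear")
  mid <- data.frame(spot_id = 1, y_px = 10.5, x_px = 21.5)
  expect_equal(score_spots(mid, map, cfg)$boundary_probability,
               mean(vals[10:11, 21:22]))
})

test_that("out-of-map spots are clamped and flagged; grid mismatch errors", {
  map <- probability_map(matrix(0.5, 16, 16))
  outside <- data.frame(spot_id = 1, y_px = 30, x_px = 5)
  sc <- score_spots(outside, map)
  expect_identical(sc$flag, "outside")
  expect_equal(sc$boundary_probability, 0.5)

  ss <- spot_set(data.frame(spot_id = 1, y_px = 2, x_px = 2,
                            integrated_intensity = 1, detection_score = 1,
                            flag = ""),
                 image_dim = c(64, 64))
  expect_error(score_spots(ss, map), "64x64.*16x16")
})

test_that("boundary fraction equals the brute-force count on all fixtures", {
  bf <- boundary_fraction(c(0.1, 0.3, 0.9), threshold = 0.2)
  expect_equal(bf$boundary_fraction, 2 / 3)
  expect_equal(sum(bf$histogram$counts), 3L)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    thr <- runif(1, 0.05, 0.95)
    bf <- boundary_fraction(p, threshold = thr)
    # independent brute-force loop
    n_above <- 0L
    for (v in p) if (v >= thr) n_above <- n_above + 1L
    expect_equal(bf$boundary_fraction, n_above / length(p))
    expect_equal(sum(bf$histogram$counts), length(p))
  }
  expect_error(boundary_fraction(numeric(0)), "undefined")
})

test_that("fraction is non-increasing as the threshold sweeps 0 to 1", {
  set.seed(5)
  p <- runif(200)
  fr <- vapply(seq(0.01, 0.99, by = 0.02),
               function(t) boundary_fraction(p, t)$boundary_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  # inclusive >= versus strict > differ exactly at ties
  expect_equal(boundary_fraction(c(0.2, 0.5), 0.2)$boundary_fraction, 1)
  expect_equal(boundary_fraction(c(0.2, 0.5), 0.2,
                                 strict = TRUE)$boundary_fraction, 0.5)
})

test_that("end-to-end colocalization conserves histogram mass", {
  sc <- cached_scene()
  ref <- refine_centroids(sc$qd_channel, detect_spots(sc$qd_channel))
  res <- colocalize(ref, ridge_probability_map(sc$boundary_channel))
  expect_equal(sum(res$histogram$counts), res$n_spots)
  expect_equal(res$boundary_fraction,
               mean(res$per_spot_probability$boundary_probability >= 0.2))
})

test_that("identical groups give p = 1 and the observed difference 0", {
  gc <- compare_groups(list(a = c(0.5, 0.6, 0.7), b = c(0.5, 0.6, 0.7)),
                       n_permutations = 199, rng_seed = 1)
  expect_equal(gc$p_value, 1)
  expect_equal(gc$observed_difference, 0)
})

test_that("exhaustive image-level permutation matches brute-force enumeration", {
  x <- c(0.9, 0.92, 0.88); y <- c(0.1, 0.12, 0.08)
  gc <- compare_groups(list(high = x, low = y), exhaustive = TRUE)
  # independent enumeration of all 20 label splits
  pool <- c(x, y)
  splits <- combn(6, 3)
  d <- apply(splits, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  obs <- mean(x) - mean(y)
  p_oracle <- mean(abs(d) >= abs(obs) - 1e-12)
  expect_equal(gc$p_value, p_oracle)
  expect_equal(p_oracle, 2 / 20) # the resolution floor of 3-vs-3 images
  expect_equal(gc$observed_difference, 0.8)
})

test_that("monte-carlo p-values use the add-one rule and are seeded", {
  x <- c(0.9, 0.92, 0.88, 0.95); y <- c(0.1, 0.12, 0.08, 0.2)
  g1 <- compare_groups(list(a = x, b = y), n_permutations = 99, rng_seed = 7)
  g2 <- compare_groups(list(a = x, b = y), n_permutations = 99, rng_seed = 7)
  expect_identical(g1$p_value, g2$p_value)
  expect_gte(g1$p_value, 1 / 100) # (b + 1) / (m + 1) can never reach 0
  expect_error(compare_groups(list(a = 0.5, b = c(0.1, 0.2))), "at least 2")
  expect_error(compare_groups(list(a = c(1, 2))), "exactly 2")
})

test_that("spot-level pooling detects strong group differences 3-vs-3", {
  cfg <- coloc_config()
  make_result <- function(p_high, n, id) {
    vals <- matrix(p_high, 16, 16)
    map <- probability_map(vals)
    spots <- data.frame(spot_id = seq_len(n),
                        y_px = runif(n, 2, 15), x_px = runif(n, 2, 15))
    colocalize(spots, map, cfg, source_id = id)
  }
  set.seed(3)
  high <- lapply(1:3, function(i) make_result(0.9, 40, paste0("h", i)))
  low <- lapply(1:3, function(i) make_result(0.05, 40, paste0("l", i)))
  gc <- compare_groups(list(ram = high, alone = low), n_permutations = 999,
                       rng_seed = 2, unit = "spot")
  expect_lt(gc$p_value, 0.05)
  expect_gt(gc$observed_difference, 0)
  # bare fractions cannot be pooled at the spot level
  expect_error(compare_groups(list(a = c(0.1, 0.2), b = c(0.3, 0.4)),
                              unit = "spot"),
               "coloc_result")
})
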