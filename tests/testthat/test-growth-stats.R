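test_that("plate averaging collapses pseudoreplicates correctly", {
  tab <- data.frame(plate_id = c("p1", "p1", "p2"), treatment = "MSO",
                    genotype = "Col0", seedling_id = c(1, 2, 1),
                    measure = "hypocotyl_length_mm", value = c(2, 4, 5))
  out <- average_pseudoreplicates(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(out$value[out$plate_id == "p1"], 3)
  expect_equal(out$value[out$plate_id == "p2"], 5) # single seedling: identity
  expect_equal(out$n_seedlings, c(2, 1))

  # equal seedling counts preserve the grand mean
  gt <- simulate_growth_table(c(MSO = 0, MEL = -1), rng_seed = 2)
  pl <- average_pseudoreplicates(gt)
  expect_equal(mean(pl$value), mean(gt$value), tolerance = 1e-12)
  expect_error(average_pseudoreplicates(gt[, -1]), "lacks columns")
})

test_that("one-way ANOVA matches the hand-computed decomposition", {
  gt <- simulate_growth_table(c(MSO = 0, MEL = -2, RAM = -1),
                              plates_per_treatment = 8, noise_sd = 1,
                              plate_sd = 0.5, rng_seed = 31)
  pl <- average_pseudoreplicates(gt)
  rep_ <- one_way_anova(pl, "primary_root_length_mm")

  # independent oracle: sums of squares from first principles
  v <- pl$value
  g <- pl$treatment
  grand <- mean(v)
  ss_between <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ss_within <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  ss_total <- sum((v - grand)^2)
  expect_equal(ss_between + ss_within, ss_total, tolerance = 1e-9)
  expect_equal(rep_$terms$sum_sq, c(ss_between, ss_within), tolerance = 1e-8)
  k <- nlevels(factor(g)); n <- length(v)
  F_oracle <- (ss_between / (k - 1)) / (ss_within / (n - k))
  expect_equal(rep_$terms$F[1], F_oracle, tolerance = 1e-8)
  p_oracle <- pf(F_oracle, k - 1, n - k, lower.tail = FALSE)
  expect_equal(rep_$terms$p[1], p_oracle, tolerance = 1e-8)
  # the simulated 2-SD effect is detected
  expect_lt(rep_$comparisons$p_adj[rep_$comparisons$comparison == "MEL - MSO"],
            0.05)
})

test_that("zero-noise equal groups give F = 0", {
  gt <- simulate_growth_table(c(A = 0, B = 0), noise_sd = 0, plate_sd = 0,
                              rng_seed = 1)
  pl <- average_pseudoreplicates(gt)
  # perturb nothing: identical values in both groups
  rep_ <- one_way_anova(pl, "primary_root_length_mm")
  expect_equal(rep_$terms$F[1], 0)
})

test_that("multiplicity adjustments are monotone, conservative and exact", {
  p <- c(0.001, 0.04, 0.2, 0.8)
  hs <- holm_sidak_adjust(p)
  expect_true(all(hs >= p))
  expect_true(all(diff(hs[order(p)]) >= 0))
  # closed-form step-down values for this vector
  expect_equal(hs, pmin(cummax(1 - (1 - p)^(4:1)), 1))
  expect_equal(holm_sidak_adjust(0.03), 0.03) # m = 1: identity
  expect_equal(sidak_adjust(0.03), 0.03)
  expect_equal(sidak_adjust(0.1, m = 3), 1 - 0.9^3)
})

test_that("requested comparisons must name existing groups", {
  gt <- simulate_growth_table(c(MSO = 0, MEL = -2), rng_seed = 5)
  pl <- average_pseudoreplicates(gt)
  expect_error(one_way_anova(pl, "primary_root_length_mm",
                             comparisons = "MEL-TAS"), "absent")
})

test_that("two-way ANOVA flags genotype effects only where they exist", {
  # interaction fixture: mutant blunts the root-number increase under
  # MEL and RAM but matches wild type on control and TAS media
  gt <- simulate_growth_table(
    treatment_effects = c(MSO = 0, MEL = 3, RAM = 3, TAS = 0),
    genotype_effects = c(Col0 = 0, rbl7 = 0),
    interaction_effects = c("rbl7:MEL" = -3, "rbl7:RAM" = -3),
    plates_per_treatment = 6, noise_sd = 0.8, plate_sd = 0.3,
    baseline = 6, measure = "n_roots", rng_seed = 77)
  pl <- average_pseudoreplicates(gt)
  rep_ <- two_way_anova(pl, "n_roots", reference = "Col0")
  cmp <- rep_$comparisons
  sig <- cmp$p_adj < 0.05
  expect_true(all(sig[grepl("^MEL|^RAM", cmp$comparison)]))
  expect_false(any(sig[grepl("^MSO|^TAS", cmp$comparison)]))
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  # the interaction term itself is detected
  expect_lt(rep_$terms$p[rep_$terms$term == "genotype:treatment"], 0.05)
})

test_that("two-way ANOVA validates its factorial structure", {
  gt <- simulate_growth_table(c(MSO = 0, MEL = 1),
                              genotype_effects = c(Col0 = 0, rbl7 = 0),
                              plates_per_treatment = 3, rng_seed = 9)
  pl <- average_pseudoreplicates(gt)
  broken <- pl[!(pl$genotype == "rbl7" & pl$treatment == "MEL"), ]
  expect_error(two_way_anova(broken, "primary_root_length_mm"),
               "genotype=rbl7, treatment=MEL")
})

test_that("null two-way comparisons stay non-significant at the nominal rate", {
  hits <- 0L
  for (i in 1:100) {
    gt <- simulate_growth_table(c(MSO = 0, MEL = 0),
                                genotype_effects = c(Col0 = 0, rbl7 = 0),
                                plates_per_treatment = 3, seeds_per_plate = 4,
                                noise_sd = 1, plate_sd = 0.3, rng_seed = i)
    pl <- average_pseudoreplicates(gt)
    rep_ <- two_way_anova(pl, "primary_root_length_mm")
    if (any(rep_$comparisons$p_adj < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 10L) # non-significant in >= 90% of null replicates
})

test_that("linear trend contrast codes doses as documented and detects trends", {
  # coefficients: equally spaced integers centred at zero
  gt <- simulate_growth_table(c(d0 = 0, d50 = -1, d100 = -2, d250 = -3),
                              plates_per_treatment = 5, noise_sd = 0.6,
                              plate_sd = 0.2, measure = "root_angle_deg",
                              rng_seed = 13)
  pl <- average_pseudoreplicates(gt)
  tr <- linear_trend_contrast(pl, "root_angle_deg",
                              c("d0", "d50", "d100", "d250"))
  expect_equal(unname(tr$coefficients), c(-3, -1, 1, 3))
  expect_lt(tr$p_value, 0.05)
  expect_lt(tr$estimate, 0) # decreasing response

  # flat series: no trend at the fixture's n
  flat <- simulate_growth_table(c(d0 = 0, d50 = 0, d100 = 0),
                                plates_per_treatment = 5, noise_sd = 0.6,
                                plate_sd = 0.2, measure = "root_angle_deg",
                                rng_seed = 14)
  plf <- average_pseudoreplicates(flat)
  trf <- linear_trend_contrast(plf, "root_angle_deg", c("d0", "d50", "d100"))
  expect_equal(unname(trf$coefficients), c(-1, 0, 1))
  expect_gt(trf$p_value, 0.05)

  # zero-noise equal means: estimate exactly 0
  eq <- simulate_growth_table(c(a = 0, b = 0, c = 0), noise_sd = 0,
                              plate_sd = 0, rng_seed = 1)
  ple <- average_pseudoreplicates(eq)
  tre <- linear_trend_contrast(ple, "primary_root_length_mm",
                               c("a", "b", "c"))
  expect_equal(tre$estimate, 0)
  expect_error(linear_trend_contrast(ple, "primary_root_length_mm",
                                     c("a", "b")), "3 ordered")
})
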