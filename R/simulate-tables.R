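# Synthetic genotype-segregation and growth-assay tables.

#' Simulate genotype segregation counts
#'
#' Draws WT / heterozygous / homozygous counts for `n_plants` genotyped
#' plants from a multinomial with the given category probabilities — e.g.
#' `c(0.25, 0.5, 0.25)` for the 1:2:1 ratio expected when selfing a
#' heterozygote carrying a single T-DNA insertion.
#'
#' @param n_plants Number of genotyped plants.
#' @param probs Probabilities for (WT, heterozygous, homozygous); must be
#'   non-negative and sum to 1.
#' @param rng_seed Integer seed.
#' @param line_id Identifier carried into the resulting table.
#' @return A [segregation_table()] with the simulated counts.
#' @export
simulate_segregation_counts <- function(n_plants,
                                        probs = c(0.25, 0.5, 0.25),
                                        rng_seed = 1L,
                                        line_id = "synthetic") {
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-8) stop("probabilities must sum to 1")
  counts <- with_seed(derive_seed(rng_seed, "segregation"),
                      as.integer(rmultinom(1, n_plants, probs)))
  segregation_table(setNames(counts, c("WT", "het", "hom")),
                    line_id = line_id)
}

#' Simulate a long-format growth-assay table
#'
#' Emulates a plate-based seedling assay: `plates_per_treatment` replicate
#' plates per treatment x genotype cell, `seeds_per_plate` seedlings per
#' plate, with per-seedling values
#' `baseline + treatment effect + genotype effect + interaction + plate
#' random effect + residual`. Seedlings within a plate are pseudoreplicates;
#' the plate random effect makes the plate the independent unit, matching how
#' the analysis averages before testing.
#'
#' @param treatment_effects Named numeric vector of treatment main effects
#'   (units of the measure). Names become treatment levels.
#' @param genotype_effects Named numeric vector of genotype main effects;
#'   default a single wild-type level.
#' @param interaction_effects Optional named numeric vector of
#'   `genotype:treatment` interaction effects, names `"genotype:treatment"`.
#' @param plates_per_treatment Replicate plates per treatment x genotype cell
#'   (>= 2).
#' @param seeds_per_plate Seedlings per plate.
#' @param noise_sd Residual (within-plate) standard deviation.
#' @param plate_sd Plate random-effect standard deviation.
#' @param baseline Grand mean of the measure.
#' @param measure Name of the measured variable (e.g.
#'   `"primary_root_length_mm"`).
#' @param rng_seed Integer seed.
#' @return A data frame with columns `plate_id`, `treatment`, `genotype`,
#'   `seedling_id`, `measure`, `value`.
#' @export
#' @examples
#' gt <- simulate_growth_table(c(MSO = 0, MEL = -2), plates_per_treatment = 4,
#'                             rng_seed = 3)
#' head(gt)
simulate_growth_table <- function(treatment_effects,
                                  genotype_effects = c(Col0 = 0),
                                  interaction_effects = NULL,
                                  plates_per_treatment = 4L,
                                  seeds_per_plate = 10L,
                                  noise_sd = 1, plate_sd = 0.5,
                                  baseline = 10,
                                  measure = "primary_root_length_mm",
                                  rng_seed = 1L) {
  if (plates_per_treatment < 2) stop("need at least 2 plates per treatment")
  if (is.null(names(treatment_effects)) || is.null(names(genotype_effects))) {
    stop("treatment_effects and genotype_effects must be named")
  }
  cells <- expand.grid(genotype = names(genotype_effects),
                       treatment = names(treatment_effects),
                       stringsAsFactors = FALSE)
  with_seed(derive_seed(rng_seed, "growth"), {
    rows <- vector("list", nrow(cells) * plates_per_treatment)
    plate_no <- 0L
    for (ci in seq_len(nrow(cells))) {
      g <- cells$genotype[ci]; t <- cells$treatment[ci]
      inter <- 0
      if (!is.null(interaction_effects)) {
        key <- paste(g, t, sep = ":")
        if (key %in% names(interaction_effects)) {
          inter <- interaction_effects[[key]]
        }
      }
      mu <- baseline + treatment_effects[[t]] + genotype_effects[[g]] + inter
      for (p in seq_len(plates_per_treatment)) {
        plate_no <- plate_no + 1L
        pe <- rnorm(1, sd = plate_sd)
        vals <- mu + pe + rnorm(seeds_per_plate, sd = noise_sd)
        rows[[plate_no]] <- data.frame(
          plate_id = sprintf("plate_%03d", plate_no),
          treatment = t, genotype = g,
          seedling_id = seq_len(seeds_per_plate),
          measure = measure, value = vals,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
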