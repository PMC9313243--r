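# Growth and gravitropism statistics: plate averaging of pseudoreplicates,
# one-way ANOVA with Holm-Sidak pairwise comparisons, two-way ANOVA with
# Sidak comparisons of genotypes within each treatment, and the
# linear-trend (linear contrast) test across an ordered dose series.
# Everything in this module is deterministic: identical tables give
# bit-identical reports.

#' Average pseudoreplicates by plate
#'
#' Individual seedlings on a plate are pseudoreplicates; the plate is the
#' independent experimental unit. Returns one record per
#' (plate, treatment, genotype, measure) holding the seedling mean.
#'
#' @param table Long-format growth table with columns `plate_id`,
#'   `treatment`, `genotype`, `seedling_id`, `measure`, `value` (see
#'   [simulate_growth_table()]).
#' @return Plate-level data frame with columns `plate_id`, `treatment`,
#'   `genotype`, `measure`, `value`, `n_seedlings`.
#' @export
average_pseudoreplicates <- function(table) {
  required <- c("plate_id", "treatment", "genotype", "measure", "value")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("growth table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$value))) stop("values must be finite")
  agg <- aggregate(value ~ plate_id + treatment + genotype + measure,
                   data = table, FUN = mean)
  cnt <- aggregate(value ~ plate_id + treatment + genotype + measure,
                   data = table, FUN = length)
  names(cnt)[names(cnt) == "value"] <- "n_seedlings"
  out <- merge(agg, cnt,
               by = c("plate_id", "treatment", "genotype", "measure"))
  out[order(out$measure, out$treatment, out$genotype, out$plate_id), ,
      drop = FALSE]
}

#' Sidak adjustment for m independent comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values, each at least as large as its raw value.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  # -expm1(m * log1p(-p)) is 1 - (1 - p)^m computed without underflow
  pmin(pmax(-expm1(m * log1p(-p)), p), 1)
}

#' Holm-Sidak step-down adjustment
#'
#' Raw p-values are ordered ascending; the i-th smallest is adjusted as
#' `1 - (1 - p_(i))^(m - i + 1)` and monotonicity is enforced with a running
#' maximum, as in the step-down Sidak (Holm-Sidak) procedure.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in the original order, each >= its raw value.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- -expm1((m - seq_len(m) + 1) * log1p(-p[ord]))
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  pmax(out, p)
}

# anova() warns on zero-residual (noise-free) fixtures; the decomposition is
# still exact, so keep the table and recompute F with the 0/0 -> 0 rule.
anova_quiet <- function(fit) {
  withCallingHandlers(anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

f_from_ss <- function(ssb, df1, ssw, df2, tol = 0) {
  if (ssb <= tol) return(list(F = 0, p = 1))
  if (ssw <= tol) return(list(F = Inf, p = 0))
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# sums of squares this small are rounding residue of an exact fit
ss_tolerance <- function(v) length(v) * (.Machine$double.eps *
                                           max(abs(v), 1))^2 * 100

# Pairwise t comparison on the pooled ANOVA error.
pooled_t_comparison <- function(means, ns, mse, df_resid, a, b) {
  est <- means[[a]] - means[[b]]
  se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
  t <- est / se
  data.frame(comparison = paste(a, "-", b), estimate = est, se = se,
             t = t, df = df_resid,
             p_raw = 2 * pt(abs(t), df_resid, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Standard between/within decomposition of plate-level means across groups,
#' with pairwise t comparisons on the pooled error term. The default
#' multiple-comparison adjustment is the Holm-Sidak step-down
#' ([holm_sidak_adjust()]); single-step Sidak and Tukey HSD are available.
#'
#' @param plate_table Plate-level table from [average_pseudoreplicates()]
#'   (columns `treatment` — or another `group` column —, `measure`,
#'   `value`).
#' @param measure Which measure to analyse.
#' @param group Grouping column (default `"treatment"`).
#' @param comparisons Character vector of `"A-B"` pairs; default all pairs.
#' @param method `"holm_sidak"` (default), `"sidak"` or `"tukey"`.
#' @return An object of class `anova_report`: `model = "one_way"`, `terms`
#'   (F statistics and df), `comparisons` (estimates, raw and adjusted p),
#'   `group_stats` (means and SE), `method`.
#' @export
one_way_anova <- function(plate_table, measure, group = "treatment",
                          comparisons = NULL,
                          method = c("holm_sidak", "sidak", "tukey")) {
  method <- match.arg(method)
  d <- plate_table[plate_table$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for measure '", measure, "'")
  d$group <- factor(d[[group]])
  lv <- levels(d$group)
  n_per <- table(d$group)
  if (length(lv) < 2 || any(n_per < 2)) {
    stop("need >= 2 groups with >= 2 plates each")
  }
  fit <- aov(value ~ group, data = d)
  at <- anova_quiet(fit)
  mse <- at["Residuals", "Mean Sq"]
  df_resid <- at["Residuals", "Df"]
  fp <- f_from_ss(at$`Sum Sq`[1], at$Df[1], at$`Sum Sq`[2], at$Df[2],
                  tol = ss_tolerance(d$value))
  means <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)

  if (is.null(comparisons)) {
    prs <- combn(lv, 2)
    comparisons <- paste(prs[1, ], prs[2, ], sep = "-")
  }
  cmp <- lapply(comparisons, function(cstr) {
    ab <- strsplit(cstr, "-", fixed = TRUE)[[1]]
    ab <- trimws(ab)
    if (length(ab) != 2 || !all(ab %in% lv)) {
      stop("comparison '", cstr, "' names a group absent from levels [",
           paste(lv, collapse = ", "), "]")
    }
    pooled_t_comparison(means, ns, mse, df_resid, ab[1], ab[2])
  })
  cmp <- do.call(rbind, cmp)
  cmp$p_adj <- switch(method,
    holm_sidak = holm_sidak_adjust(cmp$p_raw),
    sidak = sidak_adjust(cmp$p_raw),
    tukey = {
      q <- abs(cmp$t) * sqrt(2)
      ptukey(q, nmeans = length(lv), df = df_resid, lower.tail = FALSE)
    })

  structure(list(model = "one_way", measure = measure,
                 terms = data.frame(
                   term = c("group", "Residuals"),
                   df = at$Df, sum_sq = at$`Sum Sq`,
                   F = c(fp$F, NA),
                   p = c(fp$p, NA)),
                 comparisons = cmp,
                 group_stats = data.frame(
                   group = lv, mean = as.numeric(means),
                   n = as.numeric(ns),
                   se = sqrt(mse / as.numeric(ns))),
                 comparison_method = method),
            class = "anova_report")
}

#' Two-way ANOVA with Sidak genotype comparisons within each treatment
#'
#' Fits `value ~ genotype * treatment` on plate-level means (Type II sums of
#' squares, robust to mild imbalance), then compares the reference genotype
#' (wild type) with each other genotype within every treatment using the
#' pooled residual error, Sidak-adjusted over the number of comparisons.
#'
#' @param plate_table Plate-level table (columns `genotype`, `treatment`,
#'   `measure`, `value`).
#' @param measure Which measure to analyse.
#' @param reference Reference genotype level; default the first level.
#' @param method `"sidak"` (default) or `"holm_sidak"`.
#' @return An `anova_report` with `model = "two_way"`; `terms` holds the
#'   Type II F table, `comparisons` the within-treatment genotype contrasts.
#' @export
two_way_anova <- function(plate_table, measure, reference = NULL,
                          method = c("sidak", "holm_sidak")) {
  method <- match.arg(method)
  d <- plate_table[plate_table$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for measure '", measure, "'")
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment)
  if (nlevels(d$genotype) < 2 || nlevels(d$treatment) < 2) {
    stop("need >= 2 genotypes and >= 2 treatments")
  }
  cells <- table(d$genotype, d$treatment)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    stop("cell genotype=", rownames(cells)[bad[1]], ", treatment=",
         colnames(cells)[bad[2]], " has fewer than 2 plates")
  }
  fit <- lm(value ~ genotype * treatment, data = d)
  a2 <- car::Anova(fit, type = 2)
  mse <- a2["Residuals", "Sum Sq"] / a2["Residuals", "Df"]
  df_resid <- a2["Residuals", "Df"]
  if (is.null(reference)) reference <- levels(d$genotype)[1]
  if (!reference %in% levels(d$genotype)) {
    stop("reference genotype '", reference, "' not present")
  }
  others <- setdiff(levels(d$genotype), reference)

  cmp <- list()
  for (tr in levels(d$treatment)) {
    for (g in others) {
      sub <- d[d$treatment == tr, ]
      means <- tapply(sub$value, sub$genotype, mean)
      ns <- tapply(sub$value, sub$genotype, length)
      row <- pooled_t_comparison(means, ns, mse, df_resid, reference, g)
      row$comparison <- paste0(tr, ": ", reference, " - ", g)
      cmp[[length(cmp) + 1]] <- row
    }
  }
  cmp <- do.call(rbind, cmp)
  cmp$p_adj <- switch(method,
    sidak = sidak_adjust(cmp$p_raw, m = nrow(cmp)),
    holm_sidak = holm_sidak_adjust(cmp$p_raw))

  tt <- data.frame(term = rownames(a2), df = a2$Df, sum_sq = a2$`Sum Sq`,
                   F = a2$`F value`, p = a2$`Pr(>F)`)
  structure(list(model = "two_way", measure = measure, terms = tt,
                 comparisons = cmp, comparison_method = method,
                 reference = reference),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(x$model, "ANOVA of", x$measure, "\n")
  print(x$terms, row.names = FALSE)
  cat("comparisons (", x$comparison_method, "):\n", sep = "")
  print(x$comparisons[, c("comparison", "estimate", "p_raw", "p_adj")],
        row.names = FALSE)
  invisible(x)
}

#' Linear-trend (linear contrast) test across ordered dose groups
#'
#' Tests for a monotone dose-response across >= 3 ordered groups: a contrast
#' with centred coefficients is applied to the group means over the pooled
#' one-way ANOVA error. Coefficient coding:
#' `"rank"` (default, what a linear contrast over ordered groups uses) —
#' equally spaced integers centred at 0 (e.g. -3,-1,1,3 for 4 groups);
#' `"value"`/`"log"` — the centred (log-)doses supplied in `doses`.
#'
#' @param plate_table Plate-level table.
#' @param measure Which measure to analyse.
#' @param ordered_groups Character vector (>= 3) of group levels in
#'   increasing dose order.
#' @param group Grouping column (default `"treatment"`).
#' @param coding `"rank"`, `"value"` or `"log"`.
#' @param doses Numeric doses for `"value"`/`"log"` coding.
#' @return A list of class `trend_contrast`: `estimate`, `se`, `t`, `df`,
#'   `p_value`, `coefficients`, `coding`.
#' @export
linear_trend_contrast <- function(plate_table, measure, ordered_groups,
                                  group = "treatment",
                                  coding = c("rank", "value", "log"),
                                  doses = NULL) {
  coding <- match.arg(coding)
  k <- length(ordered_groups)
  if (k < 3) stop("need at least 3 ordered groups for a trend contrast")
  d <- plate_table[plate_table$measure == measure &
                   plate_table[[group]] %in% ordered_groups, , drop = FALSE]
  d$group <- factor(d[[group]], levels = ordered_groups)
  if (any(table(d$group) < 2)) stop("each group needs >= 2 plates")

  cf <- switch(coding,
    rank = {
      r <- seq_len(k) - (k + 1) / 2
      if (k %% 2 == 0) r * 2 else r # integers in both parities
    },
    value = {
      if (is.null(doses)) stop("doses required for value coding")
      doses - mean(doses)
    },
    log = {
      if (is.null(doses)) stop("doses required for log coding")
      ld <- log(doses + min(doses[doses > 0]) * 1e-3)
      ld - mean(ld)
    })

  means <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  fit <- aov(value ~ group, data = d)
  at <- anova_quiet(fit)
  mse <- at["Residuals", "Mean Sq"]
  df_resid <- at["Residuals", "Df"]

  est <- sum(cf * means)
  se <- sqrt(mse * sum(cf^2 / ns))
  t <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
  structure(list(estimate = est, se = se, t = t, df = df_resid,
                 p_value = 2 * pt(abs(t), df_resid, lower.tail = FALSE),
                 coefficients = setNames(cf, ordered_groups),
                 group_means = means, coding = coding, measure = measure),
            class = "trend_contrast")
}

#' @export
print.trend_contrast <- function(x, ...) {
  cat("linear trend contrast (", x$coding, " coding) on ", x$measure,
      ": estimate ", signif(x$estimate, 4), ", t = ", signif(x$t, 4),
      ", df = ", x$df, ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
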