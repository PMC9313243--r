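# Mendelian segregation goodness-of-fit: Pearson chi-square of observed
# genotype counts against an expected ratio (default 1:2:1 for selfing a
# heterozygote carrying a single insertion).

#' Construct a segregation count table
#'
#' @param counts Non-negative integer counts in category order (WT,
#'   heterozygous, homozygous), total >= 1. Names are kept if given.
#' @param expected_ratio Positive weights of the expected ratio, same
#'   length; default `c(1, 2, 1)`.
#' @param line_id Identifier of the plant line.
#' @return An object of class `segregation_table`.
#' @export
segregation_table <- function(counts, expected_ratio = c(1, 2, 1),
                              line_id = "line") {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("total count must be >= 1")
  if (length(expected_ratio) != length(counts)) {
    stop("expected_ratio must have one weight per category")
  }
  if (any(expected_ratio <= 0)) stop("expected_ratio weights must be positive")
  if (is.null(names(counts)) && length(counts) == 3) {
    names(counts) <- c("WT", "het", "hom")
  }
  structure(list(counts = as.integer(counts) |> setNames(names(counts)),
                 expected_ratio = expected_ratio, line_id = line_id),
            class = "segregation_table")
}

#' Segregation chi-square test
#'
#' Pearson goodness-of-fit statistic `sum((O - E)^2 / E)` with
#' `E = total * weight / sum(weights)`, no continuity correction, df =
#' categories - 1, p-value from the chi-square distribution. For the
#' observed 8:2:0 genotype table against 1:2:1 this gives 16.4 on 2 df.
#' Expected counts below 5 trigger a warning (the asymptotic p-value is then
#' rough), not an error — small families are routinely tested.
#'
#' @param table A [segregation_table()], or a numeric vector of counts.
#' @param expected_ratio Ratio weights, used when `table` is a bare vector.
#' @return An object of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `line_id`.
#' @export
#' @examples
#' r <- chisq_segregation(c(WT = 8, het = 2, hom = 0))
#' round(r$statistic, 1) # 16.4
chisq_segregation <- function(table, expected_ratio = c(1, 2, 1)) {
  if (!inherits(table, "segregation_table")) {
    table <- segregation_table(table, expected_ratio)
  }
  O <- as.numeric(table$counts)
  n <- sum(O)
  if (n == 0) stop("all-zero counts: the test is undefined")
  w <- table$expected_ratio
  E <- n * w / sum(w)
  if (any(E < 5)) {
    warning("expected counts below 5 (min ", signif(min(E), 3),
            "); the asymptotic chi-square p-value is approximate")
  }
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 observed = table$counts, expected = E,
                 line_id = table$line_id),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat("segregation chi-square (", x$line_id, "): X2 = ",
      signif(x$statistic, 4), ", df = ", x$df, ", p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Segregation tests for a CSV of lines
#'
#' Reads a CSV with columns `line_id` and one count column per genotype
#' category (all non-`line_id` columns, in file order) and runs
#' [chisq_segregation()] per line.
#'
#' @param path CSV path.
#' @param expected_ratio Ratio weights, recycled across lines.
#' @return Data frame with `line_id`, `statistic`, `df`, `p_value`.
#' @export
chisq_segregation_file <- function(path, expected_ratio = c(1, 2, 1)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"line_id" %in% names(df)) stop("CSV must contain a line_id column")
  count_cols <- setdiff(names(df), "line_id")
  out <- lapply(seq_len(nrow(df)), function(i) {
    counts <- setNames(as.numeric(df[i, count_cols]), count_cols)
    r <- chisq_segregation(segregation_table(counts, expected_ratio,
                                             line_id = df$line_id[i]))
    data.frame(line_id = r$line_id, statistic = r$statistic, df = r$df,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
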