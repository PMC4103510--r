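# Case/control carrier counting for the genotyping screen, with exact
# binomial confidence intervals and a two-sided Fisher exact test.

COHORT_GROUPS <- c("AD", "control")

#' Count variant carriers per group
#'
#' @param records Genotype tibble with columns `sample_id`, `group`
#'   (`"AD"` or `"control"`) and logical `carrier` (carries at least one
#'   copy of the variant allele). An optional `apoe` column is carried as
#'   annotation only.
#' @return A tibble with one row per group: `group`, `carriers`, `total`.
#' @export
carrier_counts <- function(records) {
  need <- c("sample_id", "group", "carrier")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Genotype table is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  if (nrow(records) == 0L) {
    abort("Genotype table is empty.", class = "polymirts_format_error")
  }
  bad <- setdiff(unique(records$group), COHORT_GROUPS)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown group label(s): %s", paste(bad, collapse = ", ")),
          class = "polymirts_format_error")
  }
  dplyr::summarise(
    dplyr::group_by(records, group = factor(.data$group, levels = COHORT_GROUPS)),
    carriers = sum(.data$carrier), total = dplyr::n(), .groups = "drop"
  ) |>
    dplyr::mutate(group = as.character(.data$group))
}

#' Carrier frequency with exact (Clopper-Pearson) confidence interval
#'
#' @param counts Tibble as returned by [carrier_counts()] (columns
#'   `group`, `carriers`, `total`), or any tibble with those columns.
#' @param conf_level Confidence level (default 0.95).
#' @return `counts` with `frequency`, `conf_low`, `conf_high` added,
#'   classed `polymirts_carriers`.
#' @export
carrier_frequency <- function(counts, conf_level = 0.95) {
  if (any(counts$total <= 0)) {
    abort("Group totals must be positive.", class = "polymirts_contract_error")
  }
  alpha <- 1 - conf_level
  x <- counts$carriers; n <- counts$total
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  out <- dplyr::mutate(counts, frequency = x / n, conf_low = lo, conf_high = hi)
  class(out) <- c("polymirts_carriers", class(tibble()))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is formed by summing the hypergeometric point
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table -- the
#' point-probability summation convention, stated explicitly because
#' two-sided conventions differ.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise:
#'   `rbind(c(a, b), c(c, d))` (e.g. carriers/non-carriers by group).
#' @return A one-row tibble: `p.value`, `odds_ratio` (sample odds ratio,
#'   `Inf`/`NaN` possible on zero cells).
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("Cells must be non-negative integers.", class = "polymirts_contract_error")
  }
  if (sum(cells) == 0) {
    abort("All-zero table.", class = "polymirts_contract_error")
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble(p.value = min(1, p), odds_ratio = (a * d) / (b * c))
}
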