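# Classical tests computed from sums of squares / difference formulas, as
# used for reporter-assay readouts: one-way ANOVA with Bonferroni
# post-hoc comparisons against the control, balanced two-way ANOVA with
# interaction, and Student's paired t-test. Degenerate zero-variance
# inputs follow the convention F = 0 (or t = 0), p = 1 when the effect
# sums of squares are zero as well.

safe_f <- function(ss_effect, df_effect, ss_resid, df_resid) {
  ms_e <- ss_effect / df_effect
  ms_r <- ss_resid / df_resid
  if (ss_effect <= 0) return(list(statistic = 0, p.value = 1))
  if (ms_r == 0) return(list(statistic = Inf, p.value = 0))
  f <- ms_e / ms_r
  list(statistic = f, p.value = pf(f, df_effect, df_resid, lower.tail = FALSE))
}

#' One-way ANOVA with Bonferroni post-hoc tests against a control
#'
#' The omnibus F is computed from between/within sums of squares. Post-hoc
#' pairwise two-sided t-tests compare every non-control group against the
#' control using the pooled residual variance and residual degrees of
#' freedom, with Bonferroni multiplication by the number of
#' control-vs-group comparisons (not all pairs), capped at 1.
#'
#' @param data A data frame of replicated measurements.
#' @param value Bare column with the response (e.g. `relative`).
#' @param group Bare column with the group label (e.g. `mirna`).
#' @param control Label of the control group for the post-hoc comparisons.
#' @return An object of class `polymirts_anova`; see [tidy()] and
#'   [glance()] methods, or inspect `$table` and `$comparisons`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("SCR", "a", "b"), each = 3),
#'                  y = c(1, 1.1, 0.9, 0.5, 0.55, 0.45, 1.2, 1.1, 1.3))
#' fit <- one_way_anova(df, y, g, control = "SCR")
#' glance(fit)
#' tidy(fit, "comparisons")
one_way_anova <- function(data, value, group, control = NULL) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  stopifnot(length(y) == length(g))
  groups <- split(y, g)
  k <- length(groups)
  if (k < 2L) abort("Need at least two groups.", class = "polymirts_contract_error")
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    abort(sprintf("Group '%s' has fewer than 2 replicates.",
                  names(groups)[ns < 2L][1]),
          class = "polymirts_contract_error")
  }
  n <- length(y)
  grand <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- n - k
  omni <- safe_f(ss_between, df_b, ss_within, df_w)
  mse <- ss_within / df_w
  table <- tibble(
    term = c("group", "residuals"),
    df = c(df_b, df_w),
    sumsq = c(ss_between, ss_within),
    meansq = c(ss_between / df_b, mse),
    statistic = c(omni$statistic, NA_real_),
    p.value = c(omni$p.value, NA_real_)
  )
  comparisons <- NULL
  if (!is.null(control)) {
    if (!control %in% names(groups)) {
      abort(sprintf("Control group '%s' not present.", control),
            class = "polymirts_contract_error")
    }
    others <- setdiff(names(groups), control)
    m <- length(others)
    comparisons <- purrr::map_dfr(others, function(gname) {
      est <- means[[gname]] - means[[control]]
      se <- sqrt(mse * (1 / ns[[gname]] + 1 / ns[[control]]))
      if (se == 0) {
        tstat <- if (est == 0) 0 else sign(est) * Inf
      } else {
        tstat <- est / se
      }
      p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df_w)
      tibble(group = gname, estimate = est, statistic = tstat, df = df_w,
             p.value = p, p.adjusted = min(1, p * m))
    })
  }
  structure(
    list(table = table, comparisons = comparisons, control = control,
         means = tibble(group = names(groups), n = as.integer(ns), mean = unname(means)),
         n = n, k = k),
    class = "polymirts_anova"
  )
}

#' Balanced two-way ANOVA with interaction
#'
#' Classical fixed-effects two-way ANOVA from sums of squares. The design
#' must be complete and balanced (every factor combination observed with
#' the same number of replicates, at least 2); anything else is an error
#' rather than silently refitted.
#'
#' @param data A data frame of replicated measurements.
#' @param value Bare response column.
#' @param factor1,factor2 Bare factor columns.
#' @return An object of class `polymirts_anova2` with a `$table` of terms
#'   (`factor1`, `factor2`, `interaction`, `residuals`).
#' @export
two_way_anova <- function(data, value, factor1, factor2) {
  y <- dplyr::pull(data, {{ value }})
  f1 <- as.character(dplyr::pull(data, {{ factor1 }}))
  f2 <- as.character(dplyr::pull(data, {{ factor2 }}))
  lev1 <- sort(unique(f1)); lev2 <- sort(unique(f2))
  a <- length(lev1); b <- length(lev2)
  if (a < 2L || b < 2L) {
    abort("Both factors need at least two levels.", class = "polymirts_contract_error")
  }
  counts <- table(f1, f2)
  if (length(unique(as.vector(counts))) != 1L || any(counts < 2L)) {
    abort("Design must be complete and balanced with >= 2 replicates per cell.",
          class = "polymirts_contract_error")
  }
  r <- as.integer(counts[1, 1])
  grand <- mean(y)
  mean1 <- tapply(y, f1, mean)
  mean2 <- tapply(y, f2, mean)
  cell <- tapply(y, list(f1, f2), mean)
  ss_a <- r * b * sum((mean1 - grand)^2)
  ss_b <- r * a * sum((mean2 - grand)^2)
  ss_cells <- r * sum((cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_ab <- max(ss_ab, 0)  # guard tiny negative rounding
  ss_tot <- sum((y - grand)^2)
  ss_e <- ss_tot - ss_cells
  ss_e <- max(ss_e, 0)
  df_a <- a - 1L; df_b2 <- b - 1L; df_ab <- df_a * df_b2
  df_e <- a * b * (r - 1L)
  fa <- safe_f(ss_a, df_a, ss_e, df_e)
  fb <- safe_f(ss_b, df_b2, ss_e, df_e)
  fab <- safe_f(ss_ab, df_ab, ss_e, df_e)
  table <- tibble(
    term = c("factor1", "factor2", "interaction", "residuals"),
    df = c(df_a, df_b2, df_ab, df_e),
    sumsq = c(ss_a, ss_b, ss_ab, ss_e),
    meansq = c(ss_a / df_a, ss_b / df_b2, ss_ab / df_ab, ss_e / df_e),
    statistic = c(fa$statistic, fb$statistic, fab$statistic, NA_real_),
    p.value = c(fa$p.value, fb$p.value, fab$p.value, NA_real_)
  )
  structure(list(table = table, levels = list(lev1, lev2), replicates = r),
            class = "polymirts_anova2")
}

#' Student's paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d`, with a
#' two-sided p-value from Student's t distribution on `n - 1` degrees of
#' freedom. All-zero differences give `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric replicate vectors of equal length (n >= 2).
#' @return An object of class `polymirts_htest` with fields `statistic`,
#'   `df`, `p.value`, `estimate` (mean difference), `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Paired vectors must have equal length.", class = "polymirts_contract_error")
  }
  n <- length(a)
  if (n < 2L) abort("Need at least two pairs.", class = "polymirts_contract_error")
  d <- a - b
  est <- mean(d)
  s <- sd(d)
  if (s == 0) {
    tstat <- if (est == 0) 0 else sign(est) * Inf
  } else {
    tstat <- est / (s / sqrt(n))
  }
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), n - 1L)
  structure(
    list(statistic = tstat, df = n - 1L, p.value = p, estimate = est, n = n,
         method = "Student's paired t-test"),
    class = "polymirts_htest"
  )
}

#' @export
print.polymirts_anova <- function(x, ...) {
  cat("One-way ANOVA\n")
  print(x$table)
  if (!is.null(x$comparisons)) {
    cat(sprintf("\nBonferroni comparisons vs '%s':\n", x$control))
    print(x$comparisons)
  }
  invisible(x)
}

#' @export
print.polymirts_anova2 <- function(x, ...) {
  cat("Two-way ANOVA (balanced, with interaction)\n")
  print(x$table)
  invisible(x)
}

#' @export
print.polymirts_htest <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %d, p = %.4g (mean difference %.4g)\n",
              x$method, x$statistic, x$df, x$p.value, x$estimate))
  invisible(x)
}

#' Tidy an ANOVA fit
#'
#' @param x A `polymirts_anova` object.
#' @param which `"anova"` for the term table, `"comparisons"` for the
#'   Bonferroni control-vs-group table.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.polymirts_anova <- function(x, which = c("anova", "comparisons"), ...) {
  which <- match.arg(which)
  if (which == "anova") return(x$table)
  if (is.null(x$comparisons)) {
    abort("Fit has no control comparisons (control was NULL).",
          class = "polymirts_contract_error")
  }
  x$comparisons
}

#' @rdname tidy.polymirts_anova
#' @exportS3Method generics::tidy
tidy.polymirts_anova2 <- function(x, ...) x$table

#' @exportS3Method generics::tidy
tidy.polymirts_htest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p.value, method = x$method)
}

#' Glance at an ANOVA fit
#'
#' @param x A `polymirts_anova` or `polymirts_anova2` object.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus statistics.
#' @exportS3Method generics::glance
glance.polymirts_anova <- function(x, ...) {
  tibble(statistic = x$table$statistic[1], p.value = x$table$p.value[1],
         df = x$table$df[1], df.residual = x$table$df[2],
         n = x$n, k = x$k)
}

#' @rdname glance.polymirts_anova
#' @exportS3Method generics::glance
glance.polymirts_anova2 <- function(x, ...) {
  tb <- x$table
  tibble(statistic.factor1 = tb$statistic[1], p.value.factor1 = tb$p.value[1],
         statistic.factor2 = tb$statistic[2], p.value.factor2 = tb$p.value[2],
         statistic.interaction = tb$statistic[3],
         p.value.interaction = tb$p.value[3],
         df.residual = tb$df[4])
}

#' @exportS3Method generics::glance
glance.polymirts_htest <- function(x, ...) tidy.polymirts_htest(x)
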