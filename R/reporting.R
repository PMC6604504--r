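#' @title Accuracy reports and nonparametric statistics
#'
#' @description Per-item accuracy summaries over stated subgroups (with
#'   half-up rounding mirrored to the precision of the location being
#'   reproduced), the Kruskal-Wallis rank test with midranks and tie
#'   correction, and the Spearman rank-order correlation.
#' @name reporting
NULL

#' Round half away from zero
#'
#' `round()` in R rounds half to even; printed survey percentages use
#' the conventional half-up rule, so it is applied explicitly.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Accuracy of a flag over a subgroup
#'
#' @param correct Logical vector (item/component correctness).
#' @param subgroup Logical vector delimiting the denominator (default
#'   all).
#' @param digits Decimal places for the rounded percentage (match the
#'   precision of the figure being reproduced: 0 or 1).
#' @return One-row tibble: `n` (numerator), `N` (denominator),
#'   `pct_raw`, `pct` (half-up rounded). An empty subgroup yields `NA`
#'   percentages (flagged, not zero).
#' @export
item_accuracy <- function(correct, subgroup = rep(TRUE, length(correct)),
                          digits = 1) {
  stopifnot(length(correct) == length(subgroup))
  N <- sum(subgroup, na.rm = TRUE)
  n <- sum(correct & subgroup, na.rm = TRUE)
  if (N == 0L) {
    return(tibble::tibble(n = 0L, N = 0L, pct_raw = NA_real_,
                          pct = NA_real_, undefined = TRUE))
  }
  raw <- 100 * n / N
  tibble::tibble(n = as.integer(n), N = as.integer(N), pct_raw = raw,
                 pct = round_half_up(raw, digits), undefined = FALSE)
}

#' Per-component accuracy report for a drug-quizzed cohort
#'
#' @param records Record tibble.
#' @param screen Matching result tibble from [screen_records()].
#' @param components Components to report (default all four).
#' @param subgroup `"passers"` (denominator = drug-quiz passers, as the
#'   printed accuracies use) or `"all"`.
#' @param digits Decimal places.
#' @return Tibble with one row per component present.
#' @export
component_accuracy <- function(records, screen,
                               components = DRUG_COMPONENTS,
                               subgroup = c("passers", "all"),
                               digits = 1) {
  subgroup <- match.arg(subgroup)
  base <- if (subgroup == "passers") screen$drug_quiz_pass %in% TRUE
          else rep(TRUE, nrow(records))
  rows <- list()
  for (cmp in components) {
    flags <- records[[paste0("comp_", cmp)]]
    sel <- base & !is.na(flags)
    if (!any(sel)) next
    acc <- item_accuracy(flags, sel, digits)
    rows[[cmp]] <- tibble::add_column(acc, component = cmp, .before = 1L)
  }
  if (!length(rows)) {
    return(tibble::tibble(component = character(), n = integer(),
                          N = integer(), pct_raw = numeric(),
                          pct = numeric(), undefined = logical()))
  }
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test
#'
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)` on midranks,
#' divided by the tie correction `1 - sum(t^3 - t) / (N^3 - N)`;
#' `df = groups - 1`. All observations identical gives `H = 0` (the
#' tie divisor is guarded). The p-value uses the asymptotic chi-square
#' approximation.
#'
#' @param x Numeric observations.
#' @param g Group labels (coerced to factor), at least two nonempty
#'   groups.
#' @return List: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2L,
            all(table(g) >= 1L))
  N <- length(x)
  r <- rank(x)  # midranks
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- nlevels(g) - 1L
  list(H = H, df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Spearman rank-order correlation
#'
#' Product-moment correlation of midranks.
#'
#' @param x,y Equal-length numeric vectors, `length >= 3`.
#' @return Correlation in \[-1, 1\]; errors when either ranking has
#'   zero variance (undefined, flagged rather than returned as 0).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("spearman_rho undefined: zero variance in a ranking",
         call. = FALSE)
  }
  stats::cor(rx, ry)
}
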