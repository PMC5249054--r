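#' Per-group mean and SD of a per-sample statistic
#'
#' @param records Data.frame with a `group` column (A/B/C) and the
#'   requested `field`.
#' @param field Column to summarise, e.g. `"n_objects"`,
#'   `"mean_V_1e5_um3"`, `"mean_SMI"`, `"sd_SMI"`.
#' @param include_excluded Keep samples flagged `excluded`? Default
#'   drops them, matching the reporting convention for single-object
#'   samples.
#' @return Data.frame with `group`, `n`, `mean`, `sd` (n-1 denominator).
#' @export
group_summary <- function(records, field, include_excluded = FALSE) {
  stopifnot(field %in% names(records))
  if (!include_excluded && "excluded" %in% names(records))
    records <- records[!records$excluded, ]
  grp <- factor(records$group, levels = c("A", "B", "C"))
  if (any(table(grp) == 0L))
    stop("empty group: ",
         paste(levels(grp)[table(grp) == 0L], collapse = ", "))
  x <- records[[field]]
  data.frame(group = levels(grp),
             n = as.integer(table(grp)),
             mean = as.numeric(tapply(x, grp, mean)),
             sd = as.numeric(tapply(x, grp, stats::sd)))
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with the midrank ties correction, compared to a
#' chi-square distribution with `k - 1` degrees of freedom (the
#' standard `stats::kruskal.test` stands behind this surface). If every
#' value is identical the test is degenerate and `p = 1` is returned by
#' convention.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector/factor of the same length (k >= 2
#'   non-empty groups).
#' @return Data.frame `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L,
            all(table(groups) > 0L), length(values) >= 3L)
  if (length(unique(values)) == 1L) {
    message("kruskal_wallis: all values identical; p = 1 by convention")
    return(data.frame(statistic = 0, df = nlevels(groups) - 1L,
                      p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  data.frame(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p_value = kt$p.value)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the row/column
#' margins, `df = k - 1`, no continuity correction (the correction is a
#' 2x2-only device and would not reproduce the reference analyses).
#'
#' @param table 2 x k matrix of counts; all row and column margins must
#'   be positive.
#' @return Data.frame `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) >= 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  data.frame(statistic = unname(ct$statistic),
             df = unname(ct$parameter), p_value = ct$p.value)
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  # equals stats::p.adjust(p, "bonferroni", n = m), but p.adjust refuses
  # family sizes smaller than the vector length
  pmin(1, m * p_values)
}

#' Kolmogorov-Smirnov normality check
#'
#' D statistic of the empirical CDF against a normal distribution with
#' the sample's own mean and SD. Because the parameters are estimated
#' from the same data, the asymptotic p-value is conservative
#' (Lilliefors bias); it is reported descriptively and flagged
#' `approximate`.
#'
#' @param values Numeric vector, n >= 4, non-zero variance.
#' @return Data.frame `statistic` (D), `p_value`, `approximate`.
#' @export
ks_normality <- function(values) {
  stopifnot(length(values) >= 4L)
  if (stats::sd(values) == 0) stop("zero variance: KS check undefined")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  data.frame(statistic = unname(kt$statistic), p_value = kt$p.value,
             approximate = TRUE)
}

#' Full group-level statistical battery for a classified cohort
#'
#' Reproduces the group-comparison stage: per-group summaries and
#' Kruskal-Wallis tests of count, mean volume, mean SMI and SD of SMI,
#' plus Pearson chi-square tests of the four morphology presence tables
#' with a Bonferroni correction over that four-test family.
#'
#' @param records Per-sample data.frame with `group`, `excluded`, the
#'   morphometry columns (`n_objects`, `mean_V_1e5_um3`, `mean_SMI`,
#'   `sd_SMI`) and logical flag columns `fl`, `fp`, `ch`, `ns`.
#' @param bonferroni_m Family size for the chi-square correction.
#' @param alpha Significance level used in the verdict column.
#' @return List: `summaries` (per group x field), `kruskal` (one row per
#'   field), `chisq` (one row per flag, with `p_adjusted` and
#'   `significant`), `tables` (the 2 x 3 presence tables).
#' @export
cohort_statistics <- function(records, bonferroni_m = 4, alpha = 0.05) {
  records <- records[!records$excluded, ]
  fields <- c("n_objects", "mean_V_1e5_um3", "mean_SMI", "sd_SMI")
  summaries <- do.call(rbind, lapply(fields, function(f) {
    s <- group_summary(records, f, include_excluded = TRUE)
    cbind(field = f, s)
  }))
  kruskal <- do.call(rbind, lapply(fields, function(f) {
    k <- kruskal_wallis(records[[f]], records$group)
    cbind(field = f, k)
  }))
  flags <- c("fl", "fp", "ch", "ns")
  tables <- lapply(flags, function(fl) presence_table(records, fl))
  names(tables) <- flags
  chisq <- do.call(rbind, lapply(flags, function(fl) {
    ct <- tryCatch(pearson_chi_square(tables[[fl]]),
                   error = function(e)
                     # a flag absent (or universal) in every group has a
                     # zero margin: the test is undefined, not failed
                     data.frame(statistic = NA_real_, df = NA_real_,
                                p_value = NA_real_))
    cbind(flag = fl, ct)
  }))
  chisq$p_adjusted <- bonferroni(chisq$p_value, m = bonferroni_m)
  chisq$significant <- chisq$p_adjusted < alpha
  list(summaries = summaries, kruskal = kruskal, chisq = chisq,
       tables = tables)
}
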