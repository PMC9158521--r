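#' Linear trend of an annual series
#'
#' Ordinary least-squares regression of a yearly quantity against calendar
#' year; the phenology literature reports the slope in days per decade.
#'
#' @param year integer vector of calendar years (>= 3 distinct).
#' @param value numeric vector, same length.
#' @return A one-row data frame `slope_per_year, slope_per_decade, intercept,
#'   p_value, n_years`; `p_value` is the two-sided OLS slope test.
#' @examples
#' yrs <- 1952:2020
#' linear_trend(yrs, 120 - 0.2 * (yrs - 2000))
#' @export
linear_trend <- function(year, value) {
  keep <- !is.na(value) & !is.na(year)
  year <- year[keep]; value <- value[keep]
  if (length(year) < 3)
    stop("need at least 3 years for a trend", call. = FALSE)
  fit <- stats::lm(value ~ year)
  # constant or exactly linear series are legitimate here; lm warns about
  # the perfect fit when computing the p-value
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(stats::coef(fit)["year"])
  p <- if (nrow(sm) == 2) unname(sm["year", "Pr(>|t|)"]) else NA_real_
  data.frame(slope_per_year = slope, slope_per_decade = 10 * slope,
             intercept = unname(stats::coef(fit)[1]),
             p_value = p, n_years = length(year))
}

#' Interannual regression of the forcing effect on the chilling effect
#'
#' Regresses the annual forcing effect `F` on the annual chilling effect `C`
#' across years. The slope reads as days of forcing-driven advance per day
#' of chilling-driven delay; `r` is the Pearson correlation, typically
#' negative when a shared warming driver reduces chilling while boosting
#' forcing.
#'
#' @param C,F equal-length annual series (days).
#' @return A list `slope, r, p_value, n`, or (when `C` has zero variance,
#'   which leaves the regression undefined) the same shape with `NA` values
#'   and `note = "zero-variance chilling effect"`.
#' @export
effect_regression <- function(C, F) {
  keep <- !is.na(C) & !is.na(F)
  C <- C[keep]; F <- F[keep]
  if (length(C) != length(F)) stop("series lengths differ", call. = FALSE)
  if (stats::var(C) == 0) {
    return(list(slope = NA_real_, r = NA_real_, p_value = NA_real_,
                n = length(C), note = "zero-variance chilling effect"))
  }
  fit <- stats::lm(F ~ C)
  ct <- stats::cor.test(C, F)
  list(slope = unname(stats::coef(fit)["C"]), r = unname(ct$estimate),
       p_value = ct$p.value, n = length(C))
}

#' Correlations between species traits and phenological trends
#'
#' Pearson correlation, across species, between a physiological trait
#' (chilling sensitivity or basic forcing requirement) and a per-species
#' phenological trend (onset, chilling-effect or forcing-effect slope).
#'
#' @param trends data frame with a `species` column and one or more numeric
#'   trend columns (e.g. `onset_trend`, `C_trend`, `F_trend`), days/decade.
#' @param traits data frame with a `species` column and trait columns `cs`
#'   and/or `basic_fr`.
#' @return Data frame `trait, response, r, p_value, n_species`; a constant
#'   trait or response yields `NA` with a note column entry.
#' @export
trait_correlations <- function(trends, traits) {
  m <- merge(trends, traits, by = "species")
  if (nrow(m) < 4)
    stop("need at least 4 species for trait correlations", call. = FALSE)
  trait_cols <- intersect(c("cs", "basic_fr"), names(m))
  resp_cols <- setdiff(intersect(names(trends), names(m)), "species")
  resp_cols <- resp_cols[vapply(m[resp_cols], is.numeric, logical(1))]
  rows <- list()
  for (tr in trait_cols) for (re in resp_cols) {
    x <- m[[tr]]; y <- m[[re]]
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, response = re, r = NA_real_, p_value = NA_real_,
        n_species = nrow(m), note = "constant vector")
      next
    }
    ct <- stats::cor.test(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, response = re, r = unname(ct$estimate),
      p_value = ct$p.value, n_species = nrow(m), note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a species trait between life forms
#'
#' Welch two-sample t-test of a per-species value between groups (shrubs vs
#' trees).
#'
#' @param values numeric vector, one per species.
#' @param groups character/factor vector of group labels, same length; each
#'   group needs at least 2 members.
#' @return A list `t, p_value, group_means, df`.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 members", call. = FALSE)
  tt <- stats::t.test(values ~ groups)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       group_means = tapply(values, groups, mean), df = unname(tt$parameter))
}

#' Significance stars for report formatting
#' @param p numeric vector of p-values.
#' @return Character vector: `***` < 0.001, `**` < 0.01, `*` < 0.05, else "".
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
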