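#' A twig-experiment sampling record
#'
#' One collection of twigs of a species on a given date, forced in a growth
#' chamber; `twig_onsets` are the chamber dates of the first spring event
#' (leaf-out or flowering) of the individual twigs.
#'
#' @param species species identifier.
#' @param sample_date collection date.
#' @param twig_onsets vector of chamber onset dates, one per twig (typically
#'   three); may be empty for twigs that never flushed.
#' @param season winter label, e.g. `"2018-19"` (metadata only).
#' @return A `twig_sample` object.
#' @export
twig_sample <- function(species, sample_date, twig_onsets,
                        season = NA_character_) {
  sample_date <- as.Date(sample_date)
  twig_onsets <- as.Date(twig_onsets)
  if (length(twig_onsets)) {
    if (any(twig_onsets < sample_date))
      stop("twig onset precedes its sampling date", call. = FALSE)
    if (any(as.integer(twig_onsets - sample_date) > 365))
      stop("twig onset more than 365 days after sampling", call. = FALSE)
  }
  structure(list(species = as.character(species), sample_date = sample_date,
                 twig_onsets = twig_onsets, season = season),
            class = "twig_sample")
}

#' Read a twig-experiment table
#'
#' CSV with columns `species,sample_date,twig_id,onset_date,season`; one row
#' per twig. Empty `onset_date` marks a twig that never flushed.
#'
#' @param path file path.
#' @return A list of [twig_sample] objects, one per (species, sample_date).
#' @export
read_experiment <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "sample_date", "onset_date")
  if (!all(need %in% names(x)))
    stop("experiment CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"season" %in% names(x)) x$season <- NA_character_
  experiment_from_table(x)
}

#' @param table data frame with columns `species`, `sample_date`,
#'   `onset_date` and optionally `season`.
#' @rdname read_experiment
#' @export
experiment_from_table <- function(table) {
  key <- paste(table$species, table$sample_date)
  lapply(split(table, factor(key, levels = unique(key))), function(g) {
    on <- g$onset_date[!is.na(g$onset_date) & nzchar(as.character(g$onset_date))]
    twig_sample(g$species[1], g$sample_date[1], as.Date(on),
                season = if ("season" %in% names(g)) g$season[1] else NA)
  })
}

#' Chilling accumulation and forcing requirement of one sample
#'
#' Turns a twig sample into a (CA, FR) point. CA is accumulated under the
#' species' chilling model from 00:00 on 1 November of the phenological year
#' to 23:00 of the sampling date. FR uses the mean onset date across twigs
#' (rounded to the nearest day) via [forcing_to_event()]; the spread across
#' twigs is retained as `FR_sd`.
#'
#' @param sample a [twig_sample].
#' @param outdoor an [hourly_series] covering 1 November to the sampling
#'   date.
#' @param chamber a [chamber_profile].
#' @param model the species' [chill_model].
#' @param Tb base temperature for forcing, deg C.
#' @return A one-row data frame `species, sample_date, season, CA, FR, FR_sd,
#'   n_twigs`, or `NULL` (with a warning) when no twig flushed.
#' @export
sample_to_point <- function(sample, outdoor, chamber, model, Tb = 5) {
  stopifnot(inherits(sample, "twig_sample"))
  if (!length(sample$twig_onsets)) {
    warning("sample ", sample$species, " ", format(sample$sample_date),
            " has no flushing twigs; skipped", call. = FALSE)
    return(NULL)
  }
  t0 <- season_start(sample$sample_date)
  ca <- accumulate_chill(outdoor, model, accum_window(t0, sample$sample_date))
  mean_onset <- as.Date(round(mean(as.numeric(sample$twig_onsets))),
                        origin = "1970-01-01")
  fr <- forcing_to_event(outdoor, chamber, sample$sample_date, mean_onset, Tb)
  fr_each <- vapply(seq_along(sample$twig_onsets), function(i) {
    forcing_to_event(outdoor, chamber, sample$sample_date,
                     sample$twig_onsets[i], Tb)
  }, numeric(1))
  data.frame(species = sample$species,
             sample_date = sample$sample_date,
             season = sample$season,
             CA = ca, FR = fr,
             FR_sd = if (length(fr_each) > 1) stats::sd(fr_each) else 0,
             n_twigs = length(sample$twig_onsets))
}

#' Convert a whole experiment to (CA, FR) points
#'
#' @param samples list of [twig_sample] objects.
#' @inheritParams sample_to_point
#' @return Data frame of points (non-flushing samples dropped with a
#'   warning).
#' @export
samples_to_points <- function(samples, outdoor, chamber, model, Tb = 5) {
  rows <- lapply(samples, sample_to_point, outdoor = outdoor,
                 chamber = chamber, model = model, Tb = Tb)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Fit the exponential chilling-forcing curve
#'
#' Fits `FR(CA) = a + b * exp(-c * CA)` to observed (CA, FR) points by
#' bounded nonlinear least squares, minimising the sum of squared FR
#' residuals. `a` is the asymptotic forcing requirement under saturating
#' chilling, `b` the chilling-removable excess and `c` the decay rate per
#' chilling unit. Bounds `a >= 0`, `b >= 0`, `0 <= c <= 1` guarantee a
#' monotone non-increasing curve; the optimiser is started from a small grid
#' of initial values and the best converged fit is kept.
#'
#' @param points data frame with numeric columns `CA` and `FR` (at least 4
#'   rows and 3 distinct CA values).
#' @return A `ca_fr_fit` object with elements `a`, `b`, `c`, `r2` (computed
#'   on the FR scale), `n_points`, `sse` and `insensitive` (`TRUE` when the
#'   points carry no FR variation and the fit degenerates to a constant).
#' @examples
#' ca <- seq(0, 2400, by = 200)
#' pts <- data.frame(CA = ca, FR = 2000 + 6000 * exp(-0.003 * ca))
#' fit_ca_fr(pts)
#' @export
fit_ca_fr <- function(points) {
  ca <- as.numeric(points$CA); fr <- as.numeric(points$FR)
  if (length(ca) < 4)
    stop("need at least 4 (CA, FR) points", call. = FALSE)
  if (length(unique(ca)) < 3)
    stop("need at least 3 distinct CA values", call. = FALSE)
  if (any(fr <= 0)) stop("FR must be positive", call. = FALSE)
  sst <- sum((fr - mean(fr))^2)
  if (sst == 0) {
    fit <- list(a = mean(fr), b = 0, c = 0, r2 = NA_real_,
                n_points = length(fr), sse = 0, insensitive = TRUE)
    class(fit) <- "ca_fr_fit"
    return(fit)
  }
  dat <- data.frame(CA = ca, FR = fr)
  starts <- expand.grid(a = c(min(fr), 0.5 * min(fr)),
                        b = max(max(fr) - min(fr), 1),
                        c = c(1e-4, 1e-3, 1e-2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(FR ~ a + b * exp(-c * CA), data = dat,
                        start = as.list(starts[i, ]),
                        lower = c(0, 0, 0), upper = c(Inf, Inf, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(stats::resid(f)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = f, sse = sse)
  }
  if (is.null(best))
    stop("chilling-forcing curve fit failed to converge from any start ",
         "(n = ", length(fr), ", CA spread ", diff(range(ca)), ")",
         call. = FALSE)
  cf <- stats::coef(best$fit)
  fit <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
              r2 = 1 - best$sse / sst, n_points = length(fr),
              sse = best$sse, insensitive = unname(cf["b"]) == 0)
  class(fit) <- "ca_fr_fit"
  fit
}

#' Evaluate a fitted chilling-forcing curve
#'
#' @param fit a `ca_fr_fit` (or any list with elements `a`, `b`, `c`).
#' @param ca chilling accumulation value(s).
#' @return Predicted forcing requirement(s), deg C hours.
#' @export
predict_fr <- function(fit, ca) {
  fit$a + fit$b * exp(-fit$c * as.numeric(ca))
}

#' @export
print.ca_fr_fit <- function(x, ...) {
  cat(sprintf("FR(CA) = %.2f + %.2f * exp(-%.3g * CA)   [R2 = %s, n = %d]\n",
              x$a, x$b, x$c,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2), x$n_points))
  if (isTRUE(x$insensitive)) cat("  (flagged chilling-insensitive: b = 0)\n")
  invisible(x)
}

#' Cross-species mixed model of the forcing requirement
#'
#' Fits `ln(FR) ~ CA + species + CA:species` with a random intercept per
#' experimental year, testing whether FR and its response to chilling differ
#' among species. The log link mirrors the exponential CA-FR relationship.
#' With a single species the species terms are dropped. The conditional R2
#' is the variance explained jointly by fixed and random effects,
#' `(var_fixed + var_random) / (var_fixed + var_random + var_residual)`.
#'
#' @param points data frame with columns `species`, `year`, `CA`, `FR`
#'   (`FR > 0`).
#' @return A `mixed_model_result` with `coefficients`, `p_values` (one per
#'   fixed-effect term, Satterthwaite F tests), `conditional_r2`,
#'   `year_variance`, `singular` flag and the underlying `model`.
#' @export
fit_mixed_model <- function(points) {
  stopifnot(all(c("species", "year", "CA", "FR") %in% names(points)))
  if (any(points$FR <= 0)) stop("FR must be positive", call. = FALSE)
  d <- data.frame(lnFR = log(points$FR), CA = as.numeric(points$CA),
                  species = factor(points$species),
                  year = factor(points$year))
  multi <- nlevels(d$species) > 1
  form <- if (multi) lnFR ~ CA * species + (1 | year)
          else lnFR ~ CA + (1 | year)
  # Satterthwaite tests need a well-conditioned fit; degenerate (e.g.
  # noise-free) data fall back to the plain mixed fit with NA p-values
  m <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d,
                     control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e)
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))))
  an <- suppressMessages(suppressWarnings(stats::anova(m)))
  pv <- if ("Pr(>F)" %in% colnames(an))
    stats::setNames(an[["Pr(>F)"]], rownames(an))
  else stats::setNames(rep(NA_real_, nrow(an)), rownames(an))
  vf <- stats::var(stats::predict(m, re.form = NA))
  vr <- sum(vapply(lme4::VarCorr(m), function(v) v[1, 1], numeric(1)))
  ve <- stats::sigma(m)^2
  res <- list(coefficients = lme4::fixef(m), p_values = pv,
              conditional_r2 = (vf + vr) / (vf + vr + ve),
              year_variance = vr,
              singular = lme4::isSingular(m), model = m)
  class(res) <- "mixed_model_result"
  res
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Mixed model ln(FR) ~ CA * species + (1 | year)\n")
  cat(sprintf("  conditional R2 = %.3f, year variance = %.4g%s\n",
              x$conditional_r2, x$year_variance,
              if (x$singular) " (singular fit)" else ""))
  for (i in seq_along(x$p_values))
    cat(sprintf("  %-12s p = %.3g\n", names(x$p_values)[i], x$p_values[i]))
  invisible(x)
}
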