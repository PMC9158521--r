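#' Species-comparable low and high chilling conditions
#'
#' Chilling accumulations from different chilling models are not directly
#' comparable, so low and high chilling conditions are defined as the CA a
#' species' own model accumulates over two fixed calendar windows of a
#' designated reference winter: 1 November to 21 December (low) and 1
#' November to 28/29 February (high), both windows closed at 23:00 of their
#' end date.
#'
#' @param reference_winter an [hourly_series] covering `t0` to `t_high`.
#' @param model the species' [chill_model].
#' @param t0 window start date (default 1 November of the winter's first
#'   calendar year, taken from the series start).
#' @param t_low end date of the low-chilling window.
#' @param t_high end date of the high-chilling window.
#' @return Named numeric vector `c(lowc = , highc = )` in chilling units.
#' @export
window_chill <- function(reference_winter, model,
                         t0 = NULL, t_low = NULL, t_high = NULL) {
  stopifnot(inherits(reference_winter, "hourly_series"))
  y <- year_of(reference_winter$start)
  if (is.null(t0)) t0 <- as.Date(sprintf("%d-11-01", y))
  if (is.null(t_low)) t_low <- as.Date(sprintf("%d-12-21", y))
  if (is.null(t_high)) t_high <- as.Date(sprintf("%d-02-28", y + 1L))
  lowc <- accumulate_chill(reference_winter, model, accum_window(t0, t_low))
  highc <- accumulate_chill(reference_winter, model, accum_window(t0, t_high))
  c(lowc = lowc, highc = highc)
}

#' Chilling sensitivity and basic forcing requirement
#'
#' Chilling sensitivity (CS) is the ratio of a species' forcing requirement
#' under the low chilling condition to that under the high chilling
#' condition, `CS = FR(lowc) / FR(highc)`, both evaluated on the fitted
#' exponential curve. `FR(highc)` is the basic FR: the species' intrinsic
#' heat demand once chilling is ample. CS close to 1 marks a species whose
#' heat demand barely depends on chilling; large CS marks strong reliance on
#' chilling to lower the forcing requirement.
#'
#' @param fit a `ca_fr_fit` for the species.
#' @param lowc,highc chilling accumulations of the low and high condition
#'   (`lowc <= highc`), e.g. from [window_chill()].
#' @param species optional species id carried into the result.
#' @return A one-row data frame `species, lowc, highc, fr_low, fr_high, cs`.
#' @examples
#' fit <- list(a = 2000, b = 4000, c = 0.002)
#' chilling_sensitivity(fit, lowc = 720, highc = 2160)
#' @export
chilling_sensitivity <- function(fit, lowc, highc, species = NA_character_) {
  if (lowc > highc) stop("lowc must not exceed highc", call. = FALSE)
  fr_low <- predict_fr(fit, lowc)
  fr_high <- predict_fr(fit, highc)
  if (fr_high <= 0)
    stop("invalid fit: FR(highc) <= 0", call. = FALSE)
  data.frame(species = species, lowc = lowc, highc = highc,
             fr_low = fr_low, fr_high = fr_high, cs = fr_low / fr_high)
}
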