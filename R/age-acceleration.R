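#' Fit the reference-group clock-versus-age regression
#'
#' Ordinary least squares of clock value on chronological age (gestational
#' age plus age at blood collection, in days), fitted over the designated
#' reference group only (the non-DS newborns). The fitted line anchors the
#' age-acceleration residuals of the whole cohort.
#'
#' @param clock A `clock_values` object or named numeric vector of clock
#'   outputs.
#' @param chron_age_days Per-sample chronological age in days (may contain
#'   `NA`; such samples are excluded from the fit).
#' @param reference_mask Logical vector marking the reference (non-DS)
#'   samples.
#' @param fit_group Label recorded on the result.
#' @return An object of class `reference_line`: `intercept` (clock units),
#'   `slope` (clock units per day), `fit_group`, `n_fit`, `r_squared`.
#' @export
fit_reference_line <- function(clock, chron_age_days, reference_mask,
                               fit_group = "non-DS") {
  values <- if (inherits(clock, "clock_values")) clock$values else clock
  keep <- reference_mask & !is.na(chron_age_days) & !is.na(values)
  if (sum(keep) < 3L)
    stop_neoclocks("need >= 3 reference samples with complete age; got ",
                   sum(keep))
  x <- chron_age_days[keep]
  if (sd(x) == 0) stop_neoclocks("degenerate fit: constant chronological age")
  fit <- lm(values[keep] ~ x)
  structure(list(intercept = unname(coef(fit)[1L]),
                 slope = unname(coef(fit)[2L]),
                 fit_group = fit_group, n_fit = sum(keep),
                 r_squared = summary(fit)$r.squared,
                 clock_name = if (inherits(clock, "clock_values"))
                   clock$clock_name else NA_character_),
            class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("reference_line (%s, n = %d): clock = %.4g + %.4g * age_days (R^2 = %.3f)\n",
              x$fit_group, x$n_fit, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Epigenetic age acceleration anchored on the reference line
#'
#' For every sample (both groups), the age acceleration is the residual
#' `clock_i - (intercept + slope * age_i)` from the reference-group line.
#' By construction the reference-group mean residual is zero. Samples with
#' missing chronological age are excluded, with the count recorded.
#'
#' @inheritParams fit_reference_line
#' @param line A [fit_reference_line()] result fitted on the reference
#'   subset of the same cohort.
#' @return An object of class `dnamaa`: `values` (named residuals, excluded
#'   samples absent), `n_excluded`, `clock_name`, `anchor`.
#' @export
compute_dnamaa <- function(clock, chron_age_days, line) {
  values <- if (inherits(clock, "clock_values")) clock$values else clock
  keep <- !is.na(chron_age_days) & !is.na(values)
  res <- values[keep] - (line$intercept + line$slope * chron_age_days[keep])
  structure(list(values = res, n_excluded = sum(!keep),
                 clock_name = if (inherits(clock, "clock_values"))
                   clock$clock_name else NA_character_,
                 anchor = "nonDS-chronological"),
            class = "dnamaa")
}

#' @export
print.dnamaa <- function(x, ...) {
  cat(sprintf("dnamaa '%s' (anchor %s): n = %d (%d excluded), mean = %.4g\n",
              x$clock_name, x$anchor, length(x$values), x$n_excluded,
              mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.dnamaa <- function(x, ...) {
  data.frame(sample_id = names(x$values), clock_name = x$clock_name,
             dnamaa = unname(x$values), anchor = x$anchor,
             stringsAsFactors = FALSE)
}

#' Convert a clock-scale effect estimate to days of age acceleration
#'
#' Divides an effect estimate (or confidence bound) expressed in clock
#' units by the reference-line slope in clock units per day. With the
#' conventionally reported slope of 0.001 per day, an estimate of 0.2442
#' corresponds to 244.2 days of acceleration.
#'
#' @param estimate Effect estimate(s) in clock units.
#' @param slope Reference slope, clock units per day; must be positive.
#' @return Days of age acceleration.
#' @export
estimate_to_days <- function(estimate, slope) {
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0)
    stop_neoclocks("'slope' must be a single positive number")
  estimate / slope
}

#' Gestational age acceleration (residuals adjusted for DS status)
#'
#' For gestational age clocks the acceleration is defined differently from
#' the chronological-age clocks: it is the residual from the linear model of
#' the clock on observed gestational age with DS status as a covariate,
#' fitted over all samples.
#'
#' @param clock A `clock_values` object or named numeric vector (days).
#' @param obs_ga_days Observed gestational age in days.
#' @param ds_status Logical DS indicator.
#' @return An object of class `dnamaa` with anchor `"GA-adjusted-DS"`.
#' @export
gestational_dnamaa <- function(clock, obs_ga_days, ds_status) {
  values <- if (inherits(clock, "clock_values")) clock$values else clock
  keep <- !is.na(obs_ga_days) & !is.na(values) & !is.na(ds_status)
  if (sum(keep) < 3L)
    stop_neoclocks("need >= 3 samples with complete gestational age")
  fit <- lm(values[keep] ~ obs_ga_days[keep] + ds_status[keep])
  res <- residuals(fit)
  names(res) <- names(values)[keep]
  structure(list(values = res, n_excluded = sum(!keep),
                 clock_name = if (inherits(clock, "clock_values"))
                   clock$clock_name else NA_character_,
                 anchor = "GA-adjusted-DS"),
            class = "dnamaa")
}
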