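#' Interval mortality rates from uncensored death ages
#'
#' Partitions age into half-open intervals `[origin + k*width,
#' origin + (k+1)*width)` and computes, per interval, the number of deaths
#' and the mouse-days lived by all animals alive at the interval start
#' (each contributes `min(death age, interval end) - interval start`).
#' The mortality rate is deaths per mouse-day - an occurrence/exposure
#' estimate of the average hazard over the interval - and is also reported
#' on the conventional "per 10,000 mouse-days" scale. If exactly one
#' animal dies in the last interval containing any death, that interval is
#' flagged `excluded` (a single terminal death gives an unstable rate) and
#' is skipped by [aging_rates_from_mortality()].
#'
#' Person-time is conserved exactly: the `mouse_days` column sums to the
#' total of all death ages (minus the origin), and `deaths` sums to the
#' cohort size.
#'
#' @param ages uncensored death ages in days, all greater than `origin`.
#' @param width interval width in days (default 200).
#' @param origin age at which the first interval starts (default 0).
#' @return A data frame of class `mortality_table` with columns
#'   `interval_start`, `interval_end`, `deaths`, `mouse_days`,
#'   `mortality_rate` (per mouse-day; `NA` when no exposure),
#'   `rate_per_10k` and `excluded`.
#' @examples
#' tab <- interval_mortality_rates(c(100, 150, rep(250, 8)), width = 200)
#' tab$mouse_days[1]  # 100 + 150 + 8 * 200 = 1850
#' @export
interval_mortality_rates <- function(ages, width = 200, origin = 0) {
  if (length(ages) == 0L) stop_validation("empty age vector")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop_validation("'width' must be a single value > 0")
  if (any(!is.finite(ages)) || any(ages <= origin))
    stop_validation("all ages must be finite and greater than 'origin'")

  kmax <- floor((max(ages) - origin) / width)
  k <- 0:kmax
  start <- origin + k * width
  end <- start + width
  deaths <- vapply(k, function(kk)
    sum(ages >= origin + kk * width & ages < origin + (kk + 1) * width), 0L)
  mouse_days <- vapply(seq_along(k), function(i)
    sum(pmax(0, pmin(ages, end[i]) - start[i])), 0)
  rate <- ifelse(mouse_days > 0, deaths / mouse_days, NA_real_)

  excluded <- rep(FALSE, length(k))
  with_deaths <- which(deaths > 0L)
  last <- with_deaths[length(with_deaths)]
  if (deaths[last] == 1L) excluded[last] <- TRUE

  out <- data.frame(interval_start = start, interval_end = end,
                    deaths = deaths, mouse_days = mouse_days,
                    mortality_rate = rate,
                    rate_per_10k = 1e4 * rate,
                    excluded = excluded)
  class(out) <- c("mortality_table", "data.frame")
  attr(out, "width") <- width
  attr(out, "origin") <- origin
  attr(out, "n") <- length(ages)
  out
}

#' Aging rates from an interval mortality table
#'
#' The aging rate between two usable consecutive intervals is the change
#' in interval mortality rate divided by the age distance between the
#' interval midpoints - a finite-difference estimate of the hazard slope.
#' Usable intervals are those not flagged `excluded` and with positive
#' exposure. The default follows the absolute-difference convention;
#' `signed = TRUE` keeps the sign so that declines in mortality are
#' distinguishable from rises. Rates are reported on the "deaths per
#' 10,000 mice per day" scale (the change per day of a mortality rate
#' expressed per 10,000 mouse-days); the abscissa `age` is the centre
#' between the two interval midpoints, i.e. their shared boundary for
#' adjacent intervals.
#'
#' @param table a `mortality_table` from [interval_mortality_rates()].
#' @param signed keep the sign of the rate change? Default `FALSE`
#'   (absolute differences).
#' @return A data frame of class `aging_rate_series` with columns `age`
#'   (days) and `rate_per_10k`.
#' @examples
#' tab <- interval_mortality_rates(simulate_gompertz_makeham(
#'   gompertz_params(2e-5, 0.008), 2000, seed = 1))
#' aging_rates_from_mortality(tab)
#' @export
aging_rates_from_mortality <- function(table, signed = FALSE) {
  stopifnot(inherits(table, "mortality_table"))
  usable <- !table$excluded & table$mouse_days > 0
  tb <- table[usable, , drop = FALSE]
  if (nrow(tb) < 2L)
    stop_validation("need at least 2 usable intervals to form aging rates")
  mid <- (tb$interval_start + tb$interval_end) / 2
  i <- seq_len(nrow(tb) - 1L)
  dm <- tb$mortality_rate[i + 1L] - tb$mortality_rate[i]
  dage <- mid[i + 1L] - mid[i]
  rate <- dm / dage
  if (!signed) rate <- abs(rate)
  out <- data.frame(age = (mid[i] + mid[i + 1L]) / 2,
                    rate_per_10k = 1e4 * rate)
  class(out) <- c("aging_rate_series", "data.frame")
  attr(out, "signed") <- signed
  out
}

#' Plot an aging-rate series
#'
#' @param x an `aging_rate_series`.
#' @param xlab,ylab,type,... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.aging_rate_series <- function(x, xlab = "Age (days)",
                                   ylab = "Aging rate (deaths per 10,000 mice per day)",
                                   type = "b", ...) {
  graphics::plot(x$age, x$rate_per_10k, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}
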