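#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of a lifespan sample by the
#' product-limit formula
#' \deqn{\hat S(t) = \prod_{t_i \le t} \left(1 - \frac{d_i}{n_i}\right),}
#' over the distinct death times \eqn{t_i}, with \eqn{d_i} deaths and
#' \eqn{n_i} animals at risk (alive just before \eqn{t_i}; animals
#' censored at \eqn{t_i} are still counted at risk there). With no
#' censoring the estimate equals the empirical survival function and drops
#' to zero at the last death.
#'
#' @param time positive ages at death or censoring, in days.
#' @param event logical death indicator (default: all deaths).
#' @return An object of class `survival_curve` with components `time`
#'   (distinct death times), `surv`, `n_risk`, `n_event`, plus the sample
#'   size `n` and the number censored.
#' @examples
#' km <- km_estimate(c(2, 4, 4, 6))
#' km$surv  # 0.75, 0.25, 0
#' median_lifespan(km)
#' @export
km_estimate <- function(time, event = rep(TRUE, length(time))) {
  if (length(time) == 0L) stop_validation("empty lifespan vector")
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
    stop_validation("ages must be positive and finite")
  event <- as.logical(event)
  if (length(event) != length(time) || anyNA(event))
    stop_validation("'event' must be logical and match 'time' in length")

  if (!any(event)) {
    warning("all observations censored; survival curve is constant at 1")
    out <- list(time = numeric(0), surv = numeric(0),
                n_risk = integer(0), n_event = integer(0),
                n = length(time), n_censored = length(time))
    class(out) <- "survival_curve"
    return(out)
  }

  dt <- sort(unique(time[event]))
  n_risk  <- vapply(dt, function(t) sum(time >= t), 0L)
  n_event <- vapply(dt, function(t) sum(time == t & event), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  out <- list(time = dt, surv = surv, n_risk = n_risk, n_event = n_event,
              n = length(time), n_censored = sum(!event))
  class(out) <- "survival_curve"
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d animals, %d deaths, %d censored\n",
              x$n, sum(x$n_event), x$n_censored))
  df <- data.frame(time = x$time, n_risk = x$n_risk,
                   n_event = x$n_event, surv = round(x$surv, 4))
  print(utils::head(df, 10L), row.names = FALSE)
  if (length(x$time) > 10L)
    cat(sprintf("  ... and %d more death times\n", length(x$time) - 10L))
  invisible(x)
}

#' Plot a survival curve
#'
#' Draws the step-function survival estimate starting at S(0) = 1.
#'
#' @param x a `survival_curve`.
#' @param xlab,ylab,... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.survival_curve <- function(x, xlab = "Age (days)",
                                ylab = "Survival probability", ...) {
  graphics::plot(c(0, x$time), c(1, x$surv), type = "s",
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Median lifespan of a survival curve
#'
#' The median lifespan is the smallest death time at which the estimated
#' survival falls to 0.5 or below (the standard Kaplan-Meier median
#' convention; ties at exactly 0.5 resolve to the first such time). With
#' uncensored data this equals the sample median under the same
#' convention. Numeric vectors are accepted and converted through
#' [km_estimate()] first.
#'
#' @param x a `survival_curve` or a numeric vector of uncensored death
#'   ages.
#' @param ... unused.
#' @return The median lifespan in days.
#' @export
median_lifespan <- function(x, ...) UseMethod("median_lifespan")

#' @rdname median_lifespan
#' @export
median_lifespan.survival_curve <- function(x, ...) {
  # small tolerance: cumulative products representing exact halves can sit
  # one ulp above 0.5
  i <- which(x$surv <= 0.5 + 1e-9)
  if (length(i) == 0L) {
    stop(errorCondition("survival curve never reaches 0.5; median undefined",
                        class = c("lifespanr_undefined_median",
                                  "lifespanr_error")))
  }
  x$time[i[1L]]
}

#' @rdname median_lifespan
#' @export
median_lifespan.numeric <- function(x, ...) {
  median_lifespan(km_estimate(x), ...)
}

#' Lifespan change between two group summaries
#'
#' Expresses the difference between a reference and a comparison summary
#' age (typically group median lifespans) in days and as a percentage of
#' the reference: \eqn{100 (ref - comp)/ref}. Positive values mean the
#' comparison group is shorter-lived. The print method rounds to whole
#' days and whole percent, matching how longevity studies usually report
#' these numbers; the stored fields are unrounded.
#'
#' @param reference reference summary age in days (> 0).
#' @param comparison comparison summary age in days.
#' @return An object of class `percent_change` with fields `days` and
#'   `percent`.
#' @examples
#' percent_change(1004, 839)  # 165 days (16%)
#' @export
percent_change <- function(reference, comparison) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop_validation("'reference' must be a single value > 0")
  if (!is.numeric(comparison) || length(comparison) != 1L)
    stop_validation("'comparison' must be a single numeric value")
  structure(list(days = reference - comparison,
                 percent = 100 * (reference - comparison) / reference,
                 reference = reference, comparison = comparison),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, ...) {
  cat(sprintf("Lifespan change: %d days (%d%%) relative to reference %g days\n",
              round(x$days), round(x$percent), x$reference))
  invisible(x)
}
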