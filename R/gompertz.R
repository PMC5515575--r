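#' Gompertz-Makeham mortality parameters
#'
#' The Gompertz-Makeham law models the death hazard of an aging cohort as
#' \deqn{h(t) = a e^{b t} + c,}
#' where `a` (> 0) is the age-dependent hazard at age 0 in deaths per
#' mouse-day, `b` (>= 0, per day) is the exponential slope with which
#' mortality accelerates with age, and `c` (>= 0, per day) is the Makeham
#' age-independent background hazard. With `b = c = 0` the law reduces to
#' an exponential lifespan distribution with rate `a`.
#'
#' @param a baseline age-dependent hazard at age 0 (deaths/mouse-day, > 0).
#' @param b hazard log-slope (per day, >= 0).
#' @param c Makeham age-independent hazard (per day, >= 0).
#' @return An object of class `gompertz_params`.
#' @examples
#' gompertz_params(a = 2e-5, b = 0.008)
#' @export
gompertz_params <- function(a, b = 0, c = 0) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop_validation("'a' must be a single finite value > 0")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop_validation("'b' must be a single finite value >= 0")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop_validation("'c' must be a single finite value >= 0")
  structure(list(a = a, b = b, c = c), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham hazard: h(t) = %g * exp(%g t) + %g  [per day]\n",
              x$a, x$b, x$c))
  cat(sprintf("  median lifespan: %.1f days\n", theoretical_median(x)))
  invisible(x)
}

# Cumulative hazard H(t) = (a/b)(e^{bt} - 1) + c t  (a t + c t when b = 0).
gompertz_cumhaz <- function(t, params) {
  with(params, if (b == 0) (a + c) * t else (a / b) * expm1(b * t) + c * t)
}

#' Gompertz-Makeham survival and hazard functions
#'
#' `gompertz_survival()` evaluates
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt}-1) - c t\}}; `gompertz_hazard()`
#' evaluates \eqn{h(t) = a e^{bt} + c}.
#'
#' @param t vector of ages in days (>= 0).
#' @param params a [gompertz_params] object.
#' @return Numeric vector of survival probabilities or hazards.
#' @export
gompertz_survival <- function(t, params) {
  stopifnot(inherits(params, "gompertz_params"))
  exp(-gompertz_cumhaz(t, params))
}

#' @rdname gompertz_survival
#' @export
gompertz_hazard <- function(t, params) {
  stopifnot(inherits(params, "gompertz_params"))
  with(params, a * exp(b * t) + c)
}

#' Simulate lifespans from a Gompertz-Makeham law
#'
#' Draws `n` i.i.d. lifespans by inverting the survival function
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt}-1) - c t\}} at uniform deviates
#' (inverse-CDF sampling). Closed-form inversion is used when `c = 0` or
#' `b = 0`; otherwise the cumulative hazard is inverted by a safeguarded
#' Newton iteration started from the upper bound `H^{-1}` of the
#' exponential envelope, which converges monotonically because the
#' cumulative hazard is convex. Output is bit-reproducible for a fixed
#' seed.
#'
#' @param params a [gompertz_params] object.
#' @param n number of lifespans to draw (>= 1).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return Numeric vector of `n` lifespans in days.
#' @examples
#' x <- simulate_gompertz_makeham(gompertz_params(2e-5, 0.008), 1000, seed = 1)
#' median(x)
#' theoretical_median(gompertz_params(2e-5, 0.008))
#' @export
simulate_gompertz_makeham <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop_validation("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::runif(n)
  target <- -log(u)  # solve H(t) = -log(U)
  a <- params$a; b <- params$b; c <- params$c
  if (b == 0) return(target / (a + c))
  if (c == 0) return(log1p(b * target / a) / b)
  # Newton from above: H is convex, so iterates decrease monotonically to
  # the root; start at the exponential-envelope bound H(t) >= (a + c) t.
  t <- target / (a + c)
  for (i in 1:100) {
    f <- gompertz_cumhaz(t, params) - target
    step <- f / (a * exp(b * t) + c)
    t <- t - step
    if (max(abs(step)) < 1e-12 * (1 + max(t))) break
  }
  t
}

#' Median lifespan implied by Gompertz-Makeham parameters
#'
#' For a pure Gompertz law (`c = 0`, `b > 0`) the age at which survival
#' reaches one half has the closed form
#' \deqn{t_{50} = \frac{1}{b}\log\!\left(1 + \frac{b}{a}\log 2\right).}
#' With a Makeham term the defining equation \eqn{S(t) = 1/2} is solved
#' numerically; with `b = 0` the exponential median \eqn{\log 2/(a+c)} is
#' returned.
#'
#' @param params a [gompertz_params] object.
#' @return The median lifespan in days.
#' @export
theoretical_median <- function(params) {
  stopifnot(inherits(params, "gompertz_params"))
  a <- params$a; b <- params$b; c <- params$c
  if (b == 0) return(log(2) / (a + c))
  if (c == 0) return(log1p(b * log(2) / a) / b)
  # numeric inversion of H(t) = log 2; expand the bracket until it covers
  upper <- log(2) / (a + c)
  while (gompertz_cumhaz(upper, params) < log(2)) {
    upper <- upper * 2
    if (!is.finite(upper)) {
      stop(errorCondition("survival never reaches 0.5",
                          class = c("lifespanr_undefined_median",
                                    "lifespanr_error")))
    }
  }
  stats::uniroot(function(t) gompertz_cumhaz(t, params) - log(2),
                 c(0, upper), tol = 1e-10)$root
}

#' Calibrate the Gompertz intercept to a target median lifespan
#'
#' Solves \eqn{S(m) = 1/2} for `a` given the slope `b` and Makeham term
#' `c`, i.e. \eqn{a = b(\log 2 - c\,m)/(e^{bm} - 1)}. Used to build
#' simulation scenarios whose group medians match printed study medians.
#'
#' @param median_days target median lifespan in days (> 0).
#' @param b hazard log-slope (per day, > 0).
#' @param c Makeham age-independent hazard (per day, >= 0); must be small
#'   enough that a positive `a` can reach the target median.
#' @return A [gompertz_params] object with the requested median.
#' @examples
#' p <- gompertz_from_median(1004, b = 0.008)
#' theoretical_median(p)
#' @export
gompertz_from_median <- function(median_days, b, c = 0) {
  if (!is.numeric(median_days) || length(median_days) != 1L || median_days <= 0)
    stop_validation("'median_days' must be a single value > 0")
  if (b <= 0) stop_validation("'b' must be > 0 to calibrate an intercept")
  a <- b * (log(2) - c * median_days) / expm1(b * median_days)
  if (a <= 0) {
    stop_validation(
      "Makeham term alone exceeds the target median; reduce 'c'")
  }
  gompertz_params(a = a, b = b, c = c)
}

#' Apply a proportional-hazards multiplier
#'
#' Multiplies the whole hazard (both `a` and `c`) by `hr`, so that the new
#' law is exactly proportional to the old one: convenient for building
#' treatment cells with a known true hazard ratio.
#'
#' @param params a [gompertz_params] object.
#' @param hr hazard ratio (> 0).
#' @return A [gompertz_params] object with hazard `hr * h(t)`.
#' @export
scale_hazard <- function(params, hr) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop_validation("'hr' must be a single finite value > 0")
  gompertz_params(a = params$a * hr, b = params$b, c = params$c * hr)
}
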