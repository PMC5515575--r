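#' Two-sample log-rank test
#'
#' Compares the survival experience of two groups by the log-rank
#' (Mantel-Cox) test. At each distinct death time with \eqn{d} total
#' deaths among \eqn{n} animals at risk (\eqn{n_a} of them in group A),
#' the test accumulates the observed group-A deaths \eqn{O_a}, their
#' conditional expectation \eqn{E_a = d\,n_a/n}, and the hypergeometric
#' variance
#' \deqn{V = d \frac{n_a}{n}\left(1 - \frac{n_a}{n}\right)\frac{n - d}{n - 1},}
#' (defined as 0 when \eqn{n = 1}). The statistic
#' \eqn{(O_a - E_a)^2 / \sum V} is referred to a chi-square distribution
#' with one degree of freedom. The statistic is symmetric in the group
#' labels and invariant under strictly monotone transformations of age.
#'
#' @param time_a,time_b ages at death or censoring for the two groups.
#' @param event_a,event_b logical death indicators (default: no
#'   censoring).
#' @return An object of class `logrank_test` with components `statistic`,
#'   `p.value`, and per-group `observed`, `expected` and the pooled
#'   `variance`.
#' @examples
#' lr <- logrank_test(c(1, 2), c(3, 4))
#' lr$statistic  # about 2.88
#' @export
logrank_test <- function(time_a, time_b,
                         event_a = rep(TRUE, length(time_a)),
                         event_b = rep(TRUE, length(time_b))) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop_validation("both groups must be non-empty")
  if (any(!is.finite(c(time_a, time_b))) || any(c(time_a, time_b) <= 0))
    stop_validation("ages must be positive and finite")
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)

  time  <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a  <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))

  death_times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in death_times) {
    at_risk <- time >= t
    n  <- sum(at_risk)
    na <- sum(at_risk & in_a)
    d  <- sum(time == t & event)
    da <- sum(time == t & event & in_a)
    O <- O + da
    E <- E + d * na / n
    if (n > 1L)
      V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }

  if (V == 0) {
    warning("log-rank variance is zero; test is degenerate (p = 1)")
    statistic <- 0
    p <- 1
  } else {
    statistic <- (O - E)^2 / V
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  total_deaths <- sum(event)
  out <- list(statistic = statistic, df = 1L, p.value = p,
              observed = c(a = O, b = total_deaths - O),
              expected = c(a = E, b = total_deaths - E),
              variance = V,
              n = c(a = length(time_a), b = length(time_b)))
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-sample log-rank test\n")
  cat(sprintf("  n = %d vs %d; observed deaths %g vs %g (expected %.2f vs %.2f)\n",
              x$n[["a"]], x$n[["b"]], x$observed[["a"]], x$observed[["b"]],
              x$expected[["a"]], x$expected[["b"]]))
  cat(sprintf("  chi-square = %.4f on 1 df, p = %.4g\n",
              x$statistic, x$p.value))
  invisible(x)
}
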