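#' Cox proportional-hazards model for lifespan data
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with
#' step-halving. Tied death times are handled by the Efron approximation
#' by default (less biased than Breslow when rounded-day records produce
#' many ties); Breslow is available for cross-checks. Standard errors come
#' from the inverse of the observed information at the maximum.
#'
#' Newton iterations stop when the score's sup-norm falls below `tol` or
#' after `max_iter` iterations. A monotone partial likelihood (a covariate
#' that perfectly separates the order of deaths) makes the coefficient
#' diverge; this is detected and reported with `converged = FALSE` and a
#' warning rather than an error.
#'
#' @param x covariate vector or matrix (one row per animal); must contain
#'   no missing values and at least two distinct covariate patterns among
#'   the deaths.
#' @param time positive ages at death or censoring, in days.
#' @param event logical death indicator (default: no censoring).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the score sup-norm.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `cox_fit` with components `coefficients`
#'   (log hazard ratios), `hazard_ratios`, `se`, `loglik` (null and
#'   maximised partial log-likelihood), `score` (score vector at the
#'   solution), `converged` and `n_iter`.
#' @examples
#' co <- build_study_cohort(paper_like_design("week1", seed = 1))
#' dw <- co[co$genotype == "dwarf", ]
#' fit <- cox_ph_fit(as.numeric(dw$treatment == "GH"), dw$age_days, dw$event)
#' fit$hazard_ratios
#' @export
cox_ph_fit <- function(x, time, event = rep(TRUE, length(time)),
                       ties = c("efron", "breslow"),
                       tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  if (anyNA(X)) stop_validation("covariates contain missing values")
  if (length(time) != nrow(X))
    stop_validation("'time' and covariate rows must match in length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop_validation("ages must be positive and finite")
  event <- as.logical(event)
  constant <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant))
    stop_validation(sprintf("covariate '%s' is constant: no contrast to fit",
                            paste(colnames(X)[constant], collapse = ", ")))
  patterns <- unique(X[event, , drop = FALSE])
  if (nrow(patterns) < 2L)
    stop_validation("fewer than 2 distinct covariate patterns among deaths")

  p <- ncol(X)
  beta <- rep(0, p)
  terms <- cox_partial_terms(beta, X, time, event, ties)
  loglik_null <- terms$loglik
  converged <- FALSE
  n_iter <- 0L
  diverged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    if (max(abs(terms$U)) < tol) { converged <- TRUE; break }
    delta <- solve(terms$I, terms$U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_terms <- cox_partial_terms(cand, X, time, event, ties)
      # accept any step that does not decrease the likelihood beyond
      # floating-point resolution; near the optimum the true gain per step
      # is far below the representable precision of the log-likelihood
      if (is.finite(cand_terms$loglik) &&
          cand_terms$loglik >= terms$loglik -
            1e-9 * (1 + abs(terms$loglik))) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    terms <- cand_terms
    if (max(abs(beta)) > 20) { diverged <- TRUE; break }
  }
  if (!converged && max(abs(terms$U)) < tol) converged <- TRUE
  if (diverged) {
    warning("monotone partial likelihood: coefficient diverging, fit not converged")
  } else if (!converged) {
    warning("Newton iterations did not converge within 'max_iter'")
  }

  vcov <- tryCatch(solve(terms$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  out <- list(coefficients = beta,
              hazard_ratios = exp(beta),
              se = se,
              vcov = vcov,
              loglik = c(null = loglik_null, max = terms$loglik),
              score = terms$U,
              info = terms$I,
              converged = converged && !diverged,
              n_iter = n_iter,
              ties = ties,
              n = nrow(X),
              n_event = sum(event))
  class(out) <- "cox_fit"
  out
}

# Partial log-likelihood, score vector and observed information at beta.
# Rows are processed in decreasing time order so the risk set at each death
# time is a prefix, and risk-set moments come from running cumulative sums.
cox_partial_terms <- function(beta, X, time, event, ties) {
  p <- ncol(X)
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; ee <- event[ord]
  Xs <- X[ord, , drop = FALSE]
  eta <- drop(Xs %*% beta)
  w <- exp(eta)

  cw  <- cumsum(w)
  cwx <- apply(Xs * w, 2L, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  cwxx <- array(0, dim = c(nrow(Xs), p, p))
  for (j in seq_len(p)) for (k in j:p) {
    cs <- cumsum(w * Xs[, j] * Xs[, k])
    cwxx[, j, k] <- cs
    cwxx[, k, j] <- cs
  }

  loglik <- 0
  U <- rep(0, p)
  I <- matrix(0, p, p)
  ends <- cumsum(rle(tt)$lengths)  # last index of each tie group (descending)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (g in seq_along(ends)) {
    rows <- starts[g]:ends[g]
    D <- rows[ee[rows]]
    d <- length(D)
    if (d == 0L) next
    s0 <- cw[ends[g]]
    s1 <- cwx[ends[g], ]
    s2 <- cwxx[ends[g], , ]
    loglik <- loglik + sum(eta[D])
    U <- U + colSums(Xs[D, , drop = FALSE])
    if (ties == "efron" && d > 1L) {
      s0d <- sum(w[D])
      s1d <- colSums(Xs[D, , drop = FALSE] * w[D])
      s2d <- crossprod(Xs[D, , drop = FALSE] * sqrt(w[D]))
      for (l in 0:(d - 1L)) {
        f <- l / d
        z0 <- s0 - f * s0d
        z1 <- s1 - f * s1d
        z2 <- s2 - f * s2d
        loglik <- loglik - log(z0)
        U <- U - z1 / z0
        I <- I + z2 / z0 - tcrossprod(z1) / z0^2
      }
    } else {
      loglik <- loglik - d * log(s0)
      U <- U - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1) / s0^2)
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d animals, %d deaths\n",
              x$ties, x$n, x$n_event))
  z <- x$coefficients / x$se
  tab <- data.frame(coef = x$coefficients,
                    `exp(coef)` = x$hazard_ratios,
                    se = x$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  partial log-likelihood %.4f (null %.4f), %d iterations%s\n",
              x$loglik[["max"]], x$loglik[["null"]], x$n_iter,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Cox score test at the null
#'
#' Computes the score (Rao) test of `beta = 0` for a Cox model:
#' \eqn{U(0)^\top I(0)^{-1} U(0)}, referred to chi-square with as many
#' degrees of freedom as covariates. For a single binary covariate with no
#' tied deaths this statistic is identical to the log-rank chi-square.
#'
#' @inheritParams cox_ph_fit
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
cox_score_test <- function(x, time, event = rep(TRUE, length(time)),
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_validation("covariates contain missing values")
  event <- as.logical(event)
  terms <- cox_partial_terms(rep(0, ncol(X)), X, time, event, ties)
  statistic <- drop(crossprod(terms$U, solve(terms$I, terms$U)))
  list(statistic = statistic, df = ncol(X),
       p.value = stats::pchisq(statistic, df = ncol(X), lower.tail = FALSE))
}
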