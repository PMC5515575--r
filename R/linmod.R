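#' Linear lifespan model with sex-adjusted group means
#'
#' With fully uncensored lifespans, the association between treatment and
#' lifespan can also be tested by ordinary least squares on the ages at
#' death, optionally with sex as a covariate. The model is
#' `age_days ~ treatment` or `age_days ~ treatment + sex`, with `saline`
#' and `male` as reference levels. Adjusted group means are model
#' predictions at each treatment level averaged over the cohort's observed
#' sex distribution (g-computation); in a saturated one-factor model they
#' reduce exactly to the sample group means.
#'
#' @param cohort a [cohort]; all records must be uncensored
#'   (`event = TRUE`).
#' @param adjust_sex include sex as a covariate? Default `TRUE`.
#' @return An object of class `linear_lifespan_fit` with `coefficients`,
#'   `se`, `adjusted_means` (days, one per treatment level), and the
#'   underlying `stats::lm` fit in `$model`.
#' @examples
#' co <- build_study_cohort(paper_like_design("week1", seed = 1))
#' lifespan_linear_model(co[co$genotype == "dwarf", ])
#' @export
lifespan_linear_model <- function(cohort, adjust_sex = TRUE) {
  if (!inherits(cohort, "cohort")) cohort <- as_cohort(cohort)
  if (!all(cohort$event))
    stop_validation("linear lifespan models require uncensored lifespans")
  df <- data.frame(age_days  = cohort$age_days,
                   treatment = factor(cohort$treatment,
                                      levels = TREATMENTS[c(2L, 1L)]),
                   sex       = factor(cohort$sex, levels = SEXES))
  form <- if (adjust_sex) age_days ~ treatment + sex else age_days ~ treatment
  mm <- stats::model.matrix(form, data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop_validation(sprintf("rank-deficient design; collinear column(s): %s",
                            paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(form, data = df)
  coefs <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  levels_present <- levels(droplevels(df$treatment))
  adjusted <- vapply(levels(df$treatment), function(tr) {
    if (!(tr %in% levels_present)) return(NA_real_)
    nd <- df
    nd$treatment <- factor(tr, levels = levels(df$treatment))
    mean(stats::predict(fit, newdata = nd))
  }, 0)
  out <- list(coefficients = coefs, se = se,
              adjusted_means = adjusted,
              sigma = summary(fit)$sigma,
              df.residual = fit$df.residual,
              adjust_sex = adjust_sex,
              model = fit)
  class(out) <- "linear_lifespan_fit"
  out
}

#' @export
print.linear_lifespan_fit <- function(x, ...) {
  cat(sprintf("Linear lifespan model (age_days ~ treatment%s)\n",
              if (x$adjust_sex) " + sex" else ""))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    t = x$coefficients / x$se)
  tab$p <- 2 * stats::pt(-abs(tab$t), df = x$df.residual)
  print(round(tab, 4))
  cat("Adjusted mean lifespans (days):\n")
  print(round(x$adjusted_means, 1))
  invisible(x)
}
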