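#' Relative expression by the delta-delta-Ct method
#'
#' Computes qRT-PCR fold change from threshold cycles. Per condition the
#' gene Ct is normalised to the reference gene,
#' \eqn{\Delta Ct = Ct_{gene} - Ct_{ref}}, and the treatment effect is
#' \eqn{\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{normal}}.
#'
#' Two sign conventions are exposed. Under `convention = "paper"` (the
#' default) the fold change is \eqn{2^{\Delta\Delta Ct}}, the formula as
#' printed in some methods sections; note that it yields fold < 1 for
#' genes whose expression is higher in the treated condition (lower Ct).
#' Under `convention = "livak"` the widely used \eqn{2^{-\Delta\Delta Ct}}
#' is returned, which reports up-regulation as fold > 1. The two are exact
#' reciprocals; choose deliberately.
#'
#' @param gene_ct_treated,ref_ct_treated gene and reference-gene threshold
#'   cycles for the treated condition.
#' @param gene_ct_normal,ref_ct_normal the same for the normal (control)
#'   condition.
#' @param convention `"paper"` (2^ddCt) or `"livak"` (2^-ddCt).
#' @return Fold change (dimensionless), vectorised over inputs.
#' @examples
#' # treated dCt = 5, normal dCt = 7, ddCt = -2
#' ddct_fold_change(25, 20, 28, 21)                        # 0.25
#' ddct_fold_change(25, 20, 28, 21, convention = "livak")  # 4
#' @export
ddct_fold_change <- function(gene_ct_treated, ref_ct_treated,
                             gene_ct_normal, ref_ct_normal,
                             convention = c("paper", "livak")) {
  convention <- match.arg(convention)
  cts <- c(gene_ct_treated, ref_ct_treated, gene_ct_normal, ref_ct_normal)
  if (any(!is.finite(cts)))
    stop_validation("all Ct values must be finite")
  if (any(cts < 10 | cts > 40))
    warning("Ct values outside the typical 10-40 range")
  ddct <- (gene_ct_treated - ref_ct_treated) -
          (gene_ct_normal - ref_ct_normal)
  if (convention == "paper") 2^ddct else 2^(-ddct)
}

#' Respiratory quotient
#'
#' The respiratory quotient RQ = VCO2/VO2 is the dimensionless ratio of
#' carbon dioxide produced to oxygen consumed over the same period, in the
#' same volume units. Values near 1.0 indicate carbohydrate oxidation and
#' values near 0.7 fat oxidation.
#'
#' @param vco2 carbon dioxide production (volume per unit time, >= 0).
#' @param vo2 oxygen consumption (same units, > 0).
#' @return RQ, vectorised over inputs.
#' @examples
#' respiratory_quotient(0.7, 1.0)  # fat-oxidation end of the range
#' @export
respiratory_quotient <- function(vco2, vo2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0))
    stop_validation("'vo2' must be finite and > 0")
  if (any(!is.finite(vco2)) || any(vco2 < 0))
    stop_validation("'vco2' must be finite and >= 0")
  vco2 / vo2
}

#' Insulin-tolerance-test series as percent of baseline
#'
#' Normalises a blood-glucose time series to its baseline measurement:
#' each value is reported as `100 * g / g[baseline_index]`. The output is
#' invariant under multiplicative rescaling of the series (unit changes).
#'
#' @param glucose numeric vector of glucose measurements.
#' @param baseline_index index of the baseline (pre-injection) value,
#'   default the first element.
#' @return Percent-of-baseline series of the same length.
#' @examples
#' itt_percent_baseline(c(100, 50, 75))  # 100 50 75
#' @export
itt_percent_baseline <- function(glucose, baseline_index = 1L) {
  if (!is.numeric(glucose) || length(glucose) == 0L)
    stop_validation("'glucose' must be a non-empty numeric vector")
  if (baseline_index < 1L || baseline_index > length(glucose))
    stop_validation("'baseline_index' out of range")
  baseline <- glucose[baseline_index]
  if (!is.finite(baseline) || baseline <= 0)
    stop_validation("baseline glucose must be finite and > 0")
  100 * glucose / baseline
}
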