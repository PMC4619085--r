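## quant: the two scalar quantifications used to evaluate knockouts.

#' Relative expression from qPCR cycle thresholds
#'
#' Computes the housekeeping-normalized fold change of a sample relative to
#' a calibrator. With the standard sign convention (default) this is
#' `2^(-ddCt)` where
#' `ddCt = (ctTarget - ctHousekeeping) - (ccTarget - ccHousekeeping)`,
#' so one extra target cycle in the sample (less RNA) halves the value.
#' `asPrinted = TRUE` switches to the literal `2^(+dCt_sample - dCt_calibrator)`
#' convention, in which higher sample Ct yields a higher value; see the
#' vignette for why the standard convention is the default.
#'
#' @param ctTarget,ctHousekeeping Sample cycle thresholds (target and
#'   endogenous-control gene).
#' @param ccTarget,ccHousekeeping Calibrator cycle thresholds.
#' @param asPrinted Use the literal positive-exponent convention.
#' @return Fold change(s); 1 when sample and calibrator are identical.
#' @examples
#' relativeExpression(22, 18, 20, 18)  # ddCt = 2 -> 0.25
#' @export
relativeExpression <- function(ctTarget, ctHousekeeping, ccTarget,
                               ccHousekeeping, asPrinted = FALSE) {
  vals <- c(ctTarget, ctHousekeeping, ccTarget, ccHousekeeping)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Ct values must be finite and positive", call. = FALSE)
  ddct <- (ctTarget - ctHousekeeping) - (ccTarget - ccHousekeeping)
  if (asPrinted) 2^ddct else 2^(-ddct)
}

#' Flow-cytometry stain index
#'
#' Separation measure between a stained (positive) and background
#' population: `(meanPos - meanBg) / (2 * sdBg)`. Zero when the means are
#' equal; the sign follows the mean difference.
#'
#' @param meanPos,meanBg Fluorescence means of the positive and background
#'   populations.
#' @param sdBg Standard deviation of the background population (must be
#'   positive).
#' @return Stain index (unitless).
#' @examples
#' stainIndex(300, 100, 50)  # 2
#' @export
stainIndex <- function(meanPos, meanBg, sdBg) {
  if (any(!is.finite(c(meanPos, meanBg, sdBg))) || any(sdBg <= 0))
    stop("sdBg must be finite and positive", call. = FALSE)
  (meanPos - meanBg) / (2 * sdBg)
}
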