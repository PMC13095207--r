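# Signal detection theory with the loglinear (add 0.5 / add 1) correction.

#' Loglinear-corrected hit and false-alarm rates
#'
#' Applies the loglinear correction to raw counts so that rates never reach
#' 0 or 1: hr = (nHit + 0.5) / (nSignal + 1), far = (nFa + 0.5) /
#' (nNoise + 1). With zero trials of a class the corrected rate is the
#' uninformative 0.5. Vectorised over counts.
#'
#' @param nHit,nSignal hits and signal-trial counts.
#' @param nFa,nNoise false alarms and noise-trial counts.
#' @return list with numeric \code{hr} and \code{far}, strictly in (0, 1).
#' @export
loglinearRates <- function(nHit, nSignal, nFa, nNoise) {
  if (any(c(nHit, nSignal, nFa, nNoise) < 0)) stop("counts must be >= 0")
  if (any(nHit > nSignal) || any(nFa > nNoise))
    stop("hits/false alarms cannot exceed their trial counts")
  list(hr = (nHit + 0.5) / (nSignal + 1), far = (nFa + 0.5) / (nNoise + 1))
}

#' Sensitivity and criterion from corrected rates
#'
#' d' = z(HR) - z(FAR) and c = -(z(HR) + z(FAR)) / 2, with z the inverse
#' standard-normal CDF. Rates must already be strictly inside (0, 1) (apply
#' \code{\link{loglinearRates}} first). Vectorised.
#'
#' @param hr,far hit and false-alarm rates in (0, 1).
#' @return data.frame with columns \code{hr}, \code{far}, \code{dprime},
#'   \code{criterion}.
#' @export
dprimeCriterion <- function(hr, far) {
  if (any(hr <= 0 | hr >= 1 | far <= 0 | far >= 1))
    stop("rates must lie strictly in (0, 1); correct the counts first")
  zh <- stats::qnorm(hr)
  zf <- stats::qnorm(far)
  data.frame(hr = hr, far = far, dprime = zh - zf,
             criterion = -(zh + zf) / 2)
}

#' SDT metrics straight from a trial table
#'
#' Convenience wrapper: counts hits/false alarms from logical
#' \code{target_present} and \code{response} columns, applies the loglinear
#' correction, and returns d' and criterion.
#'
#' @param table trial table with \code{target_present} and \code{response}.
#' @return one-row data.frame as from \code{\link{dprimeCriterion}}.
#' @export
sdtFromTrials <- function(table) {
  sig <- table$target_present
  r <- loglinearRates(sum(sig & table$response), sum(sig),
                      sum(!sig & table$response), sum(!sig))
  dprimeCriterion(r$hr, r$far)
}
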