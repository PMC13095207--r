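# Circular statistics used by the coupling analysis: the V-test for a
# prespecified mean direction and circular differences/averages.

#' Circular V-test against a prespecified mean direction
#'
#' Tests whether angles are concentrated around \code{mu0} rather than
#' uniformly distributed: V = R * cos(thetaBar - mu0) with R the
#' unnormalised sample resultant length and thetaBar its angle;
#' u = V * sqrt(2 / n) is referred to the upper tail of the standard
#' normal. A vanishing resultant (undefined mean angle) yields V = 0,
#' p = 0.5.
#'
#' @param angles sample of angles in degrees (n >= 2).
#' @param mu0 hypothesised mean direction in degrees.
#' @return list with \code{V}, \code{u}, \code{p}, and the sample resultant
#'   \code{R} and mean angle \code{theta}.
#' @export
vTest <- function(angles, mu0) {
  n <- length(angles)
  if (n < 2L) stop("need at least two angles")
  z <- sum(exp(1i * angles * pi / 180))
  R <- Mod(z)
  if (R < .Machine$double.eps^0.5)
    return(list(V = 0, u = 0, p = 0.5, R = 0, theta = NA_real_))
  theta <- wrapAngle(Arg(z) * 180 / pi)
  V <- R * cos((theta - mu0) * pi / 180)
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE), R = R,
       theta = theta)
}

#' Circular mean difference of two matched angle series
#'
#' Per-index circular difference A - B (wrapped to (-180, 180]) followed by
#' a circular average; used for the frontal-occipital (AFz-Oz) and HR-FAR
#' phase-opposition tests, whose result feeds \code{\link{vTest}} against
#' 180 degrees.
#'
#' @param anglesA,anglesB matched angle vectors in degrees.
#' @return circular mean of the per-index differences, in [0, 360).
#' @export
phaseDifference <- function(anglesA, anglesB) {
  stopifnot(length(anglesA) == length(anglesB))
  d <- circDiff(anglesA, anglesB)
  circMean(d)
}

#' Upper-tail binomial replication probability
#'
#' Probability of observing at least \code{k} out of \code{n} individually
#' significant subjects when each is significant with probability
#' \code{alpha} under the null — the small-n replication test that treats
#' each subject as an independent replication.
#'
#' @param k number of significant subjects.
#' @param n number of subjects.
#' @param alpha per-subject false-positive rate (default 0.05).
#' @return P(X >= k | n, alpha).
#' @export
binomialReplication <- function(k, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (k < 0 || k > n) stop("k must lie in 0..n")
  stats::pbinom(k - 1, n, alpha, lower.tail = FALSE)
}
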