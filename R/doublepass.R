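# Double-pass response consistency: identical-stimulus pairs, phase
# optimality classification, and the both-optimal vs otherwise contrast.

#' Find surviving double-pass stimulus pairs
#'
#' Pairs trials that presented the identical stimulus (same
#' \code{stimulus_id}, pass 1 then pass 2) and both survived artifact
#' rejection. Unpaired trials are dropped.
#'
#' @param table trial table with \code{stimulus_id}, \code{pass_index} and
#'   \code{response} columns.
#' @param kept optional indices of trials that survived rejection (rows of
#'   \code{table}); default all.
#' @return data.frame with one row per pair: \code{stimulus_id},
#'   \code{trial1}, \code{trial2} (row indices into \code{table}),
#'   \code{response1}, \code{response2}, \code{consistent},
#'   \code{target_present}.
#' @export
findPairs <- function(table, kept = seq_len(nrow(table))) {
  if (is.null(table$pass_index)) stop("table lacks a pass_index column")
  rows <- kept
  ids <- table$stimulus_id[rows]
  keep <- ids %in% names(which(table(ids) == 2L))
  rows <- rows[keep]
  rows <- rows[order(table$stimulus_id[rows], table$pass_index[rows])]
  t1 <- rows[seq(1L, length(rows), by = 2L)]
  t2 <- rows[seq(2L, length(rows), by = 2L)]
  data.frame(
    stimulus_id = table$stimulus_id[t1],
    trial1 = t1, trial2 = t2,
    response1 = table$response[t1], response2 = table$response[t2],
    consistent = table$response[t1] == table$response[t2],
    target_present = table$target_present[t1],
    stringsAsFactors = FALSE
  )
}

#' Classify a phase as optimal or suboptimal
#'
#' A trial's phase is optimal when it falls strictly within 90 degrees of
#' the resultant-vector angle at that time point and channel; the boundary
#' (exactly 90 degrees) counts as suboptimal.
#'
#' @param phase phase angle(s) in degrees.
#' @param resultantAngle optimal-phase angle(s) in degrees (recycled).
#' @return logical, TRUE where optimal.
#' @export
classifyOptimal <- function(phase, resultantAngle) {
  abs(circDiff(phase, resultantAngle)) < 90
}

#' Double-pass response consistency by phase condition
#'
#' For every time point and channel of the analysis grid, pairs are split
#' by whether both members occurred during the optimal phase (within 90
#' degrees of that cell's resultant angle) or otherwise (one or both
#' suboptimal); the proportion of response-consistent pairs is computed per
#' cell and condition, then averaged (unweighted) over channels and time.
#' Cells where a condition has no pairs are excluded from that condition's
#' average with a warning.
#'
#' @param pairs pair table from \code{\link{findPairs}}.
#' @param phase a \code{PhaseArray} (trial indices must match the trial
#'   table rows referenced by \code{pairs}).
#' @param thetaByChannel matrix [channel x time] of resultant angles on the
#'   same grid (e.g. from a \code{ResultantSeries}).
#' @param channels channel labels to use (default: rows of
#'   \code{thetaByChannel} matched against the PhaseArray channels).
#' @param window time window in seconds (default c(-0.450, 0)).
#' @param time time axis matching \code{thetaByChannel} columns; default
#'   the PhaseArray time axis restricted to \code{window}.
#' @return named numeric: \code{bothOptimal} and \code{otherwise}
#'   proportions.
#' @export
responseConsistency <- function(pairs, phase, thetaByChannel,
                                channels = NULL, window = c(-0.450, 0),
                                time = NULL) {
  stopifnot(methods::is(phase, "PhaseArray"))
  if (is.null(channels)) channels <- rownames(thetaByChannel)
  if (is.null(channels)) channels <- phase@channels[seq_len(nrow(thetaByChannel))]
  chIdx <- match(channels, phase@channels)
  if (anyNA(chIdx)) stop("missing channels in PhaseArray")
  if (is.null(time)) {
    keep <- phase@time >= window[1L] & phase@time <= window[2L]
    time <- phase@time[keep]
  } else {
    keep <- match(time, phase@time)
  }
  if (ncol(thetaByChannel) != length(time))
    stop("thetaByChannel columns must match the time grid")

  ph1 <- phase@phase[pairs$trial1, chIdx, keep, drop = FALSE]
  ph2 <- phase@phase[pairs$trial2, chIdx, keep, drop = FALSE]
  consist <- pairs$consistent

  accOpt <- accOth <- 0
  nOpt <- nOth <- 0L
  empty <- 0L
  for (j in seq_along(chIdx)) {
    for (s in seq_along(time)) {
      ang <- thetaByChannel[j, s]
      if (is.na(ang)) { empty <- empty + 1L; next }
      both <- classifyOptimal(ph1[, j, s], ang) &
              classifyOptimal(ph2[, j, s], ang)
      if (any(both)) {
        accOpt <- accOpt + mean(consist[both]); nOpt <- nOpt + 1L
      } else empty <- empty + 1L
      if (any(!both)) {
        accOth <- accOth + mean(consist[!both]); nOth <- nOth + 1L
      } else empty <- empty + 1L
    }
  }
  if (empty > 0L)
    warning(empty, " empty condition cell(s) excluded from the average")
  if (nOpt == 0L || nOth == 0L)
    stop("a condition has no pairs anywhere on the grid")
  c(bothOptimal = accOpt / nOpt, otherwise = accOth / nOth)
}

#' Paired comparison of consistency across subjects
#'
#' Two-tailed paired-samples t-test of both-optimal minus otherwise
#' consistency across subjects.
#'
#' @param bothOptimal,otherwise per-subject proportions (matched vectors,
#'   n >= 2).
#' @return list with \code{t}, \code{df}, \code{p}, \code{ci} (95 percent),
#'   \code{meanDiff}; a zero-variance difference raises a degenerate-test
#'   error.
#' @export
compareConsistency <- function(bothOptimal, otherwise) {
  stopifnot(length(bothOptimal) == length(otherwise),
            length(bothOptimal) >= 2L)
  d <- bothOptimal - otherwise
  if (stats::sd(d) == 0)
    stop("degenerate test: zero variance of condition differences")
  tt <- stats::t.test(bothOptimal, otherwise, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int), meanDiff = mean(d))
}
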