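#' Accessors for alphaSDT containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an alphaSDT S4 object.
#' @return The corresponding component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("phaseAngles", function(x) standardGeneric("phaseAngles"))
#' @rdname accessors
#' @export
setGeneric("envelope", function(x) standardGeneric("envelope"))
#' @rdname accessors
#' @export
setGeneric("resultantLength", function(x) standardGeneric("resultantLength"))
#' @rdname accessors
#' @export
setGeneric("resultantAngle", function(x) standardGeneric("resultantAngle"))
#' @rdname accessors
#' @export
setGeneric("permThreshold", function(x) standardGeneric("permThreshold"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("betaGrid", function(x) standardGeneric("betaGrid"))
#' @rdname accessors
#' @export
setGeneric("foldedGrid", function(x) standardGeneric("foldedGrid"))
#' @rdname accessors
#' @export
setGeneric("tuningFit", function(x) standardGeneric("tuningFit"))

#' @rdname accessors
setMethod("voltages", "EpochedSeries", function(x) x@voltages)
#' @rdname accessors
setMethod("timePoints", "EpochedSeries", function(x) x@time)
#' @rdname accessors
setMethod("channelLabels", "EpochedSeries", function(x) x@channels)
#' @rdname accessors
setMethod("samplingRate", "EpochedSeries", function(x) x@fs)

#' @rdname accessors
setMethod("timePoints", "PhaseArray", function(x) x@time)
#' @rdname accessors
setMethod("channelLabels", "PhaseArray", function(x) x@channels)
#' @rdname accessors
setMethod("samplingRate", "PhaseArray", function(x) x@fsOut)
#' @rdname accessors
setMethod("phaseAngles", "PhaseArray", function(x) x@phase)
#' @rdname accessors
setMethod("envelope", "PhaseArray", function(x) x@amplitude)

#' @rdname accessors
setMethod("timePoints", "ResultantSeries", function(x) x@time)
#' @rdname accessors
setMethod("channelLabels", "ResultantSeries", function(x) x@channels)
#' @rdname accessors
setMethod("resultantLength", "ResultantSeries", function(x) x@rho)
#' @rdname accessors
setMethod("resultantAngle", "ResultantSeries", function(x) x@theta)
#' @rdname accessors
setMethod("permThreshold", "ResultantSeries", function(x) x@threshold)
#' @rdname accessors
setMethod("clusterTable", "ResultantSeries", function(x) x@clusters)

#' @rdname accessors
setMethod("betaGrid", "ClassificationImage", function(x) x@beta)
#' @rdname accessors
setMethod("foldedGrid", "ClassificationImage", function(x) x@folded)
#' @rdname accessors
setMethod("tuningFit", "ClassificationImage", function(x) x@fit)

setMethod("show", "EpochedSeries", function(object) {
  d <- dim(object@voltages)
  cat("EpochedSeries:", d[1L], "trials x", d[2L], "channels x",
      d[3L], "samples\n")
  cat("  fs:", object@fs, "Hz; time:",
      sprintf("%.3f..%.3f s", min(object@time), max(object@time)), "\n")
  cat("  channels:", paste(utils::head(object@channels, 8L), collapse = ", "),
      if (length(object@channels) > 8L) "..." else "", "\n")
})

setMethod("show", "PhaseArray", function(object) {
  d <- dim(object@phase)
  cat("PhaseArray:", d[1L], "trials x", d[2L], "channels x",
      d[3L], "samples at", object@fsOut, "Hz\n")
  cat("  band:", sprintf("%.2f-%.2f Hz (IAF %.2f)", object@band[1L],
      object@band[2L], object@iaf), "\n")
})

setMethod("show", "ResultantSeries", function(object) {
  cat("ResultantSeries (", object@metric, "): ",
      length(object@time), " time points, ",
      length(object@channels), " channel(s)\n", sep = "")
  cat(sprintf("  peak rho = %.4g at t = %.3f s\n",
      max(object@rho), object@time[which.max(object@rho)]))
  nsig <- if (nrow(object@clusters)) sum(object@clusters$p < 0.05) else 0L
  cat("  clusters:", nrow(object@clusters), "found,", nsig,
      "significant (p < 0.05)\n")
  if (length(object@subjectRho))
    cat(sprintf("  subject-level: rho-bar = %.4g vs threshold %.4g (%s)\n",
        object@subjectRho, object@subjectThreshold,
        if (object@subjectRho > object@subjectThreshold) "significant"
        else "n.s."))
})

setMethod("show", "FilterBank", function(object) {
  cat("FilterBank:", length(object@sf), "SFs x", length(object@ori),
      "orientations =", length(object@sf) * length(object@ori), "cells\n")
  cat(sprintf("  SF %.2f-%.2f cpd; orientation %+.0f..%+.0f deg; raster %d px (%.0f px/deg)\n",
      min(object@sf), max(object@sf), min(object@ori), max(object@ori),
      object@patchPixels, object@pixelsPerDegree))
})

setMethod("show", "ClassificationImage", function(object) {
  cat("ClassificationImage:", nrow(object@beta), "SFs x", ncol(object@beta),
      "orientations\n")
  if (length(object@fit))
    cat(sprintf("  Gaussian fit: gain %.3g centre (%.2f cpd, %.1f deg) SD (%.2f, %.1f) offset %.3g, r2 = %.3f\n",
        object@fit$p1, object@fit$p2, object@fit$p4, object@fit$p3,
        object@fit$p5, object@fit$p6, object@fit$r2))
  if (length(object@modulation))
    cat(sprintf("  modulation vs reference: gain %.3f, SD %.3f, offset %.3f\n",
        object@modulation$gainMod, object@modulation$sdMod,
        object@modulation$offsetMod))
})
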