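#' Accessors for trajectory and series objects
#'
#' @param x an object
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("currentTrace", function(x) standardGeneric("currentTrace"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("applicationWindow", function(x) standardGeneric("applicationWindow"))

#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
#' @param i frame index
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  if (length(i) != 1 || i < 1 || i > nFrames(x))
    stop("frame index out of range: ", i)
  x@coords[, , i, drop = FALSE][, , 1]
})

#' @rdname accessors
#' @export
setMethod("seriesTimes", "DistanceSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("seriesValues", "DistanceSeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("seriesLabel", "DistanceSeries", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("intervals", "BoundIntervals", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "SweepTrace", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("currentTrace", "SweepTrace", function(x) x@current)

#' @rdname accessors
#' @export
setMethod("sampleRate", "SweepTrace", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("applicationWindow", "SweepTrace",
          function(x) c(on = x@appOn, off = x@appOff))

#' @export
setMethod("length", "DistanceSeries", function(x) length(x@values))

#' Coerce a distance series to a data.frame
#'
#' @param x a [DistanceSeries-class]
#' @param ... ignored
#' @return data.frame with columns \code{time_ns}, \code{value_nm}
#' @export
as.data.frame.DistanceSeries <- function(x, ...) {
  data.frame(time_ns = x@times, value_nm = x@values)
}

#' Coerce a kinetics result to a one-row data.frame
#'
#' @param x a [KineticsResult-class]
#' @param ... ignored
#' @export
as.data.frame.KineticsResult <- function(x, ...) {
  data.frame(i_peak_pA = x@iPeak, t_peak_s = x@tPeak, i_200ms_pA = x@i200ms,
             i_5s_pA = x@i5s, a1_pA = x@a1, a2_pA = x@a2,
             tau1_ms = x@tau1, tau2_ms = x@tau2, tau_w_ms = x@tauW,
             steady_state_pct = x@steadyStatePct,
             resensitization_pct = x@resensitizationPct,
             rise_10_90_ms = x@rise1090, fit_ok = x@fitOk)
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms,", nFrames(object), "frames,",
      sprintf("%.6g-%.6g ns\n", object@times[1],
              object@times[length(object@times)]))
  cat("  chains:", paste(unique(object@atoms$chain), collapse = " "), "\n")
})

setMethod("show", "DistanceSeries", function(object) {
  cat("DistanceSeries", if (nzchar(object@label)) paste0("(", object@label, ")"),
      ":", length(object@values), "points,",
      sprintf("range %.4g-%.4g nm\n", min(object@values), max(object@values)))
})

setMethod("show", "AtomSelector", function(object) {
  f <- c(chain = if (length(object@chain)) object@chain,
         resseq = if (length(object@resseq)) as.character(object@resseq),
         resname = if (length(object@resname)) object@resname,
         atom = if (length(object@atom)) object@atom)
  cat("AtomSelector:", paste(names(f), f, sep = "=", collapse = " "), "\n")
})

setMethod("show", "HBondSpec", function(object) {
  cat("HBondSpec:", object@mode, sprintf("cutoff %.3g nm\n", object@cutoff))
})

setMethod("show", "BoundIntervals", function(object) {
  iv <- object@intervals
  cat("BoundIntervals:", nrow(iv), "interval(s),",
      sprintf("cutoff %.3g nm, min dwell %.3g ns\n",
              object@cutoff, object@minDwell))
  if (nrow(iv) > 0)
    for (k in seq_len(nrow(iv)))
      cat(sprintf("  [%.6g, %.6g] ns\n", iv[k, 1], iv[k, 2]))
})

setMethod("show", "SweepTrace", function(object) {
  cat(sprintf(
    "SweepTrace [%s, %s]: %d samples at %.4g kHz, application %.3g-%.3g s\n",
    object@cellId, object@condition, length(object@current),
    object@rate / 1000, object@appOn, object@appOff))
})

setMethod("show", "KineticsResult", function(object) {
  cat(sprintf("KineticsResult: Ipeak %.4g pA at %.4g ms post-onset\n",
              object@iPeak, object@tPeak * 1000))
  cat(sprintf("  rise 10-90: %.3g ms; steady-state %.3g%%; resensitization %.3g%%\n",
              object@rise1090, object@steadyStatePct,
              object@resensitizationPct))
  cat(sprintf("  desensitization fit%s: tau1 %.4g ms, tau2 %.4g ms, tauW %.4g ms\n",
              if (object@fitOk) "" else " (NOT ok)",
              object@tau1, object@tau2, object@tauW))
})
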