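#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Atom selector
#'
#' A conjunction of optional atom-matching fields.  An atom matches when every
#' field that is set agrees with it; at least one field must be set.  Used
#' throughout to resolve residues such as the Cα atoms of the gamma-8
#' selectivity pair Val-176 / Gly-209.
#'
#' @slot chain single-character chain identifier, or empty when unset
#' @slot resseq residue sequence number, or empty when unset
#' @slot resname 3-letter residue code, or empty when unset
#' @slot atom atom name (e.g. \code{"CA"}), or empty when unset
#'
#' @seealso [atomSelector()], [selectAtoms()]
#' @export
setClass("AtomSelector",
  slots = c(chain = "character", resseq = "integer",
            resname = "character", atom = "character"),
  prototype = list(chain = character(), resseq = integer(),
                   resname = character(), atom = character()))

setValidity("AtomSelector", function(object) {
  n <- lengths(list(object@chain, object@resseq, object@resname, object@atom))
  if (any(n > 1)) return("each selector field must have length 0 or 1")
  if (sum(n) == 0) return("at least one selector field must be set")
  TRUE
})

setClassUnion("AtomSelectorOrNULL", c("AtomSelector", "NULL"))

#' Construct an atom selector
#'
#' @param chain optional single-character chain identifier
#' @param resseq optional residue number
#' @param resname optional 3-letter residue code
#' @param atom optional atom name
#' @return an [AtomSelector-class] object
#' @examples
#' atomSelector(resseq = 176, atom = "CA")
#' @export
atomSelector <- function(chain = NULL, resseq = NULL, resname = NULL,
                         atom = NULL) {
  new("AtomSelector",
      chain = as.character(chain %||% character()),
      resseq = as.integer(resseq %||% integer()),
      resname = as.character(resname %||% character()),
      atom = as.character(atom %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate trajectory
#'
#' An ordered set of coordinate frames over a fixed topology.  The canonical
#' internal length unit is nanometres; conversion from the ångström of PDB
#' files happens at the file boundary only.
#'
#' @slot atoms topology data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resseq}, \code{chain}, \code{mass}
#' @slot coords numeric array of dimension (atoms, 3, frames), nm
#' @slot times frame times in ns, strictly increasing
#'
#' @seealso [readPDB()], [readTrajTable()], [newTrajectory()]
#' @export
setClass("Trajectory",
  slots = c(atoms = "data.frame", coords = "array", times = "numeric"))

.atom_cols <- c("serial", "name", "element", "resname", "resseq",
                "chain", "mass")

setValidity("Trajectory", function(object) {
  a <- object@atoms
  if (!all(.atom_cols %in% names(a)))
    return(paste("atoms must have columns:", paste(.atom_cols, collapse = ", ")))
  if (nrow(a) < 1) return("topology must contain at least one atom")
  if (any(!nzchar(a$name))) return("atom names must be non-empty")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("atom masses must be positive and finite")
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an (atoms, 3, frames) array")
  if (d[1] != nrow(a)) return("coords atom count does not match topology")
  if (d[3] < 1) return("trajectory must contain at least one frame")
  if (d[3] != length(object@times))
    return("frame count does not match length of times")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (any(!is.finite(object@coords))) return("all coordinates must be finite")
  TRUE
})

#' Construct a trajectory from a topology and a coordinate array
#'
#' @param atoms topology data.frame (see [Trajectory-class])
#' @param coords numeric array (atoms, 3, frames) in nm, or an (atoms, 3)
#'   matrix for a single frame
#' @param times frame times in ns; defaults to 0, 1, ... frame index
#' @return a [Trajectory-class] object
#' @export
newTrajectory <- function(atoms, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.null(times)) times <- seq_len(dim(coords)[3]) - 1
  new("Trajectory", atoms = atoms, coords = coords, times = as.numeric(times))
}

#' Distance time series
#'
#' A per-frame distance measurement over a trajectory (pocket width, ligand
#' engagement, or hydrogen-bond distance), in nm against ns.
#'
#' @slot times frame times (ns), strictly increasing
#' @slot values distances (nm), non-negative
#' @slot label free-text description of the measurement
#' @export
setClass("DistanceSeries",
  slots = c(times = "numeric", values = "numeric", label = "character"))

setValidity("DistanceSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) == 0) return("series must be non-empty")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("values must be finite and non-negative")
  TRUE
})

distanceSeries <- function(times, values, label = "") {
  new("DistanceSeries", times = as.numeric(times), values = as.numeric(values),
      label = as.character(label)[1])
}

#' Hydrogen-bond specification
#'
#' A distance-only hydrogen-bond criterion, as applied to MD trajectories of
#' modulator binding: either the hydrogen-to-acceptor distance (weak H-bond
#' requires < 0.25 nm) or, when the bonding hydrogen is not the measured atom,
#' the heavy-atom donor-to-acceptor distance (criterion < 0.36 nm).
#'
#' @slot donor [AtomSelector-class] for the donor heavy atom
#' @slot hydrogen optional [AtomSelector-class] for the bonding hydrogen;
#'   required in \code{H_TO_ACCEPTOR} mode
#' @slot acceptor [AtomSelector-class] for the acceptor atom
#' @slot mode \code{"H_TO_ACCEPTOR"} or \code{"HEAVY_TO_HEAVY"}
#' @slot cutoff distance criterion in nm
#' @seealso [hbondSpec()], [hbondSeries()], [hbondOccupancy()]
#' @export
setClass("HBondSpec",
  slots = c(donor = "AtomSelector", hydrogen = "AtomSelectorOrNULL",
            acceptor = "AtomSelector", mode = "character", cutoff = "numeric"))

setValidity("HBondSpec", function(object) {
  if (!object@mode %in% c("H_TO_ACCEPTOR", "HEAVY_TO_HEAVY"))
    return("mode must be H_TO_ACCEPTOR or HEAVY_TO_HEAVY")
  if (object@mode == "H_TO_ACCEPTOR" && is.null(object@hydrogen))
    return("H_TO_ACCEPTOR mode requires a hydrogen selector")
  if (length(object@cutoff) != 1 || !is.finite(object@cutoff) ||
      object@cutoff <= 0)
    return("cutoff must be a single positive number (nm)")
  TRUE
})

#' Construct a hydrogen-bond specification
#'
#' The default cutoff depends on the measurement mode: 0.25 nm for the
#' hydrogen-to-acceptor distance, 0.36 nm for a heavy-atom (e.g. N-to-N)
#' distance where the bonding hydrogen is not measured directly.
#'
#' @param donor [AtomSelector-class] for the donor heavy atom
#' @param acceptor [AtomSelector-class] for the acceptor atom
#' @param hydrogen optional [AtomSelector-class] for the bonding hydrogen
#' @param mode measurement mode; defaults to \code{"H_TO_ACCEPTOR"} when a
#'   hydrogen selector is given, \code{"HEAVY_TO_HEAVY"} otherwise
#' @param cutoff distance criterion (nm); mode-dependent default
#' @return an [HBondSpec-class] object
#' @export
hbondSpec <- function(donor, acceptor, hydrogen = NULL, mode = NULL,
                      cutoff = NULL) {
  if (is.null(mode))
    mode <- if (is.null(hydrogen)) "HEAVY_TO_HEAVY" else "H_TO_ACCEPTOR"
  if (is.null(cutoff))
    cutoff <- if (mode == "H_TO_ACCEPTOR") 0.25 else 0.36
  new("HBondSpec", donor = donor, hydrogen = hydrogen, acceptor = acceptor,
      mode = mode, cutoff = as.numeric(cutoff))
}

#' Bound intervals
#'
#' Contiguous time intervals during which a ligand engagement series stays
#' below a distance cutoff, after discarding dwells shorter than a minimum
#' duration.
#'
#' @slot intervals numeric matrix with columns \code{start}, \code{end} (ns)
#' @slot cutoff engagement distance cutoff used (nm)
#' @slot minDwell minimum dwell time used (ns)
#' @seealso [classifyBound()]
#' @export
setClass("BoundIntervals",
  slots = c(intervals = "matrix", cutoff = "numeric", minDwell = "numeric"))

setValidity("BoundIntervals", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2) return("intervals must have two columns (start, end)")
  if (nrow(iv) > 0) {
    if (any(iv[, 2] <= iv[, 1])) return("each interval must have end > start")
    tol <- 1e-9
    if (any(iv[, 2] - iv[, 1] < object@minDwell - tol))
      return("each interval must be at least minDwell long")
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      return("intervals must be disjoint and ordered")
  }
  TRUE
})

#' Fast-application current sweep
#'
#' A whole-cell current response to a timed glutamate application, sampled
#' uniformly.  Inward current is negative by convention.  The reference
#' protocol applies 10 mM glutamate for 5 s.
#'
#' @slot times sample times (s)
#' @slot current samples (pA, inward negative)
#' @slot rate sampling rate (Hz)
#' @slot appOn,appOff agonist application window (s)
#' @slot cellId,condition recording labels (e.g. condition "vehicle"/"drug")
#' @seealso [readSweeps()], [simulateSweep()], [analyzeSweep()]
#' @export
setClass("SweepTrace",
  slots = c(times = "numeric", current = "numeric", rate = "numeric",
            appOn = "numeric", appOff = "numeric",
            cellId = "character", condition = "character"))

setValidity("SweepTrace", function(object) {
  n <- length(object@times)
  if (n != length(object@current))
    return("times and current must have equal length")
  if (n < 2) return("a sweep needs at least two samples")
  dt <- diff(object@times)
  period <- 1 / object@rate
  if (any(dt <= 0)) return("sample times must be strictly increasing")
  if (any(abs(dt - period) > period))
    return("sampling must be uniform within one sample period")
  if (object@appOn >= object@appOff)
    return("appOn must precede appOff")
  if (object@appOff > object@times[n] + period)
    return("appOff must lie within the sampled range")
  TRUE
})

sweepTrace <- function(times, current, rate = NULL, appOn, appOff,
                       cellId = "cell", condition = "vehicle") {
  if (is.null(rate)) rate <- 1 / stats::median(diff(times))
  new("SweepTrace", times = as.numeric(times), current = as.numeric(current),
      rate = as.numeric(rate), appOn = as.numeric(appOn),
      appOff = as.numeric(appOff), cellId = as.character(cellId)[1],
      condition = as.character(condition)[1])
}

#' Sweep kinetics summary
#'
#' All kinetic readouts of a single fast-application sweep: peak current and
#' its time, the 200-ms and end-of-application currents, the biexponential
#' desensitization fit (amplitudes, time constants, weighted tau), the
#' steady-state and resensitization percentages of peak, and the 10-90 rise
#' time.
#'
#' @slot iPeak peak current magnitude (pA)
#' @slot tPeak time of peak relative to application onset (s)
#' @slot i200ms current magnitude 200 ms after the peak (pA)
#' @slot i5s current magnitude at end of application (pA)
#' @slot a1,a2 desensitization fit amplitudes (pA)
#' @slot tau1,tau2 fit time constants (ms), \code{tau1 <= tau2} when fit is ok
#' @slot tauW amplitude-weighted time constant (ms)
#' @slot steadyStatePct steady-state current, percent of peak
#' @slot resensitizationPct resensitization, percent of peak
#' @slot rise1090 10-90 rise time (ms)
#' @slot fitOk whether the desensitization fit converged acceptably
#' @seealso [analyzeSweep()], [fitDesensitization()]
#' @export
setClass("KineticsResult",
  slots = c(iPeak = "numeric", tPeak = "numeric", i200ms = "numeric",
            i5s = "numeric", a1 = "numeric", a2 = "numeric",
            tau1 = "numeric", tau2 = "numeric", tauW = "numeric",
            steadyStatePct = "numeric", resensitizationPct = "numeric",
            rise1090 = "numeric", fitOk = "logical"))

setValidity("KineticsResult", function(object) {
  if (isTRUE(object@fitOk)) {
    if (!(object@tau1 <= object@tau2 && object@tau2 > 0))
      return("when fitOk, time constants must satisfy 0 < tau1 <= tau2")
    tol <- 1e-6
    if (is.finite(object@tauW) &&
        (object@tauW < object@tau1 - tol || object@tauW > object@tau2 + tol))
      return("tauW must lie between tau1 and tau2 when fitOk")
  }
  TRUE
})
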