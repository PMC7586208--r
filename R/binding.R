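#' Distance between two atoms in one frame
#'
#' @param traj a [Trajectory-class]
#' @param frame frame index
#' @param a,b atom indices (topology order)
#' @return Euclidean distance in nm
#' @export
atomDistance <- function(traj, frame, a, b) {
  xyz <- frameCoords(traj, frame)
  n <- nAtoms(traj)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("atom index out of range")
  sqrt(sum((xyz[a, ] - xyz[b, ])^2))
}

#' Binding-pocket width time series
#'
#' Per-frame distance between two single atoms, typically the Cα atoms of the
#' gamma-8 selectivity residues Val-176 and Gly-209 whose separation gates
#' modulator access to the pocket.
#'
#' @param traj a [Trajectory-class]
#' @param resA,resB [AtomSelector-class]s, each resolving to exactly one atom
#' @return a [DistanceSeries-class] (nm against ns)
#' @export
pocketWidthSeries <- function(traj, resA, resB) {
  ia <- .resolve_one(traj, resA, "resA selector")
  ib <- .resolve_one(traj, resB, "resB selector")
  d <- sqrt(colSums((.atom_xyz(traj, ia) - .atom_xyz(traj, ib))^2))
  distanceSeries(traj@times, d, "pocket width")
}

# 3 x nFrames coordinate matrix of one atom (robust to single-frame drop)
.atom_xyz <- function(traj, i) matrix(traj@coords[i, , ], nrow = 3)

#' Midpoint of a two-atom site
#'
#' The binding-site reference point: the arithmetic midpoint of the two
#' pocket-defining Cα positions.
#'
#' @param traj a [Trajectory-class]
#' @param frame frame index
#' @param a,b atom indices
#' @return numeric 3-vector (nm)
#' @export
siteCenter <- function(traj, frame, a, b) {
  xyz <- frameCoords(traj, frame)
  n <- nAtoms(traj)
  if (a < 1 || a > n || b < 1 || b > n) stop("atom index out of range")
  (xyz[a, ] + xyz[b, ]) / 2
}

#' Ligand centre of mass in one frame
#'
#' @param traj a [Trajectory-class]
#' @param frame frame index
#' @param ligand integer vector of ligand atom indices
#' @param masses per-atom masses (Da); defaults to the topology masses
#' @return numeric 3-vector (nm)
#' @export
ligandCOM <- function(traj, frame, ligand, masses = NULL) {
  if (length(ligand) < 1) stop("empty ligand selection")
  if (is.null(masses)) masses <- traj@atoms$mass[ligand]
  if (length(masses) != length(ligand) || any(masses <= 0))
    stop("masses must be positive, one per ligand atom")
  xyz <- frameCoords(traj, frame)[ligand, , drop = FALSE]
  colSums(xyz * masses) / sum(masses)
}

#' Ligand engagement time series
#'
#' Per-frame distance between the ligand centre of mass and the midpoint of
#' the pocket-defining Cα pair — the binding metric used to read engagement
#' of the gamma-8 pocket from a simulation.
#'
#' By default the centre of mass is taken over the heavy atoms of the
#' selection (hydrogens excluded); set \code{heavyOnly = FALSE} to include
#' all selected atoms.
#'
#' @param traj a [Trajectory-class]
#' @param ligand [AtomSelector-class] for the ligand (>= 1 atom)
#' @param resA,resB [AtomSelector-class]s for the pocket residues (one atom
#'   each)
#' @param masses optional per-atom masses for the resolved ligand selection
#' @param heavyOnly drop hydrogens from the ligand selection (default TRUE)
#' @return a [DistanceSeries-class] (nm against ns)
#' @export
engagementSeries <- function(traj, ligand, resA, resB, masses = NULL,
                             heavyOnly = TRUE) {
  lig <- selectAtoms(traj, ligand)
  if (heavyOnly && is.null(masses))
    lig <- lig[traj@atoms$element[lig] != "H"]
  if (length(lig) < 1) stop("ligand selector matched no atoms")
  ia <- .resolve_one(traj, resA, "resA selector")
  ib <- .resolve_one(traj, resB, "resB selector")
  m <- masses %||% traj@atoms$mass[lig]
  if (length(m) != length(lig) || any(m <= 0))
    stop("masses must be positive, one per ligand atom")
  w <- m / sum(m)
  com <- apply(traj@coords[lig, , , drop = FALSE], c(2, 3),
               function(v) sum(v * w))
  ctr <- (.atom_xyz(traj, ia) + .atom_xyz(traj, ib)) / 2
  d <- sqrt(colSums((com - ctr)^2))
  distanceSeries(traj@times, d, "ligand engagement")
}

#' Classify bound intervals from an engagement series
#'
#' Maximal runs of consecutive samples below the cutoff become time intervals
#' (first to last sub-cutoff sample time); runs shorter than \code{minDwell}
#' are discarded.  The default cutoff of 0.8 nm marks a broken contact, and
#' the 5-ns minimum dwell suppresses grazing approaches.
#'
#' @param series a [DistanceSeries-class]
#' @param cutoff engagement cutoff (nm)
#' @param minDwell minimum dwell time (ns)
#' @return a [BoundIntervals-class]
#' @export
classifyBound <- function(series, cutoff = 0.8, minDwell = 5) {
  stopifnot(is(series, "DistanceSeries"), cutoff > 0, minDwell >= 0)
  below <- series@values < cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  iv <- matrix(numeric(0), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  for (k in keep) {
    t0 <- series@times[starts[k]]
    t1 <- series@times[ends[k]]
    if (t1 - t0 >= minDwell && t1 > t0)
      iv <- rbind(iv, c(t0, t1))
  }
  colnames(iv) <- c("start", "end")
  new("BoundIntervals", intervals = iv, cutoff = cutoff, minDwell = minDwell)
}

#' Fraction of trajectory time covered by bound intervals
#'
#' @param x a [BoundIntervals-class]
#' @param series the [DistanceSeries-class] the intervals came from (supplies
#'   the total time span)
#' @return fraction in [0, 1]
#' @export
boundFraction <- function(x, series) {
  span <- diff(range(series@times))
  if (span <= 0) return(if (nrow(x@intervals) > 0) 1 else 0)
  sum(x@intervals[, 2] - x@intervals[, 1]) / span
}

#' Hydrogen-bond distance time series
#'
#' Per-frame distance between the bonding hydrogen and the acceptor
#' (\code{H_TO_ACCEPTOR}) or between the donor and acceptor heavy atoms
#' (\code{HEAVY_TO_HEAVY}), per the specification's mode.
#'
#' @param traj a [Trajectory-class]
#' @param spec an [HBondSpec-class]
#' @return a [DistanceSeries-class] (nm against ns)
#' @export
hbondSeries <- function(traj, spec) {
  stopifnot(is(spec, "HBondSpec"))
  iacc <- .resolve_one(traj, spec@acceptor, "acceptor selector")
  ia <- if (spec@mode == "H_TO_ACCEPTOR")
    .resolve_one(traj, spec@hydrogen, "hydrogen selector")
  else
    .resolve_one(traj, spec@donor, "donor selector")
  d <- sqrt(colSums((.atom_xyz(traj, ia) - .atom_xyz(traj, iacc))^2))
  distanceSeries(traj@times, d,
                 sprintf("H-bond distance (%s)", spec@mode))
}

#' Time-weighted hydrogen-bond occupancy
#'
#' Fraction of trajectory time during which the bond distance satisfies the
#' criterion (value < cutoff).  Each sample is weighted by its inter-frame
#' interval (half-intervals at the ends), making the estimate robust to
#' uneven snapshot spacing.
#'
#' @param series a [DistanceSeries-class]
#' @param spec an [HBondSpec-class], or a numeric cutoff in nm
#' @return occupancy fraction in [0, 1]
#' @export
hbondOccupancy <- function(series, spec) {
  cutoff <- if (is(spec, "HBondSpec")) spec@cutoff else as.numeric(spec)
  stopifnot(length(cutoff) == 1, cutoff > 0)
  t <- series@times
  n <- length(t)
  if (n == 1) return(as.numeric(series@values[1] < cutoff))
  dt <- diff(t)
  w <- c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
  sum(w[series@values < cutoff]) / sum(w)
}

#' Select the frame of maximal pocket width
#'
#' The snapshot-selection rule for docking substrates: the frame in which the
#' pocket-defining Cα pair is furthest apart (ties resolved to the earliest
#' frame).
#'
#' @inheritParams pocketWidthSeries
#' @return frame index (1-based)
#' @export
selectMaxWidthFrame <- function(traj, resA, resB) {
  s <- pocketWidthSeries(traj, resA, resB)
  which.max(s@values)  # which.max returns the first maximum
}

#' Optimal-superposition RMSD
#'
#' Least-squares rigid superposition (Kabsch: centroid translation plus the
#' SVD-derived proper rotation) of the mobile set onto the reference set,
#' followed by the root-mean-square deviation.  All supplied pairs enter the
#' fit; there is no outlier-rejection cycle.  Inputs are in nm; the result is
#' reported in ångström, the unit structural comparisons are quoted in.
#'
#' @param ref,mob n x 3 coordinate matrices (nm), n >= 3, equal sizes
#' @return RMSD in ångström
#' @export
superposeRMSD <- function(ref, mob) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (!identical(dim(ref), dim(mob)))
    stop("coordinate sets must have identical dimensions")
  if (nrow(ref) < 3) stop("superposition needs at least 3 atom pairs")
  if (ncol(ref) != 3) stop("coordinates must be n x 3")
  rc <- colMeans(ref); mc <- colMeans(mob)
  A <- sweep(ref, 2, rc); B <- sweep(mob, 2, mc)
  H <- crossprod(B, A)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)    # proper rotation, det = +1
  fitted <- B %*% t(R)
  rmsd_nm <- sqrt(mean(rowSums((fitted - A)^2)))
  rmsd_nm * 10
}
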