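#' Read a (possibly multi-model) PDB file into a Trajectory
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}; each MODEL block becomes one
#' frame (a single frame when the file has no MODEL records).  Coordinates are
#' converted from ångström to the package's canonical nanometre unit.
#' Elements are taken from the element column when present and otherwise
#' inferred from the atom name; masses come from standard atomic weights.
#' Alternate locations other than blank/"A" are dropped with a warning.
#'
#' Frame times are the 0-based model index (ns are nominal: PDB carries no
#' time axis).
#'
#' @param path path to a PDB file
#' @return a [Trajectory-class]
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  VAL E 176       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  GLY E 209      10.000   0.000   0.000  1.00  0.00"),
#'   pdb)
#' traj <- readPDB(pdb)
#' atomDistance(traj, 1, 1, 2)  # 1 nm
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0)
    stop("no ATOM/HETATM records in ", path)
  # validate coordinate fields before handing off, so errors carry line numbers
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(lines[rec], fld[1], fld[2])))
    if (anyNA(v))
      stop("malformed coordinate field in PDB record at line ",
           rec[which(is.na(v))[1]])
  }
  alt <- substr(lines[rec], 17, 17)
  if (any(!alt %in% c(" ", "", "A")))
    warning("alternate locations other than 'A' present; keeping first altLoc")
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- trimws(at$elesy)
  infer <- !nzchar(elesy) | is.na(elesy)
  if (any(infer))
    elesy[infer] <- bio3d::atom2ele(at$elety[infer])
  # normalize symbol case ("CL" -> "Cl") and map to standard atomic weights
  elesy <- paste0(toupper(substr(elesy, 1, 1)),
                  tolower(substr(elesy, 2, nchar(elesy))))
  ptable <- local({
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    e$elements
  })
  mass <- ptable$mass[match(elesy, as.character(ptable$symb))]
  if (anyNA(mass))
    stop("unknown element symbol(s): ",
         paste(unique(elesy[is.na(mass)]), collapse = ", "))
  topo <- data.frame(serial = at$eleno, name = trimws(at$elety),
                     element = elesy, resname = trimws(at$resid),
                     resseq = at$resno, chain = at$chain, mass = mass,
                     stringsAsFactors = FALSE)
  topo$chain[is.na(topo$chain)] <- ""
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(topo), 3, nfr))
  for (m in seq_len(nfr))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) * 0.1
  newTrajectory(topo, coords, times = seq_len(nfr) - 1)
}

#' Read a trajectory from a plain-text coordinate table
#'
#' The table is TSV with columns \code{time_ns}, \code{serial}, \code{x_nm},
#' \code{y_nm}, \code{z_nm}; every time must list the same set of serials.
#'
#' @param path path to the TSV table
#' @param atoms optional topology data.frame (see [Trajectory-class]) whose
#'   \code{serial} column matches the table; when omitted a pseudo-atom
#'   topology (name \code{"PSA"}, unit mass) is synthesized
#' @return a [Trajectory-class]
#' @seealso [writeTrajTable()]
#' @export
readTrajTable <- function(path, atoms = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("time_ns", "serial", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(tab)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  times <- sort(unique(tab$time_ns))
  if (length(times) != length(unique(round(tab$time_ns, 12))))
    stop("duplicate or non-monotonic times in trajectory table")
  serials <- sort(unique(tab$serial[tab$time_ns == times[1]]))
  coords <- array(NA_real_, dim = c(length(serials), 3, length(times)))
  for (k in seq_along(times)) {
    blk <- tab[tab$time_ns == times[k], , drop = FALSE]
    if (nrow(blk) != length(serials) ||
        !identical(sort(blk$serial), serials))
      stop("inconsistent atom set at time ", times[k],
           ": every frame must list the same serials")
    blk <- blk[order(blk$serial), , drop = FALSE]
    coords[, , k] <- as.matrix(blk[, c("x_nm", "y_nm", "z_nm")])
  }
  if (is.null(atoms)) {
    atoms <- data.frame(serial = serials, name = "PSA", element = "X",
                        resname = "PSA", resseq = seq_along(serials),
                        chain = "A", mass = 1, stringsAsFactors = FALSE)
  } else if (!identical(sort(atoms$serial), serials)) {
    stop("supplied topology serials do not match the table")
  } else {
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  newTrajectory(atoms, coords, times = times)
}

#' Write a trajectory as a plain-text coordinate table
#'
#' @param traj a [Trajectory-class]
#' @param path output TSV path
#' @return invisibly, \code{path}
#' @seealso [readTrajTable()]
#' @export
writeTrajTable <- function(traj, path) {
  nf <- nFrames(traj)
  na <- nAtoms(traj)
  tab <- data.frame(
    time_ns = rep(traj@times, each = na),
    serial = rep(traj@atoms$serial, nf),
    x_nm = as.vector(traj@coords[, 1, ]),
    y_nm = as.vector(traj@coords[, 2, ]),
    z_nm = as.vector(traj@coords[, 3, ]))
  utils::write.table(format(tab, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select atoms from a trajectory topology
#'
#' Returns the indices (topology order) of atoms matching the conjunction of
#' the selector's set fields; the result may be empty.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelector-class]
#' @return integer vector of atom indices
#' @examples
#' # the gamma-8 selectivity-pocket Cα atoms, given chain E:
#' # selectAtoms(traj, atomSelector(chain = "E", resseq = 176, atom = "CA"))
#' @export
selectAtoms <- function(traj, sel) {
  stopifnot(is(traj, "Trajectory"), is(sel, "AtomSelector"))
  a <- traj@atoms
  keep <- rep(TRUE, nrow(a))
  if (length(sel@chain)) keep <- keep & a$chain == sel@chain
  if (length(sel@resseq)) keep <- keep & a$resseq == sel@resseq
  if (length(sel@resname)) keep <- keep & a$resname == sel@resname
  if (length(sel@atom)) keep <- keep & a$name == sel@atom
  which(keep)
}

.resolve_one <- function(traj, sel, what = "selector") {
  idx <- selectAtoms(traj, sel)
  if (length(idx) != 1)
    stop(what, " must resolve to exactly one atom (matched ",
         length(idx), ")")
  idx
}

#' Parse a selector mini-syntax string
#'
#' Format \code{chain:resseq:atom}; empty fields are left unset, e.g.
#' \code{"E:176:CA"}, \code{":176:CA"}, \code{"::OD1"}.
#'
#' @param s selector string
#' @return an [AtomSelector-class]
#' @export
parseSelector <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  length(parts) <- 3
  parts[is.na(parts)] <- ""
  atomSelector(chain = if (nzchar(parts[1])) parts[1],
               resseq = if (nzchar(parts[2])) as.integer(parts[2]),
               atom = if (nzchar(parts[3])) parts[3])
}

#' Read fast-application current sweeps
#'
#' Reads a TSV of samples (\code{time_s}, \code{current_pA}, optional
#' \code{sweep_id} for concatenated sweeps) together with a JSON sidecar
#' providing the application window and labels
#' (\code{app_on_s}, \code{app_off_s}, \code{cell_id}, \code{condition}).
#' The sampling rate is inferred from the median sample interval.
#'
#' @param path path to the sweep TSV
#' @param meta path to the JSON sidecar
#' @return a list of [SweepTrace-class] objects, one per sweep block
#' @export
readSweeps <- function(path, meta) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("time_s", "current_pA") %in% names(tab)))
    stop("sweep table must have columns time_s, current_pA")
  side <- jsonlite::read_json(meta, simplifyVector = TRUE)
  for (k in c("app_on_s", "app_off_s"))
    if (is.null(side[[k]]))
      stop("sweep sidecar is missing required field ", k)
  ids <- if ("sweep_id" %in% names(tab)) tab$sweep_id else rep(1L, nrow(tab))
  lapply(unique(ids), function(id) {
    blk <- tab[ids == id, , drop = FALSE]
    dt <- diff(blk$time_s)
    rate <- 1 / stats::median(dt)
    if (any(abs(dt - stats::median(dt)) > stats::median(dt)))
      stop("non-uniform sampling in sweep ", id,
           " exceeds one sample period")
    sweepTrace(blk$time_s, blk$current_pA, rate = rate,
               appOn = side$app_on_s, appOff = side$app_off_s,
               cellId = side$cell_id %||% "cell",
               condition = side$condition %||% "vehicle")
  })
}

#' Write fast-application current sweeps
#'
#' Writes one or more sweeps to a TSV (\code{time_s}, \code{current_pA},
#' \code{sweep_id}) and the JSON sidecar [readSweeps()] expects.  The
#' application window and labels are taken from the first sweep.
#'
#' @param sweeps a [SweepTrace-class] or a list of them
#' @param path output TSV path
#' @param meta output JSON sidecar path
#' @return invisibly, \code{path}
#' @export
writeSweeps <- function(sweeps, path, meta) {
  if (is(sweeps, "SweepTrace")) sweeps <- list(sweeps)
  tab <- do.call(rbind, lapply(seq_along(sweeps), function(k) {
    tr <- sweeps[[k]]
    data.frame(time_s = tr@times, current_pA = tr@current, sweep_id = k)
  }))
  utils::write.table(format(tab, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sweeps[[1]]
  jsonlite::write_json(list(app_on_s = tr@appOn, app_off_s = tr@appOff,
                            cell_id = tr@cellId, condition = tr@condition),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model-score table
#'
#' TSV with columns \code{model_id}, \code{rmsd_A}, \code{dope} — the
#' quality-assessment table for candidate all-atom homology models (RMSD to
#' the reference structure, DOPE statistical-potential energy).
#'
#' @param path path to the TSV
#' @return data.frame with columns \code{model_id}, \code{rmsd}, \code{dope}
#' @seealso [rankModels()]
#' @export
readModelScores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("model_id", "rmsd_A", "dope") %in% names(tab)))
    stop("score table must have columns model_id, rmsd_A, dope")
  data.frame(model_id = as.integer(tab$model_id), rmsd = tab$rmsd_A,
             dope = tab$dope)
}
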