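# Fixture builders and independent oracles, built in code at test time.

# ---- PDB text builder (wwPDB fixed-width ATOM records) ----------------------

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resseq, x, y, z, element)
}

write_pdb_fixture <- function(models, path = tempfile(fileext = ".pdb")) {
  # models: list of data.frames with serial, name, resname, chain, resseq,
  # x, y, z (angstrom)
  lines <- character()
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    df <- models[[m]]
    lines <- c(lines, vapply(seq_len(nrow(df)), function(i)
      pdb_atom_line(df$serial[i], df$name[i], df$resname[i], df$chain[i],
                    df$resseq[i], df$x[i], df$y[i], df$z[i]), character(1)))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# ---- in-memory trajectory builders -----------------------------------------

toy_atoms <- function(n, chain = rep("A", n), resseq = seq_len(n),
                      name = rep("CA", n), element = rep("C", n),
                      mass = rep(12.011, n),
                      resname = rep("GLY", n)) {
  data.frame(serial = seq_len(n), name = name, element = element,
             resname = resname, resseq = resseq, chain = chain, mass = mass,
             stringsAsFactors = FALSE)
}

random_trajectory <- function(n_atoms = 5, n_frames = 20, seed = 1) {
  set.seed(seed)
  coords <- array(rnorm(n_atoms * 3 * n_frames), c(n_atoms, 3, n_frames)) + 5
  newTrajectory(toy_atoms(n_atoms), coords, times = seq_len(n_frames) - 1)
}

# random proper rotation (QR with positive diagonal, det forced to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply one rigid motion to every frame
transform_trajectory <- function(traj, R, shift) {
  co <- traj@coords
  for (k in seq_len(dim(co)[3]))
    co[, , k] <- co[, , k] %*% t(R) + matrix(shift, nrow(co), 3, byrow = TRUE)
  newTrajectory(atoms(traj), co, frameTimes(traj))
}

# ---- independent oracles ----------------------------------------------------

# brute-force run scan for bound intervals (independent of rle)
runscan_intervals <- function(times, values, cutoff, min_dwell) {
  below <- values < cutoff
  out <- NULL
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      if (times[j] - times[i] >= min_dwell && times[j] > times[i])
        out <- rbind(out, c(times[i], times[j]))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# explicit interval-sum occupancy oracle (half intervals at the ends)
intervalsum_occupancy <- function(times, values, cutoff) {
  n <- length(times)
  if (n == 1) return(as.numeric(values < cutoff))
  total <- 0; hit <- 0
  for (i in seq_len(n)) {
    w <- 0
    if (i > 1) w <- w + (times[i] - times[i - 1]) / 2
    if (i < n) w <- w + (times[i + 1] - times[i]) / 2
    total <- total + w
    if (values[i] < cutoff) hit <- hit + w
  }
  hit / total
}

# brute-force rigid-superposition RMSD by numerical minimization over
# Euler angles + translation (independent of the SVD route)
bruteforce_rmsd <- function(ref, mob) {
  obj <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    Rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cg, -sg, 0, sg, cg), 3, byrow = TRUE)
    M <- mob %*% t(Rz %*% Ry %*% Rx) +
      matrix(p[4:6], nrow(mob), 3, byrow = TRUE)
    sqrt(mean(rowSums((M - ref)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- optim(c(runif(3, -pi, pi), colMeans(ref) - colMeans(mob)), obj,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best * 10  # nm -> angstrom
}

# exhaustive sign-flip enumeration oracle for the paired signed-rank test
enumeration_signrank_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  ple <- mean(w_all <= w_obs + 1e-9)
  pge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# saturating-rise sweep built directly (for rise-time closed forms)
rise_trace <- function(tau_rise_ms = 1, rate = 1e5, plateau = 100) {
  times <- seq(0, 0.4, by = 1 / rate)
  appOn <- 0.1
  y <- ifelse(times < appOn, 0,
              -plateau * (1 - exp(-(times - appOn) * 1000 / tau_rise_ms)))
  sweepTrace(times, y, rate = rate, appOn = appOn, appOff = 0.4,
             cellId = "rise", condition = "vehicle")
}
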