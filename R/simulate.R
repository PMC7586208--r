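# Ground-truthed synthetic inputs: parametric agonist-application sweeps,
# stochastic ligand-binding trajectories, and model-score tables.  Every
# generator takes one explicit seed and restores the caller's RNG state.

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# normalized response time course Delta t (s) after onset:
# biexponential desensitization + plateau + slow resensitization
.trace_decay <- function(dtS, f1, tau1, f2, tau2, s, r, tauRes) {
  dtms <- dtS * 1000
  f1 * exp(-dtms / tau1) + f2 * exp(-dtms / tau2) + s +
    r * (1 - exp(-dtS / tauRes))
}

#' Simulate a fast-application AMPAR current sweep
#'
#' Phenomenological model of a 5-s glutamate-application response from a
#' TARP gamma-8-associated AMPAR: a saturating-exponential rise multiplying a
#' normalized decay
#' \eqn{D(\Delta t) = f_1 e^{-\Delta t/\tau_1} + f_2 e^{-\Delta t/\tau_2} + s
#' + r\,(1 - e^{-\Delta t/\tau_{res}})}
#' (biexponential desensitization to a steady-state plateau \eqn{s}, plus a
#' slow resensitization component \eqn{r}), scaled by the peak current,
#' signed inward-negative, with i.i.d. Gaussian noise.  Requires
#' \eqn{f_1 + f_2 + s = 1} so the normalized response is 1 at the peak.
#'
#' Returns the closed-form ground truth alongside the trace: the onset-
#' referenced \eqn{I_{200ms}}, \eqn{I_{5s}}, steady-state and
#' resensitization percentages, and \eqn{\tau_w = (f_1\tau_1 +
#' f_2\tau_2)/(f_1 + f_2)}.
#'
#' @param iPeak peak current magnitude (pA)
#' @param tauRise rise time constant (ms); 0 gives an instantaneous step
#' @param f1,f2 fast/slow desensitization fractions
#' @param tau1,tau2 desensitization time constants (ms)
#' @param s steady-state fraction (f1 + f2 + s must equal 1)
#' @param r resensitization fraction
#' @param tauRes resensitization time constant (s)
#' @param sigma noise SD (pA)
#' @param rate sampling rate (Hz)
#' @param preS,appS,tailS pre-application, application, and tail durations (s)
#' @param seed RNG seed
#' @param cellId,condition labels for the trace
#' @return list with \code{trace} (a [SweepTrace-class]), \code{truth}
#'   (closed-form \code{iPeak}, \code{i200ms}, \code{i5s},
#'   \code{steadyStatePct}, \code{resensitizationPct}, \code{tauW}), and
#'   \code{params}
#' @export
simulateSweep <- function(iPeak = 1000, tauRise = 0.5,
                          f1 = 0.5486, tau1 = 8, f2 = 0.3030, tau2 = 60,
                          s = 0.1484, r = 0.1141, tauRes = 2,
                          sigma = 50, rate = 10000,
                          preS = 0.2, appS = 5, tailS = 0.3,
                          seed = 1, cellId = "sim", condition = "vehicle") {
  if (abs(f1 + f2 + s - 1) > 1e-9)
    stop("desensitization fractions must satisfy f1 + f2 + s = 1")
  if (any(c(f1, f2, s, r) < 0)) stop("fractions must be non-negative")
  appOn <- preS; appOff <- preS + appS
  times <- (seq_len(round((preS + appS + tailS) * rate) + 1) - 1) / rate
  dt <- times - appOn
  dt[abs(dt) < 1e-12] <- 0            # guard the exact-onset sample
  env <- if (tauRise <= 0) as.numeric(dt >= 0)
  else ifelse(dt <= 0, 0, 1 - exp(-dt * 1000 / tauRise))
  decay <- .trace_decay(pmax(dt, 0), f1, tau1, f2, tau2, s, r, tauRes)
  resp <- iPeak * env * decay
  post <- times > appOff
  if (any(post)) {
    iEnd <- iPeak * .trace_decay(appS, f1, tau1, f2, tau2, s, r, tauRes)
    resp[post] <- iEnd * exp(-(times[post] - appOff) * 1000 / 5)  # deactivation
  }
  noise <- .with_seed(seed, stats::rnorm(length(times), 0, sigma))
  trace <- sweepTrace(times, -resp + noise, rate = rate,
                      appOn = appOn, appOff = appOff,
                      cellId = cellId, condition = condition)
  # ground truth from the noise-free curve itself: with a finite rise time
  # desensitization already attenuates the attained maximum below the
  # nominal amplitude, and the reads are referenced to the true peak time
  g <- function(d) {
    e <- if (tauRise <= 0) as.numeric(d >= 0)
    else 1 - exp(-pmax(d, 0) * 1000 / tauRise)
    iPeak * e * .trace_decay(pmax(d, 0), f1, tau1, f2, tau2, s, r, tauRes)
  }
  tPk <- if (tauRise <= 0) 0
  else stats::optimize(g, c(0, 0.1), maximum = TRUE, tol = 1e-10)$maximum
  iPk <- g(tPk)
  i200 <- g(tPk + 0.2)
  i5 <- g(appS)
  truth <- list(
    iPeak = iPk, tPeak = tPk, i200ms = i200, i5s = i5,
    steadyStatePct = i200 / iPk * 100,
    resensitizationPct = (i5 - i200) / iPk * 100,
    tauW = (f1 * tau1 + f2 * tau2) / (f1 + f2))
  list(trace = trace, truth = truth,
       params = list(iPeak = iPeak, tauRise = tauRise, f1 = f1, tau1 = tau1,
                     f2 = f2, tau2 = tau2, s = s, r = r, tauRes = tauRes,
                     sigma = sigma, rate = rate, preS = preS, appS = appS,
                     tailS = tailS, seed = seed))
}

#' Simulate a ligand-binding trajectory with ground truth
#'
#' A minimal stochastic emulation of a modulator diffusing near, and binding
#' into, a breathing two-helix pocket.  Two anchor pseudo-Cα atoms (labelled
#' Val-176 / Gly-209) oscillate sinusoidally about the site centre; the
#' ligand is a pseudo-atom centre of mass performing a discretized
#' Ornstein-Uhlenbeck walk — harmonic attraction toward the site centre
#' inside the binding well, free diffusion outside, with a soft outer
#' confinement standing in for the simulation box.  A donor/hydrogen/acceptor
#' triplet tracks the oxindole-to-Asn-172-type hydrogen bond: while the
#' ligand is inside the well the hydrogen sits at \code{bondOffset} from the
#' acceptor (bond satisfied); otherwise the donor atoms ride with the ligand.
#'
#' @param nFrames number of frames
#' @param dt frame spacing (ns)
#' @param width0,widthAmp,widthPeriod pocket-width baseline (nm), breathing
#'   amplitude (nm) and period (ns)
#' @param ligandStart initial ligand position (nm, site centre at origin)
#' @param diffusion diffusion coefficient (nm^2/ns)
#' @param wellRadius binding-well radius (nm); also the ground-truth bound
#'   criterion
#' @param wellK harmonic attraction rate inside the well (1/ns)
#' @param confineR soft outer confinement radius (nm)
#' @param bondOffset hydrogen-acceptor distance while bound (nm)
#' @param minDwell minimum dwell (ns) used for the ground-truth bound
#'   intervals
#' @param hbondCutoff cutoff (nm) used for the ground-truth occupancy
#' @param seed RNG seed
#' @return list with \code{traj} (a [Trajectory-class]), \code{truth}
#'   (per-frame \code{engagement} and \code{hbond} distances, logical
#'   \code{boundFlags}, \code{boundIntervals} matrix, \code{boundFraction},
#'   \code{occupancy}), and \code{params}
#' @export
simulateTrajectory <- function(nFrames = 2001, dt = 0.25,
                               width0 = 1.01, widthAmp = 0.16,
                               widthPeriod = 100,
                               ligandStart = c(1.2, 0, 0),
                               diffusion = 0.005, wellRadius = 0.8,
                               wellK = 2, confineR = 2,
                               bondOffset = 0.19, minDwell = 5,
                               hbondCutoff = 0.25, seed = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (wellRadius <= 0) stop("wellRadius must be positive")
  times <- (seq_len(nFrames) - 1) * dt
  ctr <- c(0, 0, 0)
  acc <- ctr + c(0, 0.30, 0)             # acceptor fixed near the pocket

  lig <- matrix(NA_real_, nFrames, 3)
  lig[1, ] <- ligandStart
  step_sd <- sqrt(2 * diffusion * dt)
  noise <- .with_seed(seed,
                      matrix(stats::rnorm(3 * (nFrames - 1), 0, step_sd),
                             ncol = 3))
  if (nFrames > 1) for (k in 2:nFrames) {
    x <- lig[k - 1, ]
    d <- sqrt(sum((x - ctr)^2))
    drift <- if (d < wellRadius) -wellK * (x - ctr) * dt
    else if (d > confineR) -wellK * (1 - confineR / d) * (x - ctr) * dt
    else c(0, 0, 0)
    lig[k, ] <- x + drift + noise[k - 1, ]
  }

  bound <- sqrt(rowSums(sweep(lig, 2, ctr)^2)) < wellRadius

  w <- width0 + widthAmp * sin(2 * pi * times / widthPeriod)
  A <- cbind(-w / 2, 0, 0)
  B <- cbind(w / 2, 0, 0)

  donor <- matrix(NA_real_, nFrames, 3)
  hyd <- matrix(NA_real_, nFrames, 3)
  for (k in seq_len(nFrames)) {
    if (bound[k]) {
      v <- lig[k, ] - acc
      u <- if (sqrt(sum(v^2)) > 1e-12) v / sqrt(sum(v^2)) else c(1, 0, 0)
      donor[k, ] <- acc + u * (bondOffset + 0.10)
      hyd[k, ] <- acc + u * bondOffset
    } else {
      donor[k, ] <- lig[k, ] + c(0.15, 0, 0)
      hyd[k, ] <- lig[k, ] + c(0.15, 0.10, 0)
    }
  }
  hdist <- sqrt(rowSums(sweep(hyd, 2, acc)^2))

  # ground-truth engagement: heavy-atom (pseudo-COM + donor) centre of mass,
  # matching the definition the analyzers apply
  mCom <- c(300, 14.007)
  com <- (lig * mCom[1] + donor * mCom[2]) / sum(mCom)
  engagement <- sqrt(rowSums(sweep(com, 2, ctr)^2))
  bound <- engagement < wellRadius

  atoms <- data.frame(
    serial = 1:6,
    name = c("CA", "CA", "OD1", "C1", "N1", "H1"),
    element = c("C", "C", "O", "C", "N", "H"),
    resname = c("VAL", "GLY", "ASN", "LIG", "LIG", "LIG"),
    resseq = c(176L, 209L, 172L, 1L, 1L, 1L),
    chain = c("T", "T", "T", "L", "L", "L"),
    mass = c(12.011, 12.011, 15.999, 300, 14.007, 1.008),
    stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(6, 3, nFrames))
  for (k in seq_len(nFrames)) {
    coords[1, , k] <- A[k, ]
    coords[2, , k] <- B[k, ]
    coords[3, , k] <- acc
    coords[4, , k] <- lig[k, ]
    coords[5, , k] <- donor[k, ]
    coords[6, , k] <- hyd[k, ]
  }
  traj <- newTrajectory(atoms, coords, times = times)

  # ground-truth bound intervals: plain run scan over the dynamic flags
  iv <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  k <- 1
  while (k <= nFrames) {
    if (bound[k]) {
      j <- k
      while (j < nFrames && bound[j + 1]) j <- j + 1
      if (times[j] - times[k] >= minDwell && times[j] > times[k])
        iv <- rbind(iv, c(times[k], times[j]))
      k <- j + 1
    } else k <- k + 1
  }
  colnames(iv) <- c("start", "end")

  # ground-truth occupancy: explicit interval weights (half-ends)
  wts <- if (nFrames == 1) 1 else {
    dts <- diff(times)
    c(dts[1] / 2, (dts[-length(dts)] + dts[-1]) / 2, dts[length(dts)] / 2)
  }
  occ <- sum(wts[hdist < hbondCutoff]) / sum(wts)
  span <- if (nFrames > 1) times[nFrames] - times[1] else 1

  list(traj = traj,
       truth = list(engagement = engagement, hbond = hdist,
                    boundFlags = bound, boundIntervals = iv,
                    boundFraction = sum(iv[, 2] - iv[, 1]) / span,
                    occupancy = occ),
       params = list(nFrames = nFrames, dt = dt, width0 = width0,
                     widthAmp = widthAmp, widthPeriod = widthPeriod,
                     diffusion = diffusion, wellRadius = wellRadius,
                     wellK = wellK, confineR = confineR,
                     bondOffset = bondOffset, minDwell = minDwell,
                     hbondCutoff = hbondCutoff, seed = seed))
}

#' Simulate a model-score table with a designated best model
#'
#' Random DOPE energies (one strict minimum) and RMSD values in the range
#' typical of homology-model batches; the ground-truth best model under the
#' DOPE-primary, RMSD-tie-break rule is returned with the table.
#'
#' @param n number of models
#' @param seed RNG seed
#' @param tieDope inject a DOPE tie between the two lowest-energy models
#'   (distinct RMSDs), so the tie-break decides
#' @return list with \code{scores} (data.frame \code{model_id}, \code{rmsd},
#'   \code{dope}) and \code{bestId}
#' @export
simulateModelScores <- function(n = 10, seed = 1, tieDope = FALSE) {
  stopifnot(n >= 1)
  scores <- .with_seed(seed, {
    dope <- -227000 - sample.int(4000, n)   # distinct, one strict minimum
    rmsd <- round(stats::runif(n, 1.00, 1.20), 2)
    data.frame(model_id = seq_len(n), rmsd = rmsd, dope = dope)
  })
  if (tieDope && n >= 2) {
    o <- order(scores$dope)
    scores$dope[o[2]] <- scores$dope[o[1]]
    if (scores$rmsd[o[1]] == scores$rmsd[o[2]])
      scores$rmsd[o[2]] <- scores$rmsd[o[2]] + 0.01
  }
  key <- order(scores$dope, scores$rmsd, scores$model_id)
  list(scores = scores, bestId = scores$model_id[key[1]])
}
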