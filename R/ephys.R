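# Fast-agonist-application sweep kinetics: peak, rise, biexponential
# desensitization, steady-state / resensitization percentages, stability
# screening.  Conventions: inward current negative; readouts reported as
# magnitudes; time constants in ms; percentages of peak.

#' Subtract the pre-application baseline
#'
#' Subtracts the mean current over the 50-ms window ending at application
#' onset from every sample.
#'
#' @param trace a [SweepTrace-class]
#' @return the baseline-subtracted [SweepTrace-class]
#' @export
baselineSubtract <- function(trace) {
  win <- 0.050
  period <- 1 / trace@rate
  if (trace@appOn - trace@times[1] < win - period / 2)
    stop("need at least 50 ms of pre-application samples")
  idx <- .baseline_idx(trace)
  if (!any(idx)) stop("no samples in the pre-application baseline window")
  trace@current <- trace@current - mean(trace@current[idx])
  trace
}

# the 50-ms window ending at onset; strictly before onset, so the onset
# sample (which already carries response under a fast rise) is excluded
.baseline_idx <- function(trace) {
  trace@times > trace@appOn - 0.050 - 1e-12 &
    trace@times < trace@appOn - 1e-12
}

# response sign: sign of the extreme current within the peak search window
.response_sign <- function(trace, searchS = 0.1) {
  idx <- which(trace@times >= trace@appOn &
                 trace@times <= trace@appOn + searchS)
  y <- trace@current[idx]
  s <- sign(y[which.max(abs(y))])
  if (s == 0) 1 else s
}

#' Measure the peak response
#'
#' Finds the extremum of the current (maximal absolute amplitude) within the
#' first 100 ms of agonist application — solution exchange is fast, so the
#' peak is early, and restricting the search prevents slow resensitization
#' maxima from being misread as the peak.  The peak must exceed the
#' pre-application noise floor (5 x baseline SD).
#'
#' The extremum is located on a lightly boxcar-smoothed copy of the trace
#' (default 0.5 ms, well below the kinetics of interest), so that
#' single-sample noise excursions neither displace the peak time nor inflate
#' its amplitude; set \code{smoothMs = 0} for the raw extremum.
#'
#' @param trace a baseline-subtracted [SweepTrace-class]
#' @param searchS length of the post-onset search window (s)
#' @param smoothMs boxcar width for peak detection (ms); 0 disables
#' @return list with \code{iPeak} (magnitude, pA), \code{tPeak} (s, relative
#'   to application onset), \code{sign} (response sign)
#' @export
measurePeak <- function(trace, searchS = 0.1, smoothMs = 0.5) {
  idx <- which(trace@times >= trace@appOn &
                 trace@times <= trace@appOn + searchS)
  if (length(idx) == 0) stop("no samples in the peak search window")
  y <- trace@current[idx]
  nbox <- max(1L, round(smoothMs / 1000 * trace@rate))
  if (nbox %% 2 == 0) nbox <- nbox + 1L
  if (nbox > 1 && length(y) > nbox) {
    pad <- (nbox - 1) / 2
    ypad <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
    y <- as.numeric(stats::filter(ypad, rep(1 / nbox, nbox),
                                  sides = 2))[pad + seq_along(y)]
  }
  k <- which.max(abs(y))
  iPeak <- abs(y[k])
  base <- trace@current[.baseline_idx(trace)]
  floor_ <- max(5 * stats::sd(base), 1e-9)
  if (!is.finite(iPeak) || iPeak <= floor_)
    stop("degenerate peak: amplitude does not exceed the noise floor")
  list(iPeak = iPeak, tPeak = trace@times[idx[k]] - trace@appOn,
       sign = sign(y[k]))
}

#' 10-90 rise time
#'
#' Time between the first crossings of 10 and 90 percent of the peak
#' amplitude before the peak, with linear interpolation between samples.
#'
#' @param trace a baseline-subtracted [SweepTrace-class]
#' @param iPeak peak magnitude (pA)
#' @param tPeak peak time relative to application onset (s)
#' @return rise time in ms
#' @export
riseTime <- function(trace, iPeak, tPeak) {
  sgn <- .response_sign(trace)
  tAbs <- trace@appOn + tPeak
  idx <- which(trace@times >= trace@appOn & trace@times <= tAbs)
  if (length(idx) < 1) stop("no samples between onset and peak")
  t <- trace@times[idx]
  y <- sgn * trace@current[idx]
  crossing <- function(thr) {
    k <- which(y >= thr)[1]
    if (is.na(k)) stop("rise does not cross ", thr / iPeak * 100,
                       "% of peak before the peak")
    if (k == 1) return(t[1])
    # linear interpolation within the bracketing sample pair
    t[k - 1] + (thr - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
  }
  (crossing(0.9 * iPeak) - crossing(0.1 * iPeak)) * 1000
}

# mean of the read window (length windowMs, ending at tEnd); windowMs = 0
# reads the point by linear interpolation
.window_mean <- function(trace, tEnd, windowMs, sgn) {
  if (tEnd < trace@times[1] ||
      tEnd > trace@times[length(trace@times)] + 0.5 / trace@rate)
    stop("read window at ", signif(tEnd, 6), " s lies outside the trace")
  if (windowMs == 0)
    return(sgn * stats::approx(trace@times, trace@current, tEnd,
                               rule = 2)$y)
  idx <- which(trace@times > tEnd - windowMs / 1000 & trace@times <= tEnd)
  if (length(idx) == 0) stop("no samples in the read window at ", tEnd, " s")
  mean(sgn * trace@current[idx])
}

#' Steady-state current as percent of peak
#'
#' The current remaining 200 ms after the peak, as a percentage of the peak:
#' \eqn{I_{200ms} / I_{peak} \times 100}.  The 200-ms read is the mean over a
#' short window ending there (default 5 ms; 0 = single-point read by
#' interpolation), which resists sampling noise.
#'
#' @inheritParams riseTime
#' @param windowMs read-window length (ms); 0 for a point read
#' @return steady-state percentage
#' @export
steadyStatePct <- function(trace, iPeak, tPeak, windowMs = 5) {
  sgn <- .response_sign(trace)
  i200 <- .window_mean(trace, trace@appOn + tPeak + 0.2, windowMs, sgn)
  i200 / iPeak * 100
}

#' Resensitization as percent of peak
#'
#' The slow TARP-dependent current recovery between the 200-ms read and the
#' end of a sustained (>= 5 s) agonist application:
#' \eqn{(I_{5s} - I_{200ms}) / I_{peak} \times 100}.  May be negative when
#' the current sags instead.
#'
#' @inheritParams steadyStatePct
#' @return resensitization percentage
#' @export
resensitizationPct <- function(trace, iPeak, tPeak, windowMs = 5) {
  if (trace@appOff - trace@appOn < 5 - 1e-9)
    stop("resensitization needs an agonist application of at least 5 s")
  sgn <- .response_sign(trace)
  i200 <- .window_mean(trace, trace@appOn + tPeak + 0.2, windowMs, sgn)
  i5 <- .window_mean(trace, trace@appOff, windowMs, sgn)
  (i5 - i200) / iPeak * 100
}

#' Biexponential desensitization fit
#'
#' Fits \eqn{I(\Delta t) = a_1 e^{-\Delta t/\tau_1} + a_2 e^{-\Delta t/\tau_2}
#' + c} over the first 200 ms after the peak (magnitude current, \eqn{\Delta
#' t} in ms), with \eqn{a_1, a_2 \ge 0} and \eqn{0.1 \le \tau_1 \le \tau_2
#' \le 1000} ms, and reports the amplitude-weighted time constant
#' \eqn{\tau_w = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)}.  The constant offset c
#' absorbs the steady-state plateau.  Initialization is deterministic: c from
#' the window tail, a log-linear single-exponential seed for the time
#' constants, and a fixed multi-start grid around it; the best
#' residual-sum-of-squares solution wins.  \code{fitOk} is FALSE (never an
#' exception) when the signal is flat, a time-constant bound is hit, or the
#' fit leaves most variance unexplained.
#'
#' @inheritParams riseTime
#' @param windowMs fit window after the peak (ms)
#' @return list with \code{a1}, \code{a2} (pA), \code{tau1}, \code{tau2},
#'   \code{tauW} (ms), \code{fitOk}
#' @export
fitDesensitization <- function(trace, tPeak, windowMs = 200) {
  sgn <- .response_sign(trace)
  tAbs <- trace@appOn + tPeak
  period <- 1 / trace@rate
  # fit only within the agonist application: past appOff the current
  # deactivates rather than desensitizes
  idx <- which(trace@times > tAbs &
                 trace@times <= min(tAbs + windowMs / 1000, trace@appOff))
  if (length(idx) < 10 ||
      trace@times[idx[length(idx)]] < tAbs + windowMs / 1000 - 2 * period)
    stop("need ", windowMs, " ms of samples after the peak ",
         "within the application window")
  dt <- (trace@times[idx] - tAbs) * 1000     # ms
  y <- sgn * trace@current[idx]

  bad <- list(a1 = NA_real_, a2 = NA_real_, tau1 = NA_real_,
              tau2 = NA_real_, tauW = NA_real_, fitOk = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps) return(bad)

  c0 <- mean(y[dt > windowMs - 10])
  y0 <- max(y[1] - c0, .Machine$double.eps)
  # log-linear seed for a single-exponential decay toward c0
  pos <- y - c0 > y0 * 0.05
  tau0 <- if (sum(pos) >= 2) {
    b <- stats::coef(stats::lm(log(y[pos] - c0) ~ dt[pos]))[2]
    if (is.finite(b) && b < 0) -1 / b else windowMs / 5
  } else windowMs / 5
  tau0 <- min(max(tau0, 0.5), 500)

  starts <- list(
    c(a1 = 0.7 * y0, tau1 = tau0 / 2, a2 = 0.3 * y0, tau2 = 2 * tau0),
    c(a1 = 0.5 * y0, tau1 = tau0, a2 = 0.5 * y0, tau2 = 5 * tau0),
    c(a1 = 0.9 * y0, tau1 = tau0, a2 = 0.1 * y0, tau2 = 10 * tau0),
    c(a1 = 0.3 * y0, tau1 = tau0 / 5, a2 = 0.7 * y0, tau2 = tau0),
    c(a1 = 0.5 * y0, tau1 = 2, a2 = 0.5 * y0, tau2 = 50),
    c(a1 = 0.5 * y0, tau1 = 10, a2 = 0.5 * y0, tau2 = 200))

  lower <- c(0, 0.1, 0, 0.1, -Inf)
  upper <- c(Inf, 1000, Inf, 1000, Inf)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-dt / tau1) + a2 * exp(-dt / tau2) + c,
        start = c(as.list(pmin(pmax(st, lower[1:4] + 1e-3),
                               c(Inf, 999, Inf, 999))), list(c = c0)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(bad)

  p <- stats::coef(best$fit)
  a <- c(p["a1"], p["a2"]); tau <- c(p["tau1"], p["tau2"])
  o <- order(tau)
  a <- unname(a[o]); tau <- unname(tau[o])
  tauW <- if (sum(a) > 0) sum(a * tau) / sum(a) else NA_real_

  r2 <- 1 - best$sse / sst
  bound_hit <- tau[1] <= 0.1 * 1.001 || tau[2] >= 1000 * 0.999
  amp_ok <- sum(a) > 1e-8 && is.finite(tauW)
  ok <- r2 >= 0.5 && !bound_hit && amp_ok
  list(a1 = a[1], a2 = a[2], tau1 = tau[1], tau2 = tau[2],
       tauW = tauW, fitOk = ok)
}

#' Full kinetic analysis of one sweep
#'
#' Runs the whole readout chain — baseline subtraction, peak, 10-90 rise,
#' biexponential desensitization fit, steady-state and (when the application
#' lasts >= 5 s) resensitization percentages — and returns a
#' [KineticsResult-class].
#'
#' @param trace a [SweepTrace-class]
#' @param windowMs read-window length for the 200-ms and end-of-application
#'   current reads (ms); 0 for point reads
#' @param smoothMs peak-detection boxcar width (ms), see [measurePeak()]
#' @return a [KineticsResult-class]
#' @export
analyzeSweep <- function(trace, windowMs = 5, smoothMs = 0.5) {
  trace <- baselineSubtract(trace)
  pk <- measurePeak(trace, smoothMs = smoothMs)
  sgn <- pk$sign
  rise <- tryCatch(riseTime(trace, pk$iPeak, pk$tPeak),
                   error = function(e) NA_real_)
  fit <- fitDesensitization(trace, pk$tPeak)
  ss <- steadyStatePct(trace, pk$iPeak, pk$tPeak, windowMs)
  res <- if (trace@appOff - trace@appOn >= 5 - 1e-9)
    resensitizationPct(trace, pk$iPeak, pk$tPeak, windowMs)
  else NA_real_
  i200 <- .window_mean(trace, trace@appOn + pk$tPeak + 0.2, windowMs, sgn)
  i5 <- tryCatch(.window_mean(trace, trace@appOff, windowMs, sgn),
                 error = function(e) NA_real_)
  new("KineticsResult", iPeak = pk$iPeak, tPeak = pk$tPeak, i200ms = i200,
      i5s = i5, a1 = fit$a1, a2 = fit$a2, tau1 = fit$tau1, tau2 = fit$tau2,
      tauW = fit$tauW, steadyStatePct = ss, resensitizationPct = res,
      rise1090 = rise, fitOk = fit$fitOk)
}

#' Screen sweeps for peak-current stability
#'
#' A recording qualifies for quantification only when its peak current is
#' stable for at least three consecutive sweeps; "stable" means every peak in
#' the run lies within a tolerance (default 10 percent) of that run's mean
#' peak.  Returns the earliest qualifying run, extended as far as it remains
#' stable.
#'
#' @param peaks numeric vector of per-sweep peak magnitudes (pA), or a list
#'   of [SweepTrace-class] objects (peaks are then measured)
#' @param tol relative tolerance around the run mean (default 0.10)
#' @return list with \code{accepted}, and when accepted \code{start},
#'   \code{end} (sweep indices of the qualifying run)
#' @export
stabilityFilter <- function(peaks, tol = 0.10) {
  if (is.list(peaks))
    peaks <- vapply(peaks, function(tr)
      measurePeak(baselineSubtract(tr))$iPeak, numeric(1))
  n <- length(peaks)
  if (n < 3) return(list(accepted = FALSE, start = NA_integer_,
                         end = NA_integer_, peaks = peaks))
  ok_run <- function(i, j) {
    m <- mean(peaks[i:j])
    all(abs(peaks[i:j] - m) <= tol * m)
  }
  for (i in seq_len(n - 2)) {
    if (!ok_run(i, i + 2)) next
    j <- i + 2
    while (j < n && ok_run(i, j + 1)) j <- j + 1
    return(list(accepted = TRUE, start = i, end = j, peaks = peaks))
  }
  list(accepted = FALSE, start = NA_integer_, end = NA_integer_,
       peaks = peaks)
}
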