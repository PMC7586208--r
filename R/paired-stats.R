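# Paired pre/post-drug statistics for sweep readouts.

# Exact two-sided signed-rank p by dynamic programming over the 2^n equally
# likely sign assignments.  `ranks2` are the (tie-averaged) ranks doubled, so
# they are integers; W is the sum of positive-difference ranks.
.signrank_exact_p <- function(w, ranks2) {
  total <- sum(ranks2)
  counts <- c(1, rep(0, total))          # counts[s + 1] = assignments with 2W = s
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(ranks2)
  w2 <- round(2 * w)
  ple <- sum(probs[seq_len(w2 + 1)])
  pge <- sum(probs[seq.int(w2 + 1, total + 1)])
  min(1, 2 * min(ple, pge))
}

#' Paired pre/post comparison of a sweep readout
#'
#' Compares paired per-cell values before and after modulator application:
#' a two-sided Wilcoxon signed-rank test on the raw pairs (zero differences
#' dropped, tied absolute differences given averaged ranks, exact null
#' distribution for n <= 25), and a two-sided one-sample t test of the
#' normalized values (post/pre x 100) against 100 percent.  Effect summaries
#' are mean +/- SD.
#'
#' @param pre,post equal-length numeric vectors of per-cell values
#'   (vehicle and drug conditions), n >= 3
#' @return list with \code{n}; Wilcoxon \code{W}, \code{wilcoxonP},
#'   \code{degenerate} (all differences zero); \code{preMean}, \code{preSD},
#'   \code{postMean}, \code{postSD}; \code{normalizedMean},
#'   \code{normalizedSD}, \code{tStat}, \code{tP} (vs 100 percent)
#' @examples
#' pairedCompare(pre = c(10, 12, 9, 11, 10), post = c(4, 5, 3, 6, 5))
#' @export
pairedCompare <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must be paired (equal length)")
  n <- length(pre)
  if (n < 3) stop("paired comparison needs at least 3 pairs")

  d <- post - pre
  nz <- d[d != 0]
  if (length(nz) == 0) {
    W <- NA_real_; wp <- NA_real_; degenerate <- TRUE
  } else {
    degenerate <- FALSE
    r <- rank(abs(nz))
    W <- sum(r[nz > 0])
    wp <- if (length(nz) <= 25) {
      .signrank_exact_p(W, as.integer(round(2 * r)))
    } else {
      # normal approximation with tie correction and continuity correction
      m <- length(nz)
      mu <- m * (m + 1) / 4
      tie <- table(r)
      sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie^3 - tie) / 48
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      min(1, 2 * stats::pnorm(-abs(z)))
    }
  }

  if (any(pre == 0)) {
    warning("pre value(s) of zero: normalization undefined for those pairs")
    keep <- pre != 0
  } else keep <- rep(TRUE, n)
  norm <- post[keep] / pre[keep] * 100
  nm <- mean(norm); nsd <- stats::sd(norm)
  if (length(norm) >= 2 && nsd > 0) {
    tt <- stats::t.test(norm, mu = 100)
    tStat <- unname(tt$statistic); tP <- tt$p.value
  } else {
    tStat <- if (isTRUE(all.equal(nm, 100))) 0 else sign(nm - 100) * Inf
    tP <- if (tStat == 0) 1 else 0
  }

  list(n = n, W = W, wilcoxonP = wp, degenerate = degenerate,
       preMean = mean(pre), preSD = stats::sd(pre),
       postMean = mean(post), postSD = stats::sd(post),
       normalizedMean = nm, normalizedSD = nsd, tStat = tStat, tP = tP)
}
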