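# Beat segmentation and twitch-kinetics parameters.
#
# Per beat, with B_m the peak force (above the diastolic baseline), T_m its
# time, T_1 the last upward crossing of 0.2 B_m before the peak ("beating
# start") and T_2 the first downward crossing after it:
#   F_c = 0.8 B_m / (T_m - T_1)     contraction velocity (N/s)
#   F_r = 0.8 B_m / (T_2 - T_m)     relaxation velocity (N/s)
#   FI  = integral_{T_1}^{T_2} B dt force-time integral (N s)
# and the normalized (amplitude-free) forms F'_c = 0.8/(T_m - T_1),
# F'_r = 0.8/(T_2 - T_m), FI' = FI / B_m.  Atrial-like beats have larger
# F'_c and F'_r and smaller FI' than ventricular-like beats.

#' Segment a force trace into beats
#'
#' Finds local maxima whose prominence is at least \code{min_prominence}
#' times the global amplitude range and at least \code{refractory} seconds
#' apart (the larger peak wins a conflict), and returns disjoint analysis
#' windows split at the minima between accepted peaks.
#'
#' @param force A \code{\link{force_trace}}.
#' @param min_prominence Prominence threshold as a fraction of the global
#'   range (default 0.5).
#' @param refractory Minimum peak separation in seconds (default 0.2).
#' @return A data frame with one row per beat: \code{start}, \code{end}
#'   (sample indices), \code{peak} (index of the maximum). Empty (with a
#'   warning) if no qualifying peaks exist.
#' @export
segment_beats <- function(force, min_prominence = 0.5, refractory = 0.2) {
  stopifnot(inherits(force, "force_trace"))
  x <- force$values
  n <- length(x)
  rng <- diff(range(x))
  empty <- data.frame(start = integer(0), end = integer(0), peak = integer(0))
  if (rng == 0 || n < 3L) {
    warning("no qualifying peaks found", call. = FALSE)
    return(empty)
  }
  cand <- which(diff(sign(diff(x))) < 0) + 1L   # strict local maxima
  if (!length(cand)) {
    warning("no qualifying peaks found", call. = FALSE)
    return(empty)
  }
  # prominence: drop to the highest of the two saddle minima toward the
  # nearest higher peak (or record edge) on each side
  prom <- vapply(cand, function(p) {
    hi_l <- which(x[seq_len(p - 1L)] > x[p])
    lseg <- if (length(hi_l)) max(hi_l):p else 1L:p
    hi_r <- which(x[(p + 1L):n] > x[p])
    rseg <- if (length(hi_r)) p:(p + min(hi_r)) else p:n
    x[p] - max(min(x[lseg]), min(x[rseg]))
  }, numeric(1))
  keep <- cand[prom >= min_prominence * rng]
  if (!length(keep)) {
    warning("no qualifying peaks found", call. = FALSE)
    return(empty)
  }
  # refractory: greedy by height
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  min_gap <- refractory * force$fs
  for (p in ord)
    if (!length(sel) || all(abs(sel - p) >= min_gap)) sel <- c(sel, p)
  sel <- sort(sel)
  # window boundaries: minimum between consecutive peaks
  bounds <- integer(length(sel) + 1L)
  bounds[1L] <- 1L
  bounds[length(sel) + 1L] <- n
  if (length(sel) > 1L)
    for (i in seq_len(length(sel) - 1L)) {
      seg <- sel[i]:sel[i + 1L]
      bounds[i + 1L] <- seg[which.min(x[seg])]
    }
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L], peak = sel)
}

# linear-interpolated crossing time of level y0 between samples i and i+1
.cross_time <- function(t, x, i, y0) {
  t[i] + (y0 - x[i]) / (x[i + 1L] - x[i]) * (t[i + 1L] - t[i])
}

#' Twitch-kinetics parameters of one beat
#'
#' Locates the peak \code{B_m} and the 20-percent threshold crossings
#' \code{T_1} (last upward crossing before the peak) and \code{T_2} (first
#' downward crossing after), with crossing times linearly interpolated
#' between samples, and computes the contraction velocity \code{F_c},
#' relaxation velocity \code{F_r}, force-time integral \code{FI}
#' (trapezoidal, with interpolated endpoints) and their normalized forms.
#'
#' @param force A \code{\link{force_trace}}.
#' @param window Either a row of \code{\link{segment_beats}} output or an
#'   integer vector \code{c(start, end)} of sample indices.
#' @param baseline_subtract Measure forces relative to the window minimum
#'   (diastolic baseline) before thresholding and integrating (default
#'   TRUE; the static pre-stretch offset would otherwise shift the
#'   20-percent threshold).
#' @return A one-row data frame of class \code{"beat_metrics"} with
#'   \code{B_m} (N), \code{T_1}, \code{T_m}, \code{T_2} (s), \code{F_c},
#'   \code{F_r} (N/s), \code{FI} (N s), \code{F_c_norm}, \code{F_r_norm}
#'   (1/s), \code{FI_norm} (s) and \code{baseline} (N).
#' @export
beat_parameters <- function(force, window, baseline_subtract = TRUE) {
  stopifnot(inherits(force, "force_trace"))
  if (is.data.frame(window)) window <- c(window$start[1L], window$end[1L])
  i0 <- as.integer(window[1L]); i1 <- as.integer(window[2L])
  if (i0 < 1L || i1 > length(force$values) || i1 - i0 < 2L)
    stop("invalid beat window", call. = FALSE)
  t <- force$times[i0:i1]
  x <- force$values[i0:i1]
  base <- if (baseline_subtract) min(x) else 0
  x <- x - base
  ip <- which.max(x)
  B_m <- x[ip]
  if (B_m <= 0) stop("degenerate beat: no positive force in window",
                     call. = FALSE)
  T_m <- t[ip]
  thr <- 0.2 * B_m

  up <- which(x[seq_len(ip - 1L)] < thr & x[2:ip] >= thr)
  if (!length(up))
    stop("degenerate beat: 20% threshold never crossed on the rising side",
         call. = FALSE)
  iu <- up[length(up)]
  T_1 <- .cross_time(t, x, iu, thr)

  nn <- length(x)
  dn <- which(x[ip:(nn - 1L)] >= thr & x[(ip + 1L):nn] < thr)
  if (!length(dn))
    stop("degenerate beat: 20% threshold never crossed on the falling side",
         call. = FALSE)
  id <- ip - 1L + dn[1L]
  T_2 <- .cross_time(t, x, id, thr)

  # trapezoidal integral over [T_1, T_2]; endpoint values are exactly thr
  ti <- c(T_1, t[(iu + 1L):id], T_2)
  xi <- c(thr, x[(iu + 1L):id], thr)
  FI <- sum(diff(ti) * (utils::head(xi, -1L) + utils::tail(xi, -1L)) / 2)

  F_c <- 0.8 * B_m / (T_m - T_1)
  F_r <- 0.8 * B_m / (T_2 - T_m)
  out <- data.frame(B_m = B_m, T_1 = T_1, T_m = T_m, T_2 = T_2,
                    F_c = F_c, F_r = F_r, FI = FI,
                    F_c_norm = F_c / B_m, F_r_norm = F_r / B_m,
                    FI_norm = FI / B_m, baseline = base)
  class(out) <- c("beat_metrics", "data.frame")
  out
}

#' Beat metrics for every segmented beat
#'
#' Convenience wrapper: segments the trace and computes
#' \code{\link{beat_parameters}} per window, skipping degenerate beats
#' (typically truncated first/last windows) with a message.
#'
#' @inheritParams segment_beats
#' @param baseline_subtract See \code{\link{beat_parameters}}.
#' @return A \code{"beat_metrics"} data frame with one row per usable beat.
#' @export
beat_metrics <- function(force, min_prominence = 0.5, refractory = 0.2,
                         baseline_subtract = TRUE) {
  win <- segment_beats(force, min_prominence, refractory)
  rows <- list()
  for (i in seq_len(nrow(win))) {
    m <- tryCatch(beat_parameters(force, win[i, ], baseline_subtract),
                  error = function(e) NULL)
    if (!is.null(m)) rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) < nrow(win))
    message(nrow(win) - length(rows), " degenerate beat window(s) skipped")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  class(out) <- c("beat_metrics", "data.frame")
  out
}

#' Summarize beat metrics (mean, SD, n per parameter)
#'
#' @param metrics A \code{"beat_metrics"} data frame (>= 1 row).
#' @return A data frame of class \code{"beat_summary"} with one row per
#'   parameter and columns \code{mean}, \code{sd}, \code{n}. With a single
#'   beat, SD is reported as 0 with a warning.
#' @export
beat_summary <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0)
    stop("'metrics' must contain at least one beat", call. = FALSE)
  pars <- c("B_m", "T_1", "T_m", "T_2", "F_c", "F_r", "FI",
            "F_c_norm", "F_r_norm", "FI_norm")
  n <- nrow(metrics)
  if (n == 1L) warning("single beat: SD reported as 0", call. = FALSE)
  out <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(metrics[[p]]), numeric(1)),
    sd = if (n == 1L) rep(0, length(pars))
         else vapply(pars, function(p) stats::sd(metrics[[p]]), numeric(1)),
    n = n, row.names = NULL)
  class(out) <- c("beat_summary", "data.frame")
  out
}

.summary_mean <- function(s, par) s$mean[match(par, s$parameter)]

#' Ordinal subtype-shift comparison of two beat summaries
#'
#' Compares the normalized kinetics of condition \code{b} relative to
#' reference \code{a}. Atrial-like beating has larger normalized
#' contraction and relaxation velocities and a smaller normalized
#' force-time integral than ventricular-like beating, so the verdict is
#' \code{"atrial-shifted"} when both velocities increase and FI' decreases,
#' \code{"ventricular-shifted"} when both velocities decrease and FI'
#' increases, and \code{"indeterminate"} otherwise. The report is purely
#' ordinal: no significance claim is made.
#'
#' @param a,b \code{\link{beat_summary}} objects (reference, comparison).
#' @return A list of class \code{"subtype_shift"} with per-parameter deltas
#'   (\code{b - a}), signs, and \code{verdict}.
#' @export
subtype_shift <- function(a, b) {
  stopifnot(inherits(a, "beat_summary"), inherits(b, "beat_summary"))
  pars <- c("F_c_norm", "F_r_norm", "FI_norm")
  delta <- vapply(pars, function(p) .summary_mean(b, p) - .summary_mean(a, p),
                  numeric(1))
  s <- sign(delta)
  verdict <- if (s[["F_c_norm"]] > 0 && s[["F_r_norm"]] > 0 &&
                 s[["FI_norm"]] < 0) {
    "atrial-shifted"
  } else if (s[["F_c_norm"]] < 0 && s[["F_r_norm"]] < 0 &&
             s[["FI_norm"]] > 0) {
    "ventricular-shifted"
  } else "indeterminate"
  structure(list(delta = delta, sign = s, verdict = verdict),
            class = "subtype_shift")
}

#' @export
print.subtype_shift <- function(x, ...) {
  cat("Subtype shift (b relative to a):\n")
  for (p in names(x$delta))
    cat(sprintf("  %-9s delta = %+.4g\n", p, x$delta[[p]]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
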