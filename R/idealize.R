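#' Container for cell-attached single-channel sweeps
#'
#' Holds a set of equal-length current sweeps recorded under the standard
#' single-pulse protocol (hold -80 mV, 2-s test step to 0 mV repeated every
#' 5 s, ~50 sweeps per patch, 10 kHz sampling, 2 kHz analog low-pass).
#' Openings are represented as positive deflections; inward unitary currents
#' should be flipped at ingestion (`flip_polarity`).
#'
#' @param sweeps list of numeric current vectors (pA), all the same length,
#'   or a samples-by-sweeps numeric matrix.
#' @param fs sampling rate (Hz).
#' @param unitary_current unitary current amplitude (pA), > 0.
#' @param filter_hz anti-alias low-pass corner (Hz, metadata); must satisfy
#'   `fs > 2 * filter_hz`.
#' @param flip_polarity multiply traces by -1 (inward openings recorded as
#'   negative current).
#' @return A `sweep_set` object.
#' @export
sweep_set <- function(sweeps, fs = 10000, unitary_current = 1.0,
                      filter_hz = 2000, flip_polarity = FALSE) {
  if (is.matrix(sweeps)) sweeps <- lapply(seq_len(ncol(sweeps)), function(j) sweeps[, j])
  stopifnot(is.list(sweeps), length(sweeps) >= 1L)
  len <- vapply(sweeps, length, integer(1))
  if (length(unique(len)) != 1L) stop("all sweeps must have equal length")
  if (fs <= 2 * filter_hz) stop("fs must exceed twice the filter corner")
  if (unitary_current <= 0) stop("unitary_current must be > 0")
  if (flip_polarity) sweeps <- lapply(sweeps, function(x) -x)
  structure(list(sweeps = sweeps, fs = fs, unitary_current = unitary_current,
                 filter_hz = filter_hz, duration_s = len[1] / fs),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: %d sweeps x %.3g s @ %g Hz (unitary %.3g pA)\n",
              length(x$sweeps), x$duration_s, x$fs, x$unitary_current))
  invisible(x)
}

#' Estimate the closed-level baseline of a sweep
#'
#' The baseline is the current of the closed (zero open channels) level,
#' taken as the lowest local mode of a kernel density estimate of the sweep's
#' samples. Modes below 1% of the tallest peak are ignored, and modes closer
#' than half a unitary current are merged (keeping the taller). The lowest
#' surviving mode is used even in high-open-probability patches where the
#' closed level is not the global mode. If two candidate modes have nearly
#' equal height (a bimodal tie) the lower one is chosen with a warning.
#'
#' @param x numeric current trace (pA).
#' @param unitary_current unitary amplitude (pA).
#' @return Baseline current (pA).
#' @export
estimate_baseline <- function(x, unitary_current) {
  if (anyNA(x) || any(!is.finite(x))) stop("trace contains NA/non-finite samples")
  if (stats::sd(x) == 0) stop("flat trace: baseline undefined")
  bw <- min(max(stats::bw.nrd0(x), unitary_current / 50), unitary_current / 6)
  d <- stats::density(x, bw = bw, n = 1024)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  px <- d$x[is_peak]
  py <- y[is_peak]
  keep <- py >= 0.01 * max(py)
  px <- px[keep]; py <- py[keep]
  if (length(px) == 0L) stop("no density mode found")
  # merge modes closer than half a unitary current, keeping the taller
  ord <- order(px)
  px <- px[ord]; py <- py[ord]
  i <- 1L
  while (i < length(px)) {
    if (px[i + 1L] - px[i] < 0.5 * unitary_current) {
      drop <- if (py[i] >= py[i + 1L]) i + 1L else i
      px <- px[-drop]; py <- py[-drop]
    } else i <- i + 1L
  }
  if (length(px) >= 2L && abs(py[1] - py[2]) < 0.001 * max(py))
    warning("ambiguous baseline (near-tied modes); choosing the lower mode")
  px[1]
}

#' Idealize a single sweep by the half-amplitude criterion
#'
#' Quantizes a raw current sweep into integer open-channel levels: after
#' per-sweep baseline estimation, a sample is assigned the largest level `k`
#' with `|I - baseline| >= (k - 0.5) * unitary_current` (the half-amplitude
#' event-detection rule with the event threshold at half the unitary
#' amplitude), clipped to `[0, n_max]`. Dwells shorter than `min_dwell`
#' samples are merged into the preceding level (an initial short dwell
#' adopts the following level) to suppress noise-driven single-sample
#' flickers given the 2 kHz analog filter.
#'
#' @param sweep numeric current trace (pA), length > 10.
#' @param unitary_current unitary amplitude (pA), > 0.
#' @param n_max maximum level, or `NULL` to use the maximum observed.
#' @param fs sampling rate (Hz), used for dwell times.
#' @param min_dwell minimum dwell length in samples (default 2, i.e. 0.2 ms
#'   at 10 kHz).
#' @param baseline optional known baseline (pA); skips estimation.
#' @return An `idealized_sweep`: list with integer `levels`, a `dwells`
#'   data frame (`level`, `start_s`, `duration_s`), `fs`, `baseline`,
#'   `n_max`.
#' @export
idealize_sweep <- function(sweep, unitary_current, n_max = NULL, fs = 10000,
                           min_dwell = 2, baseline = NULL) {
  if (length(sweep) <= 10L) stop("trace must contain more than 10 samples")
  if (unitary_current <= 0) stop("unitary_current must be > 0")
  if (anyNA(sweep) || any(!is.finite(sweep))) stop("trace contains NA/non-finite samples")
  if (is.null(baseline)) baseline <- estimate_baseline(sweep, unitary_current)
  lev <- floor(abs(sweep - baseline) / unitary_current + 0.5)
  if (is.null(n_max)) n_max <- max(lev)
  lev <- as.integer(pmin(pmax(lev, 0), n_max))

  if (min_dwell > 1L) lev <- merge_short_dwells(lev, as.integer(min_dwell))

  r <- rle(lev)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  dwells <- data.frame(level = r$values, start_s = starts / fs,
                       duration_s = r$lengths / fs)
  structure(list(levels = lev, dwells = dwells, fs = fs,
                 baseline = baseline, n_max = as.integer(n_max)),
            class = "idealized_sweep")
}

#' Idealize every sweep of a sweep set
#'
#' @param ss a [sweep_set()].
#' @param ... passed to [idealize_sweep()].
#' @return An `idealized_set`: list of `idealized_sweep` objects with
#'   attributes `fs`, `unitary_current`, `duration_s`.
#' @export
idealize_sweeps <- function(ss, ...) {
  stopifnot(inherits(ss, "sweep_set"))
  out <- lapply(ss$sweeps, idealize_sweep,
                unitary_current = ss$unitary_current, fs = ss$fs, ...)
  structure(out, fs = ss$fs, unitary_current = ss$unitary_current,
            duration_s = ss$duration_s, class = "idealized_set")
}

window_index <- function(window, fs, n) {
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n, ceiling(window[2] * fs))
  if (i1 <= i0) stop("empty analysis window")
  i0:i1
}

default_window <- function(duration_s, edge_s = 0.005) {
  c(edge_s, duration_s - edge_s)
}

#' Single-channel activity statistics (nPo, n, Po, ensemble average)
#'
#' Computes the patch activity measures from a set of idealized sweeps over
#' an analysis window (default: the depolarizing step excluding the first
#' and last 5 ms, to drop capacitive transients). `nPo` is the time average
#' of the open-channel level within the window, averaged across sweeps; the
#' channel count `n` is the maximum simultaneous level observed in the patch
#' across all sweeps; `Po = nPo / n`; the ensemble average is the
#' across-sweep mean of `level * unitary_current` per sample. A patch with
#' no openings at all is assigned `n = 1` by convention and flagged.
#'
#' @param idealized an `idealized_set` (or plain list of `idealized_sweep`).
#' @param unitary_current unitary amplitude (pA); defaults to the set's.
#' @param window two-element numeric window (s) within the step.
#' @return A `channel_activity_stats` list: `nPo`, `n_channels`, `Po`,
#'   `ensemble_average` (pA per sample over the full sweep),
#'   `no_openings` flag, `window`.
#' @export
activity_stats <- function(idealized, unitary_current = NULL, window = NULL) {
  if (inherits(idealized, "idealized_sweep")) idealized <- list(idealized)
  stopifnot(length(idealized) >= 1L)
  fs <- idealized[[1]]$fs
  nsamp <- length(idealized[[1]]$levels)
  if (is.null(unitary_current))
    unitary_current <- attr(idealized, "unitary_current")
  if (is.null(unitary_current)) unitary_current <- 1.0
  if (is.null(window)) window <- default_window(nsamp / fs)
  idx <- window_index(window, fs, nsamp)

  lev_mat <- vapply(idealized, function(s) as.numeric(s$levels), numeric(nsamp))
  nPo <- mean(colMeans(lev_mat[idx, , drop = FALSE]))
  n_channels <- max(lev_mat[idx, , drop = FALSE])
  no_openings <- n_channels == 0
  if (no_openings) n_channels <- 1
  structure(list(nPo = nPo, n_channels = as.integer(n_channels),
                 Po = nPo / n_channels,
                 ensemble_average = rowMeans(lev_mat) * unitary_current,
                 no_openings = no_openings, window = window),
            class = "channel_activity_stats")
}

#' @export
print.channel_activity_stats <- function(x, ...) {
  cat(sprintf("nPo = %.4g, n = %d, Po = %.4g%s\n", x$nPo, x$n_channels, x$Po,
              if (x$no_openings) " [no openings: n = 1 by convention]" else ""))
  invisible(x)
}

#' Coupled (cooperative) opening metrics
#'
#' A coupled opening is an upward level transition with a jump of at least
#' `min_jump` channels within one sampling interval, the signature of two or
#' more channels opening in unison. `coupled_frequency` is the number of such
#' events per second of analyzed depolarization (pooled across sweeps);
#' `coupled_strength` is the mean jump size (channels) over coupled events
#' (0 when none occur). The fraction of all opening transitions that are
#' coupled is reported as `coupled_fraction`.
#'
#' @param idealized an `idealized_set` (or list of `idealized_sweep`).
#' @param window analysis window (s); defaults as in [activity_stats()].
#' @param min_jump minimum simultaneous jump to call an event coupled
#'   (default 2).
#' @return List: `coupled_frequency` (events/s), `coupled_strength`
#'   (channels), `coupled_fraction`, `n_coupled`, `n_openings`.
#' @export
coupled_event_metrics <- function(idealized, window = NULL, min_jump = 2) {
  if (inherits(idealized, "idealized_sweep")) idealized <- list(idealized)
  fs <- idealized[[1]]$fs
  nsamp <- length(idealized[[1]]$levels)
  if (is.null(window)) window <- default_window(nsamp / fs)
  idx <- window_index(window, fs, nsamp)

  jumps <- unlist(lapply(idealized, function(s) {
    d <- diff(s$levels[idx])
    d[d > 0]
  }))
  coupled <- jumps[jumps >= min_jump]
  total_s <- length(idealized) * (length(idx) - 1L) / fs
  list(coupled_frequency = length(coupled) / total_s,
       coupled_strength = if (length(coupled)) mean(coupled) else 0,
       coupled_fraction = if (length(jumps)) length(coupled) / length(jumps) else 0,
       n_coupled = length(coupled), n_openings = length(jumps))
}
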