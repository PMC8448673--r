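#' Whole-cell voltage-step recording
#'
#' One trace of membrane current per test potential under the standard I_K
#' protocol (hold -70 mV, steps to +80 mV in +10 mV increments). Pulse
#' duration is configurable because published protocols vary between 200 and
#' 600 ms; the default is 600 ms.
#'
#' @param traces samples-by-voltages numeric matrix of current (pA).
#' @param voltages test potentials (mV), strictly increasing, one per column.
#' @param cm_pF membrane capacitance (pF), > 0.
#' @param fs sampling rate (Hz).
#' @param condition `"control"` or `"IBTx"`.
#' @return A `step_recording` object.
#' @export
step_recording <- function(traces, voltages, cm_pF, fs = 20000,
                           condition = c("control", "IBTx")) {
  condition <- match.arg(condition)
  stopifnot(is.matrix(traces), ncol(traces) == length(voltages))
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly increasing")
  if (!is.finite(cm_pF) || cm_pF <= 0) stop("membrane capacitance must be > 0")
  structure(list(traces = traces, voltages = voltages, cm_pF = cm_pF,
                 fs = fs, condition = condition,
                 pulse_s = nrow(traces) / fs),
            class = "step_recording")
}

#' Extract a current-voltage (I-V) curve of current densities
#'
#' Per test potential, summarizes the current over the pulse after blanking
#' the first `blank_ms` (capacitive transient), then divides by the membrane
#' capacitance to give a density in pA/pF. `statistic = "peak"` takes the
#' signed value of the largest absolute current; `"mean_late"` averages the
#' last 50 ms of the pulse. Traces reaching `clip_limit` (amplifier
#' saturation) are excluded with a warning and reported as `NA`.
#'
#' @param rec a [step_recording()].
#' @param blank_ms initial blanking interval (ms), must be shorter than the
#'   pulse.
#' @param statistic `"peak"` or `"mean_late"`.
#' @param clip_limit optional saturation level (pA); `NULL` disables the
#'   check.
#' @return An `iv_curve`: data frame with `voltage_mV`, `current_pA`,
#'   `density_pA_pF`; attributes `component`, `cm_pF`, `condition`.
#' @export
extract_iv <- function(rec, blank_ms = 5, statistic = c("peak", "mean_late"),
                       clip_limit = NULL) {
  stopifnot(inherits(rec, "step_recording"))
  statistic <- match.arg(statistic)
  if (blank_ms / 1000 >= rec$pulse_s) stop("blank_ms must be shorter than the pulse")
  i0 <- floor(blank_ms / 1000 * rec$fs) + 1L
  n <- nrow(rec$traces)
  cur <- vapply(seq_along(rec$voltages), function(j) {
    x <- rec$traces[i0:n, j]
    if (!is.null(clip_limit) && any(abs(x) >= clip_limit)) {
      warning(sprintf("trace at %+g mV reaches the clip limit; excluded",
                      rec$voltages[j]))
      return(NA_real_)
    }
    if (statistic == "peak") {
      x[which.max(abs(x))]
    } else {
      i_late <- max(1L, length(x) - floor(0.050 * rec$fs) + 1L)
      mean(x[i_late:length(x)])
    }
  }, numeric(1))
  out <- data.frame(voltage_mV = rec$voltages, current_pA = cur,
                    density_pA_pF = cur / rec$cm_pF)
  structure(out, component = "I_K", cm_pF = rec$cm_pF,
            condition = rec$condition, class = c("iv_curve", "data.frame"))
}

#' Decompose total K+ current by digital IBTx subtraction
#'
#' The iberiotoxin-sensitive (BK) component is the pointwise difference of
#' the control and IBTx current densities at each voltage; the residual IBTx-
#' insensitive current is the Kv component. The additive identity
#' `I_BK + I_Kv = I_K` holds exactly by construction.
#'
#' @param control `iv_curve` recorded before IBTx.
#' @param ibtx `iv_curve` recorded in 100 nM IBTx, same cell, identical
#'   voltage grid.
#' @return List with `i_bk` and `i_kv` (`iv_curve` objects, `component`
#'   attribute `"I_BK"` / `"I_Kv"`).
#' @export
subtract_ibtx <- function(control, ibtx) {
  stopifnot(inherits(control, "iv_curve"), inherits(ibtx, "iv_curve"))
  if (!isTRUE(all.equal(control$voltage_mV, ibtx$voltage_mV)))
    stop("control and IBTx voltage grids do not match")
  i_bk <- control
  i_bk$current_pA <- control$current_pA - ibtx$current_pA
  i_bk$density_pA_pF <- control$density_pA_pF - ibtx$density_pA_pF
  attr(i_bk, "component") <- "I_BK"
  i_kv <- ibtx
  attr(i_kv, "component") <- "I_Kv"
  list(i_bk = i_bk, i_kv = i_kv)
}

#' Gap-free current-clamp membrane-potential trace
#'
#' @param vm_mV numeric membrane-potential samples (mV), finite.
#' @param fs sampling rate (Hz).
#' @param drug optional list `list(name =, onset_s =)` annotating a bath
#'   application.
#' @return A `vm_trace` object.
#' @export
vm_trace <- function(vm_mV, fs = 1000, drug = NULL) {
  if (anyNA(vm_mV) || any(!is.finite(vm_mV))) stop("Vm trace contains non-finite values")
  if (!is.null(drug)) stopifnot(is.list(drug), !is.null(drug$onset_s))
  structure(list(vm_mV = vm_mV, fs = fs, drug = drug,
                 duration_s = length(vm_mV) / fs),
            class = "vm_trace")
}

rolling_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Membrane-potential metrics: resting Vm and drug-induced change
#'
#' The resting potential is the mean over the most stable window (minimum
#' rolling variance, default 10 s) of the pre-drug data. When a drug
#' application is annotated (or explicit windows are supplied), `delta_vm`
#' is `mean(post window) - mean(pre window)`; defaults are the last 10 s
#' before onset and from 1 s after onset to the end of the trace. Drift
#' larger than 5 mV across pre-drug rolling means raises an instability
#' flag.
#'
#' @param trace a [vm_trace()].
#' @param pre_window,post_window optional `c(start_s, end_s)` windows; the
#'   post window requires a drug annotation or an explicit window.
#' @param stable_s stable-window length (s) for the resting estimate.
#' @param settle_s dead time after drug onset excluded from the default post
#'   window.
#' @return List: `resting_vm` (mV), `delta_vm` (mV, `NA` when no drug/post
#'   window), `unstable` flag.
#' @export
vm_metrics <- function(trace, pre_window = NULL, post_window = NULL,
                       stable_s = 10, settle_s = 1) {
  stopifnot(inherits(trace, "vm_trace"))
  x <- trace$vm_mV
  fs <- trace$fs
  onset <- if (!is.null(trace$drug)) trace$drug$onset_s else NULL
  pre_end <- if (!is.null(onset)) onset else trace$duration_s
  pre <- x[seq_len(min(length(x), floor(pre_end * fs)))]

  w <- min(length(pre), max(2L, floor(stable_s * fs)))
  rm_ <- rolling_mean(pre, w)
  rm2 <- rolling_mean(pre^2, w)
  rv <- pmax(rm2 - rm_^2, 0)
  best <- which.min(rv)
  resting <- rm_[best]
  unstable <- (max(rm_) - min(rm_)) > 5

  delta <- NA_real_
  if (!is.null(post_window) || !is.null(onset)) {
    if (is.null(pre_window))
      pre_window <- c(max(0, pre_end - stable_s), pre_end)
    if (is.null(post_window))
      post_window <- c(onset + settle_s, trace$duration_s)
    pidx <- window_index(pre_window, fs, length(x))
    qidx <- window_index(post_window, fs, length(x))
    delta <- mean(x[qidx]) - mean(x[pidx])
  } else if (!is.null(pre_window)) {
    pidx <- window_index(pre_window, fs, length(x))
    resting <- mean(x[pidx])
  }
  list(resting_vm = resting, delta_vm = delta, unstable = unstable)
}
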