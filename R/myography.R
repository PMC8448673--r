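#' Percent myogenic tone
#'
#' Tone at a given intraluminal pressure is the constriction of the active
#' (spontaneously toned) artery relative to its maximally dilated passive
#' diameter at the same pressure (measured in Ca2+-free solution with
#' nifedipine): `100 * (d_passive - d_active) / d_passive`. Active diameters
#' exceeding the passive reference give negative tone; these are clipped to
#' zero and flagged via the `clipped` attribute.
#'
#' @param d_active active diameter (um), > 0. Vectorized.
#' @param d_passive passive (maximally dilated) diameter (um), > 0.
#' @param clip clip negative tone to 0 (default TRUE).
#' @return Numeric percent tone, with logical attribute `clipped`.
#' @examples
#' percent_tone(75.8, 100)  # 24.2
#' @export
percent_tone <- function(d_active, d_passive, clip = TRUE) {
  if (any(!is.finite(d_passive)) || any(d_passive <= 0))
    stop("d_passive must be > 0")
  if (any(!is.finite(d_active)) || any(d_active <= 0))
    stop("d_active must be > 0")
  tone <- 100 * (d_passive - d_active) / d_passive
  clipped <- tone < 0
  if (clip && any(clipped)) {
    warning("active diameter exceeds passive reference; tone clipped to 0")
    tone[clipped] <- 0
  }
  attr(tone, "clipped") <- clipped
  tone
}

#' KCl constriction and artery viability
#'
#' Arterial viability is gated on a robust constriction to 60 mM K+:
#' `constriction = 100 * (d_pre - d_kcl) / d_pre`, viable when it reaches
#' the threshold (default 30%). A diameter increase under KCl yields a
#' negative constriction, `viable = FALSE` and a `dilation` flag.
#'
#' @param d_pre diameter before KCl (um), > 0.
#' @param d_kcl diameter during KCl (um).
#' @param threshold_percent viability threshold (% constriction).
#' @return List: `constriction_percent`, `viable`, `dilation`.
#' @examples
#' kcl_viability(100, 35.6)  # 64.4%, viable
#' @export
kcl_viability <- function(d_pre, d_kcl, threshold_percent = 30) {
  if (!is.finite(d_pre) || d_pre <= 0) stop("d_pre must be > 0")
  constriction <- 100 * (d_pre - d_kcl) / d_pre
  list(constriction_percent = constriction,
       viable = constriction >= threshold_percent,
       dilation = constriction < 0)
}

#' Pressure-myography dataset for one artery
#'
#' @param records data frame with columns `time_s`, `pressure_mmHg`,
#'   `diameter_um`, `condition` (`"active"` or `"passive"`); one block of
#'   rows per pressure step per condition.
#' @param kcl list `list(d_pre =, d_kcl =)` diameters (um) around the 60 mM
#'   K+ challenge, or `NULL`.
#' @param stability optional data frame (`time_s`, `diameter_um`) of active
#'   diameter held at 60 mmHg for ~1 h, used for the tone-stability gate.
#' @return A `diameter_dataset` object.
#' @export
diameter_dataset <- function(records, kcl = NULL, stability = NULL) {
  need <- c("time_s", "pressure_mmHg", "diameter_um", "condition")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$diameter_um <= 0)) stop("diameters must be > 0")
  if (!all(records$condition %in% c("active", "passive")))
    stop("condition must be 'active' or 'passive'")
  structure(list(records = records, kcl = kcl, stability = stability),
            class = "diameter_dataset")
}

# mean diameter over the final `window_s` seconds of one pressure step
step_diameter <- function(records, pressure, condition, window_s = 30) {
  sub <- records[records$pressure_mmHg == pressure &
                   records$condition == condition, ]
  if (nrow(sub) == 0L) return(NA_real_)
  t1 <- max(sub$time_s)
  mean(sub$diameter_um[sub$time_s >= t1 - window_s])
}

#' Myogenic tone-pressure curve with viability and stability gating
#'
#' For every pressure with both active and passive blocks, the diameter is
#' the mean of the final `window_s` seconds of the step and tone is computed
#' with [percent_tone()]. Pressures missing the passive reference are
#' omitted with a warning. The KCl viability gate ([kcl_viability()]) and
#' the 60-mmHg stability gate (absolute tone drift across the 1-h hold below
#' `stability_drift_limit` percentage points) are evaluated when their data
#' are present.
#'
#' @param ds a [diameter_dataset()].
#' @param window_s averaging window at the end of each pressure step (s).
#' @param kcl_threshold viability threshold passed to [kcl_viability()].
#' @param stability_drift_limit maximum absolute tone drift (percentage
#'   points) tolerated over the stability hold.
#' @return A `tone_result`: data frame (`pressure_mmHg`, `d_active_um`,
#'   `d_passive_um`, `tone_percent`, `clipped`) with attributes `viability`
#'   (list or NULL), `stable` (logical or NA), `kcl`.
#' @export
tone_pressure_curve <- function(ds, window_s = 30, kcl_threshold = 30,
                                stability_drift_limit = 5) {
  stopifnot(inherits(ds, "diameter_dataset"))
  rec <- ds$records
  pressures <- sort(unique(rec$pressure_mmHg[rec$condition == "active"]))
  rows <- lapply(pressures, function(p) {
    da <- step_diameter(rec, p, "active", window_s)
    dp <- step_diameter(rec, p, "passive", window_s)
    if (is.na(dp)) {
      warning(sprintf("no passive reference at %g mmHg; pressure omitted", p))
      return(NULL)
    }
    tone <- percent_tone(da, dp)
    data.frame(pressure_mmHg = p, d_active_um = da, d_passive_um = dp,
               tone_percent = as.numeric(tone),
               clipped = attr(tone, "clipped"))
  })
  out <- do.call(rbind, rows)

  viability <- if (!is.null(ds$kcl))
    kcl_viability(ds$kcl$d_pre, ds$kcl$d_kcl, kcl_threshold) else NULL

  stable <- NA
  if (!is.null(ds$stability)) {
    dp60 <- step_diameter(rec, 60, "passive", window_s)
    if (!is.na(dp60)) {
      st <- ds$stability
      d0 <- mean(st$diameter_um[st$time_s <= min(st$time_s) + window_s])
      d1 <- mean(st$diameter_um[st$time_s >= max(st$time_s) - window_s])
      drift <- abs(as.numeric(percent_tone(d1, dp60)) -
                     as.numeric(percent_tone(d0, dp60)))
      stable <- drift < stability_drift_limit
    }
  }
  structure(out, viability = viability, stable = stable, kcl = ds$kcl,
            class = c("tone_result", "data.frame"))
}
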