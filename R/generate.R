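#' Generate synthetic cell-attached single-channel sweeps
#'
#' Simulates a set of sweeps under the standard single-pulse protocol: per
#' sweep the coupled gating chain is sampled (initial state drawn from the
#' stationary distribution), converted to current as
#' `level * unitary_current` and corrupted with white Gaussian recording
#' noise. An optional moving-average smoother approximates the 2 kHz analog
#' low-pass (off by default so the generator/idealizer round trip is exact
#' at zero noise). Ground-truth level paths are attached as attribute
#' `true_levels`.
#'
#' @param params a [coupled_markov_params()]; `params$dt` is ignored in
#'   favour of `1/fs`.
#' @param sweeps number of sweeps (default 50, the typical per-patch count).
#' @param duration_s sweep (test-pulse) duration in seconds (default 2).
#' @param fs sampling rate (Hz, default 10000).
#' @param noise_sd_pA Gaussian recording-noise sd (pA, default 0.15).
#' @param seed integer RNG seed.
#' @param lowpass apply the moving-average smoother (default FALSE).
#' @return A [sweep_set()] with attribute `true_levels` (list of integer
#'   vectors).
#' @export
gen_single_channel <- function(params, sweeps = 50, duration_s = 2,
                               fs = 10000, noise_sd_pA = 0.15, seed = 1,
                               lowpass = FALSE) {
  stopifnot(inherits(params, "coupled_markov_params"))
  n <- round(duration_s * fs)
  tm <- build_transition_matrix(params)
  pi_ <- stationary_distribution(tm)
  set.seed(seed)
  truth <- vector("list", sweeps)
  traces <- vector("list", sweeps)
  for (i in seq_len(sweeps)) {
    init <- sample(0:params$n_channels, 1L, prob = pi_)
    lev <- sim_markov_chain(unclass(tm), init, n)
    x <- lev * params$unitary_current
    if (noise_sd_pA > 0) x <- x + stats::rnorm(n, 0, noise_sd_pA)
    if (lowpass) {
      w <- max(1L, round(fs / 2000 / 2))
      x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
      x[is.na(x)] <- 0
    }
    truth[[i]] <- lev
    traces[[i]] <- x
  }
  ss <- sweep_set(traces, fs = fs, unitary_current = params$unitary_current)
  attr(ss, "true_levels") <- truth
  ss
}

boltzmann <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

#' Generate a synthetic whole-cell K+ step family
#'
#' Builds one current trace per test potential from two Boltzmann-activated
#' conductances, `I(V) = [g_BK * b(V) + g_Kv * w(V)] * (V - E_K)`, with the
#' conductances scaled so the programmed current densities at +80 mV are
#' exact. The `ibtx` flag zeroes the BK term (pharmacological block). A
#' decaying capacitive transient occupies the first 2 ms of each trace.
#'
#' @param bk_density_at_80 BK current density at +80 mV (pA/pF), >= 0.
#' @param kv_density_at_80 Kv current density at +80 mV (pA/pF), >= 0.
#' @param cm_pF membrane capacitance (pF).
#' @param voltages test potentials (mV).
#' @param pulse_s pulse duration (s, default 0.6).
#' @param fs sampling rate (Hz, default 20000).
#' @param e_k K+ reversal potential (mV); -84 mV from the 6/140 mM K+
#'   solutions at room temperature.
#' @param ibtx logical: generate the family recorded in IBTx (BK blocked).
#' @param bk_vhalf,bk_k,kv_vhalf,kv_k Boltzmann half-activation and slope
#'   (mV) for the two conductances.
#' @param noise_sd_pA Gaussian noise sd (pA, default 0).
#' @param cap_amp_pA,cap_tau_ms capacitive-transient amplitude and decay.
#' @param seed RNG seed (used only when `noise_sd_pA > 0`).
#' @return A [step_recording()].
#' @export
gen_wholecell <- function(bk_density_at_80, kv_density_at_80, cm_pF = 10,
                          voltages = seq(-70, 80, by = 10), pulse_s = 0.6,
                          fs = 20000, e_k = -84, ibtx = FALSE,
                          bk_vhalf = 20, bk_k = 18, kv_vhalf = 0, kv_k = 15,
                          noise_sd_pA = 0, cap_amp_pA = 500,
                          cap_tau_ms = 0.3, seed = 1) {
  stopifnot(bk_density_at_80 >= 0, kv_density_at_80 >= 0, cm_pF > 0)
  g_bk <- bk_density_at_80 * cm_pF / (boltzmann(80, bk_vhalf, bk_k) * (80 - e_k))
  g_kv <- kv_density_at_80 * cm_pF / (boltzmann(80, kv_vhalf, kv_k) * (80 - e_k))
  if (ibtx) g_bk <- 0
  n <- round(pulse_s * fs)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  cap <- ifelse(t_ms < 2, cap_amp_pA * exp(-t_ms / cap_tau_ms), 0)
  if (noise_sd_pA > 0) set.seed(seed)
  traces <- vapply(voltages, function(v) {
    i_ss <- (g_bk * boltzmann(v, bk_vhalf, bk_k) +
               g_kv * boltzmann(v, kv_vhalf, kv_k)) * (v - e_k)
    x <- rep(i_ss, n) + sign(v + 70 + 1e-9) * cap
    if (noise_sd_pA > 0) x <- x + stats::rnorm(n, 0, noise_sd_pA)
    x
  }, numeric(n))
  step_recording(traces, voltages, cm_pF = cm_pF, fs = fs,
                 condition = if (ibtx) "IBTx" else "control")
}

#' Generate a synthetic gap-free membrane-potential trace
#'
#' Ornstein-Uhlenbeck fluctuation (relaxation time `tau_s`, stationary sd
#' `noise_sd_mv`) around `mean_mv`, with an optional step of `drug_delta_mv`
#' at `onset_s` emulating a bath drug application. Exact discretization, so
#' zero noise gives a noiseless piecewise-constant trace.
#'
#' @param mean_mv resting membrane potential (mV).
#' @param noise_sd_mv stationary fluctuation sd (mV).
#' @param duration_s trace duration (s).
#' @param drug_delta_mv membrane-potential step at drug onset (mV; 0 = no
#'   drug).
#' @param onset_s drug onset (s); required when `drug_delta_mv != 0`.
#' @param fs sampling rate (Hz, default 1000).
#' @param tau_s OU relaxation time (s, default 0.5).
#' @param drug_name annotation label.
#' @param seed RNG seed.
#' @return A [vm_trace()].
#' @export
gen_vm <- function(mean_mv, noise_sd_mv, duration_s, drug_delta_mv = 0,
                   onset_s = NULL, fs = 1000, tau_s = 0.5,
                   drug_name = "IBTx", seed = 1) {
  n <- round(duration_s * fs)
  has_drug <- drug_delta_mv != 0 || !is.null(onset_s)
  if (has_drug) {
    if (is.null(onset_s)) stop("onset_s required when a drug step is programmed")
    if (onset_s >= duration_s) stop("duration must exceed drug onset")
  }
  mu <- rep(mean_mv, n)
  if (has_drug) {
    i_on <- floor(onset_s * fs) + 1L
    mu[i_on:n] <- mean_mv + drug_delta_mv
  }
  set.seed(seed)
  a <- exp(-1 / (fs * tau_s))
  innov_sd <- noise_sd_mv * sqrt(1 - a^2)
  dev <- numeric(n)
  dev[1] <- stats::rnorm(1, 0, noise_sd_mv)
  if (n > 1L) {
    eps <- stats::rnorm(n - 1L, 0, innov_sd)
    for (t in 2:n) dev[t] <- a * dev[t - 1L] + eps[t - 1L]
  }
  vm_trace(mu + dev, fs = fs,
           drug = if (has_drug) list(name = drug_name, onset_s = onset_s)
                  else NULL)
}

#' Generate a synthetic pressure-myography dataset
#'
#' Emulates one artery: a saturating passive diameter curve
#' `D_pass(P) = d_min + (d_max - d_min) * P / (P + p_half)`, a bell-shaped
#' active tone profile `tone(P) = peak * exp(-((P - center)/width)^2)` with
#' `D_act(P) = D_pass(P) * (1 - tone(P)/100)`, a KCl challenge scaled to the
#' programmed constriction, and a 1-h stability hold at 60 mmHg with an
#' optional linear tone drift. Programmed per-pressure tone is attached as
#' attribute `true_tone`.
#'
#' @param pressures pressure steps (mmHg).
#' @param passive_curve_params list `d_min`, `d_max` (um), `p_half` (mmHg).
#' @param tone_profile_params list `peak` (% tone), `center`, `width`
#'   (mmHg); defaults approximate a chronically exposed artery (plateau
#'   ~22-24% between 40 and 80 mmHg).
#' @param kcl_constriction_pct programmed KCl constriction (%).
#' @param noise_um Gaussian diameter noise sd (um).
#' @param step_s duration of each pressure step (s); the analyzer averages
#'   the final 30 s.
#' @param fs_hz diameter sampling rate (Hz, default 1).
#' @param stability_drift_pct absolute tone drift programmed across the 1-h
#'   stability hold (percentage points, default 0).
#' @param seed RNG seed.
#' @return A [diameter_dataset()] with attribute `true_tone` (named by
#'   pressure).
#' @export
gen_myography <- function(pressures = c(10, 20, 40, 60, 80, 100),
                          passive_curve_params = list(d_min = 60, d_max = 130,
                                                      p_half = 30),
                          tone_profile_params = list(peak = 24, center = 60,
                                                     width = 55),
                          kcl_constriction_pct = 64.4, noise_um = 0,
                          step_s = 120, fs_hz = 1,
                          stability_drift_pct = 0, seed = 1) {
  pc <- passive_curve_params
  tp <- tone_profile_params
  d_pass <- pc$d_min + (pc$d_max - pc$d_min) * pressures / (pressures + pc$p_half)
  tone <- tp$peak * exp(-((pressures - tp$center) / tp$width)^2)
  d_act <- d_pass * (1 - tone / 100)
  set.seed(seed)
  n_per <- round(step_s * fs_hz)
  block <- function(p, d, cond, t0) {
    d_t <- rep(d, n_per)
    if (noise_um > 0) d_t <- d_t + stats::rnorm(n_per, 0, noise_um)
    data.frame(time_s = t0 + seq_len(n_per) / fs_hz, pressure_mmHg = p,
               diameter_um = d_t, condition = cond)
  }
  recs <- list()
  t0 <- 0
  for (i in seq_along(pressures)) {
    recs[[length(recs) + 1L]] <- block(pressures[i], d_act[i], "active", t0)
    t0 <- t0 + step_s
  }
  for (i in seq_along(pressures)) {
    recs[[length(recs) + 1L]] <- block(pressures[i], d_pass[i], "passive", t0)
    t0 <- t0 + step_s
  }
  records <- do.call(rbind, recs)

  i60 <- which(pressures == 60)
  d_pre <- if (length(i60)) d_act[i60] else d_act[which.min(abs(pressures - 60))]
  kcl <- list(d_pre = d_pre, d_kcl = d_pre * (1 - kcl_constriction_pct / 100))

  stab_t <- seq(0, 3600, by = 1 / fs_hz)
  dp60 <- if (length(i60)) d_pass[i60] else NA_real_
  tone0 <- if (length(i60)) tone[i60] else mean(tone)
  tone_t <- tone0 + stability_drift_pct * stab_t / 3600
  stab_d <- dp60 * (1 - tone_t / 100)
  if (noise_um > 0) stab_d <- stab_d + stats::rnorm(length(stab_d), 0, noise_um)
  stability <- data.frame(time_s = stab_t, diameter_um = stab_d)

  ds <- diameter_dataset(records, kcl = kcl, stability = stability)
  attr(ds, "true_tone") <- stats::setNames(tone, pressures)
  ds
}

#' Generate synthetic PLA puncta measurements
#'
#' Cell areas are gamma-distributed with the given mean and sd; puncta
#' counts are Poisson with mean `density_per_um2 * area`.
#'
#' @param density_per_um2 programmed puncta density (puncta/um^2), >= 0.
#' @param n_cells number of cells.
#' @param area_mean,area_sd cell-area distribution (um^2).
#' @param condition condition label.
#' @param seed RNG seed.
#' @return Data frame: `cell_id`, `puncta_count`, `cell_area_um2`,
#'   `condition`.
#' @export
gen_puncta <- function(density_per_um2, n_cells, area_mean = 400,
                       area_sd = 100, condition = "FA", seed = 1) {
  stopifnot(density_per_um2 >= 0, n_cells >= 1)
  set.seed(seed)
  shape <- (area_mean / area_sd)^2
  areas <- stats::rgamma(n_cells, shape = shape, rate = shape / area_mean)
  counts <- stats::rpois(n_cells, density_per_um2 * areas)
  data.frame(cell_id = sprintf("%s_%03d", condition, seq_len(n_cells)),
             puncta_count = counts, cell_area_um2 = areas,
             condition = condition)
}

#' Generate a synthetic qPCR Ct table
#'
#' Per sample, the reference-gene Ct is drawn around `ct_ref_mean`; each
#' target gene's Ct is `Ct_ref + dct_base - log2(fold) + noise`, where
#' `fold` is the group's programmed expression relative to the calibrator.
#' With `ct_sd = 0` the 2^-ddCt pipeline recovers the programmed folds
#' exactly.
#'
#' @param true_folds named list: per gene, a named numeric vector of folds
#'   per group (calibrator group fold 1), e.g.
#'   `list(BKalpha1 = c(FA = 1, SHS = 0.5))`.
#' @param replicates samples per group.
#' @param ct_sd replicate Ct noise sd (cycles).
#' @param reference_gene reference gene name.
#' @param ct_ref_mean mean reference Ct (cycles).
#' @param dct_base baseline dCt of each target in the calibrator (cycles).
#' @param seed RNG seed.
#' @return Data frame: `sample_id`, `gene`, `ct`, `group`.
#' @export
gen_qpcr <- function(true_folds, replicates = 6, ct_sd = 0.3,
                     reference_gene = "GAPDH", ct_ref_mean = 18,
                     dct_base = 5, seed = 1) {
  stopifnot(is.list(true_folds), length(true_folds) >= 1)
  groups <- names(true_folds[[1]])
  set.seed(seed)
  rows <- list()
  for (g in groups) {
    for (r in seq_len(replicates)) {
      sid <- sprintf("%s_%02d", g, r)
      ct_ref <- ct_ref_mean + stats::rnorm(1, 0, ct_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sid, gene = reference_gene, ct = ct_ref,
                   group = g)
      for (gene in names(true_folds)) {
        fold <- true_folds[[gene]][[g]]
        ct_t <- ct_ref + dct_base - log2(fold) + stats::rnorm(1, 0, ct_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, gene = gene, ct = ct_t, group = g)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
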