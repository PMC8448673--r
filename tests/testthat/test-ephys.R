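make_ohmic_rec <- function(g_nS = 1, e_rev = -80, cm = 10, voltages = seq(-70, 80, 10),
                           fs = 20000, pulse_s = 0.2, spike_pA = 0) {
  n <- pulse_s * fs
  traces <- vapply(voltages, function(v) {
    x <- rep(g_nS * (v - e_rev), n)  # nS * mV = pA
    if (spike_pA != 0) x[1:(0.003 * fs)] <- x[1:(0.003 * fs)] + spike_pA
    x
  }, numeric(n))
  step_recording(traces, voltages, cm_pF = cm, fs = fs)
}

test_that("extract_iv reproduces Ohm's law densities", {
  iv <- extract_iv(make_ohmic_rec())
  expect_equal(iv$density_pA_pF[iv$voltage_mV == 80], 16)  # 1 nS * 160 mV / 10 pF
  expect_equal(iv$density_pA_pF, (iv$voltage_mV + 80) / 10)
  # zero conductance
  iv0 <- extract_iv(make_ohmic_rec(g_nS = 0, e_rev = 0))
  expect_true(all(iv0$density_pA_pF == 0))
})

test_that("blanking removes the capacitive spike and density scales with 1/Cm", {
  clean <- extract_iv(make_ohmic_rec())
  spiky <- extract_iv(make_ohmic_rec(spike_pA = 800), blank_ms = 5)
  expect_equal(spiky$density_pA_pF, clean$density_pA_pF)
  # doubling Cm halves every density
  half <- extract_iv(make_ohmic_rec(cm = 20))
  expect_equal(half$density_pA_pF, clean$density_pA_pF / 2)
  expect_error(extract_iv(make_ohmic_rec(), blank_ms = 300), "blank_ms")
})

test_that("saturated traces are excluded with a warning", {
  rec <- make_ohmic_rec()
  expect_warning(iv <- extract_iv(rec, clip_limit = 155), "clip")
  expect_true(any(is.na(iv$density_pA_pF)))
  expect_false(is.na(iv$density_pA_pF[iv$voltage_mV == 0]))
})

test_that("mean_late statistic averages the final 50 ms", {
  rec <- make_ohmic_rec()
  n <- nrow(rec$traces)
  rec$traces[(n - 999):n, ] <- 42  # last 50 ms at 20 kHz
  iv <- extract_iv(rec, statistic = "mean_late")
  expect_true(all(iv$current_pA == 42))
})

test_that("IBTx subtraction is exact and additive", {
  ctl <- extract_iv(gen_wholecell(30.8, 14, cm_pF = 10))
  ibtx <- extract_iv(gen_wholecell(30.8, 14, cm_pF = 10, ibtx = TRUE))
  dec <- subtract_ibtx(ctl, ibtx)
  expect_equal(dec$i_bk$density_pA_pF[dec$i_bk$voltage_mV == 80], 30.8,
               tolerance = 1e-9)
  expect_equal(attr(dec$i_bk, "component"), "I_BK")
  expect_equal(attr(dec$i_kv, "component"), "I_Kv")
  # additivity at machine precision, every voltage
  expect_equal(dec$i_bk$density_pA_pF + dec$i_kv$density_pA_pF,
               ctl$density_pA_pF, tolerance = 1e-12)
  # ibtx == control implies zero BK current
  same <- subtract_ibtx(ctl, ctl)
  expect_true(all(same$i_bk$density_pA_pF == 0))
  # mismatched grids rejected
  short <- ctl[-1, ]
  class(short) <- class(ctl)
  expect_error(subtract_ibtx(short, ibtx), "grid")
})

test_that("extract_iv recovers the programmed Boltzmann-family density at +80 mV", {
  iv <- extract_iv(gen_wholecell(20, 10, cm_pF = 15))
  expect_equal(iv$density_pA_pF[iv$voltage_mV == 80], 30, tolerance = 1e-9)
})

test_that("vm_metrics recovers resting potential and drug steps", {
  const <- vm_trace(rep(-43.2, 30000), fs = 1000)
  expect_equal(vm_metrics(const)$resting_vm, -43.2)
  expect_true(is.na(vm_metrics(const)$delta_vm))
  # programmed step at drug onset
  stepped <- vm_trace(c(rep(-43, 30000), rep(-36, 30000)), fs = 1000,
                      drug = list(name = "IBTx", onset_s = 30))
  m <- vm_metrics(stepped)
  expect_equal(m$delta_vm, 7.0)
  # constant trace with drug annotation: delta 0
  flat <- vm_trace(rep(-40, 60000), fs = 1000,
                   drug = list(name = "IBTx", onset_s = 30))
  expect_equal(vm_metrics(flat)$delta_vm, 0)
})

test_that("resting estimate is robust to white measurement noise", {
  set.seed(21)
  noisy <- vm_trace(rep(-43.2, 30000) + rnorm(30000, 0, 1), fs = 1000)
  expect_lt(abs(vm_metrics(noisy)$resting_vm - (-43.2)), 0.05)
})

test_that("pre-window drift raises the instability flag", {
  drift <- vm_trace(seq(-47, -38, length.out = 30000), fs = 1000)
  expect_true(vm_metrics(drift)$unstable)
  expect_false(vm_metrics(vm_trace(rep(-45, 30000), fs = 1000))$unstable)
})
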