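test_that("noiseless multi-level sweeps are quantized exactly", {
  lev <- rep(c(0L, 1L, 2L, 0L), c(4000, 3000, 2000, 11000))
  sw <- lev * 1.0
  ide <- idealize_sweep(sw, unitary_current = 1.0)
  expect_identical(ide$levels, lev)
  # idempotency: idealizing an idealized (noise-free) trace is the identity
  ide2 <- idealize_sweep(ide$levels * 1.0, unitary_current = 1.0)
  expect_identical(ide2$levels, ide$levels)
})

test_that("the half-amplitude threshold sits at 0.5 pA for a 1 pA unitary event", {
  sw <- c(rep(0, 50), 0.49, 0.49, rep(0, 50))
  ide <- idealize_sweep(sw, 1.0, baseline = 0, min_dwell = 1)
  expect_true(all(ide$levels == 0L))
  sw2 <- c(rep(0, 50), 0.51, 0.51, rep(0, 50))
  ide2 <- idealize_sweep(sw2, 1.0, baseline = 0, min_dwell = 1)
  expect_identical(sort(unique(ide2$levels)), c(0L, 1L))
  # exactly at threshold counts as open
  sw3 <- c(rep(0, 50), 0.50, 0.50, rep(0, 50))
  expect_identical(max(idealize_sweep(sw3, 1.0, baseline = 0,
                                      min_dwell = 1)$levels), 1L)
})

test_that("classification accuracy exceeds 99% at 0.15 pA noise", {
  p <- make_params_pinf(2, 0.36)
  ss <- gen_single_channel(p, sweeps = 5, noise_sd_pA = 0.15, seed = 3)
  truth <- attr(ss, "true_levels")
  # flicker suppression off: the reference path itself has 1-sample dwells
  ide <- idealize_sweeps(ss, min_dwell = 1)
  acc <- mean(unlist(Map(function(i, tr) mean(i$levels == tr), ide, truth)))
  expect_gt(acc, 0.99)
})

test_that("baseline estimation survives high-open-probability patches", {
  # closed level is a minority mode here; the lowest density mode must win
  p <- make_params_pinf(3, 0.7667, rho = 0.93)
  ss <- gen_single_channel(p, sweeps = 3, noise_sd_pA = 0.15, seed = 9)
  for (sw in ss$sweeps)
    expect_lt(abs(estimate_baseline(sw, 1.0)), 0.2)
  # a genuine bimodal tie warns and picks the lower mode
  expect_warning(b <- estimate_baseline(rep(c(0, 1), each = 5000), 1.0),
                 "ambiguous")
  expect_lt(abs(b), 0.1)
  expect_error(estimate_baseline(rep(1.5, 100), 1.0), "flat")
  expect_error(idealize_sweep(c(rep(0, 50), NA, rep(0, 50)), 1.0), "NA")
})

test_that("activity statistics follow their definitions", {
  n <- 20000
  half <- c(rep(1L, n / 2), rep(0L, n / 2))
  ide <- idealize_sweep(half * 1.0, 1.0, baseline = 0)
  st <- activity_stats(list(ide), unitary_current = 1, window = c(0, 2))
  expect_equal(st$nPo, 0.5)
  expect_equal(st$n_channels, 1L)
  expect_equal(st$Po, 0.5)
  # n = max simultaneous level; Po = nPo / n
  lev3 <- rep(c(0L, 3L, 1L, 0L), each = n / 4)
  st3 <- activity_stats(list(idealize_sweep(lev3 * 1.0, 1.0)),
                        unitary_current = 1, window = c(0, 2))
  expect_equal(st3$n_channels, 3L)
  expect_equal(st3$Po, st3$nPo / 3)
  # ensemble average is the pointwise mean level times the unitary current
  ide_a <- idealize_sweep(rep(c(0, 2), each = n / 2), 1.0, baseline = 0)
  ide_b <- idealize_sweep(rep(c(2, 0), each = n / 2), 1.0, baseline = 0)
  ens <- activity_stats(list(ide_a, ide_b), unitary_current = 1.0)$ensemble_average
  expect_equal(unique(round(ens, 12)), 1)
})

test_that("a patch with no openings is flagged and assigned n = 1", {
  quiet <- c(rep(0L, 100), 1L, 1L, rep(0L, 19898))  # openings outside window
  ide <- idealize_sweep(quiet * 1.0, 1.0, baseline = 0)
  st <- activity_stats(list(ide), unitary_current = 1, window = c(0.5, 1.5))
  expect_true(st$no_openings)
  expect_equal(st$n_channels, 1L)
  expect_equal(st$Po, 0)
})

test_that("nPo estimation is consistent on uncoupled simulations", {
  for (cfg in list(list(N = 2, p = 0.10), list(N = 2, p = 0.36),
                   list(N = 3, p = 0.7667))) {
    p <- make_params_pinf(cfg$N, cfg$p, rho = 0.93)
    err <- vapply(1:10, function(s) {
      ss <- gen_single_channel(p, sweeps = 50, seed = s)
      # near-tied baseline modes are an expected diagnostic here
      st <- suppressWarnings(activity_stats(idealize_sweeps(ss)))
      abs(st$nPo - cfg$N * cfg$p)
    }, numeric(1))
    expect_lt(mean(err), 0.1)
  }
})

test_that("coupled event metrics count simultaneous multi-channel openings", {
  # single-channel record: jumps of >= 2 impossible
  one <- idealize_sweep(rep(c(0, 1), each = 5000) * 1.0, 1.0, baseline = 0)
  m1 <- coupled_event_metrics(list(one), window = c(0, 1))
  expect_equal(m1$coupled_frequency, 0)
  # constructed 0,0,2,2,0: one coupled opening of strength 2
  seq5 <- c(0, 0, 2, 2, 0)
  ide5 <- idealize_sweep(rep(seq5, each = 4) * 1.0, 1.0, fs = 20)
  m5 <- coupled_event_metrics(list(ide5), window = c(0, 1))
  expect_equal(m5$n_coupled, 1L)
  expect_equal(m5$coupled_strength, 2)
  expect_equal(m5$coupled_frequency, 1 / (length(ide5$levels[1:19]) / 20))
  # unison gating: essentially every opening is coupled
  p1 <- coupled_markov_params(2, 1, 0.9, 0.9)
  ss <- gen_single_channel(p1, sweeps = 10, noise_sd_pA = 0, seed = 2)
  mu <- coupled_event_metrics(idealize_sweeps(ss, baseline = 0))
  expect_gt(mu$n_openings, 0)
  expect_equal(mu$coupled_fraction, 1)
  expect_equal(mu$coupled_strength, 2)
})

test_that("short dwells are merged into the flanking level", {
  lev <- c(rep(0L, 100), 1L, rep(0L, 100))  # single-sample flicker
  ide <- idealize_sweep(lev * 1.0, 1.0, min_dwell = 2, baseline = 0)
  expect_true(all(ide$levels == 0L))
  expect_true(all(ide$dwells$duration_s >= 2 / 10000 |
                    nrow(ide$dwells) == 1))
})
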