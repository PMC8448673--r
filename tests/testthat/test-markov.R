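test_that("parameter validation rejects out-of-range values", {
  expect_error(coupled_markov_params(0, 0.5, 0.5, 0.5), "n_channels")
  expect_error(coupled_markov_params(2, -0.1, 0.5, 0.5), "kappa")
  expect_error(coupled_markov_params(2, 0.5, 1.2, 0.5), "rho")
  expect_error(coupled_markov_params(2, 0.5, 1, 1), "both")
  expect_error(coupled_markov_params(2, 0.5, 0.5, 0.5, unitary_current = 0),
               "unitary_current")
  p <- coupled_markov_params(1, 0, 0.6, 0.8)
  expect_equal(p$p_inf, 1 / 3)
})

test_that("N = 1 transition matrix collapses to the single-channel chain for any kappa", {
  for (k in c(0, 0.37, 1)) {
    tm <- build_transition_matrix(coupled_markov_params(1, k, 0.6, 0.8))
    expect_equal(unclass(tm), matrix(c(0.8, 0.4, 0.2, 0.6), 2, 2),
                 ignore_attr = TRUE)
  }
})

test_that("fully coupled rows place mass only on the boundary levels", {
  tm <- build_transition_matrix(coupled_markov_params(2, 1, 0.6, 0.8))
  expect_equal(unname(tm["0", ]), c(0.8, 0, 0.2))   # majority closed
  expect_equal(unname(tm["1", ]), c(0.4, 0, 0.6))   # tie broken toward open
  expect_equal(unname(tm["2", ]), c(0.4, 0, 0.6))
})

test_that("kappa = 0 matrix matches exhaustive configuration enumeration for N <= 4", {
  for (N in 1:4) {
    tm <- build_transition_matrix(coupled_markov_params(N, 0, 0.6, 0.8))
    expect_equal(unclass(tm), enum_independent_tmat(N, 0.6, 0.8),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # the spec'd worked row: N = 2, from k = 1
  tm2 <- build_transition_matrix(coupled_markov_params(2, 0, 0.6, 0.8))
  expect_equal(unname(tm2["1", ]), c(0.4 * 0.8, 0.6 * 0.8 + 0.4 * 0.2,
                                     0.6 * 0.2))
})

test_that("every built matrix is row-stochastic to machine precision", {
  grid <- expand.grid(N = c(1, 2, 3, 5), kappa = c(0, 0.3, 1),
                      rho = c(0.1, 0.9), sigma_c = c(0.2, 0.95))
  for (i in seq_len(nrow(grid))) {
    tm <- build_transition_matrix(with(grid[i, ],
      coupled_markov_params(N, kappa, rho, sigma_c)))
    expect_lt(max(abs(rowSums(tm) - 1)), 1e-12)
    expect_true(all(tm >= 0))
  }
})

test_that("stationary distribution: closed forms and fixed-point identity", {
  # two-state closed form
  tm1 <- build_transition_matrix(coupled_markov_params(1, 0, 0.6, 0.8))
  expect_equal(unname(stationary_distribution(tm1)[2]), 1 / 3,
               tolerance = 1e-10)
  # independence: Binomial(3, 0.25)
  p3 <- make_params_pinf(3, 0.25, rho = 0.8)
  pi3 <- stationary_distribution(build_transition_matrix(p3))
  expect_equal(unname(pi3), dbinom(0:3, 3, 0.25), tolerance = 1e-9)
  # fixed point for a spread of parameterizations
  for (k in c(0, 0.4, 0.9)) {
    tm <- build_transition_matrix(coupled_markov_params(3, k, 0.85, 0.9))
    pi_ <- stationary_distribution(tm)
    expect_lt(max(abs(as.numeric(pi_ %*% tm) - pi_)), 1e-10)
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
  }
})

test_that("reducible chains are flagged and return the boundary distribution", {
  tm <- diag(2)  # two absorbing states
  expect_warning(pi_ <- stationary_distribution(tm), "reducible")
  expect_equal(as.numeric(pi_), c(0.5, 0.5))
  expect_true(attr(pi_, "reducible"))
})

test_that("simulation: unison gating never visits interior levels; seeds reproduce", {
  p <- coupled_markov_params(3, 1, 0.7, 0.8)
  s <- simulate_chain(p, 5000, seed = 11, init = 0)
  expect_true(all(s$levels %in% c(0L, 3L)))
  s2 <- simulate_chain(p, 5000, seed = 11, init = 0)
  expect_identical(s$levels, s2$levels)
  s3 <- simulate_chain(p, 5000, seed = 12, init = 0)
  expect_false(identical(s$levels, s3$levels))
})

test_that("simulated occupancy matches the stationary distribution", {
  # mixing time ~ 1/(1 - |second eigenvalue|) is a few steps for these
  # parameters; thinning by 25 gives effectively independent draws so the
  # multinomial chi-square is valid
  p <- coupled_markov_params(2, 0, 0.6, 0.7)
  tm <- build_transition_matrix(p)
  pi_ <- stationary_distribution(tm)
  s <- simulate_chain(p, 1e6, seed = 5)
  thin <- s$levels[seq(1, length(s$levels), by = 25)]
  obs <- tabulate(thin + 1L, nbins = 3)
  chi <- suppressWarnings(chisq.test(obs, p = pi_))
  expect_gt(chi$p.value, 0.01)
  # per-level occupancy of the full path within 3 thinned-SE of stationary
  emp <- tabulate(s$levels + 1L, nbins = 3) / length(s$levels)
  se <- sqrt(pi_ * (1 - pi_) / length(thin))
  expect_true(all(abs(emp - pi_) < 3 * se + 3e-3))
})

test_that("loglik equals direct products and floors forbidden transitions", {
  p <- coupled_markov_params(2, 0.3, 0.9, 0.95)
  tm <- build_transition_matrix(p)
  # two samples: exactly one transition entry
  s2 <- level_sequence(c(1L, 2L), dt = 1e-4, n_channels = 2)
  expect_equal(as.numeric(loglik(s2, p)), log(tm["1", "2"]))
  # 10-step toy sequence vs brute-force product oracle
  lev <- c(0L, 0L, 1L, 2L, 2L, 1L, 0L, 1L, 1L, 0L)
  s10 <- level_sequence(lev, 1e-4, 2)
  expect_equal(as.numeric(loglik(s10, p)), brute_loglik(lev, tm))
  # permuting rho and sigma_c changes the likelihood of an asymmetric record
  p_swap <- coupled_markov_params(2, 0.3, 0.95, 0.9)
  expect_false(isTRUE(all.equal(as.numeric(loglik(s10, p)),
                                as.numeric(loglik(s10, p_swap)))))
  # forbidden transitions under full coupling: floored with a warning
  p1 <- coupled_markov_params(2, 1, 0.9, 0.95)
  expect_warning(ll <- loglik(s10, p1), "forbidden")
  expect_gt(attr(ll, "n_forbidden"), 0)
  expect_lt(as.numeric(ll), -700)
  expect_error(loglik(level_sequence(1L, 1e-4, 2), p), "at least 2")
})

test_that("fit_params recovers interior parameters from simulated records", {
  truth <- coupled_markov_params(2, 0.30, 0.90, 0.95)
  for (s in 1:3) {
    fit <- fit_params(simulate_chain(truth, 1e5, seed = s))
    expect_lt(abs(fit$params$kappa - 0.30), 0.05)
    expect_lt(abs(fit$params$rho - 0.90), 0.05)
    expect_lt(abs(fit$params$sigma_c - 0.95), 0.05)
    expect_false(fit$degenerate)
  }
})

test_that("fit_params finds the uncoupled boundary when kappa = 0", {
  truth <- coupled_markov_params(2, 0, 0.9, 0.95)
  fit <- fit_params(simulate_chain(truth, 3e4, seed = 7))
  expect_lte(fit$params$kappa, 0.05)
})

test_that("an all-constant sequence yields a flagged boundary fit", {
  s <- level_sequence(rep(0L, 500), 1e-4, 2)
  fit <- fit_params(s)
  expect_true(fit$degenerate)
  expect_equal(fit$params$sigma_c, 1)
  s_open <- level_sequence(rep(2L, 500), 1e-4, 2)
  fit2 <- fit_params(s_open)
  expect_true(fit2$degenerate)
  expect_equal(fit2$params$rho, 1)
})
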