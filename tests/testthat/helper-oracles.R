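# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Transition matrix of N independent two-state channels by exhaustive
# enumeration of the 2^N binary configurations (open-to-open rho,
# closed-to-closed sigma_c), aggregated by the number of open channels.
enum_independent_tmat <- function(N, rho, sigma_c) {
  configs <- as.matrix(expand.grid(rep(list(0:1), N)))
  K <- N + 1L
  tm <- matrix(0, K, K)
  w <- numeric(nrow(configs))  # configurations with k open are equiprobable
  for (a in seq_len(nrow(configs))) {
    ka <- sum(configs[a, ])
    for (b in seq_len(nrow(configs))) {
      pr <- 1
      for (ch in seq_len(N)) {
        pr <- pr * if (configs[a, ch] == 1) {
          if (configs[b, ch] == 1) rho else 1 - rho
        } else {
          if (configs[b, ch] == 0) sigma_c else 1 - sigma_c
        }
      }
      tm[ka + 1L, sum(configs[b, ]) + 1L] <-
        tm[ka + 1L, sum(configs[b, ]) + 1L] + pr / choose(N, ka)
    }
  }
  tm
}

# direct product-of-entries log-likelihood oracle
brute_loglik <- function(levels, tm) {
  ll <- 0
  for (t in seq_len(length(levels) - 1L)) {
    p <- tm[levels[t] + 1L, levels[t + 1L] + 1L]
    ll <- ll + if (p > 0) log(p) else -700
  }
  ll
}

# sigma_c giving a desired single-channel stationary open probability at
# fixed rho: p = (1-s)/((1-s)+(1-r))
sigma_for_pinf <- function(p_inf, rho) 1 - p_inf / (1 - p_inf) * (1 - rho)

make_params_pinf <- function(N, p_inf, rho = 0.9, kappa = 0) {
  coupled_markov_params(N, kappa, rho, sigma_for_pinf(p_inf, rho))
}
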