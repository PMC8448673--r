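#' Parameters of the partially coupled gating model
#'
#' Defines the three-parameter, partially coupled binary Markov chain used to
#' model cooperative gating of a patch containing `n_channels` identical
#' two-state (closed/open) channels. Per time step, with probability `kappa`
#' all channels move in unison (following the single-channel chain applied to
#' the majority state of the patch, ties broken toward open); otherwise each
#' channel gates independently with open-to-open probability `rho` and
#' closed-to-closed probability `sigma_c`.
#'
#' The single-channel stationary open probability implied by (`rho`,
#' `sigma_c`) is `p_inf = (1 - sigma_c) / ((1 - sigma_c) + (1 - rho))`.
#'
#' @param n_channels integer number of channels in the patch, >= 1.
#' @param kappa coupling coefficient in \[0, 1\]; 0 = fully independent,
#'   1 = fully coupled (unison) gating.
#' @param rho per-step open-to-open probability in \[0, 1\].
#' @param sigma_c per-step closed-to-closed probability in \[0, 1\].
#' @param unitary_current unitary single-channel current amplitude (pA), > 0.
#' @param dt duration of one time step (s), > 0.
#' @return An object of class `coupled_markov_params`.
#' @examples
#' p <- coupled_markov_params(2, kappa = 0.3, rho = 0.9, sigma_c = 0.95)
#' p$p_inf
#' @export
coupled_markov_params <- function(n_channels, kappa, rho, sigma_c,
                                  unitary_current = 1.0, dt = 1e-4) {
  n_channels <- as.integer(n_channels)
  stopifnot(length(n_channels) == 1L, length(kappa) == 1L,
            length(rho) == 1L, length(sigma_c) == 1L)
  if (is.na(n_channels) || n_channels < 1L)
    stop("n_channels must be an integer >= 1")
  for (nm in c("kappa", "rho", "sigma_c")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("%s must lie in [0, 1], got %s", nm, format(v)))
  }
  if (rho >= 1 && sigma_c >= 1)
    stop("rho and sigma_c cannot both be 1: stationary open probability undefined")
  if (!is.finite(unitary_current) || unitary_current <= 0)
    stop("unitary_current must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  p_inf <- (1 - sigma_c) / ((1 - sigma_c) + (1 - rho))
  structure(
    list(n_channels = n_channels, kappa = kappa, rho = rho,
         sigma_c = sigma_c, unitary_current = unitary_current, dt = dt,
         p_inf = p_inf),
    class = "coupled_markov_params")
}

#' @export
print.coupled_markov_params <- function(x, ...) {
  cat(sprintf(
    "Coupled gating model: N = %d, kappa = %.4g, rho = %.4g, sigma_c = %.4g\n",
    x$n_channels, x$kappa, x$rho, x$sigma_c))
  cat(sprintf("  unitary current %.3g pA, dt %.3g s, per-channel p_inf %.4g\n",
              x$unitary_current, x$dt, x$p_inf))
  invisible(x)
}

# bare transition matrix without validation/class overhead (optimizer path)
tmat_fast <- function(N, kappa, rho, sigma_c) {
  K <- N + 1L
  tm <- matrix(0, K, K)
  for (k in 0:N) {
    row <- conv_pmf(stats::dbinom(0:k, k, rho),
                    stats::dbinom(0:(N - k), N - k, 1 - sigma_c))
    cp <- numeric(K)
    if (k >= N - k) { cp[K] <- rho; cp[1L] <- 1 - rho }
    else { cp[1L] <- sigma_c; cp[K] <- 1 - sigma_c }
    tm[k + 1L, ] <- (1 - kappa) * row + kappa * cp
  }
  tm
}

# discrete convolution of two probability vectors (indices start at 0)
conv_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Build the aggregate transition matrix of the coupled gating model
#'
#' Constructs the (N+1) x (N+1) row-stochastic transition matrix over the
#' number of simultaneously open channels k in `{0, ..., N}` as the mixture
#' `T = (1 - kappa) * T_unc + kappa * T_cpl`. `T_unc` is the independent-
#' channel kernel: each of the k open channels stays open with probability
#' `rho` and each of the N - k closed channels stays closed with probability
#' `sigma_c` (a binomial convolution). `T_cpl` moves all channels in unison
#' according to the single-channel chain applied to the majority state of the
#' patch (tie broken toward open), so coupled rows place mass only on
#' `{0, N}`.
#'
#' @param params a [coupled_markov_params()] object.
#' @return A `transition_matrix`: numeric matrix with dimnames `"0".."N"` and
#'   attribute `n_channels`.
#' @examples
#' build_transition_matrix(coupled_markov_params(1, 0.5, 0.6, 0.8))
#' @export
build_transition_matrix <- function(params) {
  stopifnot(inherits(params, "coupled_markov_params"))
  N <- params$n_channels
  K <- N + 1L
  t_unc <- matrix(0, K, K)
  t_cpl <- matrix(0, K, K)
  for (k in 0:N) {
    open_stay <- stats::dbinom(0:k, k, params$rho)          # survivors of k open
    closed_open <- stats::dbinom(0:(N - k), N - k, 1 - params$sigma_c)
    t_unc[k + 1L, ] <- conv_pmf(open_stay, closed_open)
    if (k >= N - k) {  # majority open (tie -> open)
      t_cpl[k + 1L, K] <- params$rho
      t_cpl[k + 1L, 1L] <- 1 - params$rho
    } else {
      t_cpl[k + 1L, 1L] <- params$sigma_c
      t_cpl[k + 1L, K] <- 1 - params$sigma_c
    }
  }
  tm <- (1 - params$kappa) * t_unc + params$kappa * t_cpl
  dimnames(tm) <- list(as.character(0:N), as.character(0:N))
  structure(tm, n_channels = N, class = c("transition_matrix", "matrix"))
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi %*% T = pi`, `sum(pi) = 1` by a linear solve; falls back to
#' power iteration. A reducible chain (e.g. fully coupled gating with
#' degenerate `rho`/`sigma_c` = 1, which has two absorbing boundary states)
#' is flagged via attribute `reducible` and the boundary distribution
#' (uniform over absorbing states) is returned with a warning.
#'
#' @param tm a `transition_matrix` (any square row-stochastic matrix works).
#' @return Numeric probability vector over `0..N`, possibly with attribute
#'   `reducible = TRUE`.
#' @export
stationary_distribution <- function(tm) {
  K <- nrow(tm)
  stopifnot(ncol(tm) == K)
  if (max(abs(rowSums(tm) - 1)) > 1e-9) stop("matrix is not row-stochastic")
  absorbing <- which(abs(diag(tm) - 1) < 1e-12)
  if (length(absorbing) > 1L) {
    warning("reducible chain: multiple absorbing states; returning boundary distribution")
    pi_ <- numeric(K)
    pi_[absorbing] <- 1 / length(absorbing)
    names(pi_) <- rownames(tm)
    attr(pi_, "reducible") <- TRUE
    return(pi_)
  }
  a <- rbind(t(diag(K) - tm), rep(1, K))
  b <- c(rep(0, K), 1)
  pi_ <- tryCatch(as.numeric(qr.solve(a, b)), error = function(e) NULL)
  if (is.null(pi_) || any(pi_ < -1e-8)) {
    # power iteration fallback
    pi_ <- rep(1 / K, K)
    for (i in 1:10000) {
      nxt <- as.numeric(pi_ %*% tm)
      if (max(abs(nxt - pi_)) < 1e-14) break
      pi_ <- nxt
    }
  }
  pi_[pi_ < 0] <- 0
  pi_ <- pi_ / sum(pi_)
  names(pi_) <- rownames(tm)
  pi_
}

#' Simulate the aggregate open-channel count process
#'
#' Draws a level path from the configuration-level process of the partially
#' coupled model: per step a Bernoulli(`kappa`) indicator selects a unison
#' move versus independent per-channel moves; because channels are
#' exchangeable the open-channel count is itself Markov with the matrix from
#' [build_transition_matrix()], which is what is sampled (in C++).
#'
#' @param params a [coupled_markov_params()] object.
#' @param n_steps number of samples to draw (>= 1).
#' @param seed integer RNG seed; identical seeds give identical paths.
#' @param init initial level in `0..N`, or `NULL` to draw it from the
#'   stationary distribution.
#' @return A `level_sequence`: list with `levels` (integer vector in `0..N`),
#'   `dt` and `n_channels`.
#' @export
simulate_chain <- function(params, n_steps, seed = NULL, init = NULL) {
  stopifnot(inherits(params, "coupled_markov_params"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  tm <- build_transition_matrix(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    pi_ <- stationary_distribution(tm)
    init <- sample(0:params$n_channels, 1L, prob = pi_)
  }
  lev <- sim_markov_chain(unclass(tm), as.integer(init), as.integer(n_steps))
  level_sequence(lev, dt = params$dt, n_channels = params$n_channels)
}

#' Construct a level sequence
#'
#' @param levels integer vector of simultaneously open channel counts.
#' @param dt sampling interval (s).
#' @param n_channels number of channels N; levels must lie in `0..N`.
#' @return A `level_sequence` object.
#' @export
level_sequence <- function(levels, dt, n_channels) {
  levels <- as.integer(levels)
  n_channels <- as.integer(n_channels)
  if (anyNA(levels)) stop("levels contain NA")
  if (any(levels < 0L) || any(levels > n_channels))
    stop("levels must lie in {0..n_channels}")
  structure(list(levels = levels, dt = dt, n_channels = n_channels),
            class = "level_sequence")
}

# (N+1)x(N+1) matrix of observed transition counts
transition_counts <- function(levels, n_channels) {
  K <- n_channels + 1L
  idx <- levels[-length(levels)] * K + levels[-1L] + 1L
  matrix(tabulate(idx, nbins = K * K), K, K, byrow = TRUE)
}

LOGLIK_FLOOR <- -700  # per-step floor for forbidden transitions

#' Log-likelihood of a level sequence under the coupled gating model
#'
#' Computes `sum_t log T(l_t -> l_{t+1})`. Transitions with zero model
#' probability contribute a floored log-probability of -700 each, with a
#' warning and a `n_forbidden` attribute giving their count.
#'
#' @param seq a `level_sequence` (levels must lie in `0..n_channels` of
#'   `params`).
#' @param params a [coupled_markov_params()] object.
#' @return Log-likelihood in nats (attributes: `n_forbidden`).
#' @export
loglik <- function(seq, params) {
  stopifnot(inherits(seq, "level_sequence"),
            inherits(params, "coupled_markov_params"))
  if (length(seq$levels) < 2L) stop("sequence must contain at least 2 samples")
  if (seq$n_channels != params$n_channels)
    stop("n_channels mismatch between sequence and params")
  tm <- build_transition_matrix(params)
  cnt <- transition_counts(seq$levels, params$n_channels)
  ll_counts(cnt, unclass(tm), warn = TRUE)
}

ll_counts <- function(cnt, tm, warn = FALSE) {
  lt <- suppressWarnings(log(tm))
  bad <- !is.finite(lt) | lt < LOGLIK_FLOOR
  lt[bad] <- LOGLIK_FLOOR
  n_forbidden <- sum(cnt[bad & cnt > 0])
  if (warn && n_forbidden > 0)
    warning(sprintf("%d observed transition(s) forbidden under the model; log-prob floored", n_forbidden))
  structure(sum(cnt * lt), n_forbidden = n_forbidden)
}

#' Fit the coupled gating parameters to an observed level sequence
#'
#' Maximum-likelihood estimation of (`kappa`, `rho`, `sigma_c`) for fixed
#' channel count N by gradient ascent on the logit-reparameterized unit cube
#' (central-difference numerical gradients, backtracking line search,
#' multi-start). Convergence when the log-likelihood improves by less than
#' `tol` or after `max_iter` iterations.
#'
#' A level sequence with no transitions out of a single level carries no
#' information about some parameters; such fits are returned with
#' `degenerate = TRUE` and boundary estimates (an all-closed record pins
#' `sigma_c` at its upper boundary, an all-open record pins `rho`).
#'
#' @param seq a `level_sequence`.
#' @param n_channels channel count N (defaults to the sequence's).
#' @param init optional [coupled_markov_params()] used as the first start.
#' @param n_starts number of optimization starts (default 5: `init` plus a
#'   fixed spread of interior points; deterministic, no RNG).
#' @param max_iter maximum gradient-ascent iterations per start.
#' @param tol convergence tolerance on the log-likelihood change.
#' @return A `markov_fit` list: `params` (fitted `coupled_markov_params`),
#'   `loglik`, `iterations`, `start` (index of the winning start),
#'   `converged`, `degenerate`, `n_forbidden`.
#' @examples
#' p <- coupled_markov_params(2, 0.3, 0.9, 0.95)
#' s <- simulate_chain(p, 5000, seed = 1)
#' fit_params(s)$params
#' @export
fit_params <- function(seq, n_channels = seq$n_channels, init = NULL,
                       n_starts = 5, max_iter = 5000, tol = 1e-8) {
  stopifnot(inherits(seq, "level_sequence"))
  N <- as.integer(n_channels)
  lev <- seq$levels
  if (length(lev) < 2L) stop("sequence must contain at least 2 samples")
  cnt <- transition_counts(lev, N)

  if (length(unique(lev)) == 1L) {
    all_closed <- lev[1] == 0L
    est <- list(kappa = NA_real_, rho = if (all_closed) NA_real_ else 1,
                sigma_c = if (all_closed) 1 else NA_real_)
    return(structure(list(params = est, loglik = 0, iterations = 0L,
                          start = NA_integer_, converged = TRUE,
                          degenerate = TRUE, n_forbidden = 0L),
                     class = "markov_fit"))
  }

  obj <- function(theta) {
    p <- stats::plogis(theta)
    as.numeric(ll_counts(cnt, tmat_fast(N, p[1], p[2], p[3])))
  }
  num_grad <- function(theta, h = 1e-5) {
    g <- numeric(3)
    for (i in 1:3) {
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- dn[i] - h
      g[i] <- (obj(up) - obj(dn)) / (2 * h)
    }
    g
  }

  clamp01 <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  starts <- list(c(0.10, 0.80, 0.80), c(0.50, 0.90, 0.95),
                 c(0.90, 0.60, 0.60), c(0.05, 0.95, 0.98),
                 c(0.30, 0.50, 0.50))
  if (!is.null(init))
    starts <- c(list(c(init$kappa, init$rho, init$sigma_c)), starts)
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (si in seq_along(starts)) {
    theta <- stats::qlogis(clamp01(starts[[si]]))
    ll <- obj(theta)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      g <- num_grad(theta)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      step <- 1 / max(1, gn)  # backtracking line search
      improved <- FALSE
      for (bt in 1:40) {
        cand <- theta + step * g
        llc <- obj(cand)
        if (is.finite(llc) && llc > ll) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      if (abs(llc - ll) < tol) { theta <- cand; ll <- llc; converged <- TRUE; break }
      theta <- cand
      ll <- llc
    }
    if (is.null(best) || ll > best$ll)
      best <- list(theta = theta, ll = ll, it = it, start = si,
                   converged = converged)
  }

  p <- stats::plogis(best$theta)
  pars <- coupled_markov_params(N, p[1], p[2], p[3], unitary_current = 1,
                                dt = seq$dt)
  llA <- ll_counts(cnt, unclass(build_transition_matrix(pars)))
  structure(list(params = pars, loglik = as.numeric(llA),
                 iterations = best$it, start = best$start,
                 converged = best$converged, degenerate = FALSE,
                 n_forbidden = attr(llA, "n_forbidden")),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate fit (constant level sequence); boundary estimates:\n")
    print(unlist(x$params))
  } else {
    cat(sprintf("Coupled gating fit (start %d, %d iterations, logLik %.2f)\n",
                x$start, x$iterations, x$loglik))
    print(x$params)
  }
  invisible(x)
}
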