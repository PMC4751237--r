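#' Initial histories for the nonlinear simulator
#'
#' The model needs the committing rate `p` on the delay interval \[-1, 0\]
#' and the quiescent quantity `Q(0)`.  `history_constant()` uses constant
#' values; `history_steady_state()` starts on the steady state, optionally
#' multiplied by `1 + amplitude` (a uniform relative perturbation).
#'
#' @param p0,Q0 non-negative constants.
#' @param ss a [solve_steady_state()] result.
#' @param amplitude relative perturbation size.
#' @return list with `p_hist` (function on \[-1, 0\]) and `Q0`.
#' @name history
NULL

#' @rdname history
#' @export
history_constant <- function(p0, Q0) {
  stopifnot(p0 >= 0, Q0 >= 0)
  list(p_hist = function(s) rep_len(p0, length(s)), Q0 = Q0)
}

#' @rdname history
#' @export
history_steady_state <- function(ss, amplitude = 0) {
  history_constant(ss$pbar * (1 + amplitude), ss$Qbar * (1 + amplitude))
}

#' Integrate the nonlinear quiescence model by the method of steps
#'
#' Advances the coupled renewal/delay-differential/algebraic system on a
#' uniform grid with `N` points per unit delay, locked to the integer-time
#' breakpoints where the renewal structure propagates discontinuities.  At
#' each node the algebraic pair (p, E) — implicit because the consumption
#' integral's a = 0 endpoint contains p(t) — is solved by damped fixed-point
#' iteration together with a trapezoidal predictor-corrector step for Q; the
#' consumption integral \eqn{\int_0^1 p(t-a)e^{-\mu a}da} uses the composite
#' trapezoidal rule on the stored grid.  The scheme is first-order accurate
#' or better (second-order between breakpoints).
#'
#' @param model a [cell_model()].
#' @param hist a [history] list.
#' @param t_end final time (a multiple of `1/N`).
#' @param N grid points per unit delay, at least 32.
#' @param tol fixed-point tolerance.
#' @return a `trajectory`: tibble with columns `t`, `p`, `Q`, `E`, the model
#'   and grid stored in attributes.
#' @export
integrate_model <- function(model, hist, t_end, N = 256, tol = 1e-12) {
  stopifnot(N >= 32, t_end > 0)
  h <- 1 / N
  M <- round(t_end / h)
  if (abs(M * h - t_end) > 1e-9) {
    rlang::abort("`t_end` must be a multiple of 1/N",
                 class = "delaychart_error_precondition")
  }
  mu <- model$death_rate
  th <- model$theta
  b1f <- model$beta1$value
  Gf <- model$G$value
  emu <- exp(-mu)

  # p on the extended grid: indices 1..(N+M+1) are times -1, -1+h, ..., t_end
  p <- numeric(N + M + 1)
  p[1:N] <- hist$p_hist(seq(-1, -h, by = h))
  Q <- numeric(M + 1)
  E <- numeric(M + 1)
  w <- exp(-mu * seq(0, 1, by = h))          # quadrature weights * h later
  wq <- w * h
  wq[1] <- wq[1] / 2
  wq[length(wq)] <- wq[length(wq)] / 2

  fprev <- NA_real_
  for (n in 0:M) {
    i <- N + 1 + n                            # index of time t_n in p
    pdel <- p[i - N]                          # p(t_n - 1)
    # part of the consumption integral not involving p(t_n)
    S <- sum(wq[-1] * p[(i - 1):(i - N)])
    Qprev <- if (n == 0) hist$Q0 else Q[n]
    pn <- if (n == 0) pdel else p[i - 1]
    Qn <- if (n == 0) hist$Q0 else Qprev + h * fprev
    err_old <- Inf
    damp <- 1
    for (it in seq_len(50)) {
      En <- 1 / (1 + th * (S + wq[1] * pn) + (1 - th) * Qn)
      b1 <- b1f(En)
      g <- Gf(En)
      p_new <- 2 * b1 * emu * pdel + g * Qn
      fn <- 2 * (1 - b1) * emu * pdel - (mu + g) * Qn
      Q_new <- if (n == 0) hist$Q0 else Qprev + h / 2 * (fprev + fn)
      err <- max(abs(p_new - pn), abs(Q_new - Qn))
      if (err > err_old) damp <- 0.5
      pn <- pn + damp * (p_new - pn)
      Qn <- Qn + damp * (Q_new - Qn)
      err_old <- err
      if (err < tol * (1 + abs(pn) + abs(Qn))) break
      if (it == 50L) {
        rlang::abort("fixed-point iteration for (p, E) did not converge",
                     class = "delaychart_error_numeric")
      }
    }
    En <- 1 / (1 + th * (S + wq[1] * pn) + (1 - th) * Qn)
    if (pn < -1e-10 || Qn < -1e-10) {
      rlang::abort(
        sprintf("negative state at t = %.4f (p = %.3e, Q = %.3e)",
                n * h, pn, Qn),
        class = "delaychart_error_numeric"
      )
    }
    p[i] <- pn
    Q[n + 1] <- Qn
    E[n + 1] <- En
    b1 <- b1f(En); g <- Gf(En)
    fprev <- 2 * (1 - b1) * emu * pdel - (mu + g) * Qn
  }

  out <- tibble::tibble(
    t = seq(0, t_end, by = h), p = p[(N + 1):(N + M + 1)], Q = Q, E = E
  )
  class(out) <- c("trajectory", class(out))
  attr(out, "model") <- model
  attr(out, "N") <- N
  out
}

#' Dominant-mode growth rate and frequency of a trajectory
#'
#' Extracts the dominant linear mode from a simulated series by locating the
#' local maxima of `x - center` after the transient `t_min` (peak times and
#' heights refined by 3-point parabolic interpolation): the frequency is
#' \eqn{2\pi} over the mean peak spacing and the rate is the slope of a
#' linear fit of log peak height against peak time.  For a signal
#' \eqn{a e^{\sigma t}\cos(\omega t + \phi) + c} this recovers
#' \eqn{(\sigma, \omega)} essentially exactly.  A non-oscillatory monotone
#' decay (fewer than 4 peaks) yields a rate from the log-envelope fit and
#' `freq = NA`.
#'
#' @param traj a [integrate_model()] trajectory (or any data frame with a `t`
#'   column).
#' @param center the steady-state value to subtract (e.g. `Qbar`).
#' @param t_min transient to discard.
#' @param t_max end of the measurement window: for an unstable steady state
#'   the growing mode is linear only until nonlinear saturation sets in, so
#'   the window must end before the orbit reaches the limit cycle.
#' @param var which column to analyse, default `"Q"`.
#' @return list with `rate` and `freq` (`freq` is `NA_real_` when the signal
#'   does not oscillate).
#' @export
measure_dominant_mode <- function(traj, center, t_min = 0, t_max = Inf,
                                  var = "Q") {
  keep <- traj$t >= t_min & traj$t <= t_max
  t <- traj$t[keep]
  s <- traj[[var]][keep] - center
  n <- length(s)
  if (n < 10) {
    rlang::abort("trajectory too short after `t_min`",
                 class = "delaychart_error_precondition")
  }
  ipk <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
                 s[2:(n - 1)] > 0) + 1
  # discard peaks within three decades of the integrator's error floor
  if (length(ipk) > 0) ipk <- ipk[s[ipk] > max(s[ipk]) * 1e-3]
  if (length(ipk) >= 4) {
    # parabolic refinement of peak location and height
    tp <- numeric(length(ipk)); vp <- numeric(length(ipk))
    ht <- t[2] - t[1]
    for (j in seq_along(ipk)) {
      i <- ipk[j]
      y0 <- s[i - 1]; y1 <- s[i]; y2 <- s[i + 1]
      denom <- y0 - 2 * y1 + y2
      d <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
      d <- max(-0.5, min(0.5, d))
      tp[j] <- t[i] + d * ht
      vp[j] <- y1 - 0.25 * (y0 - y2) * d
    }
    fit <- stats::lm(log(vp) ~ tp)
    rate <- unname(stats::coef(fit)[2])
    freq <- 2 * pi / mean(diff(tp))
    return(list(rate = rate, freq = freq))
  }
  # non-oscillatory: fit the log-envelope where the signal is appreciably
  # above the integrator's error floor
  ok <- abs(s) > max(abs(s)) * 1e-3
  if (sum(ok) < 5) {
    rlang::abort("too few peaks and no usable envelope",
                 class = "delaychart_error_precondition")
  }
  fit <- stats::lm(log(abs(s[ok])) ~ t[ok])
  list(rate = unname(stats::coef(fit)[2]), freq = NA_real_)
}
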