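#' Calibration of response functions to a prescribed steady state
#'
#' The two-parameter case studies pin the steady state \eqn{\bar E} rather
#' than the raw response parameters.  At a steady state,
#' \eqn{R_0(\bar E) = 1} is equivalent to
#' \deqn{G(\bar E) = \frac{(1-\alpha_3)\mu}{2e^{-\mu}-1}, \qquad
#'       \alpha_3 = 2e^{-\mu}\beta_1(\bar E),}
#' so fixing \eqn{(\mu, \beta_1(\bar E), \bar E)} determines \eqn{G(\bar E)}
#' (G-regulated case) and fixing \eqn{(\mu, G, \bar E)} determines
#' \eqn{\beta_1(\bar E) = (1 + G\frac{1-2e^{-\mu}}{\mu}) / (2e^{-\mu})}
#' (beta1-regulated case).
#'
#' `steady_G_value()` and `steady_beta1_value()` return those target values.
#' `calibrated_hill_G()` builds an increasing Hill response with
#' half-saturation at `Ebar` hitting the target, so that the local slope is
#' \eqn{G'(\bar E) = n\,G(\bar E)/(2 h) \cdot h/\bar E = n G(\bar E)/(2\bar E)}
#' for `h = Ebar`; the Hill exponent `n` is therefore the steepness dial at
#' fixed \eqn{\bar E}.  `calibrated_linear_beta1()` builds a linear
#' commitment probability through the target with slope `slope` (the slope
#' must keep values inside \[0, 1) on \[0, 1\]).
#'
#' @param mu death rate.
#' @param beta1_bar commitment probability at the steady state.
#' @param G_const constant quiescence exit rate.
#' @param Ebar prescribed steady-state environment in (0, 1).
#' @param n Hill exponent.
#' @param slope local slope \eqn{\beta_1'(\bar E)}.
#' @name calibration
NULL

#' @rdname calibration
#' @export
steady_G_value <- function(mu, beta1_bar) {
  alpha3 <- 2 * exp(-mu) * beta1_bar
  stopifnot(2 * exp(-mu) > 1, alpha3 < 1)
  (1 - alpha3) * mu / (2 * exp(-mu) - 1)
}

#' @rdname calibration
#' @export
steady_beta1_value <- function(mu, G_const) {
  stopifnot(2 * exp(-mu) > 1)
  val <- (1 + G_const * (1 - 2 * exp(-mu)) / mu) / (2 * exp(-mu))
  if (val <= 0 || val >= 1) {
    rlang::abort("calibration target for beta1(Ebar) falls outside (0, 1)",
                 class = "delaychart_error_config")
  }
  val
}

#' @rdname calibration
#' @export
calibrated_hill_G <- function(mu, beta1_bar, Ebar, n) {
  target <- steady_G_value(mu, beta1_bar)
  h <- Ebar
  gmax <- target * (Ebar^n + h^n) / Ebar^n    # = 2 * target for h = Ebar
  response_hill(gmax, n, h)
}

#' @rdname calibration
#' @export
calibrated_linear_beta1 <- function(mu, G_const, Ebar, slope) {
  target <- steady_beta1_value(mu, G_const)
  a <- target - slope * Ebar
  if (a < 0 || a + slope >= 1) {
    rlang::abort("linear beta1 leaves [0, 1) on [0, 1]; reduce `slope`",
                 class = "delaychart_error_config")
  }
  response_linear(a, slope)
}

#' Worked model instances
#'
#' Named fixtures used throughout the examples, tests and charts:
#'
#' * `"fig4"`: \eqn{\mu = 0.5}, constant \eqn{\beta_1 = 0.5}, increasing Hill
#'   G with half-saturation at \eqn{\bar E = 0.5} calibrated so that
#'   \eqn{\bar E = 0.5} is the steady state.  The default Hill exponent is 4.
#' * `"shallow"` / `"steep"`: same, but with Hill exponent 2 resp. 120
#'   (recalibrated, so \eqn{\bar E} and \eqn{\alpha_3} are unchanged and only
#'   the local steepness \eqn{G'(\bar E) = n G(\bar E)/(2\bar E)} moves).  In
#'   this setting the theta line first touches the Hopf boundary at
#'   \eqn{G'(\bar E) \approx 65}, so the shallow fixture is stable for all
#'   \eqn{\theta \in [1/2, 1]} while the steep one has a critical
#'   \eqn{\theta_{crit} \in (1/2, 2/3)}.
#' * `"extinction"`: \eqn{\mu = 0.8}, so \eqn{2e^{-\mu} < 1} and
#'   \eqn{R_0(1) < 1} — the population dies out.
#' * `"blowup"`: \eqn{\mu = 0.2} with a large constant G, so
#'   \eqn{R_0(0) > 1} — unbounded growth.
#'
#' @param name fixture name.
#' @param theta consumption weight override (default 0.8).
#' @param hill_n Hill exponent override for the G response.
#' @return a [cell_model()].
#' @export
make_fixture <- function(name = c("fig4", "shallow", "steep", "extinction",
                                  "blowup"),
                         theta = 0.8, hill_n = NULL) {
  name <- rlang::arg_match(name)
  switch(name,
    fig4 = cell_model(
      death_rate = 0.5, theta = theta,
      beta1 = response_constant(0.5),
      G = calibrated_hill_G(0.5, 0.5, 0.5, n = hill_n %||% 4)
    ),
    shallow = make_fixture("fig4", theta = theta, hill_n = hill_n %||% 2),
    steep = make_fixture("fig4", theta = theta, hill_n = hill_n %||% 120),
    extinction = cell_model(
      death_rate = 0.8, theta = theta,
      beta1 = response_constant(0.5),
      G = response_hill(1.8, 2, 0.5)
    ),
    blowup = cell_model(
      death_rate = 0.2, theta = theta,
      beta1 = response_constant(0.5),
      G = response_constant(5)
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Random valid cell models for property sweeps
#'
#' Draws a cell model satisfying the steady-state existence conditions by
#' construction: \eqn{\mu \sim U(0.05, 0.6)} (so \eqn{2e^{-\mu} > 1}),
#' \eqn{\theta \sim U(0, 1)}, a prescribed steady state
#' \eqn{\bar E \sim U(0.2, 0.8)}, an increasing Hill G calibrated through
#' \eqn{\bar E} with exponent \eqn{n \sim U(1.5, 6)}, and either a constant
#' or (with probability 1/2) a gently increasing linear commitment
#' probability.  Uses R's RNG; seed with [set.seed()].
#'
#' @return a [cell_model()].
#' @export
random_valid_model <- function() {
  for (i in seq_len(50)) {
    mu <- stats::runif(1, 0.05, 0.6)
    theta <- stats::runif(1, 0, 1)
    Ebar <- stats::runif(1, 0.2, 0.8)
    bmax <- min(0.75, 0.95 * exp(mu) / 2)
    b1bar <- stats::runif(1, 0.05, bmax)
    if (stats::runif(1) < 0.5) {
      beta1 <- response_constant(b1bar)
    } else {
      smax <- min(b1bar / Ebar, (1 - b1bar) / (1 - Ebar)) * 0.9
      beta1 <- response_linear(b1bar - 0.5 * smax * Ebar, 0.5 * smax)
    }
    G <- calibrated_hill_G(mu, beta1$value(Ebar), Ebar,
                           n = stats::runif(1, 1.5, 6))
    m <- try(cell_model(mu, theta, beta1, G), silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
  }
  rlang::abort("failed to draw a valid model")
}
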