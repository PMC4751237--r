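#' Coefficient path under variation of the consumption weight theta
#'
#' The steady state \eqn{\bar E} does not depend on \eqn{\theta}, and neither
#' do \eqn{\alpha_3} nor the sum \eqn{\alpha_1+\alpha_2 =
#' (1-2e^{-\mu})A(\bar E)}.  Varying \eqn{\theta} therefore moves the
#' coefficient point along a line of slope \eqn{-1} in the
#' \eqn{(\alpha_1,\alpha_2)}-plane, with \eqn{\alpha_1} strictly decreasing in
#' \eqn{\theta} (since \eqn{l < 1}); increasing \eqn{\theta} moves North-West.
#'
#' @inheritParams linearization_coeffs
#' @param thetas numeric vector of consumption weights in \[0, 1\].
#' @return tibble with columns `theta`, `alpha1`, `alpha2`, `alpha3`.
#' @export
theta_path <- function(model, ss, thetas = seq(0, 1, length.out = 201)) {
  purrr::map_dfr(thetas, function(th) {
    co <- linearization_coeffs(model, ss, theta = th)
    tibble::tibble(theta = th, alpha1 = co$alpha1, alpha2 = co$alpha2,
                   alpha3 = co$alpha3)
  })
}

#' Hopf point of the theta line
#'
#' The line traced by [theta_path()] intersects the Hopf boundary curve C0
#' where
#' \deqn{\frac{\omega}{\sin\omega}(\cos\omega - 1) =
#'   \frac{1-2e^{-\mu}}{1+2e^{-\mu}\beta_1(\bar E)} A(\bar E).}
#' The left-hand side decreases strictly from 0 (at \eqn{\omega = 0}) to
#' \eqn{-\infty} (at \eqn{\omega = \pi}) and the right-hand side is negative
#' (as \eqn{2e^{-\mu} > 1} and \eqn{A(\bar E) > 0}), so a unique solution
#' \eqn{\omega^* \in (0,\pi)} exists; it is found by bisection.  The
#' corresponding abscissa is \eqn{\bar\alpha_1 = c_1(\omega^*, \alpha_3)}.
#'
#' @inheritParams linearization_coeffs
#' @return list with `omega_star` and `alpha1_bar`.
#' @export
hopf_point <- function(model, ss) {
  mu <- model$death_rate
  twoe <- 2 * exp(-mu)
  if (twoe <= 1) {
    rlang::abort("2 e^{-mu} <= 1: no nontrivial steady state regime",
                 class = "delaychart_error_precondition")
  }
  if (ss$A <= 0) {
    rlang::abort("A(Ebar) must be positive",
                 class = "delaychart_error_precondition")
  }
  alpha3 <- twoe * model$beta1$value(ss$Ebar)
  rhs <- (1 - twoe) / (1 + alpha3) * ss$A
  lhs <- function(w) ifelse(w == 0, 0, w / sin(w) * (cos(w) - 1))
  lo <- 0
  hi <- pi - 1e-9
  while (lhs(hi) > rhs) hi <- pi - (pi - hi) / 10
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-14) break
    if (lhs(mid) > rhs) lo <- mid else hi <- mid
  }
  omega_star <- (lo + hi) / 2
  list(omega_star = omega_star, alpha1_bar = c1_of(omega_star, alpha3))
}

#' Critical consumption weight
#'
#' For \eqn{\theta \in [2/3, 1]} the nontrivial steady state is always
#' asymptotically stable.  On \eqn{[1/2, 1]} the test is: with
#' \eqn{\bar\alpha_1} from [hopf_point()] and the \eqn{\theta = 1/2} abscissa
#' \eqn{\alpha_1(1/2) = -\mu - G(\bar E)},
#' * if \eqn{-\mu - G(\bar E) < \bar\alpha_1}, the steady state is stable for
#'   all \eqn{\theta \in [1/2, 1]} and `NA` is returned;
#' * otherwise there is a unique \eqn{\theta_{crit} \in (1/2, 2/3)} where the
#'   theta line crosses C0: unstable below it, stable above it.  It solves
#'   \eqn{\alpha_1(\theta) = \bar\alpha_1} and is found by bisection
#'   (tolerance `1e-10`), exact since \eqn{\alpha_1(\theta)} is strictly
#'   decreasing.
#'
#' @inheritParams linearization_coeffs
#' @return numeric scalar in (1/2, 2/3), or `NA_real_`.
#' @export
theta_crit <- function(model, ss) {
  hp <- hopf_point(model, ss)
  mu <- model$death_rate
  g <- model$G$value(ss$Ebar)
  a1_half <- -mu - g
  if (a1_half < hp$alpha1_bar) return(NA_real_)
  a1_of <- function(th) linearization_coeffs(model, ss, theta = th)$alpha1
  lo <- 0.5
  hi <- 2 / 3
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-10) break
    if (a1_of(mid) > hp$alpha1_bar) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Map a boundary curve to the model-parameter plane
#'
#' Transforms a boundary curve in the \eqn{(\alpha_1,\alpha_2)}-plane into
#' the plane of (response steepness, \eqn{\theta}), for the two case studies:
#'
#' * `case = "g_regulated"`: constant \eqn{\beta_1}, regulation through the
#'   quiescence exit rate G; the steepness coordinate is \eqn{G'(\bar E)}.
#' * `case = "beta1_regulated"`: constant G, regulation through the
#'   commitment probability; the steepness coordinate is
#'   \eqn{\beta_1'(\bar E)}, which equals the G-regulated steepness times the
#'   factor \eqn{(2e^{-\mu}-1)/(2e^{-\mu}\mu)}, fully determined by \eqn{\mu}.
#'
#' The inverse parameter map is
#' \deqn{\theta = \frac{\alpha_2 - \mu\alpha_3 + 2e^{-\mu}(\alpha_1+\mu)}
#'   {3e^{-\mu}(\alpha_1+\mu) + 2(\alpha_2-\mu\alpha_3) - e^{-\mu}G(\bar E)},}
#' \deqn{G'(\bar E) = \frac{\alpha_1+\mu+G(\bar E)}{\bar E(1-\bar E)}
#'   \cdot \frac{1-l\theta}{1-2\theta}.}
#' Points at the pole \eqn{|1-2\theta| <} `pole_tol` are dropped (recorded in
#' the `"dropped"` attribute); `in_range` flags \eqn{\theta \in [0,1]}.
#'
#' @param curve a [build_curve()] tibble (typically C0 or C1_plus) whose
#'   `alpha3` matches the model's \eqn{\alpha_3 = 2e^{-\mu}\beta_1(\bar E)}.
#' @inheritParams linearization_coeffs
#' @param case which regulatory mechanism carries the steepness coordinate.
#' @param pole_tol pole-exclusion tolerance on \eqn{|1-2\theta|}.
#' @return tibble with columns `case`, `source_branch`, `omega`, `slope`,
#'   `theta`, `in_range`.
#' @export
map_to_model_plane <- function(curve, model, ss,
                               case = c("g_regulated", "beta1_regulated"),
                               pole_tol = 1e-10) {
  case <- rlang::arg_match(case)
  mu <- model$death_rate
  emu <- exp(-mu)
  gbar <- model$G$value(ss$Ebar)
  alpha3 <- 2 * emu * model$beta1$value(ss$Ebar)
  if (max(abs(curve$alpha3 - alpha3)) > 1e-8) {
    rlang::abort("`curve` was built for a different alpha3 than the model's",
                 class = "delaychart_error_precondition")
  }
  a1 <- curve$alpha1
  a2 <- curve$alpha2
  theta <- (a2 - mu * alpha3 + 2 * emu * (a1 + mu)) /
    (3 * emu * (a1 + mu) + 2 * (a2 - mu * alpha3) - emu * gbar)
  slope_g <- (a1 + mu + gbar) / (ss$Ebar * (1 - ss$Ebar)) *
    (1 - ss$l * theta) / (1 - 2 * theta)
  slope <- if (case == "g_regulated") {
    slope_g
  } else {
    slope_g * (2 * emu - 1) / (2 * emu * mu)
  }
  keep <- abs(1 - 2 * theta) >= pole_tol
  out <- tibble::tibble(
    case = case,
    source_branch = curve$branch[keep],
    omega = curve$omega[keep],
    slope = slope[keep],
    theta = theta[keep],
    in_range = theta[keep] >= 0 & theta[keep] <= 1
  )
  attr(out, "dropped") <- sum(!keep)
  if (any(!keep)) {
    rlang::inform(paste(sum(!keep), "curve point(s) dropped at the theta = 1/2 pole"))
  }
  out
}

#' Coefficients from a point of the model-parameter plane
#'
#' Inverse of [map_to_model_plane()]: given a steepness/theta pair, rebuild
#' the linearisation coefficients through
#' \eqn{A(\bar E) = \text{slope}\cdot\bar E(1-\bar E)} (times the
#' \eqn{\mu}-factor for the beta1-regulated case) and the coefficient
#' formulas of [linearization_coeffs()].
#'
#' @param slope local response steepness (\eqn{G'(\bar E)} or
#'   \eqn{\beta_1'(\bar E)} according to `case`).
#' @param theta consumption weight.
#' @inheritParams map_to_model_plane
#' @return named list with `alpha1`, `alpha2`, `alpha3`.
#' @export
coeffs_from_model_plane <- function(slope, theta, model, ss,
                                    case = c("g_regulated",
                                             "beta1_regulated")) {
  case <- rlang::arg_match(case)
  mu <- model$death_rate
  emu <- exp(-mu)
  gbar <- model$G$value(ss$Ebar)
  b1 <- model$beta1$value(ss$Ebar)
  gprime <- if (case == "g_regulated") {
    slope
  } else {
    slope * (2 * emu * mu) / (2 * emu - 1)
  }
  A <- gprime * ss$Ebar * (1 - ss$Ebar)
  fac <- A / (1 - ss$l * theta)
  list(
    alpha1 = -mu - gbar + fac * (1 - 2 * theta),
    alpha2 = 2 * emu * (mu * b1 + gbar + fac * (1.5 * theta - 1)),
    alpha3 = 2 * emu * b1
  )
}
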