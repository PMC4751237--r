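#' Environmental response functions
#'
#' The cell model couples to the environment E (a scaled resource
#' concentration in \[0, 1\]) through two continuously differentiable
#' responses: the probability \eqn{\beta_1(E)} of committing to division at
#' the cell-cycle checkpoint (the complementary probability
#' \eqn{\beta_2 = 1-\beta_1} is quiescence) and the reactivation rate
#' \eqn{G(E)} of quiescent cells.  The model itself leaves their shape open;
#' three parametric families cover the case studies:
#'
#' * `response_constant(value)`: \eqn{f(E) = v},
#' * `response_hill(gmax, n, h)`: increasing Hill function
#'   \eqn{f(E) = g_{max} E^n / (E^n + h^n)},
#' * `response_linear(a, b)`: \eqn{f(E) = a + bE} (clamped to the requested
#'   admissible range when evaluated),
#' * `response_custom(f, deriv = NULL)`: arbitrary function; if no derivative
#'   is supplied, central differences with step `1e-6` are used, with a
#'   warning, since the linearisation needs \eqn{f'} at the steady state.
#'
#' @param value,gmax,n,h,a,b family parameters.
#' @param f,deriv functions of `E` for the custom family.
#' @return an object of class `response_fn` with elements `family`, `params`,
#'   `value(E)` and `derivative(E)`.
#' @name response_fn
NULL

new_response <- function(family, params, value, derivative) {
  structure(
    list(family = family, params = params, value = value,
         derivative = derivative),
    class = "response_fn"
  )
}

#' @rdname response_fn
#' @export
response_constant <- function(value) {
  stopifnot(is.finite(value))
  force(value)
  new_response(
    "constant", list(value = value),
    function(E) rep_len(value, length(E)),
    function(E) rep_len(0, length(E))
  )
}

#' @rdname response_fn
#' @export
response_hill <- function(gmax, n, h) {
  stopifnot(gmax > 0, n > 0, h > 0)
  force(gmax); force(n); force(h)
  new_response(
    "hill_increasing", list(gmax = gmax, n = n, h = h),
    function(E) gmax * E^n / (E^n + h^n),
    function(E) gmax * n * h^n * E^(n - 1) / (E^n + h^n)^2
  )
}

#' @rdname response_fn
#' @export
response_linear <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  force(a); force(b)
  new_response(
    "linear_clamped", list(a = a, b = b),
    function(E) a + b * E,
    function(E) rep_len(b, length(E))
  )
}

#' @rdname response_fn
#' @export
response_custom <- function(f, deriv = NULL) {
  stopifnot(is.function(f))
  if (is.null(deriv)) {
    rlang::warn("no derivative supplied; using central differences (step 1e-6)")
    deriv <- function(E) (f(E + 1e-6) - f(E - 1e-6)) / 2e-6
  }
  new_response("custom", list(), f, deriv)
}

#' @export
print.response_fn <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, format, ""), sep = "=",
              collapse = ", ")
  cat("<response_fn ", x$family, if (nzchar(ps)) paste0(" (", ps, ")"), ">\n",
      sep = "")
  invisible(x)
}

#' Quiescence cell population model
#'
#' The scaled model of a cell population split into proliferating cells
#' (committing rate `p`) and quiescent cells (`Q`), coupled to the
#' environment `E` through consumption:
#' \deqn{p(t) = 2\beta_1(E(t)) e^{-\mu} p(t-1) + G(E(t)) Q(t)}
#' \deqn{Q'(t) = 2\beta_2(E(t)) e^{-\mu} p(t-1) - (\mu + G(E(t))) Q(t)}
#' \deqn{E(t) = 1 / (1 + \theta \int_0^1 p(t-a) e^{-\mu a}\,da +
#'       (1-\theta) Q(t))}
#' Time is scaled so the cell-cycle delay is 1; \eqn{\mu \ge 0} is the death
#' rate; \eqn{\theta \in [0,1]} weights the resource consumption of
#' proliferating versus quiescent cells; \eqn{\beta_2 \equiv 1 - \beta_1}.
#'
#' @param death_rate per-capita death rate \eqn{\mu \ge 0}.
#' @param theta consumption weight in \[0, 1\].
#' @param beta1 [response_fn] for the division-commitment probability; its
#'   values must lie in \[0, 1).
#' @param G [response_fn] for the quiescence exit rate; values must be
#'   positive on (0, 1\].
#' @return object of class `cell_model`.
#' @export
cell_model <- function(death_rate, theta, beta1, G) {
  stopifnot(is.numeric(death_rate), death_rate >= 0,
            is.numeric(theta), theta >= 0, theta <= 1,
            inherits(beta1, "response_fn"), inherits(G, "response_fn"))
  Egrid <- seq(0, 1, length.out = 101)
  b <- beta1$value(Egrid)
  if (any(b < 0 | b >= 1)) {
    rlang::abort("`beta1` must take values in [0, 1) on [0, 1]",
                 class = "delaychart_error_config")
  }
  if (any(G$value(Egrid[-1]) <= 0)) {
    rlang::abort("`G` must be positive on (0, 1]",
                 class = "delaychart_error_config")
  }
  structure(
    list(death_rate = death_rate, theta = theta, beta1 = beta1, G = G),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>  mu =", format(x$death_rate),
      " theta =", format(x$theta), "\n")
  cat("  beta1:", x$beta1$family, " G:", x$G$family, "\n")
  invisible(x)
}

#' Basic reproduction number at fixed environment
#'
#' Expected number of progeny arriving at the cell-cycle checkpoint per
#' checkpoint arrival, in a constant environment `E`:
#' \deqn{R_0(E) = 2 e^{-\mu} \frac{\beta_1(E)\mu + G(E)}{\mu + G(E)}.}
#' A nontrivial steady state \eqn{\bar E} solves \eqn{R_0(\bar E) = 1}.
#'
#' @param model a [cell_model()].
#' @param E environment value(s) in \[0, 1\].
#' @return numeric vector.
#' @export
R0 <- function(model, E) {
  mu <- model$death_rate
  g <- model$G$value(E)
  if (any(mu + g == 0)) {
    rlang::abort("R0 is undefined where mu = 0 and G(E) = 0",
                 class = "delaychart_error_precondition")
  }
  2 * exp(-mu) * (model$beta1$value(E) * mu + g) / (mu + g)
}

#' Nontrivial steady state of the quiescence model
#'
#' Solves \eqn{R_0(\bar E) = 1} on \[0, 1\] by bisection (tolerance `1e-12`)
#' and assembles the steady state and the derived quantities used by the
#' linearisation:
#' \deqn{l = \frac{3e^{-\mu}-2}{2e^{-\mu}-1} \in (-\infty, 1), \qquad
#'   K = \left(\tfrac{1}{\bar E}-1\right)
#'       \frac{1}{(1-2e^{-\mu}\beta_1(\bar E))(1-l\theta)},}
#' \deqn{(\bar p, \bar Q) = \left(\tfrac{1}{\bar E}-1\right)
#'   \frac{1}{1-l\theta}\left(\frac{\mu}{2e^{-\mu}-1},\, 1\right), \qquad
#'   A(\bar E) = \left(\frac{2e^{-\mu}\mu}{2e^{-\mu}-1}\beta_1'(\bar E)
#'     + G'(\bar E)\right) \bar E (1-\bar E).}
#'
#' Existence and uniqueness require \eqn{R_0(0) < 1 < R_0(1)} and the
#' monotonicity hypothesis \eqn{\beta_1'(E)(\mu+G(E)) +
#' G'(E)(1-\beta_1(E)) > 0} on (0, 1); both are checked (the hypothesis on a
#' 1001-point grid).  Distinct error classes flag the extinction regime
#' (\eqn{R_0(1) \le 1}), the unbounded-growth regime (\eqn{R_0(0) \ge 1}) and
#' hypothesis violations.
#'
#' @param model a [cell_model()].
#' @param tol bisection tolerance for \eqn{\bar E}.
#' @return object of class `steady_state`: list with `Ebar`, `pbar`, `Qbar`,
#'   `K`, `l`, `A`.
#' @export
solve_steady_state <- function(model, tol = 1e-12) {
  mu <- model$death_rate
  if (R0(model, 1) <= 1) {
    rlang::abort(
      "extinction regime: R0(1) <= 1, the population dies out and no nontrivial steady state exists",
      class = "delaychart_error_extinction"
    )
  }
  if (R0(model, 0) >= 1) {
    rlang::abort(
      "unbounded growth regime: R0(0) >= 1, the population grows beyond bound and no steady state in (0,1) exists",
      class = "delaychart_error_blowup"
    )
  }
  Egrid <- seq(1e-3, 1 - 1e-3, length.out = 1001)
  hyp <- model$beta1$derivative(Egrid) * (mu + model$G$value(Egrid)) +
    model$G$derivative(Egrid) * (1 - model$beta1$value(Egrid))
  # steep responses underflow to 0 far from their half-saturation point;
  # only genuinely negative values violate monotonicity
  if (any(hyp < 0) || all(hyp == 0)) {
    rlang::abort(
      "monotonicity hypothesis violated: beta1'(E)(mu+G(E)) + G'(E)(1-beta1(E)) must be positive on (0,1)",
      class = "delaychart_error_hypothesis"
    )
  }

  lo <- 0; hi <- 1
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (R0(model, mid) < 1) lo <- mid else hi <- mid
  }
  Ebar <- (lo + hi) / 2

  th <- model$theta
  b1 <- model$beta1$value(Ebar)
  twoe <- 2 * exp(-mu)
  if (twoe * b1 >= 1) {
    rlang::abort("inconsistent state: 2 e^{-mu} beta1(Ebar) >= 1",
                 class = "delaychart_error_precondition")
  }
  l <- (3 * exp(-mu) - 2) / (twoe - 1)
  K <- (1 / Ebar - 1) / ((1 - twoe * b1) * (1 - l * th))
  fac <- (1 / Ebar - 1) / (1 - l * th)
  pbar <- fac * mu / (twoe - 1)
  Qbar <- fac
  A <- (twoe * mu / (twoe - 1) * model$beta1$derivative(Ebar) +
          model$G$derivative(Ebar)) * Ebar * (1 - Ebar)

  structure(
    list(Ebar = Ebar, pbar = pbar, Qbar = Qbar, K = K, l = l, A = A),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>\n")
  cat(sprintf("  Ebar = %.6f   pbar = %.6f   Qbar = %.6f\n",
              x$Ebar, x$pbar, x$Qbar))
  cat(sprintf("  K = %.6f   l = %.6f   A(Ebar) = %.6f\n", x$K, x$l, x$A))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.steady_state <- function(x, ...) {
  tibble::tibble(
    term = c("Ebar", "pbar", "Qbar", "K", "l", "A"),
    estimate = c(x$Ebar, x$pbar, x$Qbar, x$K, x$l, x$A)
  )
}

#' Linearisation coefficients at the nontrivial steady state
#'
#' The characteristic equation of the linearised model is the scalar neutral
#' equation with
#' \deqn{\alpha_1 = -\mu - G(\bar E) + A(\bar E)\frac{1-2\theta}{1-l\theta},}
#' \deqn{\alpha_2 = 2e^{-\mu}\left(\mu\beta_1(\bar E) + G(\bar E) +
#'   A(\bar E)\frac{\frac{3}{2}\theta-1}{1-l\theta}\right),}
#' \deqn{\alpha_3 = 2e^{-\mu}\beta_1(\bar E) \in (0, 1),}
#' and satisfies the transcritical identity
#' \eqn{\alpha_1 + \alpha_2 = (1 - 2e^{-\mu}) A(\bar E)}.
#'
#' @param model a [cell_model()].
#' @param ss its [solve_steady_state()] result.
#' @param theta optional override of the model's consumption weight (the
#'   steady state does not depend on it).
#' @return named list with `alpha1`, `alpha2`, `alpha3`.
#' @export
linearization_coeffs <- function(model, ss, theta = model$theta) {
  mu <- model$death_rate
  b1 <- model$beta1$value(ss$Ebar)
  g <- model$G$value(ss$Ebar)
  twoe <- 2 * exp(-mu)
  fac <- ss$A / (1 - ss$l * theta)
  list(
    alpha1 = -mu - g + fac * (1 - 2 * theta),
    alpha2 = twoe * (mu * b1 + g + fac * (1.5 * theta - 1)),
    alpha3 = twoe * b1
  )
}

# (1 - e^{-(mu + lambda)}) / (mu + lambda), extended by its limit 1 at
# lambda = -mu
expm1_ratio <- function(z) {
  small <- Mod(z) < 1e-6
  out <- z
  out[small] <- 1 - z[small] / 2 + z[small]^2 / 6   # series about z = 0
  out[!small] <- (1 - exp(-z[!small])) / z[!small]
  out
}

#' Determinant of the characteristic matrix of the linearised system
#'
#' Evaluates \eqn{\det M(\lambda)} for the 2x2 characteristic matrix of the
#' linearised (p, Q) system.  Its zero set coincides with the zero set of the
#' scalar characteristic function [char_value()] with coefficients from
#' [linearization_coeffs()]; the package asserts the coincidence of zero
#' sets, not a proportionality factor.  The removable singularity at
#' \eqn{\lambda = -\mu} is handled by the limit of
#' \eqn{(1-e^{-(\mu+\lambda)})/(\mu+\lambda)}.
#'
#' @inheritParams linearization_coeffs
#' @param lambda complex evaluation point(s).
#' @return complex vector.
#' @export
char_matrix_det <- function(lambda, model, ss) {
  lambda <- as.complex(lambda)
  mu <- model$death_rate
  th <- model$theta
  b1 <- model$beta1$value(ss$Ebar)
  g <- model$G$value(ss$Ebar)
  twoe <- 2 * exp(-mu)
  Afac <- ss$A / (1 - ss$l * th)
  e <- exp(-lambda)
  q <- expm1_ratio(mu + lambda)
  M11 <- 1 - twoe * b1 * e + Afac * th * q
  M12 <- -g + Afac * (1 - th)
  M21 <- twoe * (b1 - 1) * e - Afac * th * q
  M22 <- lambda + mu + g - Afac * (1 - th)
  M11 * M22 - M12 * M21
}

#' Full linear stability assessment of a cell model
#'
#' Pipeline composition: solve the steady state, compute the linearisation
#' coefficients, and classify the coefficient point against the stability
#' region of the characteristic equation.
#'
#' @param model a [cell_model()].
#' @param tol boundary-proximity tolerance passed to [classify_point()].
#' @return object of class `stability_assessment`: list with `verdict` (the
#'   [classify_point()] row), `coeffs` and `steady_state`.
#' @export
assess_stability <- function(model, tol = 1e-8) {
  ss <- solve_steady_state(model)
  co <- linearization_coeffs(model, ss)
  verdict <- classify_point(co$alpha1, co$alpha2, co$alpha3, tol = tol)
  structure(
    list(verdict = verdict, coeffs = co, steady_state = ss),
    class = "stability_assessment"
  )
}

#' @export
print.stability_assessment <- function(x, ...) {
  cat("<stability_assessment>\n")
  cat(sprintf("  alpha = (%.6f, %.6f, %.6f)\n",
              x$coeffs$alpha1, x$coeffs$alpha2, x$coeffs$alpha3))
  cat("  steady state Ebar =", format(x$steady_state$Ebar, digits = 8), "\n")
  cat("  stable:", x$verdict$stable, " (", x$verdict$note, ")\n")
  invisible(x)
}

#' @export
tidy.stability_assessment <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "alpha2", "alpha3", "Ebar", "pbar", "Qbar", "A"),
    estimate = c(x$coeffs$alpha1, x$coeffs$alpha2, x$coeffs$alpha3,
                 x$steady_state$Ebar, x$steady_state$pbar,
                 x$steady_state$Qbar, x$steady_state$A)
  )
}

#' @export
glance.stability_assessment <- function(x, ...) {
  tibble::tibble(
    stable = x$verdict$stable,
    note = x$verdict$note,
    alpha1 = x$coeffs$alpha1,
    alpha2 = x$coeffs$alpha2,
    alpha3 = x$coeffs$alpha3,
    Ebar = x$steady_state$Ebar
  )
}
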