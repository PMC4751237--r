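#' Critical-curve coordinates
#'
#' For \eqn{\lambda = \pm i\omega} to be a characteristic root, the
#' coefficients must satisfy \eqn{\alpha_1 = c_1(\omega,\alpha_3)},
#' \eqn{\alpha_2 = c_2(\omega,\alpha_3)} with
#' \deqn{c_1 = \frac{\omega}{\sin\omega}(\cos\omega - \alpha_3), \qquad
#'       c_2 = \frac{\omega}{\sin\omega}(\alpha_3\cos\omega - 1).}
#' At \eqn{\omega = 0} the removable limit \eqn{(1-\alpha_3, \alpha_3-1)} is
#' returned; this is the corner where the zero-root half-line L meets the
#' Hopf curve C0 and where \eqn{\lambda = 0} is a double root.  Multiples of
#' \eqn{\pi} (other than 0) are poles and are rejected.
#'
#' @param omega non-negative frequency (vectorised); must avoid
#'   \eqn{m\pi, m \ge 1}.
#' @param alpha3 neutral-term coefficient, \eqn{|\alpha_3| < 1}.
#' @return tibble with columns `omega`, `alpha1`, `alpha2`.
#' @export
c_point <- function(omega, alpha3) {
  check_alpha3(alpha3)
  if (any(omega < 0)) {
    rlang::abort("`omega` must be non-negative",
                 class = "delaychart_error_precondition")
  }
  m <- round(omega / pi)
  if (any(m >= 1 & abs(omega - m * pi) < 1e-14)) {
    rlang::abort("`omega` = m*pi, m >= 1, is a pole of c1, c2",
                 class = "delaychart_error_precondition")
  }
  fac <- ifelse(omega == 0, 1, omega / sin(omega))
  tibble::tibble(
    omega = omega,
    alpha1 = fac * (cos(omega) - alpha3),
    alpha2 = fac * (alpha3 * cos(omega) - 1)
  )
}

# scalar c1 as a function of omega (vectorised), omega in a pole-free interval
c1_of <- function(omega, alpha3) {
  ifelse(omega == 0, 1 - alpha3, omega / sin(omega) * (cos(omega) - alpha3))
}

c2_of <- function(omega, alpha3) {
  ifelse(omega == 0, alpha3 - 1, omega / sin(omega) * (alpha3 * cos(omega) - 1))
}

#' Height of the Hopf boundary curve C0 over a given alpha1
#'
#' \eqn{c_1(\cdot,\alpha_3)} is strictly decreasing on \eqn{[0,\pi)} with
#' range \eqn{(-\infty, 1-\alpha_3]}, so C0 is the graph of a function
#' \eqn{\varphi(\alpha_1) = c_2(\omega^*)} where \eqn{\omega^*} solves
#' \eqn{c_1(\omega^*, \alpha_3) = \alpha_1}.  The solution is found by
#' bisection.
#'
#' @param alpha1 abscissa (vectorised), must not exceed \eqn{1 - \alpha_3}.
#' @inheritParams c_point
#' @return numeric vector \eqn{\varphi(\alpha_1)}.
#' @export
c0_height <- function(alpha1, alpha3) {
  check_alpha3(alpha3)
  if (any(alpha1 > 1 - alpha3 + 1e-14)) {
    rlang::abort(
      "`alpha1` must be <= 1 - alpha3: C0 has no point to the right of the corner",
      class = "delaychart_error_precondition"
    )
  }
  vapply(pmin(alpha1, 1 - alpha3), function(a1) {
    w <- c0_omega(a1, alpha3)
    c2_of(w, alpha3)
  }, double(1))
}

# omega in [0, pi) with c1(omega, alpha3) = a1, by bisection (c1 decreasing)
c0_omega <- function(a1, alpha3, tol = 1e-12) {
  if (a1 >= 1 - alpha3) return(0)
  lo <- 0
  hi <- pi - 1e-9
  while (c1_of(hi, alpha3) > a1) hi <- pi - (pi - hi) / 10
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (c1_of(mid, alpha3) > a1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# omega in the open interval (wl, wr) (one branch C_k^±, c1 decreasing from
# +Inf to -Inf) with c1(omega) = a1
ck_omega <- function(a1, wl, wr, alpha3, tol = 1e-12) {
  lo <- wl + 1e-9
  hi <- wr - 1e-9
  while (c1_of(lo, alpha3) < a1) lo <- wl + (lo - wl) / 10
  while (c1_of(hi, alpha3) > a1) hi <- wr - (wr - hi) / 10
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (c1_of(mid, alpha3) > a1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build a discretised boundary curve of the D-partition
#'
#' Constructs one branch of the critical-root loci in the
#' \eqn{(\alpha_1,\alpha_2)}-plane:
#' * `"L"`: the half-line \eqn{\alpha_2 = -\alpha_1},
#'   \eqn{\alpha_1 \le 1-\alpha_3} (zero root),
#' * `"C0"`: the Hopf curve for \eqn{\omega \in [0,\pi)},
#' * `"Ck_plus"` / `"Ck_minus"`: the higher branches for
#'   \eqn{\omega \in (2k\pi, (2k+1)\pi)} resp. \eqn{((2k-1)\pi, 2k\pi)}.
#'
#' Since \eqn{c_1} is strictly decreasing in \eqn{\omega} on every branch,
#' curves are sampled on an even grid in \eqn{\alpha_1} (inverted by
#' bisection), which makes them graph-like with a caller-controlled step cap.
#'
#' @param branch one of `"L"`, `"C0"`, `"Ck_plus"`, `"Ck_minus"`.
#' @param k branch index (ignored for `"L"`/`"C0"`, required `>= 1` otherwise).
#' @inheritParams c_point
#' @param n number of sample points (at least 2).
#' @param alpha1_range window of \eqn{\alpha_1} values to cover; curves are
#'   clipped to it (C0 and L additionally end at the corner
#'   \eqn{\alpha_1 = 1-\alpha_3}).
#' @return tibble with columns `branch`, `k`, `alpha3`, `omega`, `alpha1`,
#'   `alpha2` (for `"L"`, `omega` is `NA`).
#' @export
build_curve <- function(branch = c("L", "C0", "Ck_plus", "Ck_minus"),
                        k = 0, alpha3, n = 201,
                        alpha1_range = c(-12, 12)) {
  branch <- rlang::arg_match(branch)
  check_alpha3(alpha3)
  stopifnot(n >= 2, length(alpha1_range) == 2, alpha1_range[1] < alpha1_range[2])
  corner <- 1 - alpha3

  if (branch == "L") {
    a1 <- seq(alpha1_range[1], min(corner, alpha1_range[2]), length.out = n)
    return(tibble::tibble(
      branch = "L", k = 0L, alpha3 = alpha3,
      omega = NA_real_, alpha1 = a1, alpha2 = -a1
    ))
  }

  if (branch == "C0") {
    if (k != 0) {
      rlang::abort("`k` must be 0 for branch C0",
                   class = "delaychart_error_precondition")
    }
    a1 <- seq(min(corner, alpha1_range[2]), alpha1_range[1], length.out = n)
    a1[1] <- min(corner, alpha1_range[2])
    om <- vapply(a1, c0_omega, double(1), alpha3 = alpha3)
    return(tibble::tibble(
      branch = "C0", k = 0L, alpha3 = alpha3,
      omega = om, alpha1 = c1_of(om, alpha3), alpha2 = c2_of(om, alpha3)
    ))
  }

  if (k < 1) {
    rlang::abort("`k` must be >= 1 for branches Ck_plus / Ck_minus",
                 class = "delaychart_error_precondition")
  }
  lims <- if (branch == "Ck_minus") {
    c((2 * k - 1) * pi, 2 * k * pi)
  } else {
    c(2 * k * pi, (2 * k + 1) * pi)
  }
  a1 <- seq(alpha1_range[2], alpha1_range[1], length.out = n)
  om <- vapply(a1, ck_omega, double(1),
               wl = lims[1], wr = lims[2], alpha3 = alpha3)
  tibble::tibble(
    branch = branch, k = as.integer(k), alpha3 = alpha3,
    omega = om, alpha1 = c1_of(om, alpha3), alpha2 = c2_of(om, alpha3)
  )
}

#' Build every boundary curve up to branch index k_max
#'
#' Convenience wrapper returning L, C0 and \eqn{C_k^\pm} for
#' \eqn{k \le} `k_max` in one tibble, ready for plotting or CSV export.
#'
#' @inheritParams build_curve
#' @param k_max largest branch index.
#' @return tibble as in [build_curve()], rows stacked.
#' @export
build_all_curves <- function(alpha3, k_max = 3, n = 201,
                             alpha1_range = c(-12, 12)) {
  base <- list(
    build_curve("L", 0, alpha3, n, alpha1_range),
    build_curve("C0", 0, alpha3, n, alpha1_range)
  )
  ks <- purrr::flatten(purrr::map(seq_len(k_max), function(k) {
    list(
      build_curve("Ck_minus", k, alpha3, n, alpha1_range),
      build_curve("Ck_plus", k, alpha3, n, alpha1_range)
    )
  }))
  dplyr::bind_rows(c(base, ks))
}

#' Classify a coefficient pair relative to the stability region
#'
#' The stability region \eqn{S(\alpha_3)} is the connected open set bounded by
#' the half-line L and the Hopf curve C0; it is exactly
#' \eqn{\{\alpha_1 < 1-\alpha_3,\ \varphi(\alpha_1) < \alpha_2 < -\alpha_1\}}
#' with \eqn{\varphi} as in [c0_height()].  Membership is decided by this
#' strict geometric test; points within `tol` of the boundary are tagged.
#'
#' @param alpha1,alpha2 coordinates of the point (vectorised, recycled).
#' @inheritParams c_point
#' @param tol boundary-proximity tolerance for the `note` tag.
#' @return tibble with columns `alpha1`, `alpha2`, `alpha3`, `stable`
#'   (logical) and `note` (one of `"interior"`, `"near_L"`, `"near_C0"`,
#'   `"right_of_corner"`); the corner \eqn{(1-\alpha_3,\alpha_3-1)} is stored
#'   in the `"corner"` attribute.
#' @export
classify_point <- function(alpha1, alpha2, alpha3, tol = 1e-8) {
  check_alpha3(alpha3)
  dat <- vctrs_recycle(alpha1, alpha2)
  a1 <- dat[[1]]; a2 <- dat[[2]]
  corner <- 1 - alpha3
  phi <- rep(NA_real_, length(a1))
  left <- a1 < corner
  if (any(left)) phi[left] <- c0_height(a1[left], alpha3)
  stable <- left & a2 < -a1 & !is.na(phi) & a2 > phi
  note <- rep("interior", length(a1))
  note[!left] <- "right_of_corner"
  note[left & abs(a2 + a1) < tol] <- "near_L"
  note[left & !is.na(phi) & abs(a2 - phi) < tol] <- "near_C0"
  out <- tibble::tibble(
    alpha1 = a1, alpha2 = a2, alpha3 = alpha3, stable = stable, note = note
  )
  attr(out, "corner") <- c(alpha1 = corner, alpha2 = alpha3 - 1)
  out
}

vctrs_recycle <- function(x, y) {
  n <- max(length(x), length(y))
  list(rep_len(x, n), rep_len(y, n))
}

#' Classify a grid of coefficient pairs, with optional root counts
#'
#' Applies [classify_point()] to every row of a data frame of
#' \eqn{(\alpha_1,\alpha_2)} pairs and, if `count = TRUE`, attaches the
#' argument-principle unstable-root count from [count_unstable_roots()].
#'
#' @param data data frame with columns `alpha1` and `alpha2`.
#' @inheritParams c_point
#' @param count if `TRUE`, also compute `n_unstable` per point (slower).
#' @param margin marginal-root margin passed to [count_unstable_roots()].
#' @return tibble with columns `alpha1`, `alpha2`, `alpha3`, `stable`, `note`
#'   and (if requested) `n_unstable`.
#' @export
classify_grid <- function(data, alpha3, count = FALSE, margin = 1e-8) {
  stopifnot(all(c("alpha1", "alpha2") %in% names(data)))
  out <- classify_point(data$alpha1, data$alpha2, alpha3)
  if (count) {
    out$n_unstable <- purrr::map_int(
      seq_len(nrow(out)),
      function(i) count_unstable_roots(out$alpha1[i], out$alpha2[i], alpha3,
                                       margin = margin)$n_unstable
    )
  }
  out
}

#' Frequency at which the C0 curve turns in alpha2
#'
#' The slope \eqn{\partial c_2/\partial\omega} has the sign of
#' \eqn{h(\omega,\alpha_3) = \alpha_3(\sin\omega\cos\omega - \omega) +
#' \omega\cos\omega - \sin\omega} on \eqn{(0,\pi)}.  For
#' \eqn{\alpha_3 \ge -1/2} the slope is negative throughout and `NA` is
#' returned; for \eqn{\alpha_3 < -1/2} there is a unique sign change
#' \eqn{\theta(\alpha_3) \in (0,\pi)}, found here by bisection, with
#' \eqn{\theta(\alpha_3) \to \pi} as \eqn{\alpha_3 \downarrow -1}.
#'
#' @inheritParams c_point
#' @return the sign-change frequency, or `NA_real_` if the slope never
#'   changes sign.
#' @export
dc2_sign_change <- function(alpha3) {
  check_alpha3(alpha3)
  if (alpha3 >= -0.5) return(NA_real_)
  # h > 0 for small omega (leading term -(2*alpha3+1)*omega^3/3), h(pi) < 0
  lo <- 1e-4
  while (h_curve(lo, alpha3) <= 0 && lo < 1) lo <- lo * 2
  hi <- pi - 1e-12
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-13) break
    if (h_curve(mid, alpha3) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

h_curve <- function(omega, alpha3) {
  alpha3 * (sin(omega) * cos(omega) - omega) + omega * cos(omega) - sin(omega)
}
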