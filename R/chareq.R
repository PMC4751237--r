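#' Characteristic function of the neutral delay equation
#'
#' Evaluates \eqn{\Delta(\lambda) = \lambda - \alpha_1 - (\alpha_2 +
#' \alpha_3\lambda) e^{-\lambda}}, whose zeros are the characteristic roots of
#' the scalar delay equation with a neutral term. The steady state of the
#' underlying delay system is linearly stable exactly when \eqn{\Delta} has no
#' zeros with non-negative real part.
#'
#' \eqn{\Delta} is entire, so any complex `lambda` is admissible.  Because the
#' coefficients are real, \eqn{\Delta(\bar\lambda) = \overline{\Delta(\lambda)}}
#' and roots off the real axis come in conjugate pairs; the package reports
#' only the representative with non-negative imaginary part.
#'
#' @param lambda complex (vectorised) evaluation point(s).
#' @param alpha1,alpha2,alpha3 real coefficients.
#' @return complex vector of the same length as `lambda`.
#' @seealso [char_deriv()], [find_roots()], [count_unstable_roots()]
#' @examples
#' char_value(0, 1, -1, 0.3)          # 0: lambda = 0 is a root iff a1 + a2 = 0
#' char_value(log(0.5), 0, 0, 0.5)    # 0: root on the logarithmic branch
#' @export
char_value <- function(lambda, alpha1, alpha2, alpha3) {
  lambda <- as.complex(lambda)
  lambda - alpha1 - (alpha2 + alpha3 * lambda) * exp(-lambda)
}

#' Derivatives of the characteristic function
#'
#' Closed-form derivatives of \eqn{\Delta}, used by the Newton refinement in
#' [find_roots()] and by the multiplicity test of [multiplicity_at_zero()].
#'
#' @inheritParams char_value
#' @param order derivative order, 1, 2 or 3.
#' @return complex vector.
#' @export
char_deriv <- function(lambda, alpha1, alpha2, alpha3, order = 1) {
  lambda <- as.complex(lambda)
  e <- exp(-lambda)
  switch(as.character(order),
    "1" = 1 + (alpha2 - alpha3 + alpha3 * lambda) * e,
    "2" = (2 * alpha3 - alpha2 - alpha3 * lambda) * e,
    "3" = (alpha2 - 3 * alpha3 + alpha3 * lambda) * e,
    rlang::abort("`order` must be 1, 2 or 3.")
  )
}

#' A priori modulus bound for unstable characteristic roots
#'
#' Every root \eqn{\lambda} of the characteristic equation with
#' \eqn{\mathrm{Re}\,\lambda \ge 0} satisfies
#' \eqn{|\lambda| \le (|\alpha_1|+|\alpha_2|)/(1-|\alpha_3|)}, provided
#' \eqn{|\alpha_3| < 1}.  The bound makes the search for unstable roots a
#' finite problem; it fails (and infinitely many right-half-plane roots exist)
#' when \eqn{|\alpha_3| > 1}.
#'
#' @inheritParams char_value
#' @return the bound, a non-negative real number.
#' @export
modulus_bound <- function(alpha1, alpha2, alpha3) {
  check_alpha3(alpha3)
  (abs(alpha1) + abs(alpha2)) / (1 - abs(alpha3))
}

check_alpha3 <- function(alpha3, call = rlang::caller_env()) {
  if (!is.finite(alpha3) || abs(alpha3) >= 1) {
    rlang::abort(
      paste0(
        "`alpha3` must satisfy |alpha3| < 1 (got ", format(alpha3), "). ",
        "For |alpha3| > 1 the equation has infinitely many roots in the ",
        "right half-plane and the a priori modulus bound does not exist."
      ),
      class = "delaychart_error_precondition", call = call
    )
  }
  invisible(alpha3)
}

#' Multiplicity of the root at the origin
#'
#' \eqn{\lambda = 0} is a root iff \eqn{\alpha_1+\alpha_2 = 0}; a double root
#' iff additionally \eqn{\alpha_2 = \alpha_3 - 1}; a triple root iff
#' additionally \eqn{\alpha_3 = -1}.  These follow from the Taylor expansion
#' \eqn{\Delta(\lambda) = -(\alpha_1+\alpha_2) + (1+\alpha_2-\alpha_3)\lambda
#' + (\alpha_3 - \alpha_2/2)\lambda^2 + \dots}
#'
#' @inheritParams char_value
#' @param tol tolerance for the exact comparisons.
#' @return integer in 0:3.
#' @export
multiplicity_at_zero <- function(alpha1, alpha2, alpha3, tol = 1e-10) {
  if (abs(alpha1 + alpha2) > tol) return(0L)
  if (abs(alpha2 - (alpha3 - 1)) > tol) return(1L)
  if (abs(alpha3 + 1) > tol) return(2L)
  3L
}

#' Locate characteristic roots in a right half-plane window
#'
#' Finds all roots with \eqn{\mathrm{Re}\,\lambda \ge} `re_min` and
#' \eqn{0 \le \mathrm{Im}\,\lambda \le} `bound` by damped Newton iteration
#' from a regular grid of seeds, followed by deduplication and a closed-form
#' derivative test for multiplicity.  With `re_min >= 0` the a priori bound
#' guarantees the window contains every unstable root.
#'
#' @inheritParams char_value
#' @param re_min left edge of the search window.
#' @param tol convergence tolerance on \eqn{|\Delta|}.
#' @param grid_step spacing of the Newton seeds.
#' @param bound search radius; defaults to `modulus_bound(...) + 1`.
#' @return tibble with columns `re`, `im` (representative root, `im >= 0`),
#'   `residual` and `multiplicity`, ordered by decreasing `re`.
#' @export
find_roots <- function(alpha1, alpha2, alpha3, re_min = 0,
                       tol = 1e-12, grid_step = 0.25, bound = NULL) {
  check_alpha3(alpha3)
  if (is.null(bound)) bound <- modulus_bound(alpha1, alpha2, alpha3) + 1
  empty <- tibble::tibble(
    re = double(), im = double(), residual = double(), multiplicity = integer()
  )
  if (bound <= 0 || re_min > bound) return(empty)

  res <- seq(re_min, bound, by = grid_step)
  ims <- seq(0, bound, by = grid_step)
  lam <- outer(res, ims, function(x, y) complex(real = x, imaginary = y))
  lam <- as.vector(lam)
  scale <- 1 + abs(alpha1) + abs(alpha2) + bound

  for (it in seq_len(60)) {
    f <- char_value(lam, alpha1, alpha2, alpha3)
    if (all(Mod(f) < tol * scale)) break
    fp <- char_deriv(lam, alpha1, alpha2, alpha3)
    step <- f / fp
    step[!is.finite(step)] <- 0
    # damp long steps so seeds do not overshoot the window wildly
    big <- Mod(step) > 0.5
    step[big] <- step[big] * (0.5 / Mod(step[big]))
    lam <- lam - step
    if (it == 12L) {
      # prune seeds that escaped the (reflected) search region early
      keep <- is.finite(lam) & Re(lam) > re_min - 2 & abs(Im(lam)) < bound + 2 &
        Mod(lam) < 2 * bound + 4
      lam <- lam[keep]
      if (length(lam) == 0L) return(empty)
    }
  }

  lam[Im(lam) < 0] <- Conj(lam[Im(lam) < 0])
  resid <- Mod(char_value(lam, alpha1, alpha2, alpha3))
  keep <- is.finite(lam) & resid < tol * scale &
    Re(lam) >= re_min - 1e-9 & Mod(lam) <= bound + 1e-6
  lam <- lam[keep]
  if (length(lam) == 0L) return(empty)

  # merge numerically identical roots (multiple seeds converge to each root)
  # merge radius 1e-4: near a double root Newton stalls at a distance of
  # order sqrt(tol), well above the simple-root merge scale
  ord <- order(Mod(char_value(lam, alpha1, alpha2, alpha3)))
  lam <- lam[ord]
  uniq <- lam[1]
  for (z in lam[-1]) {
    if (min(Mod(z - uniq)) > 1e-4) uniq <- c(uniq, z)
  }

  mult <- vapply(uniq, function(z) root_multiplicity(z, alpha1, alpha2, alpha3),
                 integer(1))
  out <- tibble::tibble(
    re = Re(uniq), im = Im(uniq),
    residual = Mod(char_value(uniq, alpha1, alpha2, alpha3)),
    multiplicity = mult
  )
  dplyr::arrange(out, dplyr::desc(.data$re), .data$im)
}

# roots within a thin strip |Re(lambda)| <= width around the imaginary axis,
# |lambda| <= R: Newton from seeds i*omega where |Delta(i*omega)| is locally
# small, which is cheap compared to a full half-disk search
axis_roots <- function(alpha1, alpha2, alpha3, R, width) {
  empty <- tibble::tibble(
    re = double(), im = double(), residual = double(), multiplicity = integer()
  )
  step <- 0.02
  om <- seq(0, R + 1, by = step)
  v <- Mod(char_value(1i * om, alpha1, alpha2, alpha3))
  lip <- 1 + abs(alpha2) + abs(alpha3) * (2 + R)   # bound on |Delta'| near axis
  cand <- om[v < 2 * step * lip]
  if (length(cand) == 0L) return(empty)
  lam <- 1i * cand
  scale <- 1 + abs(alpha1) + abs(alpha2) + R
  for (it in seq_len(60)) {
    f <- char_value(lam, alpha1, alpha2, alpha3)
    if (all(Mod(f) < 1e-13 * scale)) break
    fp <- char_deriv(lam, alpha1, alpha2, alpha3)
    stepc <- f / fp
    stepc[!is.finite(stepc)] <- 0
    big <- Mod(stepc) > 0.25
    stepc[big] <- stepc[big] * (0.25 / Mod(stepc[big]))
    lam <- lam - stepc
  }
  lam[Im(lam) < 0] <- Conj(lam[Im(lam) < 0])
  resid <- Mod(char_value(lam, alpha1, alpha2, alpha3))
  keep <- is.finite(lam) & resid < 1e-11 * scale & abs(Re(lam)) <= 2 * width
  lam <- lam[keep]
  if (length(lam) == 0L) return(empty)
  ord <- order(Mod(char_value(lam, alpha1, alpha2, alpha3)))
  lam <- lam[ord]
  uniq <- lam[1]
  for (z in lam[-1]) if (min(Mod(z - uniq)) > 1e-4) uniq <- c(uniq, z)
  tibble::tibble(
    re = Re(uniq), im = Im(uniq),
    residual = Mod(char_value(uniq, alpha1, alpha2, alpha3)),
    multiplicity = vapply(
      uniq, function(z) root_multiplicity(z, alpha1, alpha2, alpha3), integer(1)
    )
  )
}

root_multiplicity <- function(z, alpha1, alpha2, alpha3, tol = 1e-8) {
  for (j in 1:3) {
    if (Mod(char_deriv(z, alpha1, alpha2, alpha3, order = j)) >= tol) {
      return(j)
    }
  }
  3L
}

#' Count unstable characteristic roots by the argument principle
#'
#' Computes the number of zeros of \eqn{\Delta} (with multiplicity) with
#' \eqn{\mathrm{Re}\,\lambda >} `margin` as the winding number of \eqn{\Delta}
#' along the boundary of the half-disk \eqn{\{\mathrm{Re}\,\lambda \ge
#' \mathrm{margin},\ |\lambda| \le R\}} with \eqn{R = } `modulus_bound + 1`.
#' The contour image is sampled adaptively until consecutive phase increments
#' stay below \eqn{\pi/2}, which makes the winding number a robust integer
#' without quadrature of \eqn{\Delta'/\Delta}.  Zeros on or numerically near
#' the imaginary axis (within `margin`) are located separately and reported as
#' `marginal`, not counted; if \eqn{\Delta} vanishes on the contour itself the
#' flat segment is nudged toward the axis and counts are corrected using the
#' located roots.
#'
#' @inheritParams char_value
#' @param margin half-width of the strip around the imaginary axis whose roots
#'   are classified as marginal rather than unstable.
#' @return an object of class `root_count`: a list with `n_unstable`
#'   (non-negative integer), `marginal` (tibble as in [find_roots()]) and
#'   `bound_radius`.
#' @export
count_unstable_roots <- function(alpha1, alpha2, alpha3, margin = 1e-8) {
  check_alpha3(alpha3)
  stopifnot(margin > 0)
  R <- modulus_bound(alpha1, alpha2, alpha3) + 1

  # roots near the imaginary axis: perturbations of axis roots, so seed
  # Newton from the near-zeros of Delta(i*omega); searched on a strip wide
  # enough that the counting segment can be placed away from all of them
  width <- max(margin, 1e-3)
  strip <- axis_roots(alpha1, alpha2, alpha3, R, width)
  marginal <- dplyr::filter(strip, abs(.data$re) <= margin)

  scale <- 1 + abs(alpha1) + abs(alpha2)
  # candidate segment locations, ordered by preference; skip any that sits
  # close to a located root, then fall back to the winding computation's own
  # near-zero detection
  cands <- unique(c(margin, margin * c(0.5, 2, 0.25, 4, 0.125, 8),
                    width * c(0.5, 0.99)))
  cands <- cands[cands > 0 & cands <= 2 * width]
  sep <- vapply(cands, function(x) {
    if (nrow(strip) == 0) Inf else min(abs(strip$re - x))
  }, double(1))
  cands <- cands[order(-pmin(sep, margin))]
  w <- NA_integer_
  x0 <- NA_real_
  for (x in cands) {
    res <- winding_number(alpha1, alpha2, alpha3, x, R, scale)
    if (!is.na(res)) { w <- res; x0 <- x; break }
  }
  if (is.na(w)) {
    rlang::abort(
      "a characteristic root lies on the counting contour for every candidate contour",
      class = "delaychart_error_contour"
    )
  }
  # reconcile the segment location with the requested margin using the
  # located strip roots (conjugate pairs count twice)
  wmult <- function(sel) {
    sum(strip$multiplicity[sel & strip$im > 1e-12] * 2) +
      sum(strip$multiplicity[sel & strip$im <= 1e-12])
  }
  n <- w - wmult(strip$re > x0 & strip$re <= margin) +
    wmult(strip$re > margin & strip$re <= x0)

  structure(
    list(n_unstable = as.integer(n), marginal = marginal, bound_radius = R),
    class = "root_count"
  )
}

# winding number of Delta over the boundary of {Re >= x0, |lambda| <= R},
# adaptively refined; NA if Delta comes too close to zero on the contour
winding_number <- function(alpha1, alpha2, alpha3, x0, R, scale,
                           max_depth = 60L) {
  phi <- acos(min(1, max(-1, x0 / R)))
  n_seg <- 64L
  n_arc <- max(128L, ceiling(16 * R))
  yy <- sqrt(max(R^2 - x0^2, 0))
  seg <- complex(real = x0, imaginary = seq(yy, -yy, length.out = n_seg))
  ang <- seq(-phi, phi, length.out = n_arc)
  arc <- R * exp(1i * ang)
  pts <- c(seg, arc[-1], seg[1])

  vals <- char_value(pts, alpha1, alpha2, alpha3)
  dvls <- Mod(char_deriv(pts, alpha1, alpha2, alpha3))
  for (depth in seq_len(max_depth)) {
    if (min(Mod(vals)) < 1e-10 * scale) return(NA_integer_)
    m1 <- Mod(vals[-1]); m0 <- Mod(vals[-length(vals)])
    dphase <- Arg(vals[-1] / vals[-length(vals)])
    # an interval can hide a full phase turn (a zero between samples) only if
    # Delta can traverse its own endpoint modulus: require width * Lipschitz
    # bound < endpoint modulus as an anti-aliasing condition
    lip <- 2 * pmax(dvls[-1], dvls[-length(dvls)])
    wide <- Mod(diff(pts)) * lip > 0.8 * pmin(m0, m1)
    bad <- which(abs(dphase) > pi / 2 | wide)
    if (length(bad) == 0L) break
    if (depth == max_depth) {
      rlang::abort("contour refinement did not converge",
                   class = "delaychart_error_contour")
    }
    mid <- (pts[bad] + pts[bad + 1]) / 2
    # project arc midpoints back onto the circle
    on_arc <- Mod(pts[bad]) > R - 1e-9 & Mod(pts[bad + 1]) > R - 1e-9
    mid[on_arc] <- R * mid[on_arc] / Mod(mid[on_arc])
    idx <- order(c(seq_along(pts), bad + 0.5))
    pts <- c(pts, mid)[idx]
    vals <- c(vals, char_value(mid, alpha1, alpha2, alpha3))[idx]
    dvls <- c(dvls, Mod(char_deriv(mid, alpha1, alpha2, alpha3)))[idx]
  }
  total <- sum(Arg(vals[-1] / vals[-length(vals)]))
  w <- total / (2 * pi)
  if (abs(w - round(w)) > 0.2) {
    rlang::abort("winding number did not converge to an integer",
                 class = "delaychart_error_contour")
  }
  as.integer(round(w))
}

#' @export
print.root_count <- function(x, ...) {
  cat("<root_count>\n")
  cat("  unstable roots (Re > margin, with multiplicity):", x$n_unstable, "\n")
  cat("  marginal roots on/near the imaginary axis:      ", nrow(x$marginal), "\n")
  cat("  a priori search radius:                          ",
      format(x$bound_radius, digits = 6), "\n")
  invisible(x)
}
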