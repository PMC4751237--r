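test_that("c_point evaluates the critical-curve formulas and their omega -> 0 limit", {
  p <- c_point(pi / 2, 0)
  expect_equal(p$alpha1, 0, tolerance = 1e-14)
  expect_equal(p$alpha2, -pi / 2, tolerance = 1e-14)
  p0 <- c_point(0, 0.4)
  expect_equal(c(p0$alpha1, p0$alpha2), c(0.6, -0.6))
  expect_error(c_point(pi, 0.3), class = "delaychart_error_precondition")
  expect_error(c_point(2 * pi, 0.3), class = "delaychart_error_precondition")
})

test_that("the ratio c1/c2 runs from -1 to +1 on [0, pi)", {
  for (a3 in c(-0.9, 0.3, 0.9)) {
    lo <- c_point(1e-6, a3)
    hi <- c_point(pi - 1e-6, a3)
    expect_equal(lo$alpha1 / lo$alpha2, -1, tolerance = 1e-5)
    expect_equal(hi$alpha1 / hi$alpha2, 1, tolerance = 1e-5)
    # monotone increase in between
    om <- seq(0.1, pi - 0.1, length.out = 50)
    r <- c_point(om, a3)
    expect_true(all(diff(r$alpha1 / r$alpha2) > 0))
  }
})

test_that("c0_height inverts c1 and matches an independent bisection", {
  expect_equal(c0_height(1 - 0.3, 0.3), 0.3 - 1, tolerance = 1e-10)
  expect_equal(c0_height(0, 0), -pi / 2, tolerance = 1e-10)
  # quarter-plane bound below the corner, with the value cross-checked
  v <- c0_height(-5, 0.5)
  expect_lt(v, -5)
  wstar <- oracle_bisect(
    function(w) w / sin(w) * (cos(w) - 0.5) - (-5), 1e-9, pi - 1e-9
  )
  expect_equal(v, wstar / sin(wstar) * (0.5 * cos(wstar) - 1), tolerance = 1e-8)
  expect_error(c0_height(1.01 - 0.5, 0.5),
               class = "delaychart_error_precondition")
})

test_that("built curves satisfy their defining invariants", {
  for (a3 in c(-0.7, 0, 0.6)) {
    c0 <- build_curve("C0", 0, a3, n = 101)
    expect_true(all(diff(c0$omega) > 0))
    expect_true(all(diff(c0$alpha1) < 0))
    expect_equal(c0$alpha1[1], 1 - a3)
    expect_equal(c0$alpha2[1], a3 - 1)
    # every point carries an imaginary-axis root
    expect_lt(max(Mod(char_value(1i * c0$omega, c0$alpha1, c0$alpha2, a3))),
              1e-10)
    # quarter-plane confinement (omega > 0 part)
    expect_true(all(c0$alpha2[-1] < -abs(c0$alpha1[-1]) + 1e-9))

    cm <- build_curve("Ck_minus", 1, a3, n = 101, alpha1_range = c(-8, 8))
    expect_true(all(cm$omega > pi & cm$omega < 2 * pi))
    expect_true(all(cm$alpha2 > abs(cm$alpha1)))
    expect_lt(max(Mod(char_value(1i * cm$omega, cm$alpha1, cm$alpha2, a3))),
              1e-9)

    cp <- build_curve("Ck_plus", 2, a3, n = 101, alpha1_range = c(-8, 8))
    expect_true(all(cp$omega > 4 * pi & cp$omega < 5 * pi))
    expect_true(all(cp$alpha2 < -abs(cp$alpha1)))

    L <- build_curve("L", 0, a3, n = 11)
    expect_equal(L$alpha2, -L$alpha1)
    expect_lte(max(L$alpha1), 1 - a3)
  }
  expect_error(build_curve("Ck_plus", 0, 0.3),
               class = "delaychart_error_precondition")
  expect_error(build_curve("C0", 2, 0.3),
               class = "delaychart_error_precondition")
})

test_that("distinct boundary curves do not intersect", {
  for (a3 in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    cs <- build_all_curves(a3, k_max = 2, n = 120, alpha1_range = c(-6, 6))
    cs <- dplyr::filter(cs, .data$branch != "L", is.finite(.data$alpha2),
                        abs(.data$alpha2) < 50)
    sp <- split(cs, interaction(cs$branch, cs$k, drop = TRUE))
    for (i in seq_along(sp)) {
      for (j in seq_along(sp)) {
        if (i >= j) next
        d <- sqrt(outer(sp[[i]]$alpha1, sp[[j]]$alpha1, "-")^2 +
                    outer(sp[[i]]$alpha2, sp[[j]]$alpha2, "-")^2)
        expect_gt(min(d), 0.05)
      }
    }
  }
})

test_that("near alpha3 = -1 the Hopf curve collapses onto the two limit rays", {
  c0 <- build_curve("C0", 0, -1 + 1e-6, n = 400, alpha1_range = c(-5, 2.1))
  # distance of each sampled point to the union {a2 = -a1, 0 <= a1 <= 2} and
  # {a2 = a1 <= 0}
  dist_to_limit <- pmin(
    ifelse(c0$alpha1 >= 0 & c0$alpha1 <= 2.05,
           abs(c0$alpha2 + c0$alpha1) / sqrt(2), Inf),
    ifelse(c0$alpha1 <= 0.05, abs(c0$alpha2 - c0$alpha1) / sqrt(2), Inf)
  )
  expect_lt(max(dist_to_limit), 1e-2)
})

test_that("near |alpha3| = 1 the higher branches approach the diagonal lines", {
  # perpendicular distance to the limit set {alpha2 = +/-|alpha1|}; the
  # neighbourhood of the alpha2-axis crossing is excluded because there the
  # convergence is non-uniform (the deviation scales like sqrt(1 - |alpha3|))
  vdist <- function(a1, a2, sgn) {
    pmin(abs(a2 - sgn * a1), abs(a2 + sgn * a1)) / sqrt(2)
  }
  for (a3 in c(1 - 1e-4, -1 + 1e-4)) {
    cm <- build_curve("Ck_minus", 1, a3, n = 200, alpha1_range = c(-5, 5))
    keep <- abs(cm$alpha1) > 0.2
    expect_lt(max(vdist(cm$alpha1[keep], cm$alpha2[keep], 1)), 5e-2)
    cp <- build_curve("Ck_plus", 1, a3, n = 200, alpha1_range = c(-5, 5))
    keep <- abs(cp$alpha1) > 0.2
    expect_lt(max(vdist(cp$alpha1[keep], cp$alpha2[keep], -1)), 5e-2)
  }
  # pointwise convergence toward the limit at a fixed abscissa
  devs <- vapply(c(1e-3, 1e-4, 1e-5), function(d) {
    cm <- build_curve("Ck_minus", 1, 1 - d, n = 20, alpha1_range = c(-5, -3))
    max(abs(cm$alpha2 - abs(cm$alpha1)))
  }, double(1))
  expect_true(all(diff(devs) < 0))
})

test_that("classification matches the region geometry", {
  for (a3 in c(-0.9, 0, 0.9)) {
    expect_true(classify_point(-0.5, 0, a3)$stable)
  }
  expect_false(classify_point(0.5, 0.5, 0)$stable)   # above L
  expect_false(classify_point(0, -2, 0)$stable)      # below C0
  expect_identical(count_unstable_roots(0.5, 0.5, 0)$n_unstable, 1L)
  v <- classify_point(2, -3, 0.5)
  expect_identical(v$note, "right_of_corner")
  expect_false(v$stable)
  expect_identical(classify_point(0.2, -0.2, 0.3)$note, "near_L")
  expect_equal(attr(v, "corner"), c(alpha1 = 0.5, alpha2 = -0.5))
})

test_that("classification agrees with the root count on a coarse grid", {
  g <- tidyr::expand_grid(alpha1 = seq(-4.9, 4.9, length.out = 9),
                          alpha2 = seq(-4.9, 4.9, length.out = 9))
  for (a3 in c(-0.6, 0.4)) {
    cls <- classify_grid(g, a3, count = TRUE)
    phi <- c0_height(pmin(cls$alpha1, 1 - a3), a3)
    near <- abs(cls$alpha1 + cls$alpha2) < 1e-2 |
      (cls$alpha1 <= 1 - a3 & abs(cls$alpha2 - phi) < 1e-2)
    expect_true(all((cls$n_unstable[!near] == 0) == cls$stable[!near]))
  }
})

test_that("the slope of c2 along C0 changes sign only for alpha3 < -1/2", {
  expect_true(is.na(dc2_sign_change(0)))
  expect_true(is.na(dc2_sign_change(-0.5)))
  th <- dc2_sign_change(-0.9)
  expect_gt(th, 0); expect_lt(th, pi)
  # cross-check against a dense scan of the sign of h
  om <- seq(1e-4, pi - 1e-4, length.out = 20000)
  h <- -0.9 * (sin(om) * cos(om) - om) + om * cos(om) - sin(om)
  expect_equal(th, om[max(which(h > 0))], tolerance = 1e-3)
  expect_lt(abs(dc2_sign_change(-1 + 1e-4) - pi), 0.1)
})
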