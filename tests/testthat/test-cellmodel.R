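test_that("R0 matches its closed form in degenerate and calibrated cases", {
  m <- make_fixture("fig4")
  # mu = 0: formula collapses to 2 for any positive G
  m0 <- structure(list(death_rate = 0, theta = 0.5,
                       beta1 = response_constant(0.3),
                       G = response_hill(1, 2, 0.5)), class = "cell_model")
  expect_equal(R0(m0, c(0.2, 0.7)), c(2, 2))
  # beta1 = 1: numerator equals denominator, R0 = 2 exp(-mu)
  m1 <- structure(list(death_rate = 0.4, theta = 0.5,
                       beta1 = response_constant(1),
                       G = response_hill(1, 2, 0.5)), class = "cell_model")
  expect_equal(R0(m1, 0.3), 2 * exp(-0.4))
  # calibrated fixture: R0(Ebar) = 1 at the prescribed Ebar
  expect_equal(R0(m, 0.5), 1, tolerance = 1e-12)
  # R0 > 2 exp(-mu) beta1 always
  E <- seq(0.01, 1, length.out = 20)
  expect_true(all(R0(m, E) > 2 * exp(-0.5) * m$beta1$value(E)))
})

test_that("the steady state solves R0 = 1 with the printed derived quantities", {
  m <- make_fixture("fig4")
  ss <- solve_steady_state(m)
  mu <- 0.5
  expect_equal(ss$Ebar, 0.5, tolerance = 1e-9)
  expect_equal(R0(m, ss$Ebar), 1, tolerance = 1e-10)
  expect_equal(ss$l, (3 * exp(-mu) - 2) / (2 * exp(-mu) - 1))
  expect_lt(ss$l, 1)
  expect_equal(ss$pbar / ss$Qbar, mu / (2 * exp(-mu) - 1), tolerance = 1e-12)
  expect_gt(ss$A, 0)
  expect_lt(2 * exp(-mu) * m$beta1$value(ss$Ebar), 1)
  # independent hand computation of the fig4 numbers
  b1 <- 0.5; th <- 0.8
  gbar <- (1 - 2 * exp(-mu) * b1) * mu / (2 * exp(-mu) - 1)
  expect_equal(m$G$value(0.5), gbar, tolerance = 1e-12)
  l <- (3 * exp(-mu) - 2) / (2 * exp(-mu) - 1)
  fac <- (1 / 0.5 - 1) / (1 - l * th)
  expect_equal(ss$Qbar, fac, tolerance = 1e-8)
  expect_equal(ss$pbar, fac * mu / (2 * exp(-mu) - 1), tolerance = 1e-8)
  expect_equal(ss$K, fac / (1 - 2 * exp(-mu) * b1), tolerance = 1e-8)
  expect_equal(ss$A, m$G$derivative(0.5) * 0.25, tolerance = 1e-8)
})

test_that("the three failure regimes raise distinct errors", {
  expect_error(solve_steady_state(make_fixture("extinction")),
               class = "delaychart_error_extinction")
  expect_error(solve_steady_state(make_fixture("blowup")),
               class = "delaychart_error_blowup")
  # G decreasing near E = 1 (but still with R0(0) < 1 < R0(1)) violates the
  # monotonicity hypothesis
  bad <- cell_model(
    0.3, 0.5, response_constant(0.4),
    response_custom(function(E) 0.1 + 2 * E * (1 - 0.6 * E),
                    deriv = function(E) 2 - 2.4 * E)
  )
  expect_error(solve_steady_state(bad),
               class = "delaychart_error_hypothesis")
})

test_that("linearisation coefficients satisfy the structural identities", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_valid_model()
    ss <- solve_steady_state(m)
    co <- linearization_coeffs(m, ss)
    mu <- m$death_rate
    expect_gt(co$alpha3, 0); expect_lt(co$alpha3, 1)
    # transcritical identity
    expect_lt(abs(co$alpha1 + co$alpha2 - (1 - 2 * exp(-mu)) * ss$A), 1e-10)
    expect_lt(co$alpha1 + co$alpha2, 0)
  }
})

test_that("alpha3 does not depend on theta, and A = 0 gives the transcritical point", {
  m <- make_fixture("fig4")
  ss <- solve_steady_state(m)
  a3s <- vapply(c(0, 0.5, 1),
                function(th) linearization_coeffs(m, ss, theta = th)$alpha3,
                double(1))
  expect_equal(a3s, rep(a3s[1], 3))
  # flat responses at Ebar: A = 0 forces alpha1 + alpha2 = 0
  ss0 <- ss; ss0$A <- 0
  co0 <- linearization_coeffs(m, ss0)
  expect_equal(co0$alpha1 + co0$alpha2, 0, tolerance = 1e-12)
})

test_that("the steady-state matrix determinant vanishes exactly at R0 = 1", {
  m <- make_fixture("fig4")
  detval <- function(E) {
    mu <- m$death_rate; b1 <- m$beta1$value(E); g <- m$G$value(E)
    (1 - 2 * exp(-mu) * b1) * (-(mu + g)) + g * 2 * exp(-mu) * (1 - b1)
  }
  for (E in c(0.3, 0.5, 0.8)) {
    expect_equal(detval(E), (m$death_rate + m$G$value(E)) * (R0(m, E) - 1),
                 tolerance = 1e-12)
  }
  expect_equal(detval(solve_steady_state(m)$Ebar), 0, tolerance = 1e-10)
})

test_that("the characteristic matrix determinant shares its zero set with the scalar form", {
  set.seed(12)
  for (i in 1:10) {
    m <- random_valid_model()
    ss <- solve_steady_state(m)
    co <- linearization_coeffs(m, ss)
    roots <- find_roots(co$alpha1, co$alpha2, co$alpha3, re_min = -3,
                        bound = 10)
    if (nrow(roots) > 0) {
      lam <- complex(real = roots$re, imaginary = roots$im)
      expect_lt(max(Mod(char_matrix_det(lam, m, ss))), 1e-8)
    }
    # away from the scalar zero set the determinant stays away from zero
    lam <- complex(real = runif(50, -3, 3), imaginary = runif(50, -3, 3))
    dv <- Mod(char_value(lam, co$alpha1, co$alpha2, co$alpha3))
    keep <- dv > 1e-2 & Mod(lam + m$death_rate) > 1e-3
    expect_true(all(Mod(char_matrix_det(lam[keep], m, ss)) > 1e-10))
  }
  # removable singularity at lambda = -mu
  m <- make_fixture("fig4"); ss <- solve_steady_state(m)
  v1 <- char_matrix_det(-m$death_rate, m, ss)
  v2 <- char_matrix_det(-m$death_rate + 1e-9, m, ss)
  expect_true(is.finite(Mod(v1)))
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("uniqueness: exactly one sign change of R0 - 1 on a fine grid", {
  set.seed(13)
  E <- seq(1e-4, 1, length.out = 2000)
  for (i in 1:100) {
    m <- random_valid_model()
    sgn <- sign(R0(m, E) - 1)
    expect_identical(sum(diff(sgn) != 0), 1L)
  }
})

test_that("assess_stability composes the pipeline", {
  a <- assess_stability(make_fixture("fig4", theta = 0.8))
  expect_true(a$verdict$stable)
  # theta >= 2/3 is stable regardless of response steepness
  a2 <- assess_stability(make_fixture("fig4", theta = 0.8, hill_n = 40))
  expect_true(a2$verdict$stable)
  # steep response below theta_crit is unstable, with a Hopf pair
  m3 <- make_fixture("steep", theta = 0.5)
  a3 <- assess_stability(m3)
  expect_false(a3$verdict$stable)
  co <- a3$coeffs
  expect_gte(count_unstable_roots(co$alpha1, co$alpha2, co$alpha3)$n_unstable,
             2L)
  td <- tidy(a3); expect_identical(nrow(td), 7L)
  gl <- glance(a3); expect_false(gl$stable)
})

test_that("response constructors validate and custom derivatives warn", {
  expect_error(cell_model(0.5, 0.5, response_constant(1),
                          response_hill(1, 2, 0.5)),
               class = "delaychart_error_config")
  expect_error(cell_model(0.5, 0.5, response_constant(0.5),
                          response_linear(-0.5, 0.2)),
               class = "delaychart_error_config")
  expect_warning(rf <- response_custom(function(E) 0.1 + 0.2 * E),
                 "central differences")
  expect_equal(rf$derivative(0.4), 0.2, tolerance = 1e-8)
})
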