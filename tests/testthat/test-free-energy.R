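flat_fes <- function(n_s = 201, n_z = 21) {
  structure(list(s = seq(0, 1, length.out = n_s),
                 z = seq(0, 0.05, length.out = n_z),
                 F = matrix(0, n_s, n_z), bias_factor = 15),
            class = "fes")
}

test_that("a single hill reconstructs as a scaled inverted Gaussian", {
  hills <- tibble::tibble(time = 1, s = 5, z = 0.02, sigma_s = 0.2,
                          sigma_z = 0.01, height = 0.2, biasf = 15)
  fes <- fes_from_hills(hills, s_range = c(3, 7), z_range = c(-0.02, 0.06),
                        n_s = 81, n_z = 41)
  ## far field is the maximum; depth at the centre = (gamma/(gamma-1)) h
  centre <- fes$F[which.min(abs(fes$s - 5)), which.min(abs(fes$z - 0.02))]
  expect_equal(max(fes$F) - centre, 15 / 14 * 0.2, tolerance = 1e-3)
  expect_equal(min(fes$F), 0)
  ## pointwise: F(s,z) - F(center) matches the closed form
  i <- which.min(abs(fes$s - 5.3)); j <- which.min(abs(fes$z - 0.025))
  g <- 0.2 * exp(-(fes$s[i] - 5)^2 / (2 * 0.2^2) -
                   (fes$z[j] - 0.02)^2 / (2 * 0.01^2))
  expect_equal(fes$F[i, j] - centre, 15 / 14 * (0.2 - g), tolerance = 1e-4)
  expect_error(fes_from_hills(hills[0, ]), "empty")
})

test_that("raw-S hills rescale onto the unit progress axis", {
  hills <- tibble::tibble(time = 1:2, s = c(1, 21), z = 0.01,
                          sigma_s = 0.2, sigma_z = 0.01, height = 0.2,
                          biasf = 15)
  fes <- fes_from_hills(hills, rescale_p = 21, n_s = 101, n_z = 11)
  expect_equal(range(fes$s), c(0, 1))
  ## minima (deepest bias) sit at the mapped hill centres 0 and 1
  mins <- which(apply(fes$F, 1, min) < 1e-6)
  expect_true(any(abs(fes$s[mins] - 0) < 0.02) &&
                any(abs(fes$s[mins] - 1) < 0.02))
})

test_that("flat surfaces integrate to pure area ratios", {
  fes <- flat_fes()
  expect_equal(dg_bound_unbound(fes, 0.5, 300), 0, tolerance = 1e-9)
  ## site a quarter of the range: -kT ln(1/3)
  expect_equal(dg_bound_unbound(fes, 0.25, 300), -kT(300) * log(1 / 3),
               tolerance = 0.01)
  expect_error(dg_bound_unbound(fes, -0.1), "empty bound")
})

test_that("a deep bound well dominates the ratio as by direct quadrature", {
  fes <- flat_fes()
  well <- fes$s < 0.1
  fes$F[well, ] <- -5
  fes$F <- fes$F - min(fes$F)
  got <- dg_bound_unbound(fes, 0.5, 300)
  expect_lt(got, 0)
  ## independent trapezoid quadrature on the same grid; 0.5 is a grid
  ## point, shared by both regions so the two integrals tile the axis
  kt <- kT(300)
  B <- exp(-fes$F / kt)
  q <- function(rows) trap(fes$s[rows],
                           apply(B[rows, ], 1, function(r) trap(fes$z, r)))
  expect_equal(got, -kt * log(q(fes$s <= 0.5) / q(fes$s >= 0.5)),
               tolerance = 1e-10)
})

test_that("the divider curve matches its closed form on a flat surface", {
  fes <- flat_fes()
  sv <- seq(0.1, 0.9, by = 0.05)
  curve <- dg_vs_divider_curve(fes, 300, s_values = sv)
  expect_equal(curve$dg_b, -kT(300) * log(sv / (1 - sv)), tolerance = 0.01)
  ## antisymmetric about s = 0.5 for a symmetric surface
  expect_equal(curve$dg_b, -rev(curve$dg_b), tolerance = 1e-9)
})

test_that("x* lands on the analytic inflection of a logistic curve", {
  fx <- fixture_dg_curve("logistic", s0 = 0.4)
  xs <- find_x_star(fx$curve, fx$pmf)
  expect_equal(xs$method, "first-inflection")
  ds <- diff(fx$curve$s_star[1:2])
  expect_equal(xs$s_star, 0.4, tolerance = 2 * ds)
})

test_that("x* falls back to the step midpoint without a pmf barrier", {
  fx <- fixture_dg_curve("two_plateau", s0 = 0.55, pmf_barrier = FALSE)
  xs <- find_x_star(fx$curve, fx$pmf)
  expect_equal(xs$method, "midpoint-fallback")
  expect_equal(xs$s_star, 0.55, tolerance = 0.05)
})

test_that("a strictly linear curve yields the no-divider error", {
  fx <- fixture_dg_curve("linear")
  expect_error(find_x_star(fx$curve, fx$pmf), "human intervention")
})

test_that("x* identification is deterministic", {
  fx <- fixture_dg_curve("logistic", s0 = 0.3)
  a <- find_x_star(fx$curve, fx$pmf)
  b <- find_x_star(fx$curve, fx$pmf)
  expect_identical(a, b)
})

test_that("the standard-volume correction has the right magnitude and sign", {
  expect_equal(volume_correction(1661, 300), 0)
  ## doubling the volume: |dG_V| = kT ln 2, negative for V_bulk > V-std
  expect_equal(volume_correction(3322, 300), -kT(300) * log(2))
  expect_equal(abs(volume_correction(3322, 300)), 0.413, tolerance = 1e-3)
  expect_gt(volume_correction(800, 300), 0)
  expect_error(volume_correction(-5), "positive")
})

test_that("standard volume derives from Avogadro's number", {
  expect_equal(standard_volume(), 1e27 / 6.02214076e23)
  expect_equal(standard_volume(exact = FALSE), 1661)
})

test_that("convergence window reacts to heights and diffusivity", {
  mk_colvar <- function(times, s) tibble::tibble(time = times, s = s,
                                                 z = 0, bias = 0)
  ## hills stuck at full height: no window
  hills_hot <- tibble::tibble(time = seq(1, 100), s = 1, z = 0,
                              sigma_s = 0.2, sigma_z = 0.01,
                              height = 0.2, biasf = 15)
  t <- seq(0, 100, by = 0.5)
  cv_diff <- mk_colvar(t, (1 - cos(t * 2)) / 2)   # sweeps [0, 1] rapidly
  w <- convergence_window(hills_hot, cv_diff, height0 = 0.2)
  expect_false(w$converged)

  ## heights decay below the threshold at t ~ 50, S diffusive throughout
  hills_ok <- dplyr::mutate(hills_hot,
                            height = 0.2 * exp(-time / 12))
  w2 <- convergence_window(hills_ok, cv_diff, height0 = 0.2)
  expect_true(w2$converged)
  ## 0.2 exp(-t/12) < 0.02 from t = 27.6; binning gives that within a bin
  expect_equal(w2$t_start, 12 * log(10), tolerance = 5)
  expect_equal(w2$t_end, 100)

  ## heights fine but S gets stuck late in the run: no window
  cv_stuck <- mk_colvar(t, ifelse(t < 60, (1 - cos(t * 2)) / 2,
                                  0.4 + 0.02 * sin(t)))
  w3 <- convergence_window(hills_ok, cv_stuck, height0 = 0.2,
                           span_fraction = 0.9)
  expect_false(w3$converged)
})

test_that("time statistics of a dG series are plain mean and stderr", {
  expect_equal(dg_time_stats(rep(-8.9, 4))$stderr, 0)
  expect_equal(dg_time_stats(rep(-8.9, 4))$mean, -8.9)
  st <- dg_time_stats(c(-9, -8.8, -9.2, -9.0))
  expect_equal(st$mean, -9.0)
  expect_equal(st$stderr, 0.0816, tolerance = 1e-3)
  expect_error(dg_time_stats(-9), "at least 2")
})
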