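test_that("bias energy sums anisotropic Gaussians in closed form", {
  none <- tibble::tibble(time = numeric(0), s = numeric(0), z = numeric(0),
                         sigma_s = numeric(0), sigma_z = numeric(0),
                         height = numeric(0), biasf = numeric(0))
  expect_equal(bias_energy(list(s = 0.3, z = 0.01), none), 0)
  one <- tibble::tibble(time = 1, s = 0.5, z = 0.02, sigma_s = 0.2,
                        sigma_z = 0.01, height = 0.2, biasf = 15)
  expect_equal(bias_energy(list(s = 0.5, z = 0.02), one), 0.2)
  ## two identical overlapping hills at distance sigma along s
  two <- dplyr::bind_rows(one, dplyr::mutate(one, s = 0.5 + 0.2))
  at <- list(s = 0.5, z = 0.02)
  expect_equal(bias_energy(at, two), 0.2 * (1 + exp(-0.5)))
  ## force: analytic derivative of the same sum
  f <- bias_force(at, two)
  expect_equal(unname(f["s"]),
               0.2 * exp(-0.5) * (0.5 - 0.7) / 0.2^2)
  expect_equal(unname(f["z"]), 0)
})

test_that("well-tempered heights follow the tempering rule", {
  expect_equal(next_height(0.2, 15, 0, 300), 0.2)
  ## V = (gamma-1) kT ln 2 halves the height
  v_half <- 14 * kT(300) * log(2)
  expect_equal(next_height(0.2, 15, v_half, 300), 0.1)
  ## untempered limit
  expect_equal(next_height(0.2, 1e9, 50, 300), 0.2, tolerance = 1e-6)
  expect_error(next_height(0.2, 1, 0), "exceed 1")
})

test_that("Langevin steps are deterministic and ballistic without noise", {
  flat <- structure(list(dimension = 1L, potential = function(x) 0,
                         gradient = function(x) 0 * x,
                         temperature = 0, mass = 40),
                    class = "toy_system")
  st <- list(x = 0, v = 0.1)
  out <- st
  for (i in 1:100) out <- langevin_step(out, flat, dt = 0.01, friction = 0)
  expect_equal(out$x, 0.1 * 1, tolerance = 1e-12)   # x = v t
  expect_equal(out$v, 0.1, tolerance = 1e-12)
  ## fixed seed -> bitwise identical trajectories
  dw <- toy_double_well()
  run_once <- function() {
    set.seed(42)
    s <- list(x = -0.5, v = 0)
    replicate(50, {s <<- langevin_step(s, dw); s$x})
  }
  expect_identical(run_once(), run_once())
})

test_that("Langevin sampling satisfies equipartition in a harmonic well", {
  k_spring <- 50   # kcal/mol/nm^2
  harm <- structure(list(dimension = 1L,
                         potential = function(x) 0.5 * k_spring * x^2,
                         gradient = function(x) k_spring * x,
                         temperature = 300, mass = 40),
                    class = "toy_system")
  set.seed(7)
  s <- list(x = 0, v = 0)
  n <- 20000
  xs <- numeric(n)
  for (i in seq_len(n)) { s <- langevin_step(s, harm, dt = 0.01, friction = 5); xs[i] <- s$x }
  xs <- xs[-(1:2000)]
  var_target <- kT(300) / k_spring
  ## 3 standard errors of the variance estimate, with a crude
  ## autocorrelation inflation factor
  se <- var_target * sqrt(2 / (length(xs) / 20)) * 3
  expect_lt(abs(var(xs) - var_target), se)
})

test_that("the engine deposits on schedule and reproduces bitwise", {
  dw <- toy_double_well()
  none <- run_wtmetad(dw, "identity", wtmetad_params(pace = 500),
                      n_steps = 499, seed = 1)
  expect_equal(nrow(none$hills), 0)
  r1 <- run_wtmetad(dw, "identity", wtmetad_params(sigma_s = 0.05),
                    n_steps = 2e4, seed = 9)
  r2 <- run_wtmetad(dw, "identity", wtmetad_params(sigma_s = 0.05),
                    n_steps = 2e4, seed = 9)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$colvar, r2$colvar)
  expect_equal(nrow(r1$hills), 40)
  expect_equal(r1$hills$time, seq(500, 2e4, by = 500) * 0.002)
  ## heights within (0, omega0]
  expect_true(all(r1$hills$height > 0 & r1$hills$height <= 0.2))
})

test_that("deposited heights decay at a revisited point and bias grows as logged", {
  dw <- toy_double_well()
  run <- run_wtmetad(dw, "identity", wtmetad_params(sigma_s = 0.05),
                     n_steps = 4e5, seed = 3)
  h <- run$hills
  ## heights deposited near the starting well decrease monotonically in
  ## coarse time blocks (well-visited region)
  near_well <- h[abs(h$s + 0.5) < 0.1, ]
  blocks <- split(near_well$height,
                  cut(near_well$time, 5))
  med <- vapply(blocks, stats::median, numeric(1))
  med <- med[!is.na(med)]
  expect_true(all(diff(med) < 0))
  ## the recorded bias is consistent with re-summing the ledger
  last <- utils::tail(run$colvar, 1)
  prior <- h[h$time <= last$time, ]
  expect_equal(last$bias, bias_energy(list(s = last$s), prior),
               tolerance = 0.02)
})

test_that("toy funnel energies and gradients are mutually consistent", {
  sys <- toy_funnel()
  h <- 1e-6
  for (x in list(c(0.1, 0.05), c(0.5, -0.1), c(1.5, 0.02), c(-0.25, 0))) {
    g <- sys$gradient(x)
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      num <- (sys$potential(x + e) - sys$potential(x - e)) / (2 * h)
      expect_equal(g[k], num, tolerance = 1e-4)
    }
  }
})
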