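uniform_refs <- function(P = 19, spacing = 0.1) {
  cbind(seq(0, by = spacing, length.out = P), 0)
}

test_that("the lambda heuristic reproduces its reference value and scaling", {
  ## 1 Angstrom spacing target: <d^2> = 0.01 nm^2
  expect_equal(lambda_from_spacing(0.01), 230.0)
  ## doubling the spacing divides lambda by 4
  expect_equal(lambda_from_spacing(0.04), 230.0 / 4)
  expect_equal(lambda_from_spacing(2.3), 1)
  expect_error(lambda_from_spacing(0), "positive")
  ## AUTO wiring: a path at 0.1 nm spacing gets lambda = 230
  defn <- pcv_definition(uniform_refs())
  expect_equal(defn$lambda, 230.0)
})

test_that("S hits its endpoints and Z vanishes at reference frames", {
  refs <- uniform_refs()
  defn <- pcv_definition(refs, lambda = 5000)   # sharply peaked weights
  first <- compute_pcv(refs[1, ], defn)
  last <- compute_pcv(refs[nrow(refs), ], defn)
  expect_equal(first$s, 0, tolerance = 1e-3)
  expect_equal(last$s, 1, tolerance = 1e-3)
  expect_equal(first$z, 0, tolerance = 1e-4)
  ## Z(x_i) <= 0 always, bounded by -log(P)/lambda
  defn2 <- pcv_definition(refs)                 # lambda = 230
  zs <- apply(refs, 1, function(x) compute_pcv(x, defn2)$z)
  expect_true(all(zs <= 0))
  expect_true(all(abs(zs) < log(nrow(refs)) / defn2$lambda))
})

test_that("a point equidistant from two frames lands between their indices", {
  refs <- uniform_refs(10)
  k <- 4
  x <- c((refs[k, 1] + refs[k + 1, 1]) / 2, 0)
  ## large lambda concentrates weight on the two flanking frames
  defn <- pcv_definition(refs, lambda = 3000)
  s <- compute_pcv(x, defn)$s
  expect_equal(s, (k - 1 + 0.5) / (10 - 1), tolerance = 1e-3)
})

test_that("S increases strictly along a uniform reference path", {
  refs <- uniform_refs(15)
  defn <- pcv_definition(refs)
  ss <- apply(refs, 1, function(x) compute_pcv(x, defn)$s)
  expect_true(all(diff(ss) > 0))
})

test_that("PCV values are invariant to rigid motion with superposition on", {
  set.seed(31)
  base <- lapply(1:5, function(i)
    conformation(matrix(rnorm(12, sd = 0.15), 4, 3) +
                   matrix(c(0.1 * i, 0, 0), 4, 3, byrow = TRUE),
                 frame_id = i))
  defn <- suppressWarnings(
    pcv_definition(base, lambda = 100, align = atom_selection(1:4)))
  x <- conformation(base[[3]]$coords + 0.02)
  v0 <- compute_pcv(x, defn)
  xm <- rigid_motion(x, ang = 1.3, shift = c(1, -2, 0.5))
  vm <- compute_pcv(xm, defn)
  expect_equal(vm$s, v0$s, tolerance = 1e-8)
  expect_equal(vm$z, v0$z, tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  set.seed(32)
  refs <- cbind(seq(0, 1, length.out = 11), 0.05 * sin(seq(0, pi, length.out = 11)))
  defn <- pcv_definition(refs)
  for (rep in 1:4) {
    x <- c(runif(1, 0.1, 0.9), runif(1, -0.15, 0.15))
    g <- pcv_gradient(x, defn)
    h <- 1e-6
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      num_s <- (compute_pcv(x + e, defn)$s - compute_pcv(x - e, defn)$s) / (2 * h)
      num_z <- (compute_pcv(x + e, defn)$z - compute_pcv(x - e, defn)$z) / (2 * h)
      expect_equal(g$ds[k], num_s, tolerance = 1e-5)
      expect_equal(g$dz[k], num_z, tolerance = 1e-5)
    }
  }
})

test_that("gradient limits behave: symmetry and the lambda -> 0 plateau", {
  refs <- rbind(c(0, 0), c(1, 0))
  defn <- pcv_definition(refs, lambda = 10)
  g <- pcv_gradient(c(0.5, 0.3), defn)     # symmetric midpoint
  ## s gradient along the interframe axis only
  expect_gt(abs(g$ds[1]), 1e-3)
  expect_equal(g$ds[2], 0, tolerance = 1e-10)
  ## z gradient perpendicular component dominates, x-component zero
  expect_equal(g$dz[1], 0, tolerance = 1e-10)
  ## lambda -> 0: all weights equal, s gradient vanishes
  defn0 <- pcv_definition(refs, lambda = 1e-8)
  g0 <- pcv_gradient(c(0.3, 0.1), defn0)
  expect_equal(g0$ds, c(0, 0), tolerance = 1e-6)
})

test_that("gradients through superposition are refused", {
  confs <- lapply(1:3, function(i) {
    f <- cloud4()
    f$coords <- f$coords + i * 0.1
    f$frame_id <- i
    f
  })
  defn <- suppressWarnings(pcv_definition(confs, lambda = 50,
                                          align = atom_selection(1:4)))
  expect_error(pcv_gradient(c(0, 0, 0), defn), "unsupported")
})

test_that("uneven reference spacing triggers the smoothness warning", {
  refs <- cbind(c(0, 0.1, 0.2, 0.5), 0)
  expect_warning(pcv_definition(refs, lambda = 100), "factor 2")
})

test_that("path padding extrapolates both ends linearly", {
  refs <- uniform_refs(5)
  pad <- pad_path_refs(refs, 2)
  expect_equal(nrow(pad), 9)
  expect_equal(pad[1, 1], -0.2)
  expect_equal(pad[9, 1], 0.6)
  expect_equal(pad[3:7, ], refs)
  ## conformational paths pad the same way
  confs <- lapply(seq(0, 0.4, by = 0.1), function(x)
    conformation(rbind(c(x, 0, 0), c(x, 0.1, 0))))
  padc <- pad_path_refs(confs, 1)
  expect_length(padc, 7)
  expect_equal(padc[[1]]$coords[1, 1], -0.1)
  expect_equal(padc[[7]]$coords[1, 1], 0.5)
})
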