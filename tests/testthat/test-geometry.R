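test_that("superposing a conformation onto itself is the identity", {
  a <- cloud4()
  sp <- superpose(a, a)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sp$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-12)
})

test_that("a pure rigid motion is recovered exactly", {
  a <- cloud4()
  b <- rigid_motion(a, ang = pi / 2, shift = c(1, 0, 0))
  sp <- superpose(a, b)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(a, sp)$coords, b$coords,
               tolerance = 1e-10)
})

test_that("fit rmsd of a noisy rotated copy matches the rotation-grid oracle", {
  a <- cloud4()
  ## rotated (0.7 rad about z), shifted, perturbed copy; the expected value
  ## is the minimum RMSD from exhaustive search over a refined Euler-angle
  ## grid (independent of the closed-form solver)
  b <- conformation(rbind(
    c(0.060000000000000005, -0.025, 0.10200000000000001),
    c(0.27145265618534653, 0.18526530617130732, 0.1),
    c(-0.0748435374475382, 0.1329684374568977, 0.08900000000000001),
    c(0.059062450004679745, 0.11390598745221796, 0.359)))
  sp <- superpose(a, b)
  expect_equal(sp$fit_rmsd, 0.009090771984237, tolerance = 1e-8)
})

test_that("rmsd matches a hand-computed deviation and basic contracts", {
  a <- conformation(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0)))
  b <- conformation(rbind(c(0, 0, 0), c(0.1, 0, 0.3), c(0, 0.1, 0)))
  ## identity alignment (align = NULL skips the fit): only atom 2 deviates
  expect_equal(conf_rmsd(a, b), sqrt(0.3^2 / 3))
  expect_equal(conf_rmsd(a, a), 0)
  ## rigid motion of one frame gives 0 for any selections
  m <- rigid_motion(cloud4(), ang = 1.1, shift = c(-0.2, 0.4, 0.05))
  expect_equal(conf_rmsd(cloud4(), m, align = 1:4, measure = c(2, 4)), 0,
               tolerance = 1e-10)
})

test_that("rmsd is invariant under simultaneous rigid motion of both frames", {
  a <- cloud4()
  b <- conformation(a$coords + matrix(c(0.02, -0.01, 0.03), 4, 3,
                                      byrow = TRUE) * c(1, -1, 2, 0.5))
  r0 <- conf_rmsd(a, b, align = 1:4, measure = 1:4)
  for (ang in c(0.3, 2.2)) {
    am <- rigid_motion(a, ang, c(0.5, -1, 2))
    bm <- rigid_motion(b, ang, c(0.5, -1, 2))
    expect_equal(conf_rmsd(am, bm, align = 1:4, measure = 1:4), r0,
                 tolerance = 1e-10)
  }
})

test_that("re-fitting an already fitted mobile is the identity", {
  a <- cloud4()
  b <- rigid_motion(a, 0.9, c(0.1, 0.2, -0.3))
  b$coords <- b$coords + 0.01 * matrix(sin(1:12), 4, 3)  # deterministic noise
  fitted <- apply_superposition(a, superpose(a, b))
  sp2 <- superpose(fitted, b)
  expect_equal(sp2$rotation, diag(3), tolerance = 1e-8)
  expect_equal(sp2$translation, rep(0, 3), tolerance = 1e-8)
})

test_that("rotation stays proper for mirror-degenerate input", {
  a <- cloud4()
  b <- conformation(a$coords %*% diag(c(1, 1, -1)))  # reflected copy
  sp <- superpose(a, b)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_gt(sp$fit_rmsd, 0)
})

test_that("degenerate alignment selections are rejected", {
  a <- cloud4()
  expect_error(superpose(a, a, align = 1:2), "degenerate")
  line <- conformation(cbind(seq(0, 0.3, length.out = 4), 0, 0))
  expect_error(superpose(line, line), "collinear")
  expect_error(conf_rmsd(a, a, measure = integer(0)), "empty measure")
})

test_that("superposition agrees with an independent structural-biology fit", {
  skip_if_not_installed("bio3d")
  a <- cloud4()
  b <- rigid_motion(a, 0.5, c(0.3, 0, -0.1))
  b$coords <- b$coords + 0.005 * matrix(cos(1:12), 4, 3)
  sp <- superpose(a, b)
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(b$coords)),
                   mobile = as.numeric(t(a$coords))))
  ref_rmsd <- sqrt(mean(colSums(matrix(
    (xyz_fit - as.numeric(t(b$coords)))^2, nrow = 3))))
  expect_equal(sp$fit_rmsd, ref_rmsd, tolerance = 1e-6)
})
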