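## single-atom frames at given 1-D positions, handy for exact gap control
frame_at <- function(x, id = NA) conformation(c(x, 0, 0), frame_id = id)

test_that("interframe distances recompute pairwise RMSD", {
  p <- lapply(c(0, 0, 0.2), frame_at)
  expect_equal(interframe_distances(p), c(0, 0.2))
  same <- lapply(rep(0.3, 4), frame_at)
  expect_equal(interframe_distances(same), rep(0, 3))
  ## 5-frame synthetic path vs per-pair recomputation
  set.seed(5)
  path <- lapply(1:5, function(i)
    conformation(matrix(rnorm(12, sd = 0.2), 4, 3), frame_id = i))
  got <- interframe_distances(path, align = 1:4)
  expected <- vapply(1:4, function(i)
    conf_rmsd(path[[i + 1]], path[[i]], align = 1:4), numeric(1))
  expect_equal(got, expected)
  expect_error(interframe_distances(path[1]), "at least 2")
})

test_that("geometric propagator interpolates at exact fractions", {
  a <- frame_at(0); b <- frame_at(0.35)
  expect_length(geometric_propagator(a, b, 0), 0)
  mid <- geometric_propagator(a, b, 1)[[1]]
  expect_equal(conf_rmsd(mid, a), conf_rmsd(mid, b))
  expect_equal(conf_rmsd(mid, a), 0.35 / 2)
  three <- geometric_propagator(a, b, 3)
  gaps <- interframe_distances(c(list(a), three, list(b)))
  expect_equal(gaps, rep(0.0875, 4))
})

test_that("resampling fills oversized gaps and leaves compliant paths alone", {
  ## already-uniform path: unchanged, zero insertions
  p <- lapply(seq(0, 0.4, by = 0.08), frame_at)
  out <- equidistant_resample(p, threshold = 0.1)
  expect_length(out$path, length(p))
  expect_equal(sum(out$report$inserted_per_gap), 0)

  ## two frames 0.35 nm apart at the 0.1 nm default threshold
  out2 <- equidistant_resample(list(frame_at(0), frame_at(0.35)))
  expect_equal(out2$report$threshold, 0.1)
  expect_equal(out2$report$inserted_per_gap, 3L)
  expect_length(out2$path, 5)
  expect_equal(out2$report$final_gaps, rep(0.0875, 4))
  expect_true(all(out2$report$final_gaps <= 0.1 * 1.05))
})

test_that("with the geometric propagator final gaps are exactly d/ceil(d/thr)", {
  gaps0 <- c(0.05, 0.23, 0.11, 0.4)
  xs <- cumsum(c(0, gaps0))
  p <- lapply(xs, frame_at)
  out <- equidistant_resample(p, threshold = 0.1)
  expected <- unlist(lapply(gaps0, function(d) {
    k <- ceiling(d / 0.1)
    rep(d / k, k)
  }))
  expect_equal(out$report$final_gaps, expected)
  ## frame count identity and original ordering preserved
  expect_length(out$path, length(p) + sum(out$report$inserted_per_gap))
  orig_x <- vapply(p, function(f) f$coords[1, 1], numeric(1))
  new_x <- vapply(out$path, function(f) f$coords[1, 1], numeric(1))
  expect_true(all(orig_x %in% new_x))
  expect_true(!is.unsorted(new_x))
})

test_that("resampling is idempotent", {
  p <- lapply(c(0, 0.31, 0.38, 0.8), frame_at)
  once <- equidistant_resample(p, threshold = 0.1)
  twice <- equidistant_resample(once$path, threshold = 0.1)
  expect_equal(sum(twice$report$inserted_per_gap), 0)
  expect_length(twice$path, length(once$path))
})

test_that("a propagator that cannot close a gap raises a named error", {
  stuck <- function(current, target, n) {
    lapply(seq_len(n), function(k) current)  # never approaches the target
  }
  expect_error(
    equidistant_resample(list(frame_at(0), frame_at(1)), threshold = 0.1,
                         propagator = stuck),
    "failed to reduce")
})

test_that("a stochastic propagator converges within the tolerance", {
  set.seed(99)
  noisy <- function(current, target, n) {
    pts <- geometric_propagator(current, target, n)
    lapply(pts, function(f) {
      f$coords <- f$coords + rnorm(length(f$coords), sd = 0.004)
      f
    })
  }
  out <- equidistant_resample(list(frame_at(0), frame_at(0.5)),
                              threshold = 0.1, propagator = noisy)
  expect_true(all(out$report$final_gaps <= 0.1 * 1.05))
})
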