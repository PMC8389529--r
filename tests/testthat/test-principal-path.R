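ep2 <- rbind(c(0, 0), c(1, 0))

test_that("path cost reduces to the k-means cost and expands by hand", {
  X <- rbind(c(0, 0), c(1, 0), c(0.4, 0.3))
  cl <- points_cloud(X)
  ## samples coincident with their waypoint, s = 0
  expect_equal(as.numeric(path_cost(
    list(endpoints = ep2, waypoints = rbind(X[1, ]),
         memberships = c(1L, 1L), smoothness = 0),
    points_cloud(X[c(1, 1), , drop = FALSE], 1:2))), 0)
  ## s = 0 equals the plain k-means cost for the same assignment
  W <- rbind(c(0.1, 0), c(0.8, 0.1))
  u <- c(1L, 2L, 2L)
  km <- sum((X - W[u, ])^2)
  expect_equal(as.numeric(path_cost(
    list(endpoints = ep2, waypoints = W, memberships = u, smoothness = 0),
    cl)), km)
  ## 3 samples, 1 waypoint, s = 1: hand-expanded sum
  w <- c(0.5, 0.1)
  hand <- sum((X - rbind(w, w, w))^2) +
    1 * (sum((w - ep2[1, ])^2) + sum((ep2[2, ] - w)^2))
  expect_equal(as.numeric(path_cost(
    list(endpoints = ep2, waypoints = rbind(w), memberships = rep(1L, 3),
         smoothness = 1), cl)), hand)
})

test_that("huge smoothness collapses waypoints onto the straight segment", {
  set.seed(4)
  cl <- points_cloud(matrix(runif(40), 20, 2))
  fit <- fit_principal_path(cl, ep2, n_waypoints = 4, s = 1e8)
  expected <- (seq_len(4) / 5) %o% ep2[2, ] + ((5 - seq_len(4)) / 5) %o% ep2[1, ]
  expect_equal(fit$waypoints, expected, tolerance = 1e-4)
})

test_that("zero smoothness with separated clusters recovers the centroids", {
  X <- rbind(matrix(c(0.1, 0.1), 5, 2, byrow = TRUE) + 0.01 * sin(1:10),
             matrix(c(0.9, 0.1), 5, 2, byrow = TRUE) + 0.01 * cos(1:10))
  cl <- points_cloud(X)
  fit <- fit_principal_path(cl, ep2, n_waypoints = 2, s = 0,
                            init = rbind(c(0.1, 0.1), c(0.9, 0.1)))
  expect_equal(fit$waypoints,
               rbind(colMeans(X[1:5, ]), colMeans(X[6:10, ])),
               tolerance = 1e-10)
})

test_that("small instances reach the exhaustive-assignment global optimum", {
  set.seed(7)
  cases <- list(
    list(n = 6, n_wp = 2, s = 0.5),
    list(n = 7, n_wp = 3, s = 1),
    list(n = 8, n_wp = 3, s = 0.2))
  for (cs in cases) {
    t <- sort(runif(cs$n))
    X <- cbind(cos(t * pi / 2), sin(t * pi / 2)) +
      matrix(rnorm(2 * cs$n, sd = 0.05), cs$n, 2)
    cl <- points_cloud(X)
    ep <- rbind(c(1, 0), c(0, 1))
    fit <- fit_principal_path(cl, ep, cs$n_wp, cs$s)
    got <- as.numeric(path_cost(fit, cl))
    oracle <- brute_force_principal_path(cl, ep, cs$n_wp, cs$s)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("cost trace is monotone non-increasing", {
  set.seed(21)
  fx <- fixture_arc_cloud(n = 80, noise = 0.05)
  for (s in c(0, 0.5, 5)) {
    fit <- fit_principal_path(fx$cloud, fx$endpoints, 8, s)
    expect_true(all(diff(fit$cost_trace) <= 1e-9))
  }
})

test_that("doubling s never shrinks the smoothness share of the cost", {
  set.seed(22)
  fx <- fixture_arc_cloud(n = 100, noise = 0.04)
  share <- vapply(c(0.25, 0.5, 1, 2, 4, 8), function(s) {
    fit <- fit_principal_path(fx$cloud, fx$endpoints, 6, s)
    cost <- path_cost(fit, fx$cloud)
    s * attr(cost, "smoothness_term") / as.numeric(cost)
  }, numeric(1))
  expect_true(all(diff(share) >= -1e-8))
})

test_that("smoothness selection returns sensible picks", {
  set.seed(23)
  fx <- fixture_arc_cloud(n = 120, noise = 0.05)
  grid <- 10^seq(-2, 2, length.out = 9)
  ## single-s grid: that s comes back
  one <- select_smoothness(fx$cloud, fx$endpoints, 6, s_grid = 2)
  expect_equal(one$s, 2)
  ## straight-line cloud: data term flat in s -> smallest s, flagged
  line <- points_cloud(cbind(seq(0, 1, length.out = 30), 0))
  deg <- select_smoothness(line, ep2, 4, s_grid = grid)
  expect_true(deg$degenerate)
  expect_equal(deg$s, grid[1])
  ## noisy arc: elbow pick is reproducible under a fixed seed
  p1 <- select_smoothness(fx$cloud, fx$endpoints, 6, s_grid = grid)
  p2 <- select_smoothness(fx$cloud, fx$endpoints, 6, s_grid = grid)
  expect_equal(p1$s, p2$s)
  expect_true(p1$s %in% grid && !p1$degenerate)
  expect_equal(nrow(p1$curve), length(grid))
})

test_that("snapping maps waypoints to the nearest samples, deduplicated", {
  X <- rbind(c(0, 0), c(0.2, 0.05), c(0.4, -0.02), c(0.6, 0.03),
             c(0.8, 0), c(1, 0), c(0.41, 0.3), c(0.15, -0.2),
             c(0.55, 0.2), c(0.9, 0.1))
  cl <- points_cloud(X)
  fit <- fit_principal_path(cl, ep2, 4, s = 0.5)
  ids <- snap_to_samples(fit, cl)
  ## brute-force nearest-sample table over the full chain
  chain <- rbind(ep2[1, ], fit$waypoints, ep2[2, ])
  expected <- apply(chain, 1, function(w)
    which.min(colSums((t(X) - w)^2)))
  expected <- expected[!duplicated(expected)]
  expect_equal(ids, cl$frame_ids[expected])
  expect_false(anyDuplicated(ids) > 0)

  ## waypoints equal to samples snap to exactly those samples
  fit2 <- list(endpoints = rbind(X[1, ], X[6, ]),
               waypoints = X[c(2, 4), ], memberships = c(1L, 2L),
               smoothness = 0)
  expect_equal(snap_to_samples(fit2, cl), c(1L, 2L, 4L, 6L))
  ## two waypoints nearest to the same sample: one occurrence kept
  fit3 <- fit2
  fit3$waypoints <- rbind(X[2, ] + 0.001, X[2, ] - 0.001)
  expect_equal(snap_to_samples(fit3, cl), c(1L, 2L, 6L))
})

test_that("tidiers expose the fitted path as tables", {
  set.seed(2)
  fx <- fixture_arc_cloud(n = 40, noise = 0.03)
  fit <- fit_principal_path(fx$cloud, fx$endpoints, 5, s = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 7)           # 5 waypoints + 2 fixed endpoints
  expect_equal(sum(td$fixed), 2)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_waypoints, 5)
})
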