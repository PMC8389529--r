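## Principal path: approximate minimum free energy path through a cloud
## of sampled conformations, found by minimizing a k-means cost with a
## quadratic smoothness regularizer between consecutive waypoints
## (including two fixed endpoint configurations).

#' Points cloud for path finding
#'
#' Samples are feature vectors; for molecular input use
#' [cloud_from_conformations()] which superposes every frame onto a common
#' reference and flattens the measure-atom coordinates.
#'
#' @param samples Numeric N x d matrix (N >= 2).
#' @param frame_ids Integer vector of source frame ids (default 1..N).
#' @return An object of class `"points_cloud"`.
#' @export
points_cloud <- function(samples, frame_ids = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(samples))) stop("samples must be finite")
  frame_ids <- frame_ids %||% seq_len(nrow(samples))
  if (length(frame_ids) != nrow(samples))
    stop("frame_ids length must equal sample count")
  structure(list(samples = samples, frame_ids = as.integer(frame_ids)),
            class = "points_cloud")
}

#' Feature-space embedding of a molecular path
#'
#' Superposes every frame onto `reference` using the alignment selection,
#' then flattens the measure-atom coordinates into one row per frame.
#' This makes squared Euclidean distance in feature space equal to
#' (number of measure atoms) times the squared RMSD metric used elsewhere.
#'
#' @param frames List of [conformation()] objects.
#' @param reference Reference `conformation` (typically the bound state).
#' @param align,measure Atom selections (see [atom_selection()]).
#' @return A [points_cloud()].
#' @export
cloud_from_conformations <- function(frames, reference,
                                     align = NULL, measure = NULL) {
  im <- sel_idx(measure, reference)
  rows <- t(vapply(frames, function(f) {
    if (!is.null(align)) f <- apply_superposition(f, superpose(f, reference, align))
    as.numeric(t(f$coords[im, , drop = FALSE]))
  }, numeric(3L * length(im))))
  ids <- vapply(frames, function(f) f$frame_id, integer(1))
  if (anyNA(ids)) ids <- seq_along(frames)
  points_cloud(rows, ids)
}

#' Regularized k-means path cost
#'
#' Data term plus smoothness term:
#' \eqn{\sum_i \lVert x_i - w_{u_i}\rVert^2 +
#'      s \sum_j \lVert w_{j+1} - w_j \rVert^2},
#' the smoothness sum running over all consecutive pairs including the two
#' fixed endpoints.
#'
#' @param model A `"principal_path"` model (see [fit_principal_path()]),
#'   or a list with `endpoints` (2 x d), `waypoints` (Nc x d),
#'   `memberships`, `smoothness`.
#' @param cloud A [points_cloud()].
#' @return Scalar cost; attributes `data_term` and `smoothness_term` carry
#'   the two contributions.
#' @export
path_cost <- function(model, cloud) {
  X <- cloud$samples
  W <- model$waypoints
  if (ncol(X) != ncol(W)) stop("dimension mismatch between model and cloud")
  u <- model$memberships
  data_term <- sum((X - W[u, , drop = FALSE])^2)
  chain <- rbind(model$endpoints[1, ], W, model$endpoints[2, ])
  smooth_term <- sum(diff(chain)^2)
  structure(data_term + model$smoothness * smooth_term,
            data_term = data_term, smoothness_term = smooth_term)
}

## Exact waypoint update given memberships: solve the coupled tridiagonal
## system (n_j + 2s) w_j - s w_{j-1} - s w_{j+1} = sum_{u_i=j} x_i, with
## the fixed endpoints entering the boundary rows' right-hand sides.
solve_waypoints <- function(X, u, n_wp, endpoints, s) {
  d <- ncol(X)
  counts <- tabulate(u, nbins = n_wp)
  rhs <- matrix(0, n_wp, d)
  for (j in seq_len(n_wp)) {
    if (counts[j] > 0)
      rhs[j, ] <- colSums(X[u == j, , drop = FALSE])
  }
  if (s > 0) {
    A <- diag(counts + 2 * s, n_wp)
    if (n_wp > 1) {
      idx <- seq_len(n_wp - 1)
      A[cbind(idx, idx + 1)] <- -s
      A[cbind(idx + 1, idx)] <- -s
    }
    rhs[1, ] <- rhs[1, ] + s * endpoints[1, ]
    rhs[n_wp, ] <- rhs[n_wp, ] + s * endpoints[2, ]
    solve(A, rhs)
  } else {
    ## plain k-means update; empty waypoints re-seeded at the midpoint of
    ## their neighbours (endpoints included in the chain)
    W <- rhs
    for (j in seq_len(n_wp)) {
      if (counts[j] > 0) W[j, ] <- rhs[j, ] / counts[j]
    }
    chain <- rbind(endpoints[1, ], W, endpoints[2, ])
    for (j in which(counts == 0))
      W[j, ] <- (chain[j, ] + chain[j + 2, ]) / 2
    W
  }
}

assign_nearest <- function(X, W) {
  ## squared distances N x Nc; ties broken toward the lowest waypoint index
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  max.col(-d2, ties.method = "first")
}

#' Fit a principal path
#'
#' Alternating minimization of the regularized k-means functional: each
#' sample is assigned to its nearest waypoint, then all waypoints are
#' updated jointly by solving the tridiagonal linear system coupling
#' consecutive waypoints through the smoothness term, with the two fixed
#' endpoints as boundary conditions. The cost trace is non-increasing
#' because both half-steps are exact minimizers.
#'
#' @param cloud A [points_cloud()].
#' @param endpoints 2 x d matrix: the fixed first and last path points
#'   (bound and fully unbound configurations).
#' @param n_waypoints Number of free waypoints Nc (>= 1).
#' @param s Smoothness hyper-parameter (>= 0). Large `s` pulls the path
#'   toward the straight segment between the endpoints; `s = 0` recovers
#'   plain k-means with ordered centroids.
#' @param init `"linear"` (equispaced between the endpoints) or
#'   `"samples"` (a subsample of the cloud in frame order), or a Nc x d
#'   matrix of starting waypoints.
#' @param max_iter,tol Convergence controls: stop when the relative cost
#'   change drops below `tol` or after `max_iter` iterations.
#' @param restarts Additional random initializations (waypoints drawn from
#'   the cloud, ordered by projection onto the endpoint axis); the lowest
#'   final cost wins. Alternating minimization can stall in local minima
#'   on clumpy clouds; a handful of restarts recovers the global optimum
#'   on all instances small enough to verify exhaustively. Uses the R RNG.
#' @return An object of class `"principal_path"`: list with `endpoints`,
#'   `waypoints`, `memberships`, `smoothness`, `cost_trace`, `converged`.
#' @examples
#' set.seed(1)
#' cl <- fixture_arc_cloud(n = 60, noise = 0.02)
#' fit <- fit_principal_path(cl$cloud, cl$endpoints, n_waypoints = 6, s = 1)
#' fit$converged
#' @export
fit_principal_path <- function(cloud, endpoints, n_waypoints, s,
                               init = "linear", max_iter = 500, tol = 1e-8,
                               restarts = 7) {
  endpoints <- as.matrix(endpoints)
  best <- fit_principal_path_once(cloud, endpoints, n_waypoints, s,
                                  init, max_iter, tol)
  if (!is.matrix(init) && restarts > 0 && nrow(cloud$samples) > n_waypoints) {
    X <- cloud$samples
    axis <- endpoints[2, ] - endpoints[1, ]
    for (r in seq_len(restarts)) {
      pick <- sample.int(nrow(X), n_waypoints)
      W0 <- X[pick[order(X[pick, , drop = FALSE] %*% axis)], , drop = FALSE]
      cand <- fit_principal_path_once(cloud, endpoints, n_waypoints, s,
                                      W0, max_iter, tol)
      if (utils::tail(cand$cost_trace, 1) <
          utils::tail(best$cost_trace, 1) - 1e-12)
        best <- cand
    }
  }
  best
}

fit_principal_path_once <- function(cloud, endpoints, n_waypoints, s,
                                    init, max_iter, tol) {
  X <- cloud$samples
  if (!all(is.finite(endpoints)) || !all(is.finite(X)))
    stop("non-finite inputs")
  if (s < 0) stop("smoothness s must be non-negative")
  if (n_waypoints < 1) stop("need at least one waypoint")
  if (ncol(endpoints) != ncol(X)) stop("endpoint dimension mismatch")
  W <- if (is.matrix(init)) {
    init
  } else if (identical(init, "linear")) {
    a <- seq_len(n_waypoints) / (n_waypoints + 1)
    (1 - a) %o% endpoints[1, ] + a %o% endpoints[2, ]
  } else if (identical(init, "samples")) {
    X[round(seq(1, nrow(X), length.out = n_waypoints + 2))[2:(n_waypoints + 1)],
      , drop = FALSE]
  } else stop("unknown init")

  cost_trace <- numeric(0)
  u <- assign_nearest(X, W)
  for (it in seq_len(max_iter)) {
    W <- solve_waypoints(X, u, n_waypoints, endpoints, s)
    model <- list(endpoints = endpoints, waypoints = W,
                  memberships = u, smoothness = s)
    cost_trace <- c(cost_trace, as.numeric(path_cost(model, cloud)))
    u_new <- assign_nearest(X, W)
    if (identical(u_new, u) && it > 1) break
    u <- u_new
    if (it > 1) {
      rel <- abs(cost_trace[it - 1] - cost_trace[it]) /
        max(abs(cost_trace[it - 1]), .Machine$double.eps)
      if (rel < tol) break
    }
  }
  structure(
    list(endpoints = endpoints, waypoints = W, memberships = u,
         smoothness = s, cost_trace = cost_trace,
         converged = length(cost_trace) < max_iter),
    class = "principal_path"
  )
}

#' @export
print.principal_path <- function(x, ...) {
  cat(sprintf(
    "<principal_path> %d waypoints, s = %g, final cost %.6g (%d iterations)\n",
    nrow(x$waypoints), x$smoothness, utils::tail(x$cost_trace, 1),
    length(x$cost_trace)))
  invisible(x)
}

#' Smoothness trade-off scan
#'
#' Fits the path for every `s` in a grid and records the data and
#' smoothness terms of the final cost. The default pick is the elbow of
#' the normalized data-term versus log(s) curve (point of maximum discrete
#' curvature); it is advisory and callers may override. When the data term
#' is flat across the grid (samples on a straight line) the elbow is
#' undefined and the smallest `s` is returned with `degenerate = TRUE`.
#'
#' @inheritParams fit_principal_path
#' @param s_grid Positive, sorted vector of candidate smoothness values.
#' @param ... Passed to [fit_principal_path()].
#' @return List with `s` (the pick), `curve` (a tibble: `s`, `data_term`,
#'   `smoothness_term`, `cost`) and `degenerate` (`TRUE` when the cloud is
#'   collinear, so the path shape cannot trade fit against smoothness and
#'   the elbow is undefined; the smallest `s` is then returned).
#' @export
select_smoothness <- function(cloud, endpoints, n_waypoints, s_grid, ...) {
  if (length(s_grid) == 0) stop("s_grid is empty")
  if (any(s_grid <= 0) || is.unsorted(s_grid))
    stop("s_grid must be positive and sorted")
  rows <- purrr::map(s_grid, function(s) {
    fit <- fit_principal_path(cloud, endpoints, n_waypoints, s, ...)
    cost <- path_cost(fit, cloud)
    tibble::tibble(s = s, data_term = attr(cost, "data_term"),
                   smoothness_term = attr(cost, "smoothness_term"),
                   cost = as.numeric(cost))
  })
  curve <- dplyr::bind_rows(rows)
  if (length(s_grid) == 1L)
    return(list(s = s_grid, curve = curve, degenerate = FALSE))
  ## collinear cloud: the fitted path is a straight segment for every s,
  ## only its parameterization changes -- no geometric trade-off exists
  sv <- svd(scale(cloud$samples, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    return(list(s = s_grid[1], curve = curve, degenerate = TRUE))
  }
  rng <- diff(range(curve$data_term))
  if (rng < 1e-12 * max(abs(curve$data_term), 1)) {
    return(list(s = s_grid[1], curve = curve, degenerate = TRUE))
  }
  y <- (curve$data_term - min(curve$data_term)) / rng
  x <- log(curve$s)
  n <- length(x)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    h1 <- x[i] - x[i - 1]; h2 <- x[i + 1] - x[i]
    yp <- (y[i + 1] - y[i - 1]) / (h1 + h2)
    ypp <- 2 * (h1 * y[i + 1] - (h1 + h2) * y[i] + h2 * y[i - 1]) /
      (h1 * h2 * (h1 + h2))
    kappa[i] <- abs(ypp) / (1 + yp^2)^1.5
  }
  pick <- which.max(kappa)
  list(s = curve$s[pick], curve = curve, degenerate = FALSE)
}

#' Snap waypoints back to physical frames
#'
#' For each path point (including the two fixed endpoints) the nearest
#' cloud sample in feature space is identified; consecutive duplicates and
#' out-of-order revisits are collapsed so the result is a strictly
#' ordered, duplicate-free frame sequence.
#'
#' @param model A fitted `"principal_path"`.
#' @param cloud The [points_cloud()] the model was fitted to.
#' @return Integer vector of frame ids in path order.
#' @export
snap_to_samples <- function(model, cloud) {
  X <- cloud$samples
  if (nrow(X) == 0L) stop("empty cloud")
  chain <- rbind(model$endpoints[1, ], model$waypoints, model$endpoints[2, ])
  d2 <- outer(rowSums(chain^2), rowSums(X^2), "+") - 2 * chain %*% t(X)
  nearest <- max.col(-d2, ties.method = "first")
  ids <- cloud$frame_ids[nearest]
  ids[!duplicated(ids)]
}

#' @rdname glance
#' @export
glance.principal_path <- function(x, ...) {
  cost <- utils::tail(x$cost_trace, 1)
  tibble::tibble(
    n_waypoints = nrow(x$waypoints), smoothness = x$smoothness,
    iterations = length(x$cost_trace), final_cost = cost,
    converged = x$converged
  )
}

#' @rdname tidy
#' @export
tidy.principal_path <- function(x, ...) {
  W <- rbind(x$endpoints[1, , drop = FALSE], x$waypoints,
             x$endpoints[2, , drop = FALSE])
  out <- tibble::as_tibble(W, .name_repair = ~ paste0("w", seq_along(.x)))
  out$waypoint <- seq_len(nrow(W)) - 1L
  out$fixed <- out$waypoint %in% c(0L, nrow(W) - 1L)
  dplyr::relocate(out, "waypoint", "fixed")
}
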