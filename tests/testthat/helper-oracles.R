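## Shared test helpers: small deterministic fixtures and independent
## brute-force oracles kept deliberately naive.

## a rigid motion: rotation about z by `ang` plus translation
rigid_motion <- function(conf, ang = 0, shift = c(0, 0, 0)) {
  R <- rbind(c(cos(ang), -sin(ang), 0),
             c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  conformation(sweep(conf$coords %*% t(R), 2, shift, "+"),
               conf$atom_labels, conf$frame_id)
}

## deterministic 4-atom asymmetric cloud (nm)
cloud4 <- function() {
  conformation(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.2, 0),
                     c(0.1, 0.1, 0.25)))
}

## exhaustive principal-path oracle: global minimum of the regularized
## k-means cost over ALL membership assignments, with the exact
## tridiagonal waypoint solve per assignment
brute_force_principal_path <- function(cloud, endpoints, n_wp, s) {
  X <- cloud$samples
  n <- nrow(X)
  assigns <- as.matrix(expand.grid(rep(list(seq_len(n_wp)), n)))
  best <- Inf
  for (r in seq_len(nrow(assigns))) {
    u <- as.integer(assigns[r, ])
    W <- pathmetad:::solve_waypoints(X, u, n_wp, endpoints, s)
    cost <- path_cost(list(endpoints = endpoints, waypoints = W,
                           memberships = u, smoothness = s), cloud)
    if (cost < best) best <- as.numeric(cost)
  }
  best
}

## trapezoid rule (independent of the package's internal quadrature)
trap <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
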