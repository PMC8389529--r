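## Synthetic-data generators: the three kinds of controlled inputs used
## to exercise the pipeline at desk scale -- noisy point clouds around a
## curved 1-D manifold (path finding), the exactly integrable funnel
## host-guest system (end-to-end free energy recovery), and dG-versus-
## divider curves with known inflection structure.

#' Noisy arc point cloud
#'
#' `n` points spread along a quarter circle of given radius from
#' `(radius, 0)` to `(0, radius)` with isotropic Gaussian noise: a curved
#' 1-D manifold whose principal path is known by construction.
#'
#' @param n Number of samples.
#' @param noise Gaussian noise standard deviation (same units as
#'   `radius`).
#' @param radius Arc radius (default 1).
#' @param seed Optional integer seed.
#' @return List: `cloud` (a [points_cloud()]), `endpoints` (2 x 2 matrix,
#'   the exact arc ends), `arc` (function mapping arc parameter in [0, 1]
#'   to exact arc points).
#' @export
fixture_arc_cloud <- function(n = 100, noise = 0.05, radius = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- stats::runif(n)
  ang <- t * pi / 2
  pts <- radius * cbind(cos(ang), sin(ang)) +
    matrix(stats::rnorm(2 * n, sd = noise), n, 2)
  order_t <- order(t)
  list(cloud = points_cloud(pts[order_t, , drop = FALSE]),
       endpoints = radius * rbind(c(1, 0), c(0, 1)),
       arc = function(u) radius * cbind(cos(u * pi / 2), sin(u * pi / 2)))
}

#' Exact free energy profile of the funnel system
#'
#' The transverse coordinate integrates analytically
#' (\eqn{\int e^{-k_y y^2 / 2kT} dy = \sqrt{2\pi kT/k_y}}), giving the
#' exact profile
#' \eqn{F(x) = V(x) - \tfrac{kT}{2}\log\!\big(2\pi kT / k_y(x)\big)}
#' up to a constant.
#'
#' @param system A [toy_funnel()] system.
#' @param x Positions at which to evaluate (nm).
#' @return Tibble with `x` and `F` (kcal/mol, gauged to minimum zero).
#' @export
funnel_exact_profile <- function(system, x) {
  kt <- kT(system$temperature)
  F <- system$vx(x) - 0.5 * kt * log(2 * pi * kt / system$ky(x))
  tibble::tibble(x = x, F = F - min(F))
}

#' Exact bound/unbound free energy difference of the funnel system
#'
#' Semi-analytic quadrature: the transverse Gaussian integral is taken in
#' closed form and the longitudinal integral
#' \eqn{\int e^{-V(x)/kT}\sqrt{2\pi kT/k_y(x)}\,dx} is evaluated
#' adaptively on each side of the divider.
#'
#' @param system A [toy_funnel()] system.
#' @param x_star Dividing position (nm; default the barrier position).
#' @param pad How far beyond the confining walls to integrate (nm).
#' @return \eqn{\Delta G_b = -kT\log(Q_\mathrm{site}/Q_\mathrm{bulk})} in
#'   kcal/mol.
#' @export
funnel_exact_dg <- function(system, x_star = NULL, pad = 0.3) {
  kt <- kT(system$temperature)
  x_star <- x_star %||% system$params[4]
  integrand <- function(x)
    exp(-system$vx(x) / kt) * sqrt(2 * pi * kt / system$ky(x))
  lo <- system$domain[1] - pad
  hi <- system$domain[2] + pad
  q_site <- stats::integrate(integrand, lo, x_star, rel.tol = 1e-9)$value
  q_bulk <- stats::integrate(integrand, x_star, hi, rel.tol = 1e-9)$value
  -kt * log(q_site / q_bulk)
}

#' Funnel host-guest fixture
#'
#' Bundles the funnel system with its reference unbinding path (points on
#' the channel axis at the given spacing, so the automatic lambda equals
#' 2.3/spacing^2), a sample cloud drawn along the channel for path
#' finding, and the exact dividing position and free energy difference.
#'
#' @param spacing Reference-path spacing (nm, default 0.1 -- the uniform
#'   interframe target, giving lambda = 230 nm^-2).
#' @param n_samples Size of the sample cloud for path finding.
#' @param cloud_noise Transverse noise of the sample cloud (nm).
#' @param seed Optional integer seed.
#' @param ... Passed to [toy_funnel()].
#' @return List: `system`, `refs` (P x 2 matrix on the channel axis),
#'   `cloud` (a [points_cloud()]), `endpoints`, `x_star_exact`,
#'   `dg_exact` (kcal/mol).
#' @export
fixture_funnel <- function(spacing = 0.1, n_samples = 120,
                           cloud_noise = 0.04, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  system <- toy_funnel(...)
  x_lo <- 0
  x_hi <- system$domain[2] - 0.1
  xs <- seq(x_lo, x_hi, by = spacing)
  refs <- cbind(xs, 0)
  t <- stats::runif(n_samples)
  pts <- cbind(x_lo + t * (x_hi - x_lo), 0) +
    matrix(stats::rnorm(2 * n_samples, sd = cloud_noise), n_samples, 2)
  ord <- order(t)
  list(system = system,
       refs = unname(refs),
       cloud = points_cloud(pts[ord, , drop = FALSE]),
       endpoints = rbind(c(x_lo, 0), c(x_hi, 0)),
       x_star_exact = system$params[4],
       dg_exact = funnel_exact_dg(system))
}

#' Synthetic dG-versus-divider curves with known inflection structure
#'
#' @param kind `"logistic"` (inflection exactly at `s0`), `"two_plateau"`
#'   (one sharp step of width `width` centred at `s0` between two flat
#'   plateaus) or `"linear"` (no inflection at all).
#' @param n Number of samples on [0, 1].
#' @param s0 Step / inflection centre.
#' @param amplitude Curve amplitude (kcal/mol).
#' @param rate Logistic rate.
#' @param width Step width for `"two_plateau"`.
#' @param pmf_barrier If `TRUE`, the accompanying profile has a local
#'   maximum at `s0`; if `FALSE` it is featureless (monotone).
#' @return List: `curve` (a `"dg_curve"` tibble), `pmf` (tibble `s`,
#'   `pmf`), `s0`.
#' @export
fixture_dg_curve <- function(kind = c("logistic", "two_plateau", "linear"),
                             n = 201, s0 = 0.4, amplitude = 5, rate = 25,
                             width = 0.04, pmf_barrier = TRUE) {
  kind <- match.arg(kind)
  s <- seq(0.01, 0.99, length.out = n)
  dg <- switch(kind,
    logistic = -amplitude + amplitude / (1 + exp(-rate * (s - s0))),
    two_plateau = -amplitude + amplitude *
      stats::pnorm((s - s0) / (width / 2)),
    linear = -amplitude + amplitude * s)
  curve <- tibble::tibble(s_star = s, dg_b = dg)
  class(curve) <- c("dg_curve", class(curve))
  pmf <- if (pmf_barrier) {
    tibble::tibble(s = s, pmf = 3 * exp(-(s - s0)^2 / (2 * 0.03^2)))
  } else {
    tibble::tibble(s = s, pmf = 2 * s)
  }
  list(curve = curve, pmf = pmf, s0 = s0)
}

#' Write a fixture to disk
#'
#' File-level interface to the generators, mainly for the command-line
#' workflow: the arc cloud as CSV, the funnel system as a JSON spec plus
#' reference path CSV (with the exact free energy difference recorded),
#' the dG curves as CSV.
#'
#' @param kind `"arc-cloud"`, `"funnel-system"` or `"dg-curve"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for reproducibility.
#' @param ... Passed to the corresponding `fixture_*()` generator.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixture <- function(kind = c("arc-cloud", "funnel-system", "dg-curve"),
                             dir = ".", seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(kind,
    "arc-cloud" = {
      fx <- fixture_arc_cloud(seed = seed, ...)
      f <- file.path(dir, "arc_cloud.csv")
      utils::write.csv(data.frame(x = fx$cloud$samples[, 1],
                                  y = fx$cloud$samples[, 2]),
                       f, row.names = FALSE)
      f
    },
    "funnel-system" = {
      fx <- fixture_funnel(seed = seed, ...)
      f1 <- file.path(dir, "funnel_system.json")
      jsonlite::write_json(
        list(params = fx$system$params, temperature = fx$system$temperature,
             mass = fx$system$mass, x_star_exact = fx$x_star_exact,
             dg_exact = fx$dg_exact),
        f1, auto_unbox = TRUE, digits = NA)
      f2 <- file.path(dir, "funnel_refs.csv")
      utils::write.csv(data.frame(x = fx$refs[, 1], y = fx$refs[, 2]),
                       f2, row.names = FALSE)
      c(f1, f2)
    },
    "dg-curve" = {
      fx <- fixture_dg_curve(...)
      f <- file.path(dir, "dg_curve.csv")
      utils::write.csv(
        data.frame(s_star = fx$curve$s_star, dg_b = fx$curve$dg_b,
                   pmf = fx$pmf$pmf),
        f, row.names = FALSE)
      f
    })
  invisible(files)
}
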