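## Well-tempered metadynamics on (S, Z) with an upper wall on Z, driven
## by underdamped Langevin dynamics on built-in toy systems whose free
## energies are exactly integrable. The inner loop is compiled (see
## src/metad_engine.cpp); hills bookkeeping, tempering and all analysis
## stay in R.

#' Well-tempered metadynamics parameters
#'
#' Defaults follow the production setup of the reference workflow:
#' Gaussians of nominal height 0.2 kcal/mol, bias factor 15, widths 0.2
#' (raw S units) and 0.01 nm^2 (Z), deposition every 500 steps, and an
#' upper wall on Z at 0.05 nm^2. The wall constant is not part of that
#' setup and defaults to 2000 kcal/mol/nm^4.
#'
#' @param height Initial Gaussian height omega_0 (kcal/mol).
#' @param bias_factor Tempering factor gamma (> 1).
#' @param sigma_s Gaussian width along S (raw frame-index units, or nm for
#'   an identity CV).
#' @param sigma_z Gaussian width along Z (nm^2).
#' @param pace Deposition stride in MD steps.
#' @param wall_z Upper wall position on Z (nm^2).
#' @param wall_k One-sided harmonic wall constant (kcal/mol/nm^4).
#' @return A list of class `"wtmetad_params"`.
#' @export
wtmetad_params <- function(height = 0.2, bias_factor = 15, sigma_s = 0.2,
                           sigma_z = 0.01, pace = 500L, wall_z = 0.05,
                           wall_k = 2000) {
  stopifnot(height > 0, bias_factor > 1, sigma_s > 0, sigma_z > 0,
            pace >= 1, wall_z > 0, wall_k >= 0)
  structure(list(height = height, bias_factor = bias_factor,
                 sigma_s = sigma_s, sigma_z = sigma_z, pace = as.integer(pace),
                 wall_z = wall_z, wall_k = wall_k),
            class = "wtmetad_params")
}

#' Toy double-well system (1-D)
#'
#' \eqn{U(x) = h\,((x/w)^2 - 1)^2}: minima at x = -w and x = +w, barrier
#' of height `h` at x = 0. Self-confining; the coordinate itself serves as
#' the collective variable.
#'
#' @param barrier Barrier height h (kcal/mol).
#' @param half_sep Half well separation w (nm).
#' @param temperature Temperature (K).
#' @param mass Particle mass (amu).
#' @return A `"toy_system"`: potential/gradient closures plus the coded
#'   parameters consumed by the compiled engine.
#' @export
toy_double_well <- function(barrier = 3, half_sep = 0.5,
                            temperature = 300, mass = 40) {
  h <- barrier; w <- half_sep
  structure(list(
    dimension = 1L,
    potential = function(x) h * ((x[1] / w)^2 - 1)^2,
    gradient = function(x) 4 * h * x[1] * ((x[1] / w)^2 - 1) / w^2,
    temperature = temperature, mass = mass,
    domain = c(-2 * w, 2 * w),
    code = 1L, params = c(h, w),
    x0 = -w
  ), class = "toy_system")
}

#' Toy funnel host-guest system (2-D)
#'
#' A deep bound well at the origin connected through a barrier to a flat
#' solvated plateau, with a transverse harmonic channel whose stiffness
#' relaxes from `ky_bound` to `ky_bulk` past the barrier (the "funnel").
#' \deqn{U(x, y) = -D e^{-x^2/2\sigma_b^2} + B e^{-(x-x_b)^2/2\sigma_t^2}
#'   + \tfrac12 k_y(x)\, y^2 + \mathrm{walls}(x)}
#' The transverse integral is Gaussian, so the free energy profile along
#' x and the bound/unbound free energy difference are exactly integrable
#' (see [funnel_exact_profile()] and [funnel_exact_dg()]).
#'
#' @param depth Bound-well depth D (kcal/mol).
#' @param sigma_bound Bound-well width (nm).
#' @param barrier Barrier height B (kcal/mol) at `x_barrier`.
#' @param x_barrier Barrier position (nm).
#' @param sigma_barrier Barrier width (nm).
#' @param ky_bound,ky_bulk Transverse stiffness in the bound region and in
#'   the bulk (kcal/mol/nm^2).
#' @param x_switch,switch_width Centre and width of the stiffness switch.
#' @param x_min,x_max Confining wall positions along x (nm).
#' @param k_wall Harmonic wall constant (kcal/mol/nm^2).
#' @param temperature Temperature (K).
#' @param mass Particle mass (amu).
#' @return A `"toy_system"`.
#' @export
toy_funnel <- function(depth = 5, sigma_bound = 0.15, barrier = 1.2,
                       x_barrier = 0.5, sigma_barrier = 0.08,
                       ky_bound = 60, ky_bulk = 40, x_switch = 0.5,
                       switch_width = 0.1, x_min = -0.3, x_max = 1.9,
                       k_wall = 200, temperature = 300, mass = 40) {
  p <- c(depth, sigma_bound, barrier, x_barrier, sigma_barrier,
         ky_bound, ky_bulk, x_switch, switch_width, x_min, x_max, k_wall)
  ky <- function(x) ky_bulk + (ky_bound - ky_bulk) / (1 + exp((x - x_switch) / switch_width))
  vx <- function(x) {
    -depth * exp(-x^2 / (2 * sigma_bound^2)) +
      barrier * exp(-(x - x_barrier)^2 / (2 * sigma_barrier^2)) +
      k_wall * pmax(x - x_max, 0)^2 + k_wall * pmax(x_min - x, 0)^2
  }
  structure(list(
    dimension = 2L,
    potential = function(x) vx(x[1]) + 0.5 * ky(x[1]) * x[2]^2,
    gradient = function(x) {
      e <- exp((x[1] - x_switch) / switch_width)
      dky <- -(ky_bound - ky_bulk) * e / (switch_width * (1 + e)^2)
      dvx <- depth * x[1] / sigma_bound^2 * exp(-x[1]^2 / (2 * sigma_bound^2)) -
        barrier * (x[1] - x_barrier) / sigma_barrier^2 *
          exp(-(x[1] - x_barrier)^2 / (2 * sigma_barrier^2)) +
        2 * k_wall * pmax(x[1] - x_max, 0) - 2 * k_wall * pmax(x_min - x[1], 0)
      c(dvx + 0.5 * dky * x[2]^2, ky(x[1]) * x[2])
    },
    vx = vx, ky = ky,
    temperature = temperature, mass = mass,
    domain = c(x_min, x_max),
    code = 2L, params = p,
    x0 = c(0, 0)
  ), class = "toy_system")
}

#' Metadynamics bias potential from a hills ledger
#'
#' Sum of anisotropic Gaussians. One-dimensional ledgers (no `z` column,
#' or all-`NA` `z`) are supported for identity-CV runs.
#'
#' @param point Named list or vector with `s` and optionally `z`.
#' @param hills Hills tibble with columns `s`, `sigma_s`, `height` and
#'   optionally `z`, `sigma_z`.
#' @return Bias energy (kcal/mol).
#' @export
bias_energy <- function(point, hills) {
  if (nrow(hills) == 0L) return(0)
  s <- if (is.list(point)) point$s else point[["s"]]
  e <- (s - hills$s)^2 / (2 * hills$sigma_s^2)
  if (!is.null(hills$z) && !all(is.na(hills$z))) {
    z <- if (is.list(point)) point$z else point[["z"]]
    e <- e + (z - hills$z)^2 / (2 * hills$sigma_z^2)
  }
  sum(hills$height * exp(-e))
}

#' Metadynamics bias force (negative gradient) in CV space
#'
#' @inheritParams bias_energy
#' @return Named vector with components `s` and (for 2-D ledgers) `z`.
#' @export
bias_force <- function(point, hills) {
  if (nrow(hills) == 0L) return(c(s = 0, z = 0))
  s <- if (is.list(point)) point$s else point[["s"]]
  es <- (s - hills$s)^2 / (2 * hills$sigma_s^2)
  two_d <- !is.null(hills$z) && !all(is.na(hills$z))
  if (two_d) {
    z <- if (is.list(point)) point$z else point[["z"]]
    g <- hills$height * exp(-es - (z - hills$z)^2 / (2 * hills$sigma_z^2))
    c(s = sum(g * (s - hills$s) / hills$sigma_s^2),
      z = sum(g * (z - hills$z) / hills$sigma_z^2))
  } else {
    g <- hills$height * exp(-es)
    c(s = sum(g * (s - hills$s) / hills$sigma_s^2))
  }
}

#' Well-tempered height of the next Gaussian
#'
#' \eqn{\omega = \omega_0 \exp(-V/((\gamma - 1) k T))} with `V` the bias
#' already accumulated at the deposition point.
#'
#' @param height0 Nominal height omega_0 (kcal/mol).
#' @param bias_factor Tempering factor gamma (> 1).
#' @param bias Current bias at the point (kcal/mol).
#' @param temperature Temperature (K).
#' @return Height in kcal/mol, in (0, omega_0].
#' @export
next_height <- function(height0, bias_factor, bias, temperature = 300) {
  if (bias_factor <= 1) stop("bias factor must exceed 1")
  height0 * exp(-bias / ((bias_factor - 1) * kT(temperature)))
}

#' One Langevin step (BAOAB splitting)
#'
#' Reference R implementation of the symmetric splitting integrator for
#' underdamped Langevin dynamics; the production loop uses the identical
#' compiled scheme. Deterministic given the R RNG state.
#'
#' @param state List with numeric `x` (nm) and `v` (nm/ps).
#' @param system A `"toy_system"`.
#' @param bias_gradient Optional function `x -> dV/dx` (kcal/mol/nm) for
#'   an external bias; `NULL` for none.
#' @param dt Time step (ps).
#' @param friction Friction coefficient (ps^-1).
#' @return Updated `state` (with `force` attribute in kcal/mol/nm).
#' @export
langevin_step <- function(state, system, bias_gradient = NULL,
                          dt = 0.002, friction = 10) {
  if (dt <= 0) stop("dt must be positive")
  m <- system$mass
  kTkj <- kT(system$temperature) * .KCAL2KJ
  grad <- function(x) {
    g <- system$gradient(x)
    if (!is.null(bias_gradient)) g <- g + bias_gradient(x)
    if (!all(is.finite(g))) stop("non-finite force")
    g
  }
  f <- -grad(state$x) * .KCAL2KJ          # kJ/mol/nm
  v <- state$v + 0.5 * dt * f / m
  x <- state$x + 0.5 * dt * v
  c1 <- exp(-friction * dt)
  c2 <- sqrt((1 - c1^2) * kTkj / m)
  v <- c1 * v + c2 * stats::rnorm(length(v))
  x <- x + 0.5 * dt * v
  f <- -grad(x) * .KCAL2KJ
  v <- v + 0.5 * dt * f / m
  list(x = x, v = v)
}

#' Run well-tempered metadynamics on a toy system
#'
#' Langevin dynamics with hills deposited every `pace` steps at the
#' current CV point, heights tempered by [next_height()], and a one-sided
#' harmonic wall on Z above `wall_z` (path CV only). The CV is either the
#' first coordinate itself (`cv = "identity"`) or a toy-mode
#' [pcv_definition()], in which case raw S (frame-index units) is biased
#' and Z feels the wall. The compiled loop keeps the bias and its gradient
#' tabulated on a fine CV grid, refreshed at every deposition.
#'
#' @param system A `"toy_system"`.
#' @param cv `"identity"` or a toy-mode [pcv_definition()].
#' @param params A [wtmetad_params()].
#' @param n_steps Number of MD steps.
#' @param dt Time step (ps).
#' @param friction Langevin friction (ps^-1).
#' @param seed Integer seed (one pseudo-random stream per run).
#' @param x0 Starting coordinates (defaults to the system's bound state).
#' @param colvar_stride CV series sampling stride in steps.
#' @return List of class `"wtmetad_run"`: `hills` tibble (`time`, `s`,
#'   `z`, `sigma_s`, `sigma_z`, `height`, `biasf`), `colvar` tibble
#'   (`time`, `s`, `z`, `bias`), plus `params`, `cv`, `system`.
#' @examples
#' \donttest{
#' sys <- toy_double_well()
#' run <- run_wtmetad(sys, "identity",
#'                    wtmetad_params(sigma_s = 0.05, pace = 250),
#'                    n_steps = 5e4, seed = 1)
#' nrow(run$hills)
#' }
#' @export
run_wtmetad <- function(system, cv = "identity", params = wtmetad_params(),
                        n_steps, dt = 0.002, friction = 10, seed = NULL,
                        x0 = NULL, colvar_stride = 100L) {
  stopifnot(inherits(system, "toy_system"), inherits(params, "wtmetad_params"))
  if (!is.null(seed)) set.seed(seed)
  identity_cv <- identical(cv, "identity")
  if (!identity_cv && !(inherits(cv, "pcv_definition") && isTRUE(cv$toy)))
    stop("cv must be \"identity\" or a toy-mode pcv_definition")
  x0 <- x0 %||% system$x0
  if (identity_cv) {
    refs <- matrix(0, 1, 1); lambda <- 1
    grid_s <- c(system$domain[1] - 0.2, system$domain[2] + 0.2)
    grid_z <- c(0, 0); nz <- 1L
  } else {
    refs <- cv$frames; lambda <- cv$lambda
    grid_s <- c(0.5, cv$P + 0.5)
    zmin <- -log(cv$P) / lambda - 3 * params$sigma_z
    grid_z <- c(zmin, params$wall_z + 6 * params$sigma_z)
    nz <- max(16L, ceiling(diff(grid_z) / (params$sigma_z / 4)))
  }
  ns <- max(32L, ceiling(diff(grid_s) / (params$sigma_s / 4)))
  out <- run_wtmetad_cpp(
    system$code, system$params, system$temperature, system$mass,
    if (identity_cv) 0L else 1L, refs, lambda,
    params$height, params$bias_factor, params$sigma_s, params$sigma_z,
    params$pace, params$wall_z, params$wall_k,
    as.integer(n_steps), dt, friction, as.numeric(x0),
    as.integer(colvar_stride),
    grid_s[1], grid_s[2], as.integer(ns), grid_z[1], grid_z[2], nz)
  hills <- tibble::as_tibble(out$hills)
  colvar <- tibble::as_tibble(out$colvar)
  if (identity_cv) {
    hills$z <- NA_real_; hills$sigma_z <- NA_real_
    colvar$z <- NA_real_
  }
  structure(list(hills = hills, colvar = colvar, params = params,
                 cv = cv, system = system),
            class = "wtmetad_run")
}

#' @export
print.wtmetad_run <- function(x, ...) {
  cat(sprintf(
    "<wtmetad_run> %d hills, %d CV samples, final height %.4g kcal/mol\n",
    nrow(x$hills), nrow(x$colvar), utils::tail(x$hills$height, 1)))
  invisible(x)
}
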