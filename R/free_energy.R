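## Free energy analysis: reconstruct F(S, Z) from deposited hills,
## integrate it into bound/unbound partition functions, identify the
## dividing frame x*, apply the standard-volume correction and assess
## convergence of the run.

#' Free energy surface from a hills ledger
#'
#' \eqn{F = -\frac{\gamma}{\gamma - 1} \sum_k G_k} evaluated on a regular
#' grid, then gauged so the minimum is exactly zero. Hills deposited in
#' raw S units can be relabelled to the rescaled [0, 1] convention by
#' passing the number of reference frames `rescale_p`.
#'
#' @param hills Hills tibble (`s`, `sigma_s`, `height`, optionally `z`,
#'   `sigma_z`; see [run_wtmetad()] / [read_hills()]).
#' @param bias_factor Tempering factor gamma used in the run (taken from
#'   the ledger's `biasf` column when present).
#' @param s_range,z_range Grid extents. Defaults cover the deposited hills
#'   plus three Gaussian widths.
#' @param n_s,n_z Grid resolution (default 200 x 50).
#' @param rescale_p Number of path frames P: when given, hill centres in
#'   raw S are mapped through `(s - 1)/(P - 1)` so the surface axis is the
#'   rescaled progress in [0, 1].
#' @return Object of class `"fes"`: list with `s`, `z` (axes), `F` (matrix
#'   `n_s` x `n_z`, kcal/mol; a vector for 1-D ledgers), `bias_factor`.
#' @export
fes_from_hills <- function(hills, bias_factor = NULL, s_range = NULL,
                           z_range = NULL, n_s = 200, n_z = 50,
                           rescale_p = NULL) {
  if (nrow(hills) == 0L) stop("empty hills ledger")
  bias_factor <- bias_factor %||%
    (if (!is.null(hills$biasf)) hills$biasf[1] else
      stop("bias_factor not given and no biasf column"))
  pref <- bias_factor / (bias_factor - 1)
  sc <- hills$s
  ss <- hills$sigma_s
  if (!is.null(rescale_p)) {
    sc <- (sc - 1) / (rescale_p - 1)
    ss <- ss / (rescale_p - 1)
  }
  one_d <- is.null(hills$z) || all(is.na(hills$z))
  s_range <- s_range %||%
    (if (!is.null(rescale_p)) c(0, 1)
     else range(sc) + c(-3, 3) * max(ss))
  s <- seq(s_range[1], s_range[2], length.out = n_s)
  if (one_d) {
    Fv <- -pref * vapply(s, function(si)
      sum(hills$height * exp(-(si - sc)^2 / (2 * ss^2))), numeric(1))
    Fv <- Fv - min(Fv)
    return(structure(list(s = s, z = NULL, F = Fv,
                          bias_factor = bias_factor),
                     class = "fes"))
  }
  z_range <- z_range %||% range(hills$z) + c(-3, 3) * max(hills$sigma_z)
  z <- seq(z_range[1], z_range[2], length.out = n_z)
  ## accumulate in chunks of hills: vectorized but bounded memory
  Fm <- matrix(0, n_s, n_z)
  nh <- nrow(hills)
  for (lo in seq(1L, nh, by = 10000L)) {
    hi <- min(lo + 9999L, nh)
    idx <- lo:hi
    Es <- outer(s, sc[idx], function(a, b) (a - b)^2) /
      rep(2 * ss[idx]^2, each = n_s)                 # n_s x chunk
    Ez <- outer(z, hills$z[idx], function(a, b) (a - b)^2) /
      rep(2 * hills$sigma_z[idx]^2, each = n_z)      # n_z x chunk
    Fm <- Fm + exp(-Es) %*% (t(exp(-Ez)) * hills$height[idx])
  }
  Fm <- -pref * Fm
  Fm <- Fm - min(Fm)
  structure(list(s = s, z = z, F = Fm, bias_factor = bias_factor),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  if (is.null(x$z))
    cat(sprintf("<fes> 1-D profile, %d points, max %.3g kcal/mol\n",
                length(x$s), max(x$F)))
  else
    cat(sprintf("<fes> %d x %d grid, max %.3g kcal/mol\n",
                length(x$s), length(x$z), max(x$F)))
  invisible(x)
}

#' Free energy profile along S
#'
#' Marginalizes a 2-D surface over Z:
#' \eqn{F_S(s) = -kT \log \int e^{-F(s,z)/kT} dz}, gauged to zero at its
#' minimum. For 1-D surfaces the profile itself is returned.
#'
#' @param fes A `"fes"` object.
#' @param temperature Temperature (K).
#' @param z_max Restrict the marginalization to `z <= z_max` (default: no
#'   restriction beyond the grid).
#' @return Tibble with columns `s`, `pmf` (kcal/mol).
#' @export
pmf_along_s <- function(fes, temperature = 300, z_max = NULL) {
  if (is.null(fes$z))
    return(tibble::tibble(s = fes$s, pmf = fes$F - min(fes$F)))
  kt <- kT(temperature)
  keep <- if (is.null(z_max)) seq_along(fes$z) else which(fes$z <= z_max)
  B <- exp(-fes$F[, keep, drop = FALSE] / kt)
  q <- apply(B, 1, function(r) trapz_int(fes$z[keep], r))
  pmf <- -kt * log(q)
  tibble::tibble(s = fes$s, pmf = pmf - min(pmf))
}

trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## double trapezoid over the s rows and z columns of matrix M
trapz2 <- function(s, z, M) {
  col_int <- apply(M, 1, function(r) trapz_int(z, r))
  trapz_int(s, col_int)
}

#' Bound/unbound free energy difference from the FES
#'
#' Integrates the Boltzmann weight of the surface on either side of the
#' dividing value `s_star`:
#' \eqn{\Delta G_b = -kT \log(Q_\mathrm{site}/Q_\mathrm{bulk})} with
#' \eqn{Q_\mathrm{site} = \iint_{s < s^*} e^{-F(s,z)/kT}} and the
#' complement for the bulk (trapezoidal quadrature; `z` restricted below
#' the wall via `z_max`).
#'
#' @param fes A `"fes"` object.
#' @param s_star Dividing value of S, strictly inside the grid, or a
#'   `"dividing_frame"` from [find_x_star()].
#' @param temperature Temperature (K).
#' @param z_max Upper integration limit on Z (e.g. the wall position).
#' @return \eqn{\Delta G_b} in kcal/mol (negative favours the bound side).
#' @export
dg_bound_unbound <- function(fes, s_star, temperature = 300, z_max = NULL) {
  if (inherits(s_star, "dividing_frame")) s_star <- s_star$s_star
  kt <- kT(temperature)
  site <- fes$s < s_star
  if (!any(site) || all(site))
    stop("s_star leaves an empty bound or unbound region")
  ## split the straddling grid cell exactly at s_star: both regions get an
  ## interpolated boundary column, so the two integrals tile the grid
  i_lo <- max(which(site))
  frac <- if (i_lo < length(fes$s))
    (s_star - fes$s[i_lo]) / (fes$s[i_lo + 1] - fes$s[i_lo]) else 0
  if (is.null(fes$z)) {
    B <- exp(-fes$F / kt)
    b_star <- if (i_lo < length(fes$s))
      (1 - frac) * B[i_lo] + frac * B[i_lo + 1] else B[i_lo]
    q_site <- trapz_int(c(fes$s[site], s_star), c(B[site], b_star))
    q_bulk <- trapz_int(c(s_star, fes$s[!site]), c(b_star, B[!site]))
  } else {
    keep <- if (is.null(z_max)) seq_along(fes$z) else which(fes$z <= z_max)
    B <- exp(-fes$F[, keep, drop = FALSE] / kt)
    b_star <- if (i_lo < length(fes$s))
      (1 - frac) * B[i_lo, ] + frac * B[i_lo + 1, ] else B[i_lo, ]
    q_site <- trapz2(c(fes$s[site], s_star), fes$z[keep],
                     rbind(B[site, , drop = FALSE], b_star))
    q_bulk <- trapz2(c(s_star, fes$s[!site]), fes$z[keep],
                     rbind(b_star, B[!site, , drop = FALSE]))
  }
  -kt * log(q_site / q_bulk)
}

#' Binding free energy as a function of the dividing frame
#'
#' Evaluates [dg_bound_unbound()] over a set of candidate dividers,
#' producing the curve whose inflection structure identifies x*.
#'
#' @inheritParams dg_bound_unbound
#' @param s_values Candidate dividing values (>= 10 recommended); default
#'   is the interior of the FES grid.
#' @return Tibble of class `"dg_curve"` with columns `s_star`, `dg_b`.
#' @export
dg_vs_divider_curve <- function(fes, temperature = 300, s_values = NULL,
                                z_max = NULL) {
  s_values <- s_values %||%
    fes$s[fes$s > min(fes$s) & fes$s < max(fes$s)]
  out <- tibble::tibble(
    s_star = s_values,
    dg_b = vapply(s_values, function(sv)
      dg_bound_unbound(fes, sv, temperature, z_max), numeric(1)))
  class(out) <- c("dg_curve", class(out))
  out
}

#' Identify the bound/unbound dividing frame x*
#'
#' Operationalizes the semiautomatic rule set: (1) smooth the
#' \eqn{\Delta G_b(s^*)} curve with a local quadratic (Savitzky-Golay)
#' filter; (2) collect inflection candidates where the second finite
#' difference changes sign; (3) accept the first candidate from the bound
#' side that coincides with a transition-state-like local maximum of the
#' free energy profile within `pmf_window` of the candidate; (4) if no
#' candidate passes, fall back to the midpoint of the two shoulders
#' bracketing the sharpest step (the single-sharp-inflection case between
#' two plateaus). A strictly monotone curve with no inflection raises an
#' error: no divider can be proposed and human intervention is needed.
#' The choice is advisory; callers may override with
#' `dividing_frame(s_star, method = "manual")`.
#'
#' @param curve A `"dg_curve"` tibble (columns `s_star`, `dg_b`).
#' @param pmf Free energy profile along s, as returned by
#'   [pmf_along_s()] (columns `s`, `pmf`); optional but required for the
#'   transition-state cross-check.
#' @param smooth_frac Savitzky-Golay window as a fraction of the curve
#'   length (default 0.05).
#' @param pmf_window Half-width in s within which a pmf local maximum
#'   validates a candidate (default 0.05).
#' @param pmf_prominence Minimum prominence (kcal/mol) for a pmf local
#'   maximum to count as transition-state-like (default 0.5); filters the
#'   kT-scale ripple of a reconstructed profile.
#' @return Object of class `"dividing_frame"`: `s_star`, `frame_index`
#'   (index into the curve grid), `method` (`"first-inflection"` or
#'   `"midpoint-fallback"`).
#' @export
find_x_star <- function(curve, pmf = NULL, smooth_frac = 0.05,
                        pmf_window = 0.05, pmf_prominence = 0.5) {
  s <- curve$s_star
  y <- curve$dg_b
  n <- length(s)
  if (n < 10) stop("curve must be sampled at >= 10 candidates")
  win <- max(5L, 2L * floor(smooth_frac * n / 2) + 1L)  # odd, >= 5
  if (win >= n) win <- if (n %% 2L) n - 2L else n - 1L
  ys <- signal::sgolayfilt(y, p = 2, n = win)
  d2 <- diff(ys, differences = 2)
  ## curvature below numerical noise (flat plateaus, linear stretches)
  ## must not spawn inflection candidates
  d2[abs(d2) < 1e-7 * max(diff(range(y)), .Machine$double.eps)] <- 0
  nz <- which(d2 != 0)
  sgn <- sign(d2[nz])
  flip_at <- nz[which(sgn[-1] * sgn[-length(sgn)] < 0) + 1L]  # index into d2
  cand <- flip_at + 1L                                        # index into s
  if (length(cand) == 0L)
    stop("no inflection point found on the dG_b curve; ",
         "human intervention is needed to place the divider")

  if (!is.null(pmf)) {
    lm_s <- pmf$s[prominent_maxima(pmf$pmf, pmf_prominence)]
    for (ci in cand) {
      if (any(abs(lm_s - s[ci]) <= pmf_window)) {
        return(dividing_frame(s[ci], ci, "first-inflection"))
      }
    }
  }
  ## midpoint fallback: shoulders of the sharpest step around the first
  ## candidate -- the nearest points left and right where the slope decays
  ## to 10% of its value at the step
  dy <- abs(diff(ys))
  ci <- cand[1]
  step_slope <- dy[min(ci, length(dy))]
  thr <- 0.1 * step_slope
  left <- ci
  while (left > 1L && dy[max(left - 1L, 1L)] > thr) left <- left - 1L
  right <- ci
  while (right < n && dy[min(right, length(dy))] > thr) right <- right + 1L
  s_star <- (s[left] + s[right]) / 2
  dividing_frame(s_star, which.min(abs(s - s_star)), "midpoint-fallback")
}

## indices of local maxima with prominence >= prom: the peak must drop by
## at least prom on both sides before a higher value is reached
prominent_maxima <- function(v, prom) {
  k <- length(v)
  if (k < 3) return(integer(0))
  lm <- which(c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] &
                  v[2:(k - 1)] >= v[3:k], FALSE))
  keep <- vapply(lm, function(i) {
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > v[i])
    drop_l <- v[i] - min(left[seq(max(higher_l, 1), i - 1)], v[i - 1])
    right <- v[seq(i + 1, k)]
    higher_r <- which(right > v[i])
    lim_r <- if (length(higher_r)) min(higher_r) else length(right)
    drop_r <- v[i] - min(right[seq_len(lim_r)])
    min(drop_l, drop_r) >= prom
  }, logical(1))
  lm[keep]
}

#' Construct a dividing frame
#'
#' @param s_star Dividing value of rescaled S, strictly in (0, 1).
#' @param frame_index Index of the corresponding path frame or curve
#'   sample.
#' @param method `"first-inflection"`, `"midpoint-fallback"` or
#'   `"manual"`.
#' @return Object of class `"dividing_frame"`.
#' @export
dividing_frame <- function(s_star, frame_index = NA_integer_,
                           method = c("manual", "first-inflection",
                                      "midpoint-fallback")) {
  method <- match.arg(method)
  if (!(s_star > 0 && s_star < 1))
    stop("s_star must lie strictly inside (0, 1)")
  structure(list(s_star = s_star, frame_index = as.integer(frame_index),
                 method = method),
            class = "dividing_frame")
}

#' @export
print.dividing_frame <- function(x, ...) {
  cat(sprintf("<dividing_frame> s* = %.4f (%s)\n", x$s_star, x$method))
  invisible(x)
}

#' Standard-volume correction
#'
#' \eqn{\Delta G_V = -kT \log(V_\mathrm{bulk}/V^\circ)}: the free energy
#' of changing the unbound ligand from the sampled bulk volume to the
#' standard-state volume of 1661 cubic Angstrom (1 M). Positive when the
#' sampled bulk is smaller than the standard volume.
#'
#' @param v_bulk Sampled unbound volume (A^3), e.g. from [ses_volume()].
#' @param temperature Temperature (K).
#' @return Energy in kcal/mol.
#' @examples
#' volume_correction(1661)   # 0
#' volume_correction(3322)   # -0.41 kcal/mol
#' @export
volume_correction <- function(v_bulk, temperature = 300) {
  if (!is.numeric(v_bulk) || v_bulk <= 0) stop("v_bulk must be positive")
  -kT(temperature) * log(v_bulk / standard_volume(exact = FALSE))
}

#' Converged time window of a metadynamics run
#'
#' Finds the earliest time after which (a) the residual hill height stays
#' below `height_fraction` of the nominal height and (b) S is fully
#' diffusive: within every sliding sub-window of width `window_width` the
#' sampled S spans at least `span_fraction` of the full S range. Because
#' tempered heights scale with the local free energy, the deposited
#' heights at any instant form a band spanning a factor
#' \eqn{e^{(1-1/\gamma)\Delta F/((\gamma-1)kT)}}; the residual height is
#' therefore measured as a running quantile of the heights in consecutive
#' time bins (`height_quantile`, default 0.9) rather than a strict
#' maximum. Returns a failure flag rather than erroring when no window
#' exists.
#'
#' @param hills Hills tibble.
#' @param colvar Colvar tibble (rescaled or raw S; the span criterion is
#'   relative to the run's own S range).
#' @param height_fraction Residual-height threshold as a fraction of the
#'   nominal height (default 0.1).
#' @param span_fraction Required fractional S span per sub-window
#'   (default 0.9).
#' @param window_width Sliding window width in time units (default: a
#'   fifth of the span after the height criterion is first met).
#' @param height0 Nominal hill height (default: maximum deposited).
#' @param height_quantile Quantile of per-bin heights compared against
#'   the threshold (1 reproduces a strict per-bin maximum).
#' @param n_bins Number of time bins for the height criterion.
#' @return List with `t_start`, `t_end`, `converged`, `t_height` (when the
#'   height criterion is first met) and `diagnostics` (per-window spans).
#' @export
convergence_window <- function(hills, colvar, height_fraction = 0.1,
                               span_fraction = 0.9, window_width = NULL,
                               height0 = NULL, height_quantile = 0.9,
                               n_bins = 40) {
  stopifnot(nrow(colvar) > 0)
  t_end <- max(colvar$time)
  height0 <- height0 %||% max(hills$height)
  thr <- height_fraction * height0
  bins <- cut(hills$time, breaks = seq(min(hills$time), max(hills$time),
                                       length.out = n_bins + 1),
              include.lowest = TRUE)
  qh <- tapply(hills$height, bins, stats::quantile,
               probs = height_quantile, names = FALSE)
  bin_start <- seq(min(hills$time), max(hills$time),
                   length.out = n_bins + 1)[-(n_bins + 1)]
  ok_h <- !is.na(qh) & qh < thr
  ## earliest bin from which every later bin passes
  good <- which(rev(cumprod(rev(ok_h))) == 1)
  t_height <- if (length(good)) bin_start[good[1]] else NA_real_
  fail <- list(t_start = NA_real_, t_end = t_end, converged = FALSE,
               t_height = t_height, diagnostics = NULL)
  if (is.na(t_height) || t_height >= t_end) return(fail)
  window_width <- window_width %||% ((t_end - t_height) / 5)
  s_all <- range(colvar$s)
  need <- span_fraction * diff(s_all)
  starts <- seq(t_height, t_end - window_width, length.out = 25)
  spans <- vapply(starts, function(t0) {
    sel <- colvar$time >= t0 & colvar$time <= t0 + window_width
    if (sum(sel) < 2) return(0)
    diff(range(colvar$s[sel]))
  }, numeric(1))
  diagnostics <- tibble::tibble(window_start = starts, s_span = spans)
  ok <- spans >= need
  ## earliest start from which every later window passes
  good_from <- which(rev(cumprod(rev(ok))) == 1)
  if (length(good_from) == 0L) {
    fail$diagnostics <- diagnostics
    return(fail)
  }
  list(t_start = starts[good_from[1]], t_end = t_end, converged = TRUE,
       t_height = t_height, diagnostics = diagnostics)
}

#' Time-average statistics of a binding free energy series
#'
#' @param dg Numeric vector of binding free energy values evaluated at
#'   successive times inside the converged window.
#' @return Tibble with `mean`, `stderr` (sd/sqrt(n)) and `n`.
#' @export
dg_time_stats <- function(dg) {
  if (length(dg) < 2) stop("need at least 2 points in the window")
  tibble::tibble(mean = mean(dg),
                 stderr = stats::sd(dg) / sqrt(length(dg)),
                 n = length(dg))
}
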