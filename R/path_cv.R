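## Path collective variables: progress along a reference path S(x) and
## distance from it Z(x), defined through softmin-weighted squared-RMSD
## distances to an ordered set of reference frames.
##
## Conventions: the distance metric is the squared RMSD (mean, not sum,
## of squared deviations) in nm^2, so lambda carries nm^-2 and Z is in
## nm^2 -- consistent with a lambda of 230 nm^-2 at 0.1 nm spacing and a
## Z wall at 0.05 nm^2. Raw S runs over frame indices 1..P; the rescaled
## convention maps it to [0, 1] with 0 the bound and 1 the unbound state.

#' Path CV definition
#'
#' Holds the ordered reference frames, the smoothness parameter lambda and
#' the atom selections. Reference frames may be [conformation()] objects
#' (distances use superposition on the align atoms) or a plain P x d
#' matrix of feature vectors ("toy mode": plain squared Euclidean
#' distances, no superposition, exact gradients).
#'
#' @param frames List of [conformation()]s, or a numeric P x d matrix of
#'   reference points (one row per frame).
#' @param lambda Inverse squared length (nm^-2), or `NULL`/`"AUTO"` to set
#'   it from the mean squared interframe distance via
#'   [lambda_from_spacing()].
#' @param align,measure Atom selections for conformational references.
#' @param rescaled If `TRUE` (default) S is reported in [0, 1].
#' @return An object of class `"pcv_definition"`.
#' @examples
#' refs <- matrix(seq(0, 1.8, by = 0.1), ncol = 1)
#' defn <- pcv_definition(refs)   # lambda AUTO -> 230 nm^-2
#' defn$lambda
#' @export
pcv_definition <- function(frames, lambda = NULL, align = NULL,
                           measure = NULL, rescaled = TRUE) {
  toy <- is.matrix(frames)
  P <- if (toy) nrow(frames) else length(frames)
  if (P < 2L) stop("need at least 2 reference frames")
  gaps2 <- pcv_ref_gaps2(frames, align, measure)
  if (max(gaps2) / max(min(gaps2), .Machine$double.eps) > 4)
    warning("consecutive reference-frame RMSDs vary by more than a factor 2; ",
            "S(x) may progress unevenly")
  if (is.null(lambda) || identical(lambda, "AUTO"))
    lambda <- lambda_from_spacing(mean(gaps2))
  if (lambda <= 0) stop("lambda must be positive")
  structure(
    list(frames = frames, lambda = lambda, align = align,
         measure = measure, rescaled = rescaled, P = P, toy = toy),
    class = "pcv_definition")
}

#' Pad a reference path beyond its physical ends
#'
#' Path collective variables behave poorly when sampled density piles up
#' against the first or last reference frame: the softmin sum is one-sided
#' there and metadynamics hills centred at the boundary lose half their
#' mass outside the reachable range, which systematically over-deepens
#' boundary basins. The standard remedy is to extend the path by a few
#' linearly extrapolated frames at each end, moving both path ends into
#' unsampled territory.
#'
#' @param refs P x d matrix of reference points (toy mode), or a list of
#'   [conformation()]s (coordinates extrapolated linearly).
#' @param n Number of frames to add at each end (default 2).
#' @return Padded references of the same kind, length P + 2n.
#' @export
pad_path_refs <- function(refs, n = 2) {
  if (n == 0) return(refs)
  if (is.matrix(refs)) {
    d1 <- refs[1, ] - refs[2, ]
    d2 <- refs[nrow(refs), ] - refs[nrow(refs) - 1, ]
    pre <- t(vapply(n:1, function(k) refs[1, ] + k * d1, refs[1, ]))
    post <- t(vapply(seq_len(n), function(k) refs[nrow(refs), ] + k * d2,
                     refs[1, ]))
    rbind(pre, refs, post)
  } else {
    P <- length(refs)
    d1 <- refs[[1]]$coords - refs[[2]]$coords
    d2 <- refs[[P]]$coords - refs[[P - 1]]$coords
    pre <- lapply(n:1, function(k)
      conformation(refs[[1]]$coords + k * d1, refs[[1]]$atom_labels))
    post <- lapply(seq_len(n), function(k)
      conformation(refs[[P]]$coords + k * d2, refs[[P]]$atom_labels))
    c(pre, refs, post)
  }
}

## squared interframe distances of the reference path (nm^2)
pcv_ref_gaps2 <- function(frames, align = NULL, measure = NULL) {
  if (is.matrix(frames)) {
    rowSums(diff(frames)^2)
  } else {
    interframe_distances(frames, align, measure)^2
  }
}

#' Lambda heuristic from the interframe spacing
#'
#' Sets the path-smoothness parameter from a quantity available before any
#' biased run: `lambda = 2.3 / <d^2>` with `<d^2>` the mean squared
#' interframe distance. At the 0.1 nm spacing target (`<d^2>` = 0.01 nm^2)
#' this gives 230.0 nm^-2.
#'
#' @param mean_squared_interframe_distance Mean squared spacing (nm^2).
#' @return lambda in nm^-2.
#' @examples
#' lambda_from_spacing(0.01)   # 230
#' @export
lambda_from_spacing <- function(mean_squared_interframe_distance) {
  if (!is.numeric(mean_squared_interframe_distance) ||
      mean_squared_interframe_distance <= 0)
    stop("mean squared interframe distance must be positive")
  2.3 / mean_squared_interframe_distance
}

## squared distances (nm^2) from configuration x to every reference frame
pcv_distances2 <- function(x, defn) {
  if (defn$toy) {
    v <- if (inherits(x, "conformation")) as.numeric(t(x$coords)) else as.numeric(x)
    rowSums(sweep(defn$frames, 2, v)^2)
  } else {
    vapply(defn$frames, function(f)
      conf_rmsd(x, f, align = defn$align, measure = defn$measure)^2,
      numeric(1))
  }
}

#' Evaluate the path collective variables
#'
#' \eqn{S(x)} is the softmin-weighted average frame index,
#' \eqn{\sum_i i\,e^{-\lambda d_i^2} / \sum_i e^{-\lambda d_i^2}}, rescaled
#' to [0, 1] as \eqn{(S-1)/(P-1)} when the definition requests it;
#' \eqn{Z(x) = -\lambda^{-1}\log\sum_i e^{-\lambda d_i^2}} measures the
#' squared distance from the path. Log-sum-exp stabilization is applied.
#'
#' @param x A [conformation()] or (toy mode) a numeric vector.
#' @param defn A [pcv_definition()].
#' @return List with elements `s` (dimensionless) and `z` (nm^2).
#' @export
compute_pcv <- function(x, defn) {
  d2 <- pcv_distances2(x, defn)
  if (!all(is.finite(d2))) stop("non-finite distances to reference frames")
  lam <- defn$lambda
  m <- min(d2)
  w <- exp(-lam * (d2 - m))
  W <- sum(w)
  s_raw <- sum(seq_along(d2) * w) / W
  z <- m - log(W) / lam
  s <- if (defn$rescaled) (s_raw - 1) / (defn$P - 1) else s_raw
  list(s = s, z = z)
}

#' Path CV values along a series of configurations
#'
#' @param xs List of conformations (or rows of a matrix in toy mode).
#' @param defn A [pcv_definition()].
#' @return A tibble with columns `frame`, `s`, `z`.
#' @export
compute_pcv_series <- function(xs, defn) {
  if (is.matrix(xs)) xs <- asplit(xs, 1)
  vals <- purrr::map(xs, compute_pcv, defn = defn)
  tibble::tibble(frame = seq_along(vals),
                 s = purrr::map_dbl(vals, "s"),
                 z = purrr::map_dbl(vals, "z"))
}

#' Analytic PCV gradients (toy mode)
#'
#' Gradients of S and Z with respect to the configuration coordinates.
#' Only supported for matrix-valued (toy) reference frames, where no
#' superposition enters and the gradients are exact; conformational
#' definitions with alignment raise an error.
#'
#' @param x Numeric vector (toy configuration).
#' @param defn A [pcv_definition()] in toy mode.
#' @return List with vectors `ds` and `dz` (same length as `x`).
#' @export
pcv_gradient <- function(x, defn) {
  if (!defn$toy)
    stop("unsupported mode: gradients through the superposition step are not available")
  x <- as.numeric(x)
  lam <- defn$lambda
  diffs <- sweep(defn$frames, 2, x, "-")      # P x d, x_i - x
  d2 <- rowSums(diffs^2)
  m <- min(d2)
  w <- exp(-lam * (d2 - m))
  W <- sum(w)
  idx <- seq_len(defn$P)
  s_raw <- sum(idx * w) / W
  ## grad d_i^2 = 2 (x - x_i) = -2 diffs
  gd2 <- -2 * diffs                           # P x d, rows are grad d_i^2
  gs_raw <- (-lam / W) * colSums((idx - s_raw) * w * gd2)
  gz <- colSums(w * gd2) / W
  ds <- if (defn$rescaled) gs_raw / (defn$P - 1) else gs_raw
  list(ds = ds, dz = gz)
}
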