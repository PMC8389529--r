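## Rigid-body superposition and RMSD with distinct alignment and
## measurement atom selections -- the metric underlying path finding,
## equidistant resampling and the path collective variables.

#' Molecular conformation
#'
#' A single frame: an n x 3 matrix of atomic positions in nanometres plus
#' optional atom labels (element or atom name) and a frame identifier.
#'
#' @param coords Numeric n x 3 matrix of positions (nm). A length-3 vector
#'   is accepted for a single atom.
#' @param atom_labels Optional character vector of length n (element
#'   symbols or atom names).
#' @param frame_id Optional integer identifier.
#' @return An object of class `"conformation"`.
#' @examples
#' conformation(rbind(c(0, 0, 0), c(0.15, 0, 0)), c("C", "O"))
#' @export
conformation <- function(coords, atom_labels = NULL, frame_id = NA_integer_) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.null(atom_labels) && length(atom_labels) != nrow(coords))
    stop("atom_labels length must match atom count")
  structure(
    list(coords = coords, atom_labels = atom_labels,
         frame_id = as.integer(frame_id)),
    class = "conformation"
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d atoms, frame_id %s\n",
              nrow(x$coords), x$frame_id))
  invisible(x)
}

n_atoms <- function(conf) nrow(conf$coords)

#' Atom selection
#'
#' An ordered set of atom indices with a role: `"align"` selections define
#' the rigid-body fit, `"measure"` selections define which atoms enter the
#' deviation. The two may differ (e.g. align on a rigid host ring or a set
#' of C-alpha atoms, measure on ligand heavy atoms plus pocket residues).
#'
#' @param indices Integer vector of 1-based atom indices, unique.
#' @param role `"align"` or `"measure"`.
#' @return An object of class `"atom_selection"`.
#' @export
atom_selection <- function(indices, role = c("align", "measure")) {
  role <- match.arg(role)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (any(indices < 1L)) stop("selection indices must be >= 1 (1-based)")
  structure(list(indices = indices, role = role), class = "atom_selection")
}

sel_idx <- function(sel, conf) {
  if (is.null(sel)) return(seq_len(n_atoms(conf)))
  idx <- if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  if (any(idx > n_atoms(conf)))
    stop("selection index exceeds atom count")
  idx
}

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over the alignment
#' selection. The rotation is always proper (determinant +1): in the
#' mirror-degenerate case the smallest singular direction is sign-flipped.
#'
#' @param mobile,reference `conformation` objects with equal atom counts.
#' @param align Alignment `atom_selection` (or integer indices, or `NULL`
#'   for all atoms). At least 3 non-collinear atoms are required.
#' @return An object of class `"superposition"`: list with `rotation`
#'   (3 x 3), `translation` (length 3, nm) and `fit_rmsd` (nm). The fitted
#'   coordinates are `coords %*% rotation + translation` (rows as points).
#' @examples
#' ref <- conformation(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))
#' sp <- superpose(ref, ref, NULL)
#' sp$fit_rmsd   # 0
#' @export
superpose <- function(mobile, reference, align = NULL) {
  ia <- sel_idx(align, mobile)
  ib <- sel_idx(align, reference)
  if (length(ia) < 3L)
    stop("degenerate selection: at least 3 alignment atoms required")
  A <- mobile$coords[ia, , drop = FALSE]
  B <- reference$coords[ib, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("alignment selections differ in size")
  ac <- colMeans(A); bc <- colMeans(B)
  A0 <- sweep(A, 2, ac); B0 <- sweep(B, 2, bc)
  ## collinearity check: rank of centred cloud must be >= 2
  sv_rank <- svd(A0, nu = 0, nv = 0)$d
  if (sum(sv_rank > max(sv_rank) * 1e-10) < 2L)
    stop("degenerate selection: alignment atoms are collinear")
  C <- crossprod(A0, B0)           # 3 x 3 covariance
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- as.numeric(bc - ac %*% R)
  fitted <- sweep(A %*% R, 2, tr, "+")
  fit_rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, fit_rmsd = fit_rmsd),
            class = "superposition")
}

#' Apply a superposition to a conformation
#'
#' @param conf A `conformation`.
#' @param sp A `superposition` from [superpose()].
#' @return The transformed `conformation`.
#' @export
apply_superposition <- function(conf, sp) {
  conf$coords <- sweep(conf$coords %*% sp$rotation, 2, sp$translation, "+")
  conf
}

#' RMSD between two conformations
#'
#' Superposes `a` onto `b` over the alignment selection, then returns the
#' (unweighted) root-mean-square deviation over the measurement selection.
#' With `align = NULL` and `fit = FALSE` no superposition is performed.
#'
#' @param a,b `conformation` objects with equal atom counts.
#' @param align Alignment selection, or `NULL` to skip the fit.
#' @param measure Measurement selection (`NULL` = all atoms).
#' @return Length in nm (non-negative).
#' @examples
#' a <- conformation(rbind(c(0,0,0), c(0.3,0,0), c(0,0.3,0)))
#' conf_rmsd(a, a)   # 0
#' @export
conf_rmsd <- function(a, b, align = NULL, measure = NULL) {
  im <- sel_idx(measure, a)
  if (length(im) == 0L) stop("empty measure selection")
  if (!is.null(align)) a <- apply_superposition(a, superpose(a, b, align))
  da <- a$coords[im, , drop = FALSE]
  db <- b$coords[sel_idx(measure, b), , drop = FALSE]
  sqrt(mean(rowSums((da - db)^2)))
}
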