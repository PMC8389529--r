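## Grid-based solvent-excluded-surface (SES) volume of a union of atom
## spheres: the bulk volume traced by the unbound ligand, needed for the
## standard-volume correction. A probe sphere rolling on the atoms
## defines the surface; interior cavities count as inside.

#' Bondi-type van der Waals radii (Angstrom)
#'
#' @param elements Character vector of element symbols; unknown elements
#'   fall back to 1.7 A with a warning.
#' @return Numeric vector of radii.
#' @export
element_radii <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90)
  key <- paste0(toupper(substr(elements, 1, 1)),
                tolower(substr(elements, 2, 2)))
  r <- tab[key]
  miss <- is.na(r)
  if (any(miss)) {
    r[miss] <- tab[toupper(substr(elements[miss], 1, 1))]
    still <- is.na(r)
    if (any(still)) {
      warning("unknown element(s) ", paste(unique(elements[still]),
                                           collapse = ", "),
              "; using 1.7 A")
      r[still] <- 1.7
    }
  }
  unname(r)
}

#' Atom sphere set
#'
#' @param centers Numeric n x 3 matrix of sphere centres (Angstrom).
#' @param radii Positive radii (Angstrom), recycled to n.
#' @return Object of class `"atom_spheres"`.
#' @export
atom_spheres <- function(centers, radii) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3, byrow = TRUE)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, all(is.finite(centers)))
  radii <- rep_len(radii, nrow(centers))
  if (any(radii <= 0)) stop("radii must be positive")
  structure(list(centers = centers, radii = radii), class = "atom_spheres")
}

#' Collect ligand atoms from unbound frames
#'
#' Concatenates the ligand-atom spheres of all listed frames into one
#' union set (duplicates are harmless: the volume routine works on the
#' union). Element radii come from [element_radii()]; coordinates are
#' converted from nm to Angstrom.
#'
#' @param path List of [conformation()] objects.
#' @param unbound_frame_ids Frame ids (matching `frame_id`) of the frames
#'   past the dividing frame, i.e. the dissociated state.
#' @param ligand_selection [atom_selection()] of the ligand atoms.
#' @return An [atom_spheres()] set.
#' @export
collect_unbound_atoms <- function(path, unbound_frame_ids,
                                  ligand_selection = NULL) {
  ids <- vapply(path, function(f) f$frame_id, integer(1))
  keep <- path[ids %in% unbound_frame_ids]
  if (length(keep) == 0L) stop("no frames match the unbound frame ids")
  pieces <- lapply(keep, function(f) {
    il <- sel_idx(ligand_selection, f)
    list(xyz = f$coords[il, , drop = FALSE] * 10,
         el = (f$atom_labels %||% rep("C", n_atoms(f)))[il])
  })
  centers <- do.call(rbind, lapply(pieces, `[[`, "xyz"))
  radii <- element_radii(unlist(lapply(pieces, `[[`, "el")))
  atom_spheres(centers, radii)
}

#' Solvent-excluded-surface volume on a grid
#'
#' Grid algorithm: (1) grid points farther than `r_i + probe` from every
#' atom are probe-accessible candidates; accessibility is propagated by a
#' flood fill from the box boundary, so interior cavities remain inside;
#' (2) a point is inside the SES iff it lies within `r_i + probe` of some
#' atom and farther than `probe` from every accessible point. The volume
#' is the inside count times `spacing^3`.
#'
#' @param spheres An [atom_spheres()] set (or a `conformation`, converted
#'   with carbon radii).
#' @param probe Probe radius (Angstrom, default 1.4).
#' @param spacing Grid spacing (Angstrom, default 0.3). A spacing larger
#'   than the probe triggers a warning.
#' @param padding Box padding beyond the spheres (default
#'   `probe + max(radii) + 2`).
#' @return Volume in A^3, with attributes `n_inside`, `spacing`, `probe`.
#' @examples
#' v <- ses_volume(atom_spheres(c(0, 0, 0), 1.9))
#' abs(v - 4 / 3 * pi * 1.9^3) / v < 0.02
#' @export
ses_volume <- function(spheres, probe = 1.4, spacing = 0.3, padding = NULL) {
  stopifnot(inherits(spheres, "atom_spheres"))
  if (probe < 0) stop("probe must be non-negative")
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing > probe && probe > 0)
    warning("grid spacing exceeds the probe radius; volume may be inaccurate")
  ctr <- spheres$centers
  rad <- spheres$radii
  padding <- padding %||% (probe + max(rad) + 2)
  lo <- apply(ctr, 2, min) - padding
  hi <- apply(ctr, 2, max) + padding
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  nx <- lengths(ax)

  ## squared distance to the nearest (r_i + probe)-inflated sphere surface:
  ## occupied = within r_i + probe of some atom
  gx <- ax[[1]]; gy <- ax[[2]]; gz <- ax[[3]]
  occupied <- array(FALSE, dim = nx)
  for (i in seq_len(nrow(ctr))) {
    rr <- (rad[i] + probe)^2
    dx2 <- (gx - ctr[i, 1])^2
    dy2 <- (gy - ctr[i, 2])^2
    dz2 <- (gz - ctr[i, 3])^2
    ## only touch the local sub-box of this sphere
    ix <- which(dx2 <= rr); iy <- which(dy2 <= rr); iz <- which(dz2 <= rr)
    if (!length(ix) || !length(iy) || !length(iz)) next
    sub <- outer(outer(dx2[ix], dy2[iy], "+"), dz2[iz], "+") <= rr
    occupied[ix, iy, iz] <- occupied[ix, iy, iz] | sub
  }

  ## flood fill accessibility from the box boundary through ~occupied
  free <- !occupied
  acc <- array(FALSE, dim = nx)
  acc[1, , ] <- free[1, , ]; acc[nx[1], , ] <- free[nx[1], , ]
  acc[, 1, ] <- acc[, 1, ] | free[, 1, ]; acc[, nx[2], ] <- acc[, nx[2], ] | free[, nx[2], ]
  acc[, , 1] <- acc[, , 1] | free[, , 1]; acc[, , nx[3]] <- acc[, , nx[3]] | free[, , nx[3]]
  repeat {
    grown <- acc
    grown[-1, , ] <- grown[-1, , ] | acc[-nx[1], , ]
    grown[-nx[1], , ] <- grown[-nx[1], , ] | acc[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | acc[, -nx[2], ]
    grown[, -nx[2], ] <- grown[, -nx[2], ] | acc[, -1, ]
    grown[, , -1] <- grown[, , -1] | acc[, , -nx[3]]
    grown[, , -nx[3]] <- grown[, , -nx[3]] | acc[, , -1]
    grown <- grown & free
    if (identical(grown, acc)) break
    acc <- grown
  }

  ## dilate the accessible region by the probe radius. Plain voxel-centre
  ## dilation quantizes the accessible region and inflates the SES by a
  ## surface shell of order spacing/2, so the boundary layer of accessible
  ## voxels is dilated with its continuum clearance added: voxel y with
  ## clearance c(y) = min_i(|y - c_i| - r_i - probe) certifies an
  ## accessible ball of radius c(y), hence covers everything within
  ## probe + c(y). For a sphere this reproduces the exact surface.
  if (probe > 0) {
    clear <- array(Inf, dim = nx)
    for (i in seq_len(nrow(ctr))) {
      d <- sqrt(outer(outer((gx - ctr[i, 1])^2, (gy - ctr[i, 2])^2, "+"),
                      (gz - ctr[i, 3])^2, "+")) - (rad[i] + probe)
      clear <- pmin(clear, d)
    }
    layer <- which(acc & clear < sqrt(3) * spacing, arr.ind = TRUE)
    dil <- array(FALSE, dim = nx)
    for (v in seq_len(nrow(layer))) {
      iy <- layer[v, ]
      rho <- probe + clear[iy[1], iy[2], iy[3]]
      if (rho <= 0) next
      rr <- rho^2
      dx2 <- (gx - gx[iy[1]])^2
      dy2 <- (gy - gy[iy[2]])^2
      dz2 <- (gz - gz[iy[3]])^2
      ix <- which(dx2 <= rr); iy2 <- which(dy2 <= rr); iz <- which(dz2 <= rr)
      sub <- outer(outer(dx2[ix], dy2[iy2], "+"), dz2[iz], "+") <= rr
      dil[ix, iy2, iz] <- dil[ix, iy2, iz] | sub
    }
    inside <- occupied & !dil
  } else {
    inside <- occupied
  }
  structure(sum(inside) * spacing^3,
            n_inside = sum(inside), spacing = spacing, probe = probe)
}
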