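## Plain-text structure IO: multi-model PDB (MODEL/ENDMDL, Angstrom) and
## XYZ trajectories, plus selection files. Coordinates are converted to
## nm on input and back to Angstrom on output.

#' Read a multi-model PDB file as a list of conformations
#'
#' Parses `ATOM`/`HETATM` records (fixed columns) grouped by
#' `MODEL`/`ENDMDL`; a file without MODEL records yields one frame.
#' Coordinates are converted from Angstrom to nm.
#'
#' @param path Path to a PDB file.
#' @return List of [conformation()] objects (`frame_id` = model number).
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_id <- 0L
  cur <- integer(0)
  frames <- list()
  atom_rows <- list()
  flush <- function() {
    if (length(atom_rows) == 0L) return()
    al <- vapply(atom_rows, `[[`, "", "el")
    xyz <- do.call(rbind, lapply(atom_rows, `[[`, "xyz"))
    frames[[length(frames) + 1L]] <<-
      conformation(xyz / 10, atom_labels = al, frame_id = model_id)
    atom_rows <<- list()
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      model_id <- suppressWarnings(as.integer(substr(lines[i], 7, 14)))
      if (is.na(model_id)) model_id <- length(frames) + 1L
    } else if (r == "ENDMDL") {
      flush()
    } else if (r %in% c("ATOM  ", "HETATM")) {
      ln <- lines[i]
      x <- as.numeric(substr(ln, 31, 38))
      y <- as.numeric(substr(ln, 39, 46))
      z <- as.numeric(substr(ln, 47, 54))
      el <- trimws(substr(ln, 77, 78))
      if (el == "") {
        ## fall back to first letter of the atom name field
        el <- gsub("[^A-Za-z].*$", "", trimws(substr(ln, 13, 16)))
        el <- substr(el, 1, 1)
      }
      atom_rows[[length(atom_rows) + 1L]] <- list(el = el, xyz = c(x, y, z))
    }
  }
  flush()
  if (length(frames) == 0L) stop("no ATOM records found in ", path)
  frames
}

#' Write conformations as a multi-model PDB file
#'
#' @param frames List of [conformation()] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(frames, path) {
  if (inherits(frames, "conformation")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    f <- frames[[m]]
    writeLines(sprintf("MODEL %8d", m), con)
    xyz <- f$coords * 10   # nm -> Angstrom
    lab <- f$atom_labels %||% rep("C", nrow(xyz))
    for (i in seq_len(nrow(xyz))) {
      el <- substr(lab[i], 1, 2)
      writeLines(sprintf(
        "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, substr(lab[i], 1, 4), xyz[i, 1], xyz[i, 2], xyz[i, 3],
        toupper(el)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` rows
#' (Angstrom), repeated per frame. Converted to nm.
#'
#' @param path Path to an `.xyz` file.
#' @return List of [conformation()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <-
      conformation(xyz / 10, atom_labels = el,
                   frame_id = length(frames) + 1L)
    i <- i + 2L + n
  }
  frames
}

#' Write an XYZ trajectory
#'
#' @param frames List of [conformation()] objects (or a single one).
#' @param path Output file path.
#' @param comment Comment line content (recycled per frame).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comment = "pathmetad") {
  if (inherits(frames, "conformation")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    xyz <- f$coords * 10
    lab <- f$atom_labels %||% rep("C", nrow(xyz))
    writeLines(as.character(nrow(xyz)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       lab, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an atom selection file
#'
#' Plain text list of 0-based atom indices (whitespace or newline
#' separated; `#` comments allowed), converted to the package's 1-based
#' convention.
#'
#' @param path Path to the selection file.
#' @param role Selection role, `"align"` or `"measure"`.
#' @return An [atom_selection()].
#' @export
read_selection <- function(path, role = c("align", "measure")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+"))
  idx0 <- as.integer(toks)
  if (any(is.na(idx0))) stop("non-integer token in selection file ", path)
  atom_selection(idx0 + 1L, role = match.arg(role))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
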