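## Plain-text HILLS / COLVAR IO in the common metadynamics dialect:
## a "#! FIELDS ..." header followed by whitespace-separated numeric
## rows. Readers tolerate interspersed comment lines, so files produced
## by external engines can be analysed directly.

read_fields_file <- function(path) {
  lines <- readLines(path)
  head_i <- grep("^#!\\s*FIELDS", lines)
  if (length(head_i) == 0L)
    stop("no '#! FIELDS' header found in ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", lines[head_i[1]])),
                     "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    return(tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(fields)), fields)))
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  colnames(mat) <- fields
  tibble::as_tibble(mat)
}

#' Read a HILLS file
#'
#' @param path Path to a HILLS-dialect file (`#! FIELDS time s z sigma_s
#'   sigma_z height biasf`, or the 1-D variant without `z`).
#' @return A hills tibble.
#' @export
read_hills <- function(path) {
  out <- read_fields_file(path)
  need <- c("time", "s", "height")
  if (!all(need %in% names(out)))
    stop("HILLS file must contain at least: ", paste(need, collapse = ", "))
  out
}

#' Write a HILLS file
#'
#' @param hills Hills tibble (from [run_wtmetad()] or [read_hills()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  one_d <- is.null(hills$z) || all(is.na(hills$z))
  cols <- if (one_d) c("time", "s", "sigma_s", "height", "biasf")
          else c("time", "s", "z", "sigma_s", "sigma_z", "height", "biasf")
  write_fields_file(hills[cols], path)
}

#' Read a COLVAR file
#'
#' @param path Path to a COLVAR-dialect file (`#! FIELDS time s z bias`).
#' @return A colvar tibble with strictly increasing times.
#' @export
read_colvar <- function(path) {
  out <- read_fields_file(path)
  if (!all(c("time", "s") %in% names(out)))
    stop("COLVAR file must contain at least: time, s")
  if (is.unsorted(out$time, strictly = FALSE))
    stop("COLVAR times must be non-decreasing")
  out
}

#' Write a COLVAR file
#'
#' @param colvar Colvar tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(colvar, path) {
  cols <- intersect(c("time", "s", "z", "bias"), names(colvar))
  write_fields_file(colvar[cols], path)
}

## bit-stable fixed formatting shared by both writers
write_fields_file <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  if (nrow(df)) {
    mat <- vapply(df, function(col) sprintf("%.10g", col),
                  character(nrow(df)))
    if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1)
    writeLines(apply(mat, 1, paste, collapse = " "), con)
  }
  invisible(path)
}
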