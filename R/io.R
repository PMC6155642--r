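## Geometry and table I/O: XYZ, extended XYZ (cell + atom-class labels),
## multi-frame trajectory XYZ, and TSV tables.

#' Write a system as (extended) XYZ
#'
#' Standard XYZ layout (count line, comment line, \code{element x y z}
#' records). The extended variant stores the orthorhombic cell as
#' \code{cell="a b c"} on the comment line and appends the atom class as a
#' fifth column, which makes the file round-trippable into a full
#' \code{molsys}.
#'
#' @param sys a \code{molsys}
#' @param path output file
#' @param extended write cell and class labels (default TRUE)
#' @param comment comment-line text (prepended to any cell record)
#' @return \code{path}, invisibly
#' @export
write_xyz <- function(sys, path, extended = TRUE, comment = "") {
  con <- file(path, "w"); on.exit(close(con))
  .write_xyz_con(sys, con, extended, comment)
  invisible(path)
}

.write_xyz_con <- function(sys, con, extended, comment) {
  n <- nrow(sys$xyz)
  writeLines(as.character(n), con)
  cmt <- comment
  if (extended && !is.null(sys$cell))
    cmt <- paste0(cmt, ' cell="', paste(format(sys$cell, digits = 10),
                                        collapse = " "), '"')
  writeLines(trimws(cmt), con)
  for (i in seq_len(n)) {
    if (extended)
      writeLines(sprintf("%-2s %15.8f %15.8f %15.8f %s", sys$element[i],
                         sys$xyz[i, 1], sys$xyz[i, 2], sys$xyz[i, 3],
                         sys$classes[i]), con)
    else
      writeLines(sprintf("%-2s %15.8f %15.8f %15.8f", sys$element[i],
                         sys$xyz[i, 1], sys$xyz[i, 2], sys$xyz[i, 3]), con)
  }
}

#' Read an (extended) XYZ file
#'
#' If class labels are present (extended variant) and \code{bonds} is NULL,
#' bonds are inferred by distance (pairs closer than 1.25x the sum of
#' covalent-like radii); supplying \code{bonds} overrides inference. A
#' \code{cell="a b c"} record on the comment line restores periodicity;
#' \code{require_cell = TRUE} makes a missing cell an error.
#'
#' @param path XYZ file
#' @param bonds optional 2-column bond index matrix
#' @param require_cell error if no cell record is present
#' @return a \code{molsys} (classes default to element-based guesses for
#'   plain XYZ: C -> C_sp3, O -> O_hydroxyl, N -> N_amine, H -> H_C)
#' @export
read_xyz <- function(path, bonds = NULL, require_cell = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ at line 1: not an atom count")
  if (length(lines) < n + 2) stop("malformed XYZ: expected ", n, " atoms")
  cmt <- lines[2]
  cell <- NULL
  m <- regmatches(cmt, regexec('cell="([^"]+)"', cmt))[[1]]
  if (length(m) == 2) cell <- as.numeric(strsplit(trimws(m[2]),
                                                  "[[:space:]]+")[[1]])
  if (require_cell && is.null(cell))
    stop("periodic system expected but no cell record on line 2")
  el <- character(n); cls <- rep(NA_character_, n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 2]), "[[:space:]]+")[[1]]
    if (length(tok) < 4)
      stop("malformed XYZ record at line ", i + 2)
    el[i] <- tok[1]
    xyz[i, ] <- as.numeric(tok[2:4])
    if (anyNA(xyz[i, ])) stop("non-numeric coordinate at line ", i + 2)
    if (length(tok) >= 5) cls[i] <- tok[5]
  }
  if (anyNA(cls)) {
    guess <- c(C = "C_sp3", O = "O_hydroxyl", N = "N_amine", H = "H_C")
    cls[is.na(cls)] <- guess[el[is.na(cls)]]
  }
  if (is.null(bonds)) {
    rad <- c(C = 0.77, O = 0.73, N = 0.75, H = 0.37)
    bl <- list()
    for (i in seq_len(n - 1)) {
      d <- sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ], "-")
      if (!is.null(cell))
        d <- d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
      r <- sqrt(rowSums(d^2))
      cut <- 1.25 * (rad[el[i]] + rad[el[(i + 1):n]])
      j <- which(r < cut)
      for (jj in j) bl[[length(bl) + 1L]] <- c(i, i + jj)
    }
    bonds <- if (length(bl)) do.call(rbind, bl) else
      matrix(integer(0), ncol = 2)
  }
  molecular_system(cls, xyz, bonds, cell = cell)
}

#' Write trajectory frames as multi-frame extended XYZ
#' @param traj a \code{trajectory}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  sys <- traj$template
  for (fi in seq_along(traj$frames)) {
    fsys <- sys
    fsys$xyz <- traj$frames[[fi]]
    if (!is.null(sys$cell)) fsys$cell <- traj$frame_cell[fi, ]
    .write_xyz_con(fsys, con, TRUE,
                   sprintf("frame=%d time=%.6f", fi,
                           (fi - 1) * traj$frame_stride * traj$dt))
  }
  invisible(path)
}

#' Write a data frame as a TSV table with comment-header metadata
#' @param df data.frame
#' @param path output file
#' @param meta named character vector written as \code{# name: value} lines
#' @return \code{path}, invisibly
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
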