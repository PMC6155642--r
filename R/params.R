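## Force-field parameter container and the pairwise energy primitives.
##
## Energy model:
##   stretch  E = ks (r - r0)^2                       [kcal/mol, ks per A^2]
##   bend     E = kb (theta - theta0)^2               [kb per rad^2]
##   torsion  E = sum_n Vn/2 (1 + cos(n phi - gamma_n)), gamma = (0, 180, 0) deg
##   LJ       E = eps_ij [ (rm/r)^12 - 2 (rm/r)^6 ],  rm = rv_i + rv_j,
##            eps_ij = sqrt(eps_i eps_j)              (arithmetic / geometric)
##   dipole   E = K mu1 mu2 (cos chi - 3 cos a1 cos a2) / (D r^3)
## Both nonbonded terms are multiplied by a C^1 polynomial taper that takes
## them smoothly to zero over the final `taper` Angstroms before the cutoff.

.CLASS_RANK <- setNames(seq_along(.CLASSES), names(.CLASSES))

#' Canonical bond-class key for a pair of atom classes
#' @param ci,cj atom class names
#' @return character key \code{"A:B"} with A, B in the package's fixed class
#'   order (the order also fixes the sign convention of the bond dipole:
#'   positive \code{mu} points from A to B).
#' @export
bond_class <- function(ci, cj) {
  ri <- .CLASS_RANK[ci]; rj <- .CLASS_RANK[cj]
  if (anyNA(c(ri, rj))) stop("unknown atom class: ", ci, " / ", cj)
  ifelse(ri <= rj, paste(ci, cj, sep = ":"), paste(cj, ci, sep = ":"))
}

.angle_class <- function(ci, cj, ck) {
  ends <- c(ci, ck)[order(.CLASS_RANK[c(ci, ck)])]
  paste(ends[1], cj, ends[2], sep = ":")
}

.torsion_class <- function(cb, cc) {
  # wildcard key on the central bond, canonical bond order
  paste("X", bond_class(cb, cc), "X", sep = ":")
}

#' MM3-like starting force-field parameters
#'
#' The uncalibrated parameter set used as the optimizer start: intramolecular
#' constants typical of MM3-class force fields for alcohols/amines, the CO2
#' stretch/bend constants from the closed-form frequency inversion, and
#' literature-magnitude Lennard-Jones radii/well depths and bond-dipole
#' magnitudes. Nonbonded values are refined by \code{\link{fit_parameters}}.
#'
#' Bond-dipole sign convention: \code{mu > 0} points from the first class of
#' the canonical key to the second, i.e. from the negative to the positive end
#' of the bond; chemically sensible signs are built in (O and N are the
#' negative ends).
#'
#' @return An object of class \code{ffparams}: a list with data frames
#'   \code{atoms} (class, rv, eps), \code{bonds} (class, ks, r0, mu),
#'   \code{angles} (class, kb, theta0 in degrees), \code{torsions}
#'   (class, V1..V3) and scalars \code{dielectric}, \code{cut_vdw},
#'   \code{cut_dip}, \code{taper}.
#' @export
mm_start_parameters <- function() {
  atoms <- data.frame(
    class = c("C_co2", "O_co2", "C_sp3", "N_amine", "O_hydroxyl",
              "H_C", "H_N", "H_O"),
    rv  = c(1.94, 1.82, 2.04, 1.93, 1.82, 1.62, 1.60, 1.60),
    eps = c(0.056, 0.059, 0.027, 0.043, 0.059, 0.020, 0.018, 0.015),
    stringsAsFactors = FALSE)
  bonds <- data.frame(
    class = c("C_co2:O_co2", "O_hydroxyl:H_O", "N_amine:H_N",
              "C_sp3:O_hydroxyl", "C_sp3:N_amine", "C_sp3:C_sp3",
              "C_sp3:H_C"),
    ks = c(1043.07, 520, 460, 380, 360, 320, 330),
    r0 = c(1.16, 0.96, 1.01, 1.42, 1.47, 1.53, 1.10),
    mu = c(-2.20, 1.70, 1.30, -1.20, -1.00, 0, 0),
    stringsAsFactors = FALSE)
  angles <- data.frame(
    class = c("O_co2:C_co2:O_co2",
              "C_sp3:O_hydroxyl:H_O",
              "O_hydroxyl:C_sp3:H_C",
              "C_sp3:C_sp3:O_hydroxyl",
              "H_C:C_sp3:H_C",
              "C_sp3:C_sp3:H_C",
              "C_sp3:C_sp3:N_amine",
              "N_amine:C_sp3:H_C",
              "C_sp3:N_amine:H_N",
              "H_N:N_amine:H_N"),
    kb = c(49.283, 55, 55, 60, 40, 45, 60, 50, 50, 45),
    theta0 = c(180, 108.5, 109.5, 109.5, 108.0, 110.0, 109.5, 109.5,
               109.5, 106.4),
    stringsAsFactors = FALSE)
  torsions <- data.frame(
    class = c("X:C_sp3:C_sp3:X", "X:C_sp3:O_hydroxyl:X", "X:C_sp3:N_amine:X"),
    V1 = c(0, 0, 0), V2 = c(0, 0, 0), V3 = c(0.50, 0.35, 0.30),
    stringsAsFactors = FALSE)
  ff <- list(atoms = atoms, bonds = bonds, angles = angles,
             torsions = torsions,
             dielectric = 1.0, cut_vdw = 10.0, cut_dip = 12.0, taper = 1.0)
  class(ff) <- "ffparams"
  validate_ff(ff)
  ff
}

#' Calibrated default force-field parameters
#'
#' Reads the parameter file shipped with the package, which holds the result
#' of calibrating the nonbonded parameters against the reference dimer
#' energetics (see \code{\link{fit_parameters}} and the methods vignette).
#'
#' @return An \code{ffparams} object.
#' @export
mm_parameters <- function() {
  path <- system.file("extdata", "co2mea_fitted.prm", package = "co2mea")
  if (!nzchar(path) || !file.exists(path)) return(mm_start_parameters())
  read_parameters(path)
}

#' Validate a force-field parameter set
#'
#' Checks positivity of force constants, radii, well depths and cutoffs and
#' that the vdW cutoff does not exceed the dipole cutoff.
#'
#' @param ff an \code{ffparams} object
#' @return \code{ff}, invisibly; stops on violation.
#' @export
validate_ff <- function(ff) {
  stopifnot(inherits(ff, "ffparams"))
  if (any(ff$atoms$rv <= 0) || any(ff$atoms$eps <= 0))
    stop("LJ rv and eps must be positive")
  if (any(ff$bonds$ks <= 0) || any(ff$bonds$r0 <= 0))
    stop("bond ks and r0 must be positive")
  if (any(ff$angles$kb <= 0)) stop("angle kb must be positive")
  if (ff$cut_vdw <= 0 || ff$cut_dip <= 0 || ff$taper <= 0)
    stop("cutoffs and taper width must be positive")
  if (ff$cut_vdw > ff$cut_dip)
    stop("vdW cutoff must not exceed the dipole cutoff")
  invisible(ff)
}

.ff_atom_row <- function(ff, cls) {
  i <- match(cls, ff$atoms$class)
  if (anyNA(i)) stop("no LJ parameters for atom class: ",
                     paste(cls[is.na(i)], collapse = ", "))
  i
}

.ff_bond_row <- function(ff, key) {
  i <- match(key, ff$bonds$class)
  if (anyNA(i)) stop("no bond parameters for class: ",
                     paste(key[is.na(i)], collapse = ", "))
  i
}

## C^1 polynomial switching function: 1 below rcut - w, 0 at rcut.
.taper_s <- function(r, rcut, w) {
  t <- pmin(pmax((r - (rcut - w)) / w, 0), 1)
  1 - t * t * (3 - 2 * t)
}

#' Lennard-Jones pair energy between two atom classes
#'
#' 6-12 potential in minimum-position form
#' \code{eps_ij * ((rm/r)^12 - 2 (rm/r)^6)} with \code{rm = rv_i + rv_j}
#' (arithmetic rule) and \code{eps_ij = sqrt(eps_i * eps_j)} (geometric rule),
#' tapered smoothly to zero at the vdW cutoff.
#'
#' @param class_i,class_j atom class names
#' @param r separation in Angstrom (vectorized)
#' @param ff an \code{ffparams} object
#' @return energy in kcal/mol
#' @export
#' @examples
#' ff <- mm_start_parameters()
#' rm <- sum(ff$atoms$rv[ff$atoms$class %in% c("C_co2", "O_co2")][1:2])
#' lj_pair_energy("O_co2", "O_co2", 2 * ff$atoms$rv[2], ff)  # = -eps at rm
lj_pair_energy <- function(class_i, class_j, r, ff) {
  stopifnot(all(r > 0))
  i <- .ff_atom_row(ff, class_i); j <- .ff_atom_row(ff, class_j)
  rm <- ff$atoms$rv[i] + ff$atoms$rv[j]
  eps <- sqrt(ff$atoms$eps[i] * ff$atoms$eps[j])
  x6 <- (rm / r)^6
  e <- eps * (x6 * x6 - 2 * x6)
  e * .taper_s(r, ff$cut_vdw, ff$taper) * (r < ff$cut_vdw)
}

#' Bond-dipole pair interaction energy
#'
#' Classical point-dipole interaction between two bond-centered dipoles:
#' \code{E = K mu1 mu2 (cos chi - 3 cos a1 cos a2) / (D r^3)} where \code{r}
#' joins the bond midpoints, \code{chi} is the angle between the dipole axes
#' and \code{a1}, \code{a2} the angles each axis makes with the
#' midpoint-midpoint vector; tapered to zero at the dipole cutoff.
#'
#' @param d1,d2 lists with fields \code{a}, \code{b} (3-vectors, bond end
#'   positions in Angstrom) and \code{mu} (signed magnitude in Debye, along
#'   a -> b)
#' @param ff an \code{ffparams} object (supplies dielectric, cutoff, taper)
#' @return energy in kcal/mol
#' @export
#' @examples
#' ff <- mm_start_parameters()
#' d1 <- list(a = c(-0.5, 0, 0), b = c(0.5, 0, 0), mu = 1)
#' d2 <- list(a = c(2.5, 0, 0), b = c(3.5, 0, 0), mu = 1)
#' dipole_pair_energy(d1, d2, ff)  # head-to-tail at 3 A: ~ -1.066
dipole_pair_energy <- function(d1, d2, ff) {
  u1 <- d1$b - d1$a; u2 <- d2$b - d2$a
  m1 <- (d1$a + d1$b) / 2; m2 <- (d2$a + d2$b) / 2
  rv <- m2 - m1; r <- sqrt(sum(rv * rv))
  if (r < 1e-9) stop("singular geometry: coincident dipole midpoints")
  u1 <- u1 / sqrt(sum(u1 * u1)); u2 <- u2 / sqrt(sum(u2 * u2))
  if (r >= ff$cut_dip) return(0)
  cchi <- sum(u1 * u2)
  ca1 <- sum(u1 * rv) / r; ca2 <- sum(u2 * rv) / r
  e <- .KDIP * d1$mu * d2$mu * (cchi - 3 * ca1 * ca2) /
    (ff$dielectric * r^3)
  e * .taper_s(r, ff$cut_dip, ff$taper)
}

#' Scale one bond class's dipole magnitude
#'
#' Returns a copy of the parameter set with the dipole magnitude of one bond
#' class multiplied by \code{factor} and everything else untouched. Used for
#' the reduced-hydroxyl-dipole control simulations.
#'
#' @param ff an \code{ffparams} object
#' @param bond_class canonical bond-class key (default the hydroxyl O-H bond)
#' @param factor scaling factor in (0, 1]
#' @return a new \code{ffparams} object
#' @export
#' @examples
#' ff <- mm_start_parameters()
#' ff10 <- scale_bond_dipole(ff, factor = 0.1)
scale_bond_dipole <- function(ff, bond_class = "O_hydroxyl:H_O", factor) {
  stopifnot(factor > 0, factor <= 1)
  i <- .ff_bond_row(ff, bond_class)
  ff$bonds$mu[i] <- ff$bonds$mu[i] * factor
  ff
}

#' @export
print.ffparams <- function(x, ...) {
  cat("Force-field parameters (", nrow(x$atoms), " atom classes, ",
      nrow(x$bonds), " bond classes)\n", sep = "")
  cat("  cutoffs: vdW ", x$cut_vdw, " A, dipole ", x$cut_dip,
      " A, taper ", x$taper, " A, dielectric ", x$dielectric, "\n", sep = "")
  invisible(x)
}

#' Write a parameter file
#'
#' Plain-text key-value format, one record per line:
#' \code{atom <class> <rv> <eps>}, \code{bond <class> <ks> <r0> <mu>},
#' \code{angle <class> <kb> <theta0>}, \code{torsion <class> <V1> <V2> <V3>},
#' \code{global <name> <value>}. Lines starting with \code{#} are comments.
#'
#' @param ff an \code{ffparams} object
#' @param path output file
#' @param comment optional provenance lines written as a header
#' @return \code{path}, invisibly
#' @export
write_parameters <- function(ff, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# co2mea force-field parameter file", con)
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  with(ff, {
    for (i in seq_len(nrow(atoms)))
      writeLines(sprintf("atom %s %.10g %.10g", atoms$class[i],
                         atoms$rv[i], atoms$eps[i]), con)
    for (i in seq_len(nrow(bonds)))
      writeLines(sprintf("bond %s %.10g %.10g %.10g", bonds$class[i],
                         bonds$ks[i], bonds$r0[i], bonds$mu[i]), con)
    for (i in seq_len(nrow(angles)))
      writeLines(sprintf("angle %s %.10g %.10g", angles$class[i],
                         angles$kb[i], angles$theta0[i]), con)
    for (i in seq_len(nrow(torsions)))
      writeLines(sprintf("torsion %s %.10g %.10g %.10g", torsions$class[i],
                         torsions$V1[i], torsions$V2[i], torsions$V3[i]), con)
    for (g in c("dielectric", "cut_vdw", "cut_dip", "taper"))
      writeLines(sprintf("global %s %.10g", g, ff[[g]]), con)
  })
  invisible(path)
}

#' Read a parameter file written by \code{\link{write_parameters}}
#' @param path parameter file
#' @return an \code{ffparams} object
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[[:space:]]+")
  rec <- function(kind, n) {
    rows <- Filter(function(t) t[1] == kind, tok)
    bad <- Filter(function(t) length(t) != n + 2, rows)
    if (length(bad)) stop("malformed ", kind, " record: ",
                          paste(bad[[1]], collapse = " "))
    rows
  }
  at <- rec("atom", 2)
  bo <- rec("bond", 3)
  an <- rec("angle", 2)
  to <- rec("torsion", 3)
  gl <- rec("global", 1)
  num <- function(rows, k) vapply(rows, function(t) as.numeric(t[k]), 0)
  chr <- function(rows) vapply(rows, function(t) t[2], "")
  ff <- list(
    atoms = data.frame(class = chr(at), rv = num(at, 3), eps = num(at, 4),
                       stringsAsFactors = FALSE),
    bonds = data.frame(class = chr(bo), ks = num(bo, 3), r0 = num(bo, 4),
                       mu = num(bo, 5), stringsAsFactors = FALSE),
    angles = data.frame(class = chr(an), kb = num(an, 3),
                        theta0 = num(an, 4), stringsAsFactors = FALSE),
    torsions = data.frame(class = chr(to), V1 = num(to, 3), V2 = num(to, 4),
                          V3 = num(to, 5), stringsAsFactors = FALSE),
    dielectric = 1, cut_vdw = 10, cut_dip = 12, taper = 1)
  for (t in gl) ff[[t[2]]] <- as.numeric(t[3])
  class(ff) <- "ffparams"
  validate_ff(ff)
  ff
}
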