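## Energy and force evaluation (R front end over the compiled engine).

#' Total potential energy, decomposed
#'
#' Evaluates the full force-field energy of a system: harmonic stretches and
#' bends, cosine-series torsions, tapered 6-12 Lennard-Jones, tapered
#' bond-dipole electrostatics and the optional spherical-wall term. Nonbonded
#' exclusions: atom pairs separated by one or two bonds carry no LJ or dipole
#' interaction; 1-4 and more distant pairs count at full strength; dipole
#' pairs whose bonds share an atom are excluded. Under a periodic cell the
#' minimum-image convention is applied and the effective dipole cutoff is
#' clamped to half the shortest edge.
#'
#' @param sys a \code{molsys}
#' @param ff an \code{ffparams}
#' @return list with \code{decomp} (named vector: stretch, bend, torsion, lj,
#'   dipole, wall), \code{total}, and \code{virial} (kcal/mol)
#' @export
total_energy <- function(sys, ff) {
  .check_cell(sys, ff)
  comp <- .compile(sys, ff)
  cpp_energy(comp, sys$xyz, .cell_or_zero(sys), .wall_vec(sys),
             FALSE, -1)[c("decomp", "total", "virial")]
}

#' Analytic forces
#'
#' Gradient of \code{\link{total_energy}} with respect to all coordinates,
#' with sign convention force = -gradient.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces in kcal mol^-1 A^-1
#' @export
forces <- function(sys, ff) {
  .check_cell(sys, ff)
  comp <- .compile(sys, ff)
  cpp_energy(comp, sys$xyz, .cell_or_zero(sys), .wall_vec(sys),
             TRUE, -1)$forces
}

## single call returning everything (internal)
.energy_forces <- function(sys, ff, comp = NULL) {
  if (is.null(comp)) comp <- .compile(sys, ff)
  cpp_energy(comp, sys$xyz, .cell_or_zero(sys), .wall_vec(sys), TRUE, -1)
}

#' Bonded energy terms
#'
#' @inheritParams total_energy
#' @return named vector with \code{stretch}, \code{bend}, \code{torsion}
#' @export
bonded_energy <- function(sys, ff) {
  total_energy(sys, ff)$decomp[c("stretch", "bend", "torsion")]
}

#' Interaction energy between the two molecules of a dimer
#'
#' The dimer is relaxed under the supplied constraints; the interaction
#' energy is then evaluated at the complex geometry against the frozen
#' fragments, \code{Eint = E(complex) - E(fragment A) - E(fragment B)} with
#' both fragments kept exactly as they sit in the complex. This is the
#' interaction energy in the quantum-chemistry sense (the quantity compared
#' against counterpoise-corrected binding energies); monomer deformation is
#' not part of it. With this reference the dipole-dipole and LJ components
#' of the decomposition are purely intermolecular sums.
#'
#' @param sys a two-molecule \code{molsys} (the starting dimer geometry)
#' @param ff an \code{ffparams}
#' @param constraints list of constraints for the dimer relaxation (see
#'   \code{\link{minimize}}); default none
#' @param optimize relax the dimer first (default TRUE); if FALSE the
#'   energies are evaluated at the given geometry
#' @return list with \code{Eint} (kcal/mol), \code{components} (named vector:
#'   mumu, lj, bonded - the bonded part is zero by construction with frozen
#'   fragments), \code{dimer} (the relaxed complex) and \code{monomers}
#'   (the frozen fragments)
#' @export
interaction_energy <- function(sys, ff, constraints = list(),
                               optimize = TRUE) {
  if (n_molecules(sys) != 2)
    stop("interaction_energy needs a system of exactly two molecules")
  if (optimize) {
    dim_opt <- minimize(sys, ff, constraints = constraints)$system
  } else dim_opt <- sys
  mons <- lapply(1:2, function(m) subset_molecules(dim_opt, m))
  ed <- total_energy(dim_opt, ff)
  em <- lapply(mons, function(m) total_energy(m, ff))
  eint <- ed$total - em[[1]]$total - em[[2]]$total
  dmono <- em[[1]]$decomp + em[[2]]$decomp
  dd <- ed$decomp - dmono
  comps <- c(mumu = unname(dd["dipole"]), lj = unname(dd["lj"]),
             bonded = unname(dd["stretch"] + dd["bend"] + dd["torsion"]))
  list(Eint = eint, components = comps, dimer = dim_opt, monomers = mons)
}

#' Extract molecules from a system by molecule index
#' @param sys a \code{molsys}
#' @param which integer vector of molecule ids to keep
#' @return a \code{molsys} with the selected molecules (no cell, no wall)
#' @export
subset_molecules <- function(sys, which) {
  keep <- sys$mol %in% which
  idx <- which(keep)
  remap <- match(seq_len(nrow(sys$xyz)), idx)
  bk <- sys$bonds[keep[sys$bonds[, 1]] & keep[sys$bonds[, 2]], , drop = FALSE]
  molecular_system(sys$classes[keep], sys$xyz[keep, , drop = FALSE],
                   cbind(remap[bk[, 1]], remap[bk[, 2]]),
                   vel = if (is.null(sys$vel)) NULL
                         else sys$vel[keep, , drop = FALSE])
}
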