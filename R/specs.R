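# Polymorph specifications: lattice + symmetry class + interface energies.

#' Interface free-energy table
#'
#' Standard binding free-energy gain (kcal/mol per buried peptide) to
#' construct a buried interface on each cleavage plane: backbone axis
#' (`dG_a`), sidechain axis (`dG_b`), intra-cell steric zipper (`dG_zip`,
#' parallel to the b plane but stronger than `dG_b`), and hydrogen-bond axis
#' (`dG_c`).  For a herringbone lattice the lateral (ab-plane) energies are
#' instead composed from the two overhang parameters `eps` and `eps_prime`
#' (see [interface_free_energy()]); `dG_a`, `dG_b`, `dG_zip` may then be left
#' `NA`.
#'
#' Attractive interfaces have negative energies; a positive `dG_c` almost
#' surely indicates a sign-convention error and triggers a warning.
#'
#' @param dG_a,dG_b,dG_zip,dG_c per-peptide interface energies, kcal/mol.
#' @param eps,eps_prime herringbone interface parameters, kcal/mol
#'   (`NA` for a rectangular lattice).
#' @param ese optional named numeric vector of standard errors (metadata
#'   only; not propagated into rates).
#' @return an object of class `energy_table`.
#' @export
energy_table <- function(dG_a = NA_real_, dG_b = NA_real_, dG_zip = NA_real_,
                         dG_c = NA_real_, eps = NA_real_, eps_prime = NA_real_,
                         ese = NULL) {
  vals <- c(dG_a = dG_a, dG_b = dG_b, dG_zip = dG_zip, dG_c = dG_c,
            eps = eps, eps_prime = eps_prime)
  if (!all(vapply(vals, is.numeric, logical(1))))
    stop("all energies must be numeric (use NA_real_ for unset entries)")
  if (!is.na(dG_c) && dG_c > 0)
    warning("positive dG_c: a repulsive hydrogen-bond interface is almost surely a sign error")
  structure(c(as.list(vals), list(ese = ese)), class = "energy_table")
}

#' Polymorph specification
#'
#' Bundles a label, the in-plane symmetry class, the lattice parameters and
#' the interface energy table for one polymorph.  The antiparallel (AP)
#' polymorph is rectangular (plane group p1); the parallel (P) polymorph has
#' herringbone symmetry (plane group p2) and must provide `eps`/`eps_prime`.
#'
#' @param label `"AP"` or `"P"`.
#' @param symmetry `"rectangular_p1"` or `"herringbone_p2"`.
#' @param lattice a [lattice_params()].
#' @param energies an [energy_table()].
#' @return an object of class `polymorph_spec`.
#' @export
polymorph_spec <- function(label = c("AP", "P"),
                           symmetry = c("rectangular_p1", "herringbone_p2"),
                           lattice, energies) {
  label <- match.arg(label)
  symmetry <- match.arg(symmetry)
  stopifnot(inherits(lattice, "lattice_params"),
            inherits(energies, "energy_table"))
  if (label == "AP" && symmetry != "rectangular_p1")
    stop("the AP polymorph is rectangular (p1)")
  if (label == "P" && symmetry != "herringbone_p2")
    stop("the P polymorph is herringbone (p2)")
  if (symmetry == "herringbone_p2") {
    if (is.na(energies$eps) || is.na(energies$eps_prime) || is.na(energies$dG_zip))
      stop("a herringbone spec requires eps, eps_prime and dG_zip")
  } else {
    if (anyNA(c(energies$dG_a, energies$dG_b, energies$dG_zip, energies$dG_c)))
      stop("a rectangular spec requires dG_a, dG_b, dG_zip and dG_c")
  }
  if (is.na(energies$dG_c)) stop("dG_c is required for every polymorph")
  structure(list(label = label, symmetry = symmetry, lattice = lattice,
                 energies = energies),
            class = "polymorph_spec")
}

#' Reference IFQINS polymorph specifications
#'
#' Published parameterisation of the two competing IFQINS hexapeptide
#' nanocrystal polymorphs.  The antiparallel (AP) designed structure has a
#' rectangular p1 cell, a = 20.0, b = 19.1 Angstrom, holding two peptides
#' across b (the intra-cell steric zipper), with per-peptide interface
#' energies dG_a = -9.2, dG_b = -6.2, dG_zip = -16.4, dG_c = -29.3 kcal/mol.
#' The parallel (P) crystal (4R0P) is herringbone p2 with translational cell
#' a = 43.2, b = 19.6 Angstrom (two peptides along a and along b), lateral
#' energetics composed from eps = -18.84 and eps' = -5.99 kcal/mol, with the
#' intra-cell zipper and hydrogen-bond interfaces both at -25.3 kcal/mol.  The c repeat is not part of the published lattice
#' description; the canonical cross-beta strand spacing 4.8 Angstrom is the
#' configurable default.
#'
#' @param c_repeat hydrogen-bond axis repeat per peptide, Angstrom.
#' @return a `polymorph_spec`.
#' @export
default_ap_spec <- function(c_repeat = 4.8) {
  polymorph_spec(
    "AP", "rectangular_p1",
    lattice_params(a = 20.0, b = 19.1, c = c_repeat, gamma = 83,
                   peptides_per_cell = c(1, 2, 1)),
    energy_table(dG_a = -9.2, dG_b = -6.2, dG_zip = -16.4, dG_c = -29.3,
                 ese = c(dG_a = 0.1, dG_b = 0.1, dG_zip = 0.3, dG_c = 0.2))
  )
}

#' @rdname default_ap_spec
#' @export
default_p_spec <- function(c_repeat = 4.8) {
  polymorph_spec(
    "P", "herringbone_p2",
    lattice_params(a = 43.2, b = 19.6, c = c_repeat, gamma = 90,
                   peptides_per_cell = c(2, 2, 1)),
    energy_table(dG_zip = -25.3, dG_c = -25.3, eps = -18.84, eps_prime = -5.99,
                 ese = c(dG_zip = 0.2, dG_c = 0.2, eps = 0.2, eps_prime = 0.2))
  )
}
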