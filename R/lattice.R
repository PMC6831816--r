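# Lattice geometry: integer block shapes -> physical dimensions and face
# areas for each polymorph's unit cell.

#' Lattice parameters of a polymorph unit cell
#'
#' Describes the translational unit cell of a nanocrystal lattice and how
#' many peptides it holds along each axis.  Axes follow the crystallographic
#' convention for cross-beta assemblies: `a` is the backbone
#' (terminus-terminus) axis, `b` the sidechain-stacking axis, and `c` the
#' hydrogen-bonding (fibril) axis.
#'
#' @param a,b,c cell lengths in Angstrom; all must be positive.
#' @param gamma in-plane cell angle in degrees, in (0, 180].  Carried for
#'   completeness; the kinetic model uses orthogonal box dimensions only.
#' @param peptides_per_cell integer vector of length 3: number of peptides the
#'   cell holds along a, b, c.
#' @return an object of class `lattice_params`.
#' @examples
#' lattice_params(a = 20.0, b = 19.1, c = 4.8, gamma = 83,
#'                peptides_per_cell = c(1, 2, 1))
#' @export
lattice_params <- function(a, b, c, gamma = 90, peptides_per_cell = c(1, 1, 1)) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), length(a) == 1,
            length(b) == 1, length(c) == 1)
  if (!(a > 0 && b > 0 && c > 0))
    stop("lattice constants must be strictly positive")
  if (!(gamma > 0 && gamma <= 180))
    stop("gamma must lie in (0, 180] degrees")
  ppc <- as.integer(peptides_per_cell)
  if (length(ppc) != 3 || any(is.na(ppc)) || any(ppc < 1))
    stop("peptides_per_cell must be three integers >= 1")
  structure(list(a = a, b = b, c = c, gamma = gamma,
                 peptides_per_cell = ppc),
            class = "lattice_params")
}

#' Integer block shape of an aggregate
#'
#' The shape (n_a, n_b, n_c) counts peptides along the backbone, sidechain
#' and hydrogen-bond axes.  `n_b` is restricted to 1 or an even integer:
#' species with an odd number of sheets greater than one would expose a
#' broken steric zipper while burying the weaker b interface ("inside-out"
#' species) and are excluded from the reaction network.
#'
#' @param n_a,n_b,n_c peptide counts, each >= 1.
#' @return an object of class `block_shape` (named integer vector).
#' @export
block_shape <- function(n_a, n_b, n_c) {
  n <- as.integer(c(n_a, n_b, n_c))
  if (any(is.na(n)) || any(n < 1))
    stop("shape indices must be integers >= 1")
  if (n[2] > 1 && n[2] %% 2 == 1)
    stop("n_b must be 1 or even (inside-out species are excluded)")
  structure(stats::setNames(n, c("n_a", "n_b", "n_c")), class = "block_shape")
}

#' Per-peptide cell dimensions
#'
#' Divides the lattice constants by the number of peptides per cell along
#' each axis, giving the physical extent contributed by one peptide.
#'
#' @param spec a [polymorph_spec()].
#' @return named numeric vector (a, b, c) in Angstrom.
#' @export
per_peptide_cell <- function(spec) {
  stopifnot(inherits(spec, "polymorph_spec"))
  lat <- spec$lattice
  out <- c(lat$a, lat$b, lat$c) / lat$peptides_per_cell
  stats::setNames(out, c("a", "b", "c"))
}

#' Physical dimensions of a block
#'
#' @param shape a [block_shape()] (or length-3 integer vector).
#' @param spec a [polymorph_spec()].
#' @return named numeric vector of block dimensions in Angstrom, linear in
#'   every shape index.
#' @export
block_dimensions <- function(shape, spec) {
  shape <- as_shape(shape)
  per_peptide_cell(spec) * as.numeric(shape)
}

#' Area of a block face
#'
#' Area of the face perpendicular to `axis`: the product of the two block
#' dimensions spanning that face.  Collisions are resolved on the surface
#' area of the assembly-competent planes, so this is the geometric input to
#' the collision kernels.
#'
#' @inheritParams block_dimensions
#' @param axis one of "a", "b", "c".
#' @return face area in Angstrom^2.
#' @export
face_area <- function(shape, spec, axis) {
  axis <- match.arg(axis, c("a", "b", "c"))
  dims <- block_dimensions(shape, spec)
  prod(dims[setdiff(c("a", "b", "c"), axis)])
}

#' Effective a-axis repeat under the lattice symmetry
#'
#' For a herringbone (p2) lattice, translation along `a` combined with a
#' 180-degree rotation maps the lattice onto itself, so the effective repeat
#' is half the translational cell length; a rectangular (p1) lattice repeats
#' at the full cell length.
#'
#' @param lattice a [lattice_params()].
#' @param symmetry `"herringbone_p2"` or `"rectangular_p1"`.
#' @return repeat length in Angstrom.
#' @examples
#' effective_a_repeat(lattice_params(43.2, 19.6, 4.8), "herringbone_p2") # 21.6
#' @export
effective_a_repeat <- function(lattice, symmetry = c("rectangular_p1", "herringbone_p2")) {
  stopifnot(inherits(lattice, "lattice_params"))
  symmetry <- match.arg(symmetry)
  if (symmetry == "herringbone_p2") lattice$a / 2 else lattice$a
}

# coerce vectors to block_shape without revalidating objects already checked
as_shape <- function(shape) {
  if (inherits(shape, "block_shape")) return(shape)
  block_shape(shape[[1]], shape[[2]], shape[[3]])
}
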