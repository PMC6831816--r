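# Rate constants and propensities for the three reaction classes: bimolecular
# joins, unimolecular splits, and compound collision-with-split reactions.

#' A species of the reaction network
#'
#' A species is a polymorph tag plus an integer block shape.  Monomers are
#' untagged (`"MONOMER"`) and always have shape (1,1,1); committed blocks
#' carry the `"AP"` or `"P"` tag and never mix polymorphs.
#'
#' @param tag `"MONOMER"`, `"AP"` or `"P"`.
#' @param shape a [block_shape()] (defaults to the monomer shape).
#' @return an object of class `species`.
#' @export
species <- function(tag = c("MONOMER", "AP", "P"), shape = block_shape(1, 1, 1)) {
  tag <- match.arg(tag)
  shape <- as_shape(shape)
  npep <- prod(shape)
  if (tag == "MONOMER" && npep != 1) stop("monomers have shape (1,1,1)")
  if (tag != "MONOMER" && npep == 1) stop("a committed species has >= 2 peptides")
  structure(list(tag = tag, shape = shape), class = "species")
}

axis_index <- function(axis) match(axis, c("a", "b", "c"))

# cross-section indices (the two axes spanning the face perpendicular to axis)
cross_axes <- function(axis) setdiff(1:3, axis_index(axis))

#' Collision rate constant for a simple join
#'
#' Diffusion-limited collision kernel for two blocks meeting on matching
#' faces perpendicular to `contact_axis`:
#' \deqn{k = 2 e^{-3} (D_A + D_B) \sqrt{2 A},}
#' where A is the contact-face area and the barrier factor e^-3 accounts for
#' the translational and rotational degrees of freedom lost on joining.  The
#' kernel is symmetric in its arguments.
#'
#' @param sA,sB [species()] objects (the contact-face cross-sections must
#'   match for a simple join; see [compound_join_split_rate()] otherwise).
#' @param contact_axis `"a"`, `"b"` or `"c"`.
#' @param spec the [polymorph_spec()] giving the cell geometry.
#' @param cond a [solvent_conditions()].
#' @return rate constant in m^3/s.
#' @export
collision_rate_constant <- function(sA, sB, contact_axis, spec,
                                    cond = solvent_conditions()) {
  stopifnot(inherits(sA, "species"), inherits(sB, "species"))
  ax <- match.arg(contact_axis, c("a", "b", "c"))
  cr <- cross_axes(ax)
  if (any(sA$shape[cr] != sB$shape[cr]))
    stop("contact-face cross-sections do not match; not a simple join")
  contact_kernel(spec, as.numeric(sA$shape), as.numeric(sB$shape),
                 axis_index(ax), as.numeric(sA$shape)[cr], cond)
}

# kernel shared by simple and compound channels: overlap gives the matching
# face in cell units
contact_kernel <- function(spec, shapeA, shapeB, ax, overlap, cond) {
  cell <- per_peptide_cell(spec)
  DA <- rod_diffusion_coefficient(cell * shapeA, cond)
  DB <- rod_diffusion_coefficient(cell * shapeB, cond)
  cr <- setdiff(1:3, ax)
  area_m2 <- prod(cell[cr] * overlap) * .const$ang^2
  2 * .const$barrier * (DA + DB) * sqrt(2 * area_m2)
}

#' Propensity of a bimolecular reaction
#'
#' Number densities enter the rate equations directly (well-mixed solution,
#' no spatial correlations).  For homodimerisation the pair count N_A N_B is
#' replaced by the symmetry-corrected N_A (N_A - 1)/2.
#'
#' @param k bimolecular rate constant (m^3/s).
#' @param nA,nB copy numbers of the two reactant species.
#' @param V simulation volume (m^3).
#' @param homo logical: are the two reactants the same species?
#' @return propensity in 1/s.
#' @export
bimolecular_propensity <- function(k, nA, nB, V, homo = FALSE) {
  stopifnot(nA >= 0, nB >= 0, V > 0, k >= 0)
  if (homo) k * nA * (nA - 1) / (2 * V) else k * nA * nB / V
}

#' Rate constant for a unimolecular split
#'
#' Arrhenius rate to fracture a block on one plane:
#' \deqn{k = \tau_0^{-1} \exp(\Delta G_{plane} / k_B T),}
#' with the buried-interface free energy from [interface_free_energy()]
#' (negative for attractive tables, so stronger interfaces split more
#' slowly) and the monomer diffusion time tau0 as the dynamical timescale.
#' Equivalent parallel planes share the rate constant; their number enters
#' the propensity as a multiplicity factor (e.g. n_c - 1 c planes).
#'
#' @param shape the parent [block_shape()].
#' @param plane a [split_plane()] allowed for the shape.
#' @param spec a [polymorph_spec()].
#' @param tau0 monomer diffusion time in seconds (see [monomer_tau0()]).
#' @param cond a [solvent_conditions()] (sets k_B T).
#' @return rate constant in 1/s.
#' @export
split_rate_constant <- function(shape, plane, spec, tau0,
                                cond = solvent_conditions()) {
  stopifnot(tau0 > 0)
  dG <- interface_free_energy(spec, plane, shape)
  exp(dG / kBT_kcal(cond$temperature)) / tau0
}

#' Rate constant for a compound collision-with-split reaction
#'
#' Blocks whose contact faces mismatch in one or two dimensions can still
#' react through a virtual non-rectangular intermediate: the colliding pair
#' joins on the overlap of the contact faces and the overhanging material is
#' cleaved off, leaving only rectangular products.  The rate constant
#' combines the collision kernel with the cleavage rates,
#' \deqn{k = k_{join} \prod_i \tau_0 k_{split,i},}
#' one factor per cleavage plane (one plane for a single mismatched
#' dimension, a pair of planes when both cross dimensions mismatch).  When
#' the doubly-overhanging material can be divided by two different plane
#' pairs, both are evaluated and only the fastest is retained in the kinetic
#' system.
#'
#' @inheritParams collision_rate_constant
#' @param cleavage_choice `NULL` (fastest choice, the network default) or 1/2
#'   to force a specific decomposition of a doubly-overhanging block.
#' @param tau0 monomer diffusion time (s).
#' @return a list with elements `k` (m^3/s), `products` (list of product
#'   block shapes; pieces of one peptide are free monomers), `n_cleavages`,
#'   and `choice`; or `NULL` when the channel is geometrically forbidden.
#' @export
compound_join_split_rate <- function(sA, sB, contact_axis, cleavage_choice = NULL,
                                     spec, cond = solvent_conditions(),
                                     tau0 = monomer_tau0(spec, cond)) {
  stopifnot(inherits(sA, "species"), inherits(sB, "species"))
  ax <- match.arg(contact_axis, c("a", "b", "c"))
  resolve_join_channel(spec, as.numeric(sA$shape), as.numeric(sB$shape),
                       axis_index(ax), cond, tau0, choice = cleavage_choice)
}

#' Prune negligible reaction channels
#'
#' Any process with rate constant below the pruning threshold is discarded
#' from the rate-equation system.  The threshold applies to the rate constant
#' in the engine's internal units (m^3/s for bimolecular channels, 1/s for
#' unimolecular ones).
#'
#' @param k rate constant (>= 0).
#' @param threshold pruning threshold (default 1e-50).
#' @return `TRUE` if the channel is to be discarded.
#' @export
prune_rate <- function(k, threshold = 1e-50) {
  stopifnot(all(k >= 0))
  k < threshold
}

# ---- join-channel resolution (shared by ops, enumeration and oracle) -------

# Legality of joining two blocks along the b axis: two single sheets meet on
# their zip faces; two even-n_b blocks meet on b faces; anything else would
# create an inside-out species.
b_join_allowed <- function(nbA, nbB) {
  (nbA == 1 && nbB == 1) || (nbA %% 2 == 0 && nbB %% 2 == 0)
}

# Resolve the join channel between shapeA and shapeB (numeric length-3) on
# contact axis ax (1=a, 2=b, 3=c).  Returns NULL if forbidden, else a list
# (kind, k, products, n_cleavages, choice).  `choice` selects the cleavage
# decomposition when a block overhangs in both cross dimensions.
resolve_join_channel <- function(spec, shapeA, shapeB, ax, cond, tau0,
                                 choice = NULL) {
  if (ax == 2 && !b_join_allowed(shapeA[2], shapeB[2])) return(NULL)
  cr <- setdiff(1:3, ax)
  mism <- cr[shapeA[cr] != shapeB[cr]]
  overlap <- pmin(shapeA[cr], shapeB[cr])
  kjoin <- contact_kernel(spec, shapeA, shapeB, ax, overlap, cond)
  kBT <- kBT_kcal(cond$temperature)

  core <- pmin(shapeA, shapeB)
  core[ax] <- shapeA[ax] + shapeB[ax]

  if (length(mism) == 0) {
    return(list(kind = "join", k = kjoin, products = list(core),
                n_cleavages = 0L, choice = 1L))
  }

  # which block overhangs along each mismatched axis (cut the larger one)
  cut_block <- vapply(mism, function(d) if (shapeA[d] > shapeB[d]) 1L else 2L,
                      integer(1))

  # one cleavage event: cut `shape` along axis d down to `keep`; returns the
  # reduced block, the severed piece and the cleavage rate constant, or NULL
  # if the cut is forbidden by the zipper rule
  cleave <- function(shape, d, keep) {
    rest <- shape[d] - keep
    plane_axis <- c("a", "b", "c")[d]
    if (d == 2) {
      cls <- classify_b_split(shape[2], keep, rest)
      if (cls == "forbidden") return(NULL)
      plane_axis <- cls
    }
    ks <- split_rate_constant(as_shape(shape), split_plane(plane_axis), spec,
                              tau0, cond)
    reduced <- shape; reduced[d] <- keep
    piece <- shape; piece[d] <- rest
    list(reduced = reduced, piece = piece, k = ks)
  }

  orders <- if (length(mism) == 2 && cut_block[1] == cut_block[2]) {
    list(mism, rev(mism))            # doubly-overhanging block: two plane pairs
  } else {
    list(mism)
  }
  if (!is.null(choice)) {
    if (choice > length(orders)) return(NULL)
    orders <- orders[choice]
  }

  best <- NULL
  for (ci in seq_along(orders)) {
    shp <- list(shapeA, shapeB)
    pieces <- list()
    kfac <- 1
    ok <- TRUE
    for (d in orders[[ci]]) {
      bi <- cut_block[match(d, mism)]
      cl <- cleave(shp[[bi]], d, overlap[match(d, cr)])
      if (is.null(cl)) { ok <- FALSE; break }
      shp[[bi]] <- cl$reduced
      pieces <- c(pieces, list(cl$piece))
      kfac <- kfac * tau0 * cl$k
    }
    if (!ok) next
    k <- kjoin * kfac
    if (is.null(best) || k > best$k) {
      best <- list(kind = "join_split", k = k,
                   products = c(list(core), pieces),
                   n_cleavages = length(orders[[ci]]),
                   choice = if (is.null(choice)) ci else choice)
    }
  }
  best
}
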