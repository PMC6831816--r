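# Translational diffusion of blocks treated as rod-like particles, and the
# monomer diffusion timescale tau0 that anchors the Arrhenius split rates.

#' Solvent conditions
#'
#' @param temperature kelvin (default 300, the comparison temperature for the
#'   assembly barriers).
#' @param viscosity dynamic viscosity in Pa s (default 0.89e-3, water at
#'   about 25 C).
#' @return an object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 300, viscosity = 0.89e-3) {
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "solvent_conditions")
}

#' Translational diffusion coefficient of a rod-like block
#'
#' Maps a rectangular block to an equivalent cylinder: length L is the
#' longest dimension and the diameter d that of the circle with the block's
#' cross-sectional area.  The coefficient follows the cylinder result with
#' end-effect interpolation,
#' \deqn{D = k_B T (\ln p + \nu(p)) / (3 \pi \eta L),\quad p = L/d,}
#' \deqn{\nu(p) = 0.312 + 0.565/p + 0.100/p^2,}
#' with the aspect ratio clamped below at p = 1 for compact blocks.  Coupling
#' between orientation and direction of motion is ignored.
#'
#' @param dims numeric length-3 vector of block dimensions in Angstrom.
#' @param cond a [solvent_conditions()].
#' @return diffusion coefficient in m^2/s.
#' @export
rod_diffusion_coefficient <- function(dims, cond = solvent_conditions()) {
  dims <- as.numeric(dims)
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0))
    stop("dims must be three positive lengths (Angstrom)")
  stopifnot(inherits(cond, "solvent_conditions"))
  L <- max(dims)
  cross <- prod(dims) / L
  d <- 2 * sqrt(cross / pi)
  p <- max(L / d, 1)
  nu <- 0.312 + 0.565 / p + 0.100 / p^2
  .const$kB * cond$temperature * (log(p) + nu) /
    (3 * pi * cond$viscosity * L * .const$ang)
}

#' Monomer diffusion timescale tau0
#'
#' Time for a single peptide to diffuse its own length (three-dimensional
#' mean-squared-displacement convention): tau0 = l^2 / (6 D), where l is the
#' longest per-peptide cell dimension and D the rod diffusion coefficient of
#' the monomer block.
#'
#' @param spec a [polymorph_spec()].
#' @param cond a [solvent_conditions()].
#' @return tau0 in seconds.
#' @export
monomer_tau0 <- function(spec, cond = solvent_conditions()) {
  cell <- per_peptide_cell(spec)
  D <- rod_diffusion_coefficient(cell, cond)
  (max(cell) * .const$ang)^2 / (6 * D)
}
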