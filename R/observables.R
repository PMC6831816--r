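# Polymorph-resolved observables: mass fractions by aggregate
# dimensionality, cross-sectional aspect ratios, crossover concentration.

#' System state
#'
#' A multiset of species counts together with the simulation volume and
#' simulated time.
#'
#' @param species a data frame with columns `tag` ("MONOMER", "AP", "P"),
#'   `n_a`, `n_b`, `n_c`, `count`.
#' @param volume simulation volume in m^3.
#' @param time simulated time in seconds.
#' @return an object of class `system_state`.
#' @export
system_state <- function(species, volume, time = 0) {
  req <- c("tag", "n_a", "n_b", "n_c", "count")
  if (!is.data.frame(species) || !all(req %in% names(species)))
    stop("species must be a data frame with columns tag, n_a, n_b, n_c, count")
  if (any(species$count < 0)) stop("species counts must be non-negative")
  stopifnot(volume > 0)
  structure(list(species = species[req], volume = volume, time = time),
            class = "system_state")
}

state_table <- function(state) {
  if (inherits(state, "system_state")) state$species else state
}

#' Polymorph-resolved mass fractions by aggregate dimensionality
#'
#' Peptide-mass-weighted fractions of the total peptide pool incorporated in
#' aggregates of each polymorph: `1dplus` counts peptides in any tagged
#' aggregate (size >= 2); `2d` those in aggregates extended in at least two
#' of the three shape indices; `3d` those extended in all three.  By
#' construction `frac_3d <= frac_2d <= frac_1dplus` for each polymorph.
#'
#' @param state a [system_state()] or its species data frame.
#' @return one-row data frame with columns
#'   `frac_1dplus_ap`, `frac_2d_ap`, `frac_3d_ap` and the `_p` equivalents.
#' @export
mass_fractions <- function(state) {
  sp <- state_table(state)
  pep <- sp$n_a * sp$n_b * sp$n_c
  total <- sum(pep * sp$count)
  ndim <- (sp$n_a > 1) + (sp$n_b > 1) + (sp$n_c > 1)
  frac <- function(tag, min_dim) {
    if (total == 0) return(0)
    sel <- sp$tag == tag & ndim >= min_dim
    sum(pep[sel] * sp$count[sel]) / total
  }
  data.frame(frac_1dplus_ap = frac("AP", 0), frac_2d_ap = frac("AP", 2),
             frac_3d_ap = frac("AP", 3),
             frac_1dplus_p = frac("P", 0), frac_2d_p = frac("P", 2),
             frac_3d_p = frac("P", 3))
}

#' Mean cross-sectional aspect ratio of a polymorph
#'
#' Number-weighted mean of n_a/n_b over the aggregates of one polymorph,
#' with free monomers counted in both polymorph averages at ratio 1.  In the
#' monomer-only limit (no aggregates of the class) the mean is 1 by
#' convention.  An average pulled above 1 signals sheet-pair/ribbon growth
#' led by the a interface; the first steric zipper appears at n_b = 2.
#'
#' @param state a [system_state()] or its species data frame.
#' @param polymorph `"AP"` or `"P"`.
#' @return dimensionless mean aspect ratio.
#' @export
mean_aspect_ratio <- function(state, polymorph = c("AP", "P")) {
  polymorph <- match.arg(polymorph)
  sp <- state_table(state)
  sel <- sp$tag == polymorph | sp$tag == "MONOMER"
  n <- sp$count[sel]
  if (sum(n) == 0) return(1)
  ratio <- sp$n_a[sel] / sp$n_b[sel]
  sum(ratio * n) / sum(n)
}

#' Crossover concentration between AP and P dominance
#'
#' Locates the concentration at which the final aggregated masses of the two
#' polymorphs are equal, by log-linear interpolation of the zero crossing of
#' (AP - P) across a concentration series.  Scanning upward in
#' concentration, the first crossing from AP excess to P excess is used.
#'
#' @param final_records data frame with columns `concentration` (molar) and
#'   `mass_ap`, `mass_p` (final aggregated masses or mass fractions).
#' @return a list with `status` (`"crossover"`, `"ap_dominated"`,
#'   `"p_dominated"` or `"mixed"`), `crossover` (molar; `NA` when one-sided)
#'   and `bracket` (the two concentrations bracketing the crossing).
#' @examples
#' crossover_concentration(data.frame(
#'   concentration = c(1.5e-3, 15e-3), mass_ap = c(0.6, 0.2),
#'   mass_p = c(0.3, 0.5)))  # ~4.7 mM
#' @export
crossover_concentration <- function(final_records) {
  req <- c("concentration", "mass_ap", "mass_p")
  if (!all(req %in% names(final_records)))
    stop("final_records needs columns concentration, mass_ap, mass_p")
  rec <- final_records[order(final_records$concentration), ]
  if (nrow(rec) < 2) stop("need at least two concentrations")
  d <- rec$mass_ap - rec$mass_p
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0)
  if (length(idx) == 0) {
    status <- if (all(d >= 0)) "ap_dominated" else
      if (all(d <= 0)) "p_dominated" else "mixed"
    return(list(status = status, crossover = NA_real_,
                bracket = range(rec$concentration)))
  }
  i <- idx[1]
  lc <- log10(rec$concentration[c(i, i + 1)])
  w <- d[i] / (d[i] - d[i + 1])
  list(status = "crossover",
       crossover = 10^(lc[1] + w * (lc[2] - lc[1])),
       bracket = rec$concentration[c(i, i + 1)])
}
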