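# Event-driven stochastic simulation of the assembly reaction network.

#' Run configuration
#'
#' Collects everything one stochastic assembly run needs.  Concentration is
#' imposed through the simulation volume, V = N / (c * N_Avogadro); peptide
#' count is the scale knob, with intensive observables (mass fractions,
#' aspect ratios) the intended outputs.
#'
#' @param concentration peptide concentration in mol/L.
#' @param total_peptides number of peptides in the simulation volume.
#' @param ap_spec,p_spec the two [polymorph_spec()]s.
#' @param polymorphs character subset of `c("AP", "P")` enabled in the run.
#' @param solvent a [solvent_conditions()].
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @param replicates number of replicate trajectories.
#' @param max_time stop criterion: simulated seconds.
#' @param max_events stop criterion: executed reaction events (default
#'   `25 * total_peptides`, past the plateau of the 1D+ fraction at the
#'   study conditions).
#' @param n_report number of log-spaced observation times.
#' @param t_report_min first observation time (s).
#' @param prune_threshold discard channels with smaller rate constants.
#' @param live_floor bimolecular channels with rate constants below this are
#'   kept in the network but served through an exact upper-bounded background
#'   group rather than the hot channel array (see the methods vignette).
#' @return an object of class `run_config`.
#' @export
run_config <- function(concentration, total_peptides = 1e4,
                       ap_spec = default_ap_spec(), p_spec = default_p_spec(),
                       polymorphs = c("AP", "P"),
                       solvent = solvent_conditions(), seed = 1L,
                       replicates = 1L, max_time = 1e4,
                       max_events = 25 * total_peptides,
                       n_report = 60L, t_report_min = 1e-9,
                       prune_threshold = 1e-50, live_floor = 1e-40) {
  stopifnot(is.numeric(concentration), concentration > 0,
            total_peptides >= 2, replicates >= 1,
            max_time > 0, max_events >= 1,
            inherits(solvent, "solvent_conditions"))
  polymorphs <- match.arg(polymorphs, c("AP", "P"), several.ok = TRUE)
  stopifnot(inherits(ap_spec, "polymorph_spec"), ap_spec$label == "AP",
            inherits(p_spec, "polymorph_spec"), p_spec$label == "P")
  volume <- total_peptides / (concentration * 1e3 * .const$avogadro)
  structure(list(
    concentration = concentration,
    total_peptides = as.double(total_peptides),
    volume = volume,
    ap_spec = ap_spec, p_spec = p_spec, polymorphs = polymorphs,
    solvent = solvent, seed = as.integer(seed),
    replicates = as.integer(replicates),
    max_time = max_time, max_events = as.double(max_events),
    n_report = as.integer(n_report), t_report_min = t_report_min,
    prune_threshold = prune_threshold, live_floor = live_floor
  ), class = "run_config")
}

spec_for_engine <- function(spec, cond) {
  cell <- per_peptide_cell(spec)
  en <- spec$energies
  list(cell = as.numeric(cell),
       herring = spec$symmetry == "herringbone_p2",
       dG = as.numeric(c(en$dG_a, en$dG_b, en$dG_zip, en$dG_c)),
       eps = as.numeric(en$eps), eps_prime = as.numeric(en$eps_prime),
       tau0 = monomer_tau0(spec, cond))
}

#' Commit a colliding monomer pair to a polymorph
#'
#' When two free monomers collide, the nascent dimer commits to the parallel
#' or antiparallel geometry with equal probability; a committed peptide
#' returns to the uncommitted state only by leaving its assembly.  Mixed
#' P/AP aggregates never form.
#'
#' @param n number of independent commitments to draw.
#' @param polymorphs the enabled polymorph labels.
#' @return character vector of committed labels.
#' @export
commit_polymorph <- function(n = 1, polymorphs = c("AP", "P")) {
  polymorphs[sample.int(length(polymorphs), n, replace = TRUE)]
}

#' Run replicate stochastic assembly trajectories
#'
#' Samples the aggregation-fragmentation network with the event-driven
#' Gillespie algorithm: all allowed joins, compound collision-with-split
#' reactions and splits among present species are enumerated (rate constants
#' computed once per reactant signature and cached), one event is selected
#' with probability proportional to its propensity, the waiting time is
#' exponential in the total propensity, and the state is updated with
#' incremental reuse of prior rate information.  Trajectories are
#' reproducible: replicate r is seeded with `seed + r`.
#'
#' @param config a [run_config()].
#' @param track_occupancy record time-weighted occupancy of every visited
#'   state (feasible for small systems only; used for master-equation
#'   checks).
#' @param audit return the cached channel table (reaction signature, class,
#'   rate constant) of each replicate.
#' @return an object of class `assembly_run`: list with `config` and
#'   `replicates`, each replicate holding `trajectory` (long-format species
#'   counts at the report times), `final` (final species table), `status`,
#'   `time`, `events` and `diagnostics` (plus `occupancy`/`audit` on
#'   request).
#' @export
run_assembly <- function(config, track_occupancy = FALSE, audit = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cond <- config$solvent
  engAP <- spec_for_engine(config$ap_spec, cond)
  engP <- spec_for_engine(config$p_spec, cond)
  enabled <- match(config$polymorphs, c("AP", "P"))
  grid <- 10^seq(log10(config$t_report_min), log10(config$max_time),
                 length.out = config$n_report)
  reps <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(config$seed + r)
    reps[[r]] <- cpp_run_assembly(
      engAP, engP, enabled,
      .const$kB * cond$temperature, cond$viscosity,
      kBT_kcal(cond$temperature),
      config$total_peptides, config$volume,
      config$max_time, config$max_events, grid,
      config$prune_threshold, config$live_floor,
      track_occupancy, audit)
    reps[[r]]$replicate <- r
  }
  structure(list(config = config, replicates = reps), class = "assembly_run")
}

#' @export
print.assembly_run <- function(x, ...) {
  cat(sprintf("assembly run: %g peptides at %.3g M, %d replicate(s)\n",
              x$config$total_peptides, x$config$concentration,
              x$config$replicates))
  for (r in x$replicates)
    cat(sprintf("  replicate %d: %s after %g events, t = %.3g s, %d species\n",
                r$replicate, r$status, r$events, r$time, nrow(r$final)))
  invisible(x)
}

#' Observables along recorded trajectories
#'
#' @param run an [run_assembly()] result.
#' @return data frame with one row per replicate and report time: mass
#'   fractions by dimensionality for both polymorphs, mean aspect ratios and
#'   the number of distinct species present.
#' @export
compute_observables <- function(run) {
  stopifnot(inherits(run, "assembly_run"))
  out <- lapply(run$replicates, function(rep) {
    tr <- rep$trajectory
    do.call(rbind, lapply(split(tr, tr$record), function(snap) {
      cbind(data.frame(replicate = rep$replicate, time = snap$time[1]),
            mass_fractions(snap),
            data.frame(mean_aspect_ap = mean_aspect_ratio(snap, "AP"),
                       mean_aspect_p = mean_aspect_ratio(snap, "P"),
                       species_count = nrow(snap)))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decade concentration sweep
#'
#' Runs replicate trajectories over a concentration series (by default the
#' decade series 5 nM, 50 nM, ..., 50 mM) under otherwise identical
#' conditions.
#'
#' @param concentrations concentrations in mol/L.
#' @param ... passed to [run_config()] (seed, replicates, total_peptides, ...).
#' @return an object of class `assembly_sweep`: list of `assembly_run`s.
#' @export
sweep_assembly <- function(concentrations = 5e-9 * 10^(0:7), ...) {
  runs <- lapply(concentrations, function(conc)
    run_assembly(run_config(concentration = conc, ...)))
  structure(list(concentrations = concentrations, runs = runs),
            class = "assembly_sweep")
}

#' Final polymorph-resolved aggregated mass of a sweep
#'
#' @param sweep an [sweep_assembly()] result.
#' @return data frame with one row per concentration: replicate-averaged
#'   final 1D+ mass fractions (`mass_ap`, `mass_p`) plus their min/max
#'   spread over replicates.
#' @export
final_polymorph_mass <- function(sweep) {
  stopifnot(inherits(sweep, "assembly_sweep"))
  rows <- mapply(function(conc, run) {
    fr <- do.call(rbind, lapply(run$replicates,
                                function(rep) mass_fractions(rep$final)))
    data.frame(concentration = conc,
               mass_ap = mean(fr$frac_1dplus_ap),
               mass_p = mean(fr$frac_1dplus_p),
               min_ap = min(fr$frac_1dplus_ap), max_ap = max(fr$frac_1dplus_ap),
               min_p = min(fr$frac_1dplus_p), max_p = max(fr$frac_1dplus_p))
  }, sweep$concentrations, sweep$runs, SIMPLIFY = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-concentration summary of a sweep
#'
#' Mean, minimum and maximum over replicates of the final observables,
#' matching the min/max spread convention used for replicate ensembles.
#'
#' @param sweep an [sweep_assembly()] result.
#' @return data frame, one row per concentration and observable.
#' @export
sweep_summary <- function(sweep) {
  stopifnot(inherits(sweep, "assembly_sweep"))
  rows <- mapply(function(conc, run) {
    fr <- do.call(rbind, lapply(run$replicates, function(rep) {
      cbind(mass_fractions(rep$final),
            data.frame(mean_aspect_ap = mean_aspect_ratio(rep$final, "AP"),
                       mean_aspect_p = mean_aspect_ratio(rep$final, "P")))
    }))
    do.call(rbind, lapply(names(fr), function(v)
      data.frame(concentration = conc, observable = v,
                 mean = mean(fr[[v]]), min = min(fr[[v]]), max = max(fr[[v]]))))
  }, sweep$concentrations, sweep$runs, SIMPLIFY = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
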