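# Structured run configuration files (YAML).

config_known_keys <- c(
  "concentration", "concentrations", "total_peptides", "seed", "replicates",
  "max_time", "max_events", "n_report", "t_report_min", "prune_threshold",
  "live_floor", "polymorphs", "solvent", "ap_spec", "p_spec")

spec_from_list <- function(x, label) {
  lat <- x$lattice
  if (is.null(lat)) stop(sprintf("%s_spec needs a lattice block", tolower(label)))
  lattice <- lattice_params(lat$a, lat$b, lat$c,
                            gamma = lat$gamma %||% 90,
                            peptides_per_cell = lat$peptides_per_cell %||% c(1, 1, 1))
  en <- x$energies
  if (is.null(en)) stop(sprintf("%s_spec needs an energies block", tolower(label)))
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  energies <- energy_table(dG_a = num_or_na(en$dG_a), dG_b = num_or_na(en$dG_b),
                           dG_zip = num_or_na(en$dG_zip), dG_c = num_or_na(en$dG_c),
                           eps = num_or_na(en$eps),
                           eps_prime = num_or_na(en$eps_prime))
  symmetry <- x$symmetry %||% if (label == "P") "herringbone_p2" else "rectangular_p1"
  polymorph_spec(label, symmetry, lattice, energies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from YAML
#'
#' Reads a structured text configuration, validates it against the schema
#' (unknown or missing required keys are rejected with actionable messages;
#' sign-convention mistakes in the energies trigger warnings) and fills in
#' documented defaults.  A `concentrations` list instead of a single
#' `concentration` marks a sweep configuration; [run_sweep_from_config()]
#' handles either.
#'
#' @param path path to a YAML file.
#' @return a [run_config()] (or list of them for a sweep), with the
#'   effective configuration attached as attribute `"effective"`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_known_keys)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s (known keys: %s)",
                 paste(unknown, collapse = ", "),
                 paste(config_known_keys, collapse = ", ")))
  concs <- raw$concentrations %||% raw$concentration
  if (is.null(concs))
    stop("configuration must set `concentration` (mol/L) or `concentrations`")
  concs <- as.numeric(concs)
  if (any(!is.finite(concs)) || any(concs <= 0))
    stop("concentrations must be positive numbers in mol/L")
  ap <- if (is.null(raw$ap_spec)) default_ap_spec() else spec_from_list(raw$ap_spec, "AP")
  p <- if (is.null(raw$p_spec)) default_p_spec() else spec_from_list(raw$p_spec, "P")
  solv <- if (is.null(raw$solvent)) solvent_conditions() else
    solvent_conditions(temperature = raw$solvent$temperature %||% 300,
                       viscosity = raw$solvent$viscosity %||% 0.89e-3)
  total <- raw$total_peptides %||% 1e4
  make <- function(conc) run_config(
    concentration = conc, total_peptides = total,
    ap_spec = ap, p_spec = p,
    polymorphs = as.character(raw$polymorphs %||% c("AP", "P")),
    solvent = solv, seed = raw$seed %||% 1L,
    replicates = raw$replicates %||% 1L,
    max_time = raw$max_time %||% 1e4,
    max_events = raw$max_events %||% (25 * total),
    n_report = raw$n_report %||% 60L,
    t_report_min = raw$t_report_min %||% 1e-9,
    prune_threshold = raw$prune_threshold %||% 1e-50,
    live_floor = raw$live_floor %||% 1e-40)
  if (length(concs) == 1) {
    cfg <- make(concs)
    attr(cfg, "effective") <- effective_config(cfg)
    cfg
  } else {
    cfgs <- lapply(concs, make)
    attr(cfgs, "effective") <- lapply(cfgs, effective_config)
    cfgs
  }
}

#' Effective configuration of a run
#'
#' Expands a [run_config()] back into the fully explicit key-value form
#' (defaults filled in), suitable for logging; re-loading an effective
#' configuration reproduces identical trajectories.
#'
#' @param config a [run_config()].
#' @return a named list mirroring the YAML schema.
#' @export
effective_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec_list <- function(s) list(
    symmetry = s$symmetry,
    lattice = list(a = s$lattice$a, b = s$lattice$b, c = s$lattice$c,
                   gamma = s$lattice$gamma,
                   peptides_per_cell = s$lattice$peptides_per_cell),
    energies = Filter(function(x) !is.na(x),
                      list(dG_a = s$energies$dG_a, dG_b = s$energies$dG_b,
                           dG_zip = s$energies$dG_zip, dG_c = s$energies$dG_c,
                           eps = s$energies$eps,
                           eps_prime = s$energies$eps_prime)))
  list(concentration = config$concentration,
       total_peptides = config$total_peptides,
       seed = config$seed, replicates = config$replicates,
       max_time = config$max_time, max_events = config$max_events,
       n_report = config$n_report, t_report_min = config$t_report_min,
       prune_threshold = config$prune_threshold,
       live_floor = config$live_floor,
       polymorphs = config$polymorphs,
       solvent = list(temperature = config$solvent$temperature,
                      viscosity = config$solvent$viscosity),
       ap_spec = spec_list(config$ap_spec),
       p_spec = spec_list(config$p_spec))
}

#' Run a configuration file
#'
#' @param path YAML configuration path (single-concentration or sweep).
#' @return an `assembly_run` or `assembly_sweep`.
#' @export
run_sweep_from_config <- function(path) {
  cfg <- load_config(path)
  if (inherits(cfg, "run_config")) return(run_assembly(cfg))
  runs <- lapply(cfg, run_assembly)
  structure(list(concentrations = vapply(cfg, `[[`, numeric(1), "concentration"),
                 runs = runs), class = "assembly_sweep")
}
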