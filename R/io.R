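# Configuration, serialization, fixtures and small scientific utilities.

# average residue masses (Da) of the 20 standard amino acids
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01524

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water, in daltons.
#'
#' @param sequence one-letter amino-acid string over the 20 standard letters.
#' @return mass in Da.
#' @examples
#' peptide_average_mass("IFQINS")  # 720.82
#' @export
peptide_average_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 1) stop("sequence must contain at least one residue")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(.residue_mass))
  if (length(bad))
    stop(sprintf("unknown amino-acid letter(s): %s",
                 paste(unique(bad), collapse = ", ")))
  sum(.residue_mass[aa]) + .water_mass
}

#' Synthetic block free-energy table
#'
#' Generates reference block free energies G_ijk from known per-interface
#' terms under the additive model used by the estimators, emulating the
#' averaged minimised-block energies of the physical workflow.  A block
#' (i,j,k) contains (i-1) a planes of energy j*k*dG_a, floor(j/2) zipper and
#' floor((j-1)/2) b planes of energy i*k*dG_zip / i*k*dG_b, and (k-1) c
#' planes of energy i*j*dG_c; for the herringbone polymorph the zipper
#' planes carry the half-c overhang deficit (factor k - 1/2 instead of k),
#' matching the 9.5 divisor of the zipper estimator.  Gaussian noise of
#' standard deviation `sigma` emulates sampling error; at `sigma = 0` the
#' estimators recover the generating terms exactly.
#'
#' @param energies an [energy_table()] supplying dG_a, dG_b, dG_zip, dG_c.
#' @param polymorph `"AP"` or `"P"`.
#' @param sigma noise standard deviation, kcal/mol (>= 0).
#' @param shapes integer matrix of shapes to emit (rows i,j,k); defaults to
#'   the set the estimators require.
#' @param n_samples nominal number of averaged blocks recorded as metadata.
#' @return data frame with columns `n_a`, `n_b`, `n_c`, `G`, `n_samples`,
#'   `ese`; reproducible under `set.seed()`.
#' @export
synthetic_block_energies <- function(energies, polymorph = c("AP", "P"),
                                     sigma = 0, shapes = required_block_shapes(),
                                     n_samples = 50L) {
  polymorph <- match.arg(polymorph)
  stopifnot(inherits(energies, "energy_table"), sigma >= 0, n_samples >= 1)
  if (anyNA(c(energies$dG_a, energies$dG_b, energies$dG_zip, energies$dG_c)))
    stop("generator needs dG_a, dG_b, dG_zip and dG_c")
  shapes <- as.matrix(shapes)
  i <- shapes[, 1]; j <- shapes[, 2]; k <- shapes[, 3]
  kzip <- if (polymorph == "P") k - 0.5 else k
  G <- (i - 1) * j * k * energies$dG_a +
    floor(j / 2) * i * kzip * energies$dG_zip +
    floor((j - 1) / 2) * i * k * energies$dG_b +
    (k - 1) * i * j * energies$dG_c
  if (sigma > 0) G <- G + stats::rnorm(length(G), 0, sigma)
  data.frame(n_a = i, n_b = j, n_c = k, G = G,
             n_samples = as.integer(n_samples),
             ese = sigma / sqrt(n_samples))
}

#' Read/write block free-energy tables as TSV
#'
#' Tab-separated with a header row (`n_a`, `n_b`, `n_c`, `G`, optionally
#' `n_samples`, `ese`), '.' decimal separator.
#'
#' @param records data frame of block energy records.
#' @param path file path.
#' @return `read_block_energies` returns the data frame;
#'   `write_block_energies` returns `path` invisibly.
#' @export
write_block_energies <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_energies
#' @export
read_block_energies <- function(path) {
  rec <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("n_a", "n_b", "n_c", "G") %in% names(rec)))
    stop("block energy table needs columns n_a, n_b, n_c, G")
  rec
}

#' Write observables or summary tables as TSV
#'
#' @param records data frame (e.g. from [compute_observables()] or
#'   [sweep_summary()]).
#' @param path file path.
#' @param meta optional named list written as a `# key: value` header
#'   (seed, package version, config hash).
#' @return `path`, invisibly.
#' @export
write_observables <- function(records, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = " "),
                              character(1))), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}
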