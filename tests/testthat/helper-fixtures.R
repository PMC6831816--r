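# shared fixtures: reference specs, a soft-energy toy parameterisation for
# reversible-network tests, and small state builders

ap <- default_ap_spec()
pp <- default_p_spec()
cond300 <- solvent_conditions()

# soft energies give split rates comparable to collision rates in a small
# volume, so toy networks reach stationarity quickly
soft_ap_spec <- function() {
  polymorph_spec("AP", "rectangular_p1",
                 lattice_params(20.0, 19.1, 4.8, 83, c(1, 2, 1)),
                 energy_table(dG_a = -1.0, dG_b = -0.8, dG_zip = -1.5,
                              dG_c = -2.0))
}

make_state <- function(..., volume = 1e-20, time = 0) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(tag = r[[1]], n_a = r[[2]], n_b = r[[3]], n_c = r[[4]],
               count = r[[5]])))
  system_state(df, volume = volume, time = time)
}

expect_shape_valid <- function(n_a, n_b, n_c) {
  expect_true(n_a >= 1 && n_b >= 1 && n_c >= 1)
  expect_true(n_b == 1 || n_b %% 2 == 0)
}

# parse "TAG:i,j,k" signatures from enumerate_reactions output
parse_sigs <- function(products) {
  lapply(strsplit(products, " \\+ ")[[1]], function(s) {
    parts <- strsplit(s, "[:,]")[[1]]
    list(tag = parts[1], shape = as.integer(parts[2:4]))
  })
}
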