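test_that("collision kernel follows 2 e^-3 (D_A + D_B) sqrt(2A)", {
  mono <- species("MONOMER")
  k <- collision_rate_constant(mono, mono, "c", ap, cond300)
  D <- rod_diffusion_coefficient(per_peptide_cell(ap), cond300)
  expect_equal(k, 2 * exp(-3) * 2 * D * sqrt(2 * 20.0 * 9.55 * 1e-20))
  # the printed worked magnitude: D ~ 3e-10 m^2/s on a 9.55 x 4.8 A face
  # gives k ~ 5.7e-20 m^3/s; our monomer kernel sits on that scale
  chain <- species("AP", block_shape(1, 1, 5))
  k2 <- collision_rate_constant(mono, chain, "c", ap, cond300)
  expect_gt(k2, 1e-20); expect_lt(k2, 2e-19)
  # symmetric in its arguments
  expect_equal(collision_rate_constant(chain, mono, "c", ap, cond300), k2)
  # mismatched faces are not simple joins
  expect_error(collision_rate_constant(chain, species("AP", block_shape(2, 1, 5)),
                                       "c", ap, cond300), "not a simple join")
})

test_that("propensities carry number densities and the homodimer factor", {
  expect_equal(bimolecular_propensity(1, 10, 10, 1, homo = TRUE), 45)
  expect_equal(bimolecular_propensity(1, 2, 3, 1), 6)
  expect_equal(bimolecular_propensity(5, 0, 3, 1), 0)
  expect_equal(bimolecular_propensity(5, 3, 0, 1), 0)
  expect_equal(bimolecular_propensity(2, 4, 5, 10), 4)
})

test_that("split rates are Arrhenius in the buried-interface energy", {
  tau0 <- monomer_tau0(ap, cond300)
  k <- split_rate_constant(block_shape(1, 1, 8), split_plane("c"), ap, tau0,
                           cond300)
  expect_equal(k * tau0, exp(-29.3 / kBT_kcal(300)))
  expect_equal(k * tau0, 4.5e-22, tolerance = 0.02)
  # zero-energy interface splits at the attempt frequency 1/tau0
  zero <- polymorph_spec("AP", "rectangular_p1", ap$lattice,
                         energy_table(dG_a = 0, dG_b = -1, dG_zip = -1,
                                      dG_c = -1))
  expect_equal(split_rate_constant(block_shape(3, 1, 1), split_plane("a"),
                                   zero, tau0, cond300), 1 / tau0)
  # monotone: a larger buried interface splits strictly more slowly
  ks <- vapply(1:6, function(nc)
    split_rate_constant(block_shape(2, 2, nc), split_plane("a"), ap, tau0,
                        cond300), numeric(1))
  expect_true(all(diff(ks) < 0))
  ks_p <- vapply(c(1, 2, 4, 6, 8), function(nb)
    split_rate_constant(block_shape(2, nb, 3), split_plane("a"), pp, tau0,
                        cond300), numeric(1))
  expect_true(all(diff(ks_p) < 0))
})

test_that("compound collisions combine joining and cleavage (worked case)", {
  tau0 <- monomer_tau0(ap, cond300)
  sA <- species("AP", block_shape(3, 4, 4))
  sB <- species("AP", block_shape(2, 4, 6))
  ch <- compound_join_split_rate(sA, sB, "a", spec = ap, cond = cond300,
                                 tau0 = tau0)
  expect_equal(ch$n_cleavages, 1L)
  shapes <- lapply(ch$products, as.numeric)
  expect_setequal(lapply(shapes, paste, collapse = ","),
                  list("5,4,4", "2,4,2"))
  # rate is tau0 * k_c(2,4) * k_join with the join kernel on the 4 x 4
  # overlap face and the diffusion coefficients of the original blocks
  kc <- split_rate_constant(block_shape(2, 4, 6), split_plane("c"), ap, tau0,
                            cond300)
  cell <- per_peptide_cell(ap)
  DA <- rod_diffusion_coefficient(cell * c(3, 4, 4), cond300)
  DB <- rod_diffusion_coefficient(cell * c(2, 4, 6), cond300)
  kjoin <- 2 * exp(-3) * (DA + DB) *
    sqrt(2 * cell[["b"]] * 4 * cell[["c"]] * 4 * 1e-20)
  expect_equal(ch$k, tau0 * kc * kjoin, tolerance = 1e-12)
})

test_that("matching shapes reduce the compound channel to the simple join", {
  sA <- species("AP", block_shape(2, 4, 3))
  ch <- compound_join_split_rate(sA, sA, "a", spec = ap, cond = cond300)
  expect_equal(ch$kind, "join")
  expect_equal(ch$n_cleavages, 0L)
  expect_equal(ch$k, collision_rate_constant(sA, sA, "a", ap, cond300))
})

test_that("doubly-overhanging collisions keep only the fastest plane pair", {
  # soft energies keep both cleavage exponentials well above underflow
  soft <- soft_ap_spec()
  tau0 <- monomer_tau0(soft, cond300)
  sA <- species("AP", block_shape(2, 4, 4))
  sB <- species("AP", block_shape(2, 6, 8))
  ch1 <- compound_join_split_rate(sA, sB, "a", 1, soft, cond300, tau0)
  ch2 <- compound_join_split_rate(sA, sB, "a", 2, soft, cond300, tau0)
  best <- compound_join_split_rate(sA, sB, "a", NULL, soft, cond300, tau0)
  expect_equal(ch1$n_cleavages, 2L)
  # the two plane pairs bury different energies, so their rates differ by a
  # finite ratio
  expect_gt(abs(log(ch1$k / ch2$k)), 0.1)
  expect_equal(best$k, max(ch1$k, ch2$k))
  expect_length(best$products, 3)  # two-to-three body process
  # peptide conservation in both decompositions
  for (ch in list(ch1, ch2))
    expect_equal(sum(vapply(ch$products, prod, numeric(1))),
                 prod(sA$shape) + prod(sB$shape))
  # symmetric under exchange of the colliding species
  swapped <- compound_join_split_rate(sB, sA, "a", NULL, soft, cond300, tau0)
  expect_equal(swapped$k / best$k, 1)
})

test_that("no emitted channel creates an inside-out species", {
  set.seed(11)
  tau0 <- monomer_tau0(ap, cond300)
  nbs <- c(1, 2, 4, 6)
  for (rep in 1:200) {
    shA <- c(sample(1:5, 1), sample(nbs, 1), sample(1:8, 1))
    shB <- c(sample(1:5, 1), sample(nbs, 1), sample(1:8, 1))
    axis <- sample(c("a", "b", "c"), 1)
    ch <- compound_join_split_rate(species(if (all(shA == 1)) "MONOMER" else "AP",
                                           block_shape(shA[1], shA[2], shA[3])),
                                   species(if (all(shB == 1)) "MONOMER" else "AP",
                                           block_shape(shB[1], shB[2], shB[3])),
                                   axis, NULL, ap, cond300, tau0)
    if (is.null(ch)) next
    expect_gte(ch$k, 0)
    for (p in ch$products) {
      p <- as.numeric(p)
      expect_shape_valid(p[1], p[2], p[3])
    }
    expect_equal(sum(vapply(ch$products, prod, numeric(1))),
                 prod(shA) + prod(shB))
  }
})

test_that("pruning discards channels below the threshold", {
  expect_true(prune_rate(1e-51))
  expect_false(prune_rate(1e-49))
  expect_true(prune_rate(0))
  expect_error(prune_rate(-1))
})
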