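test_that("b-direction splits classify into zipper, b-plane and forbidden", {
  expect_equal(classify_b_split(2, 1, 1), "zip")
  expect_equal(classify_b_split(4, 2, 2), "b")
  expect_equal(classify_b_split(4, 1, 3), "forbidden")
  expect_error(classify_b_split(4, 2, 3), "conserve")
  # under the inside-out exclusion no reachable species has odd n_b > 1:
  # every allowed split of a valid parent yields valid parts
  for (parent in seq(2, 12, by = 2)) {
    for (left in 1:(parent - 1)) {
      cls <- classify_b_split(parent, left, parent - left)
      parts_valid <- all(c(left, parent - left) %in%
                           c(1, seq(2, parent, by = 2)))
      expect_equal(cls != "forbidden", parts_valid)
    }
  }
})

test_that("interface free energies follow the rectangular and herringbone rules", {
  expect_equal(interface_free_energy(ap, split_plane("a"), block_shape(1, 4, 3)),
               12 * -9.2)
  expect_equal(interface_free_energy(pp, split_plane("a"), block_shape(1, 4, 3)),
               (2 * 4 - 1) * (-18.84 / 2) * 2.5)
  expect_equal(interface_free_energy(pp, split_plane("b"), block_shape(2, 4, 2)),
               (-18.84 + 2 * -5.99) * 1.5)
  expect_equal(interface_free_energy(pp, split_plane("zip"), block_shape(2, 2, 3)),
               2 * -25.3 * 2.5)
  # single-sheet association on the herringbone a face buries half a zipper
  for (nc in 1:4)
    expect_equal(interface_free_energy(pp, split_plane("a"), block_shape(3, 1, nc)),
                 (-18.84 / 2) * (nc - 0.5))
  # linear in n_c (AP) and in n_c - 1/2 (P)
  for (plane in c("a", "b", "zip")) {
    e_ap <- vapply(1:5, function(nc)
      interface_free_energy(ap, split_plane(plane), block_shape(2, 4, nc)),
      numeric(1))
    expect_equal(e_ap / (1:5), rep(e_ap[1], 5))
    e_p <- vapply(1:5, function(nc)
      interface_free_energy(pp, split_plane(plane), block_shape(2, 4, nc)),
      numeric(1))
    expect_equal(e_p / (1:5 - 0.5), rep(e_p[1] / 0.5, 5))
  }
})

test_that("large-aggregate limits reduce to eps/2 and eps + eps'", {
  lim <- large_aggregate_limits(pp$energies)
  expect_equal(unname(lim["a"]), -9.42)
  expect_equal(unname(lim["b"]), -24.83)
  zero <- energy_table(dG_zip = -1, dG_c = -1, eps = 0, eps_prime = 0)
  expect_equal(unname(large_aggregate_limits(zero)), c(0, 0))
  expect_equal(unname(large_aggregate_limits(ap$energies)), c(-9.2, -6.2))
})

test_that("interface estimators invert the additive generator exactly", {
  for (pm in c("AP", "P")) {
    truth <- energy_table(dG_a = -9.2, dG_b = -6.2, dG_zip = -16.4, dG_c = -29.3)
    rec <- synthetic_block_energies(truth, pm, sigma = 0)
    est <- estimate_interface_energies(rec, pm)
    expect_equal(est$dG_a, truth$dG_a, tolerance = 1e-12)
    expect_equal(est$dG_b, truth$dG_b, tolerance = 1e-12)
    expect_equal(est$dG_zip, truth$dG_zip, tolerance = 1e-12)
    expect_equal(est$dG_c, truth$dG_c, tolerance = 1e-12)
  }
  flat <- synthetic_block_energies(
    energy_table(dG_a = -1, dG_b = -1, dG_zip = -1, dG_c = -1), "AP", sigma = 0)
  flat$G <- 0
  est0 <- estimate_interface_energies(flat, "AP")
  expect_equal(unlist(est0[c("dG_a", "dG_b", "dG_zip", "dG_c")]),
               c(dG_a = 0, dG_b = 0, dG_zip = 0, dG_c = 0))
})

test_that("noisy tables give estimates within propagated uncertainty", {
  truth <- energy_table(dG_a = -9.2, dG_b = -6.2, dG_zip = -16.4, dG_c = -29.3)
  sigma <- 0.1
  set.seed(42)
  rec <- synthetic_block_energies(truth, "AP", sigma = sigma)
  est <- estimate_interface_energies(rec, "AP")
  # error propagation through the linear combinations (independent noise)
  sd_c <- sigma * sqrt(1 + 100) / 9
  sd_zip <- sigma * sqrt(1 + 4) / 10
  sd_b <- sigma * sqrt(1 + 4) / 6
  sd_a <- sigma * sqrt(1 + 4) / 12
  expect_lt(abs(est$dG_c - truth$dG_c), 3 * sd_c)
  expect_lt(abs(est$dG_zip - truth$dG_zip), 3 * sd_zip)
  expect_lt(abs(est$dG_b - truth$dG_b), 3 * sd_b)
  expect_lt(abs(est$dG_a - truth$dG_a), 3 * sd_a)
})

test_that("missing block shapes are reported by name", {
  truth <- energy_table(dG_a = -1, dG_b = -1, dG_zip = -1, dG_c = -1)
  rec <- synthetic_block_energies(truth, "AP", sigma = 0)
  rec <- rec[!(rec$n_a == 1 & rec$n_b == 2 & rec$n_c == 10), ]
  expect_error(estimate_interface_energies(rec, "AP"), "\\(1,2,10\\)")
})

test_that("energy bookkeeping closes over a join-split cycle", {
  # joining two blocks on a plane and re-splitting on the same plane buries
  # and releases the same interface energy
  for (spec in list(ap, pp)) for (plane in c("a", "zip", "c")) {
    shape <- block_shape(2, 2, 4)
    e_join <- interface_free_energy(spec, split_plane(plane), shape)
    e_split <- interface_free_energy(spec, split_plane(plane), shape)
    expect_equal(e_join - e_split, 0)
    expect_lt(e_join, 0)
  }
})
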