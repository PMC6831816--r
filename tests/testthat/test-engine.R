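small_run <- function(conc = 5e-3, n = 400, seed = 5, reps = 1, ...) {
  run_assembly(run_config(concentration = conc, total_peptides = n,
                          seed = seed, replicates = reps, ...))
}

test_that("trajectories are reproducible and seed-separated", {
  r1 <- small_run()
  r2 <- small_run()
  expect_identical(r1$replicates[[1]]$trajectory, r2$replicates[[1]]$trajectory)
  expect_identical(r1$replicates[[1]]$final, r2$replicates[[1]]$final)
  r3 <- small_run(seed = 6)
  expect_false(identical(r1$replicates[[1]]$final, r3$replicates[[1]]$final))
})

test_that("peptides are conserved at every recorded state", {
  run <- small_run(conc = 5e-2, n = 500, reps = 2)
  for (rep in run$replicates) {
    tr <- rep$trajectory
    for (snap in split(tr, tr$record)) {
      expect_equal(sum(snap$n_a * snap$n_b * snap$n_c * snap$count), 500)
      # no inside-out species ever appears
      expect_true(all(snap$n_b == 1 | snap$n_b %% 2 == 0))
      expect_true(all(snap$count > 0))
    }
    fin <- rep$final
    expect_equal(sum(fin$n_a * fin$n_b * fin$n_c * fin$count), 500)
  }
})

test_that("monomer commitment is equiprobable and reversible by dissociation", {
  set.seed(1)
  draws <- commit_polymorph(1e5)
  expect_lt(abs(mean(draws == "P") - 0.5), 0.005)
  # engine level: no mixed-polymorph species can exist by construction, and
  # dimers of both polymorphs appear from a pure-monomer start
  run <- small_run(conc = 5e-3, n = 2000, seed = 9)
  fin <- run$replicates[[1]]$final
  expect_setequal(intersect(unique(fin$tag), c("AP", "P")), c("AP", "P"))
  # disabling a polymorph removes it entirely
  solo <- run_assembly(run_config(5e-3, 500, polymorphs = "AP", seed = 2))
  expect_false("P" %in% solo$replicates[[1]]$final$tag)
})

test_that("stationary occupancy matches the master-equation solution", {
  # Toy network: two peptides, AP only, soft energies.  Reachable states are
  # two monomers or one dimer on the a, zip or c contact; the chemical
  # master equation is a 4-state CTMC solved directly for its stationary
  # distribution, against time-averaged occupancy from the engine.
  soft <- soft_ap_spec()
  conc <- 0.05
  V <- 2 / (conc * 1e3 * 6.02214076e23)
  st <- make_state(list("MONOMER", 1, 1, 1, 2), volume = V)
  rx <- enumerate_reactions(st, ap_spec = soft, polymorphs = "AP",
                            cond = cond300)
  joins <- rx[rx$kind == "join", ]
  expect_equal(nrow(joins), 3)
  split_total <- function(axis) {
    s <- c(1, 1, 1); s[match(axis, c("a", "b", "c"))] <- 2
    std <- make_state(list("AP", s[1], s[2], s[3], 1), volume = V)
    rr <- enumerate_reactions(std, ap_spec = soft, polymorphs = "AP",
                              cond = cond300)
    sum(rr$propensity[rr$kind == "split"])
  }
  # generator over states (2 monomers; dimer on a, zip or c contact)
  states <- c("mono", "a", "b", "c")
  Q <- matrix(0, 4, 4, dimnames = list(states, states))
  for (axis in c("a", "b", "c")) {
    Q["mono", axis] <- joins$propensity[joins$axis == axis]
    Q[axis, "mono"] <- split_total(axis)
  }
  diag(Q) <- -rowSums(Q)
  pi_stat <- qr.solve(rbind(t(Q), rep(1, 4)), c(rep(0, 4), 1))
  names(pi_stat) <- states

  cfg <- run_config(concentration = conc, total_peptides = 2, ap_spec = soft,
                    polymorphs = "AP", seed = 41, replicates = 1,
                    max_time = 1e6, max_events = 2e5)
  run <- run_assembly(cfg, track_occupancy = TRUE)
  occ <- run$replicates[[1]]$occupancy
  occ$frac <- occ$time / sum(occ$time)
  key <- c(mono = "0:1,1,1=2;", a = "1:2,1,1=1;", b = "1:1,2,1=1;",
           c = "1:1,1,2=1;")
  emp <- vapply(key, function(k) sum(occ$frac[occ$state == k]), numeric(1))
  names(emp) <- names(key)
  expect_equal(sum(emp), 1, tolerance = 1e-12)
  for (s in states)
    expect_lt(abs(emp[[s]] - pi_stat[[s]]), 0.03)
})

test_that("rate constants are cached, not recomputed per event", {
  run <- small_run(conc = 5e-2, n = 1000, seed = 3)
  d <- run$replicates[[1]]$diagnostics
  fires <- d$fires_split + d$fires_join + d$fires_join_split
  # one evaluation pass per (pair, axis) and per split channel; far fewer
  # than one per event once the network is warm
  expect_lte(d$rate_evaluations, 4 * d$n_species^2 + 4 * d$n_species + 6)
  expect_gt(fires, d$n_species)
  # identical repeat run performs the identical number of evaluations
  run2 <- small_run(conc = 5e-2, n = 1000, seed = 3)
  expect_identical(run2$replicates[[1]]$diagnostics, d)
})

test_that("the cached channel table agrees with the reference enumeration", {
  cfg <- run_config(5e-3, 60, seed = 8, max_events = 40)
  run <- run_assembly(cfg, audit = TRUE)
  rep <- run$replicates[[1]]
  aud <- rep$audit
  st <- system_state(rep$final, volume = cfg$volume)
  # the engine's hot array holds channels at or above the live floor; the
  # background group (not audited) serves anything below it
  rx <- enumerate_reactions(st, cond = cond300, prune_threshold = 1e-40)
  present <- rep$final
  sig <- sprintf("%s:%d,%d,%d", present$tag, present$n_a, present$n_b,
                 present$n_c)
  # every reference join/compound channel between present species appears in
  # the audit with the same rate constant
  for (i in which(rx$kind %in% c("join", "join_split"))) {
    rs <- strsplit(rx$reactants[i], " \\+ ")[[1]]
    if (rs[1] == rs[2] && startsWith(rs[1], "MONOMER")) {
      hit <- aud$kind == "join" & aud$axis == rx$axis[i] &
        aud$reactant_a == rs[1] & aud$reactant_b == rs[2]
    } else {
      hit <- aud$kind == rx$kind[i] & aud$axis == rx$axis[i] &
        ((aud$reactant_a == rs[1] & aud$reactant_b == rs[2]) |
           (aud$reactant_a == rs[2] & aud$reactant_b == rs[1]))
    }
    expect_true(any(hit), info = rx$reactants[i])
    expect_equal(max(aud$k[hit]), rx$k[i], tolerance = 1e-10,
                 info = paste(rx$kind[i], rx$reactants[i], rx$axis[i]))
  }
  # split channels: per-axis rate constants match, and the engine
  # multiplicity equals the number of per-position reference rows
  for (s in sig[present$tag != "MONOMER"]) {
    for (axis in c("a", "b", "c")) {
      ref <- rx[rx$kind == "split" & rx$reactants == s & rx$axis == axis, ]
      eng <- aud[aud$kind == "split" & aud$reactant_a == s & aud$axis == axis, ]
      if (nrow(ref) == 0) next
      expect_equal(nrow(eng), length(unique(ref$k)), info = s)
      for (kk in unique(ref$k)) {
        hit <- abs(eng$k / kk - 1) < 1e-10
        expect_true(any(hit), info = paste(s, axis))
        expect_equal(sum(eng$multiplicity[hit]),
                     sum(abs(ref$k / kk - 1) < 1e-10), info = paste(s, axis))
      }
    }
  }
})

test_that("assembly terminates by the configured stop criteria", {
  run_ev <- small_run(n = 300, max_events = 50)
  expect_equal(run_ev$replicates[[1]]$status, "max_events")
  expect_equal(run_ev$replicates[[1]]$events, 50)
  run_t <- small_run(n = 300, max_time = 1e-7)
  expect_equal(run_t$replicates[[1]]$status, "max_time")
  expect_lte(run_t$replicates[[1]]$time, 1e-7)
})

test_that("replicate summaries are stable across seeds at mM concentration", {
  run <- small_run(conc = 5e-3, n = 1500, seed = 21, reps = 10)
  finals <- vapply(run$replicates,
                   function(r) mass_fractions(r$final)$frac_1dplus_ap,
                   numeric(1))
  expect_lt(stats::sd(finals) / mean(finals), 0.20)
})
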