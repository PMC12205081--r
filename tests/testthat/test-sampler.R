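test_that("replica-swap probability follows the closed form", {
  expect_equal(exchange_probability(0.4, 0.4, 10, -3), 1)
  expect_equal(exchange_probability(0.4, 0.5, 7, 7), 1)
  # (beta_i - beta_j)(E_i - E_j) = -0.5 -> exp(-0.5)
  expect_equal(exchange_probability(0.4, 0.5, 5, 0), exp(-0.5))
  # symmetry under swapping the replicas
  expect_equal(exchange_probability(0.35, 0.42, 12, 3),
               exchange_probability(0.42, 0.35, 3, 12))
})

test_that("free-particle moves are always accepted and sweeps count moves", {
  res <- data.frame(index = 1:6, category = "polar_spacer",
                    sidechain_epsilon = 0, label = paste0("S", 1:6))
  topo <- chain_topology(res, box_edge = 100)
  mod <- energy_model(k_bond = 0, k_angle = 0, eps_rep = 0,
                      hbond_strength = 0)
  set.seed(1)
  f0 <- initial_frame(topo, mod, 300, prepare = FALSE)
  f1 <- mc_sweep(f0, topo, mod, 300, n_sweeps = 10)
  expect_equal(attr(f1, "acceptance_rate"), 1)   # every dE == 0
  expect_equal(f1$sweep_index, 10L)
})

test_that("stored frame energies are recomputable", {
  topo <- build_preset("wt", 90)
  mod <- energy_model()
  ens <- simulate_ensemble(topo, mod, 300, n_sweeps = 100, stride = 20,
                           seed = 2)
  for (f in seq_len(dim(ens$frames[[1]])[3])) {
    fresh <- potential_energy(topo, mod, ens$frames[[1]][, , f], 300)
    expect_equal(ens$energies[f, 1], fresh, tolerance = 1e-8)
  }
})

test_that("identical config and seed give identical ensembles", {
  topo <- build_preset("wt", 90)
  mod <- energy_model()
  ladder <- replica_ladder(n_replicas = 3, exchange_interval = 10)
  e1 <- run_remd(topo, mod, ladder, n_sweeps = 60, stride = 20, seed = 7)
  e2 <- run_remd(topo, mod, ladder, n_sweeps = 60, stride = 20, seed = 7)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$config_digest, e2$config_digest)
  expect_identical(e1$exchange_log, e2$exchange_log)
  e3 <- run_remd(topo, mod, ladder, n_sweeps = 60, stride = 20, seed = 8)
  expect_false(identical(e1$frames, e3$frames))
})

test_that("ladder guards and degenerate runs behave as specified", {
  expect_error(replica_ladder(200, 316), "250")
  expect_error(replica_ladder(280, 420), "250|400")
  expect_error(replica_ladder(spacing = "explicit",
                              temperatures = c(300, 290),
                              n_replicas = 2), "increasing")
  topo <- build_preset("no_lock_homopolymer", 20)
  mod <- energy_model()
  # single-temperature run reduces to plain Metropolis: empty exchange log
  ens <- simulate_ensemble(topo, mod, 300, n_sweeps = 50, seed = 1)
  expect_equal(nrow(ens$exchange_log), 0L)
  expect_error(simulate_ensemble(topo, mod, 300, n_sweeps = 0, seed = 1),
               "positive")
})

test_that("identical-temperature replicas always swap and walk uniformly", {
  topo <- build_preset("no_lock_homopolymer", 16)
  mod <- energy_model()
  ladder <- structure(list(temperatures = c(300, 300.000001, 300.000002),
                           spacing_rule = "explicit",
                           exchange_interval = 5L),
                      class = "replica_ladder")
  ens <- run_remd(topo, mod, ladder, n_sweeps = 600, stride = 50,
                  seed = 3)
  # near-identical temperatures: acceptance ratio close to 1
  expect_gt(sum(ens$exchange_log$accepts) /
              sum(ens$exchange_log$attempts), 0.95)
  # each replica spends roughly a third of its time on each rung
  walk <- ens$replica_walk
  occ <- table(factor(walk, levels = 1:3), col(walk))
  expect_true(all(occ / nrow(walk) > 1 / 3 - 3 * sqrt(2 / 9 / nrow(walk))))
})

test_that("REMD frames carry ladder temperatures and swap bookkeeping", {
  topo <- build_preset("wt", 90)
  ladder <- replica_ladder(n_replicas = 4, exchange_interval = 10)
  ens <- run_remd(topo, energy_model(), ladder, n_sweeps = 200,
                  stride = 20, seed = 4)
  expect_equal(length(ens$frames), 4L)
  expect_equal(ens$temperatures, ladder$temperatures)
  expect_true(all(ens$exchange_log$accepts <= ens$exchange_log$attempts))
  expect_true(all(ens$replica_walk %in% 1:4))
})

test_that("two-chain runs keep chains apart without attraction", {
  topo <- build_preset("no_lock_homopolymer", 20, n_chains = 2)
  topo$residues$sidechain_epsilon[] <- 0
  mod <- energy_model(hbond_strength = 0)
  # local moves only over a short run: free chains must not meet
  ens <- simulate_two_chain(topo, mod, c(280, 310), n_sweeps = 40,
                            seed = 5, prepare = FALSE,
                            moves = move_set(1, 0, 0))
  cfg <- analysis_config()
  sel <- cg_selection(topo)
  for (t in c(280, 310)) {
    fr <- ensemble_frames(ens, t)
    inter <- sum(vapply(seq_len(dim(fr)[3]), function(f)
      sum(side_chain_contacts(fr[, , f], sel, cfg, "intermolecular",
                              box = topo$box_edge)) / 2, numeric(1)))
    expect_equal(inter, 0)
  }
  expect_error(simulate_two_chain(build_preset("wt", 90), energy_model(),
                                  c(280, 310), 10, seed = 1), "n_chains")
})
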