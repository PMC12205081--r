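test_that("bonded terms vanish at their rest geometry", {
  # 4-residue chain laid out at exact bond lengths, far apart otherwise,
  # with every interaction switched off
  res <- data.frame(index = 1:4, category = "polar_spacer",
                    sidechain_epsilon = 0, label = paste0("S", 1:4))
  topo <- chain_topology(res, box_edge = 50)
  mod <- energy_model(k_angle = 0, hbond_strength = 0)
  b <- topo$backbone_bond_length
  coords <- matrix(0, 8, 3)
  for (i in 1:4) {
    coords[2 * i - 1, ] <- c((i - 1) * b, 0, 0)
    # side chains at their bond length, alternating sides so that no
    # excluded-volume overlap remains
    coords[2 * i, ] <- c((i - 1) * b, (-1)^i * topo$sidechain_bond_length,
                         0)
  }
  e <- potential_energy(topo, mod, coords, 300)
  expect_equal(e, 0, tolerance = 1e-10)
})

test_that("with attractions off and beads far apart only bonded terms remain", {
  res <- data.frame(index = 1:5, category = "polar_spacer",
                    sidechain_epsilon = 0, label = paste0("S", 1:5))
  topo <- chain_topology(res, box_edge = 200)
  mod <- energy_model(hbond_strength = 0)
  set.seed(11)
  # place residues >2 nm apart so all non-bonded terms are zero
  coords <- matrix(0, 10, 3)
  for (i in 1:5) {
    bb <- c(5 * i, 0.3 * i, 0)
    coords[2 * i - 1, ] <- bb
    coords[2 * i, ] <- bb + c(0, 0, topo$sidechain_bond_length)
  }
  bonded <- 0
  for (i in 1:4) {
    d <- sqrt(sum((coords[2 * i - 1, ] - coords[2 * i + 1, ])^2))
    bonded <- bonded + 0.5 * mod$k_bond *
      (d - topo$backbone_bond_length)^2
  }
  for (i in 2:4) {
    v1 <- coords[2 * (i - 1) - 1, ] - coords[2 * i - 1, ]
    v2 <- coords[2 * (i + 1) - 1, ] - coords[2 * i - 1, ]
    a <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    bonded <- bonded + 0.5 * mod$k_angle * (a - mod$theta0)^2
  }
  expect_equal(potential_energy(topo, mod, coords, 290), bonded,
               tolerance = 1e-8)
})

test_that("potential energy matches the brute-force oracle on random frames", {
  set.seed(42)
  res <- data.frame(
    index = 1:5,
    category = c("sticker", "hydrophobic_spacer", "polar_spacer",
                 "flexible", "sticker"),
    sidechain_epsilon = c(3, 1.5, 0.7, 0.3, 3),
    label = paste0("R", 1:5))
  lock <- lock_spec(c(1, 2), c(4, 5), epsilon_lock = 6)
  for (rep in 1:8) {
    topo <- chain_topology(res, lock = lock,
                           n_chains = if (rep %% 2) 1L else 2L,
                           box_edge = 4)
    mod <- energy_model(alpha = 3, hbond_strength = 2)
    coords <- random_cg_frame(topo, spread = 1.5)
    for (temp in c(280, 310)) {
      expect_equal(potential_energy(topo, mod, coords, temp),
                   oracle_energy(topo, mod, coords, temp),
                   tolerance = 1e-9)
    }
  }
})

test_that("energy is invariant under box translations of all beads", {
  topo <- build_preset("wt", 90)
  mod <- energy_model()
  set.seed(7)
  f <- initial_frame(topo, mod, 280, prepare = FALSE)
  e0 <- potential_energy(topo, mod, f$coords, 300)
  shifted <- sweep(f$coords, 2, c(topo$box_edge, -2 * topo$box_edge, 0),
                   "+")
  expect_equal(potential_energy(topo, mod, shifted, 300), e0,
               tolerance = 1e-8)
})

test_that("coordinate shape mismatches are rejected", {
  topo <- build_preset("wt", 90)
  expect_error(potential_energy(topo, energy_model(),
                                matrix(0, 10, 3), 300), "coordinates")
})
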