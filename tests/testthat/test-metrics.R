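test_that("radius of gyration closed forms and oracle agreement", {
  expect_equal(radius_of_gyration(matrix(1.5, 4, 3)), 0)
  two <- rbind(c(0, 0, 0), c(0.8, 0, 0))
  expect_equal(radius_of_gyration(two), 0.4)
  # mass weighting: masses 3 and 1 at distance d -> sqrt(3)/4 * d
  expect_equal(radius_of_gyration(two, masses = c(3, 1)),
               sqrt(3) / 4 * 0.8)
  set.seed(1)
  for (i in 1:5) {
    coords <- matrix(rnorm(90), 30, 3)
    m <- runif(30, 0.5, 2)
    com <- colSums(coords * m) / sum(m)
    direct <- sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
    expect_equal(radius_of_gyration(coords, m), direct,
                 tolerance = 1e-10)
  }
  expect_error(radius_of_gyration(matrix(0, 0, 3)), "empty")
})

test_that("rg is invariant under rigid transforms", {
  set.seed(2)
  coords <- matrix(rnorm(60), 20, 3)
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 0.9
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- coords %*% t(R) + matrix(c(1, -2, 0.5), 20, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(coords),
               tolerance = 1e-10)
})

test_that("SASA of isolated and occluded spheres", {
  cfg <- analysis_config()
  one <- sasa(matrix(0, 1, 3), radii = 0.2, cfg)
  expect_equal(one$total, 4 * pi * (0.2 + cfg$sasa_probe_radius)^2,
               tolerance = 0.01)
  # two spheres beyond occlusion range: sum of isolated areas
  far <- sasa(rbind(c(0, 0, 0), c(2, 0, 0)), radii = c(0.2, 0.3), cfg)
  expect_equal(far$total,
               4 * pi * ((0.2 + 0.14)^2 + (0.3 + 0.14)^2),
               tolerance = 0.02)
  # overlapping dimer agrees with a 10x denser sampling of the same
  # algorithm (refinement oracle)
  dimer <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  a1 <- sasa(dimer, radii = 0.2, cfg)$total
  a2 <- sasa(dimer, radii = 0.2,
             analysis_config(sasa_points = 9600))$total
  expect_lt(abs(a1 - a2) / a2, 0.02)
  # fully buried small sphere has zero accessible area
  buried <- sasa(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                 radii = c(0.05, 0.5), cfg)
  expect_equal(buried$per_atom[1], 0)
})

test_that("side-chain contacts: cutoff, adjacency and oracle equivalence", {
  cfg <- analysis_config()
  # two residues 0.5 nm apart in sequence-separation 10 -> contact
  res <- data.frame(index = 1:12, category = "polar_spacer",
                    sidechain_epsilon = 0.5, label = paste0("S", 1:12))
  topo <- chain_topology(res, box_edge = 20)
  sel <- cg_selection(topo)
  coords <- matrix(0, 24, 3)
  for (i in 1:12) {
    coords[2 * i - 1, ] <- c(i * 1.4, 0, 0)
    coords[2 * i, ] <- c(i * 1.4, 0.3, 0)
  }
  coords[2 * 12, ] <- coords[2 * 1, ] + c(0.5, 0, 0)   # SC1-SC12 0.5 nm
  coords[2 * 3, ] <- coords[2 * 1, ] + c(0, 0.5, 0)    # SC1-SC3 0.5 nm
  m <- side_chain_contacts(coords, sel, cfg, "intramolecular", box = 20)
  expect_true(m[1, 12])
  expect_false(m[1, 3])  # adjacency exclusion |i-j| <= 3
  expect_true(isSymmetric(m))

  # randomised frames against the brute-force oracle (also with two
  # chains / intermolecular scope and periodic wrapping)
  set.seed(33)
  res25 <- data.frame(index = 1:25, category = "polar_spacer",
                      sidechain_epsilon = 0.5, label = paste0("S", 1:25))
  for (i in 1:20) {
    nc <- if (i %% 2) 1L else 2L
    topo <- chain_topology(res25, n_chains = nc, box_edge = 3)
    sel <- cg_selection(topo)
    coords <- random_cg_frame(topo, spread = 4)  # forces wrapping
    for (scope in c("intramolecular", "intermolecular")) {
      if (scope == "intermolecular" && nc == 1) next
      got <- side_chain_contacts(coords, sel, cfg, scope, box = 3)
      want <- oracle_contacts(coords, sel, cfg$contact_cutoff,
                              cfg$adjacency_exclusion, scope, 3)
      expect_identical(unname(got), want)
    }
  }
})

test_that("hydrogen-bond rule: distance, angle, and per-triple oracle", {
  cfg <- analysis_config()
  mk_sites <- function(da, ang_deg) {
    # donor at origin, acceptor at distance da, hydrogen at angle
    a <- ang_deg * pi / 180
    hbond_sites(
      donor_xyz = matrix(c(0, 0, 0), 1),
      hydrogen_xyz = matrix(0.1 * c(cos(a), sin(a), 0), 1),
      acceptor_xyz = matrix(c(da, 0, 0), 1),
      donor_res = 1L, acceptor_res = 10L,
      donor_chain = 1L, acceptor_chain = 1L)
  }
  expect_equal(count_hbonds(mk_sites(0.30, 10), cfg)$count, 1L)
  expect_equal(count_hbonds(mk_sites(0.36, 5), cfg)$count, 0L)
  expect_equal(count_hbonds(mk_sites(0.30, 31), cfg)$count, 0L)
  expect_equal(count_hbonds(mk_sites(0.30, 29.9), cfg)$count, 1L)

  set.seed(9)
  for (rep in 1:10) {
    n <- 10
    sites <- hbond_sites(
      donor_xyz = matrix(runif(3 * n, 0, 1), n),
      hydrogen_xyz = matrix(runif(3 * n, 0, 1), n),
      acceptor_xyz = matrix(runif(3 * n, 0, 1), n),
      donor_res = 1:n, acceptor_res = 1:n,
      donor_chain = rep(1:2, length.out = n),
      acceptor_chain = rep(1:2, length.out = n))
    sites$hydrogen_xyz <- sites$donor_xyz +
      0.1 * (sites$hydrogen_xyz - sites$donor_xyz)
    for (scope in c("intramolecular", "intermolecular")) {
      got <- count_hbonds(sites, cfg, scope, box = 2)$count
      expect_identical(got, oracle_hbonds(sites, cfg, scope, 2))
    }
  }
})

test_that("ensemble averages: discard window, SE and sampling sanity", {
  set.seed(4)
  const <- ensemble_average(rep(3.2, 50), 0.2, block_count = 5)
  expect_equal(const$mean, 3.2)
  expect_equal(const$se, 0)
  # fraction 0.2 on 500 frames retains exactly frames 101..500
  ms <- ensemble_average(seq_len(500), 0.2)
  expect_identical(ms$retained, 101:500)
  expect_equal(ms$mean, mean(101:500))
  # iid gaussian: block-bootstrap SE within 3x of sigma/sqrt(n)
  v <- rnorm(1000, sd = 2)
  ms <- ensemble_average(v, 0, block_count = 10)
  expect_lt(ms$se, 3 * 2 / sqrt(1000))
  expect_gt(ms$se, 2 / sqrt(1000) / 3)
  expect_error(ensemble_average(1:5, 0.2, block_count = 10), "blocks")
})

test_that("strand assignment needs a ladder plus extended backbone", {
  # fabricated frames: two antiparallel strands of a 20-residue chain
  # with amide sites facing -> every interior paired residue is strand
  res <- data.frame(index = 1:20, category = "polar_spacer",
                    sidechain_epsilon = 0.1, label = paste0("S", 1:20))
  lock <- lock_spec(3:8, 13:18, epsilon_lock = 5)
  topo <- chain_topology(res, lock = lock, box_edge = 30)
  b <- topo$backbone_bond_length
  coords <- matrix(0, 40, 3)
  for (i in 1:10) {   # strand 1 along +x, side chains out of the plane
    coords[2 * i - 1, ] <- c(i * b, 0, 0)
    coords[2 * i, ] <- c(i * b, 0, 0.3)
  }
  for (i in 11:20) {  # strand 2 alongside, antiparallel, SCs also +z
    coords[2 * i - 1, ] <- c((21 - i) * b, 0.33, 0)
    coords[2 * i, ] <- c((21 - i) * b, 0.33, 0.3)
  }
  ens <- fake_ensemble(topo, list(coords, coords), 280)
  p <- beta_strand_probability(ens, config = analysis_config())
  # paired interior residues are strand in every frame; the chain ends
  # and the loop are not
  expect_true(all(p[4:7] == 1))
  expect_true(all(p[14:17] == 1))
  expect_true(all(p[c(1, 10, 11, 20)] == 0))
  # saturation example: permanently bonded lock residues -> probability 1
  expect_true(all(p >= 0 & p <= 1))
})
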