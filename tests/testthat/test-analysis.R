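# Deterministic geometric fixtures for the thermo-switch inference.
# "Cold" frames: an extended chain whose lock segments are paired
# antiparallel with side chains perpendicular to the sheet plane, so
# the registry pairs are simultaneously hydrogen bonded (backbone) and
# in side-chain contact, as in a real beta-hairpin.  "Hot" frames: a
# collapsed serpentine with the lock segments pushed out of the core.

lock_fixture_topology <- function() {
  topo <- build_preset("wt", 90)
  topo$box_edge <- 200  # fixture geometry is built in open space
  topo
}

locked_frame <- function(topo) {
  coords <- matrix(0, 180, 3)
  place <- function(i, bb, sc_dir) {
    coords[2 * i - 1, ] <<- bb
    coords[2 * i, ] <<- bb + sc_dir * topo$sidechain_bond_length
  }
  up <- c(0, 0, 1)
  for (k in 0:5) {
    place(25 + k, c(0.5 * k, 0, 0), up)       # segment A
    place(82 - k, c(0.5 * k, 0.33, 0), up)    # segment B, antiparallel
  }
  for (i in 1:24) place(i, c(-0.45 * (25 - i), -0.45 * (25 - i), 0),
                        c(0, 0, 1))
  for (i in 31:76) place(i, c(2.5 + 0.45 * (i - 30), 0.24, 0),
                         c(0, 0, 1))
  for (i in 83:90) place(i, c(-0.45 * (i - 82), 0.48 + 0.45 * (i - 82), 0),
                         c(0, 0, 1))
  coords
}

# dense serpentine (side chains all on one face, adjacent rows in
# contact), with the lock segments pushed out of the core
hot_frame <- function(topo) {
  b <- topo$backbone_bond_length
  coords <- matrix(0, 180, 3)
  row_len <- 9L
  for (i in seq_len(90) - 1L) {
    row <- i %/% row_len
    colp <- i %% row_len
    if (row %% 2L == 1L) colp <- row_len - 1L - colp
    bb <- c(colp * b, row * 0.5, 0)
    coords[2 * i + 1, ] <- bb
    coords[2 * i + 2, ] <- bb + c(0, 0, 0.15)
  }
  out <- function(i, k, dir) {
    bb <- c(dir * (8 + 0.45 * k), 10, 0)
    coords[2 * i - 1, ] <- bb
    coords[2 * i, ] <- bb + c(0, 0, topo$sidechain_bond_length)
    coords
  }
  for (k in 0:5) coords <- out(25 + k, k, 1)
  for (k in 0:5) coords <- out(77 + k, k, -1)
  coords
}

cold_frames <- function(topo, n = 12)
  replicate(n, locked_frame(topo), simplify = FALSE)

test_that("delta-contact profile: self-difference, antisymmetry, planted pair", {
  topo <- lock_fixture_topology()
  lo <- fake_ensemble(topo, cold_frames(topo), 280)
  hi <- fake_ensemble(topo, replicate(12, hot_frame(topo),
                                      simplify = FALSE), 310)
  self <- delta_contact_profile(lo, lo, n_boot = 20)
  expect_true(all(self$delta == 0))
  d1 <- delta_contact_profile(lo, hi, n_boot = 20)
  d2 <- delta_contact_profile(hi, lo, n_boot = 20)
  expect_equal(d1$delta, -d2$delta)
  # profile sums to twice the total pair-frequency change (symmetry)
  cm_lo <- contact_map(lo)$matrix
  cm_hi <- contact_map(hi)$matrix
  expect_equal(sum(d1$delta),
               2 * (sum(cm_hi[upper.tri(cm_hi)]) -
                    sum(cm_lo[upper.tri(cm_lo)])), tolerance = 1e-10)

  # constructed gain at exactly one pair: +0.4 at (5, 20)
  res <- data.frame(index = 1:30, category = "polar_spacer",
                    sidechain_epsilon = 0.1, label = paste0("S", 1:30))
  small <- chain_topology(res, box_edge = 50)
  base <- matrix(0, 60, 3)
  for (i in 1:30) {
    base[2 * i - 1, ] <- c(1.5 * i, 0, 0)
    base[2 * i, ] <- c(1.5 * i, 0.3, 0)
  }
  touch <- base
  touch[2 * 20 - 1, ] <- base[2 * 5 - 1, ] + c(0.5, 0, 0)
  touch[2 * 20, ] <- base[2 * 5, ] + c(0.5, 0, 0)
  lo2 <- fake_ensemble(small, replicate(10, base, simplify = FALSE), 280)
  hi2 <- fake_ensemble(small, c(replicate(4, touch, simplify = FALSE),
                                replicate(6, base, simplify = FALSE)),
                       310)
  d <- delta_contact_profile(lo2, hi2, n_boot = 20)
  expect_equal(d$delta[5], 0.4, tolerance = 1e-10)
  expect_equal(d$delta[20], 0.4, tolerance = 1e-10)
  expect_true(all(d$delta[-c(5, 20)] == 0))
})

test_that("group heatmap equals sub-block means and vanishes off-contact", {
  topo <- lock_fixture_topology()
  lo <- fake_ensemble(topo, cold_frames(topo), 280)
  hm <- group_contact_heatmap(lo, groups = list(a = 25:30, b = 77:82),
                              temperatures = 280)
  cm <- contact_map(lo)
  expect_equal(hm$maps[[1]]["a", "b"], mean(cm$matrix[25:30, 77:82]))
  expect_equal(hm$maps[[1]]["a", "b"], hm$maps[[1]]["b", "a"])
  expect_gt(hm$maps[[1]]["a", "b"], 0)
  hm0 <- group_contact_heatmap(lo, groups = list(t1 = 1:10, t2 = 60:70),
                               temperatures = 280)
  expect_equal(hm0$maps[[1]]["t1", "t2"], 0)
  expect_error(group_contact_heatmap(lo, groups = list(a = integer(0))),
               "empty")
})

test_that("detect_lock recovers the planted segments on the geometric fixture", {
  topo <- lock_fixture_topology()
  lo <- fake_ensemble(topo, cold_frames(topo), 280)
  hi <- fake_ensemble(topo, replicate(12, hot_frame(topo),
                                      simplify = FALSE), 310)
  call <- detect_lock(lo, hi)
  expect_equal(call$verdict, "lock_detected")
  seg_rng <- lapply(call$segments, range)
  expect_true(any(vapply(seg_rng, function(r)
    abs(r[1] - 25) <= 1 && abs(r[2] - 30) <= 1, logical(1))))
  expect_true(any(vapply(seg_rng, function(r)
    abs(r[1] - 77) <= 1 && abs(r[2] - 82) <= 1, logical(1))))
  # swapped ensembles: global contact loss on "heating" -> no lock
  expect_equal(detect_lock(hi, lo)$verdict, "no_lock")
  # identical ensembles -> zero profile -> no lock
  expect_equal(detect_lock(lo, lo)$verdict, "no_lock")
})

test_that("trend classification from constructed rung values", {
  set.seed(12)
  temps <- c(280, 290, 300)
  dec <- trend_report(list(rnorm(100, 2.0, 0.001),
                           rnorm(100, 1.8, 0.001),
                           rnorm(100, 1.6, 0.001)), temps)
  expect_equal(dec$classification, "decreasing")
  inc <- trend_report(list(rnorm(100, 1.0, 0.001),
                           rnorm(100, 1.2, 0.001),
                           rnorm(100, 1.4, 0.001)), temps)
  expect_equal(inc$classification, "increasing")
  flat <- trend_report(list(rep(1.5, 100), rep(1.5, 100), rep(1.5, 100)),
                       temps)
  expect_equal(flat$classification, "flat")
  expect_error(trend_report(list(1:10, 1:10), c(280, 290)), "rungs")
})
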