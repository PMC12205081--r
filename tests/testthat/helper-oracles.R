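# Independent brute-force oracles and small fixtures shared by tests.
# These re-derive every quantity from first principles, separately from
# the package's computational path.

min_image <- function(d, box) {
  if (is.na(box) || box <= 0) return(d)
  d - box * round(d / box)
}

dist_pbc <- function(p, q, box) {
  sqrt(sum(min_image(p - q, box)^2))
}

# straight R re-implementation of the full CG energy, term by term
oracle_energy <- function(topology, model, coords, temperature) {
  n <- nrow(topology$residues)
  nc <- topology$n_chains
  box <- topology$box_edge
  bb_idx <- function(r) 2 * r - 1
  sc_idx <- function(r) 2 * r
  cats <- rep(topology$residues$category, nc)
  eps_sc <- rep(topology$residues$sidechain_epsilon, nc)
  chain_of <- rep(seq_len(nc), each = n)
  within <- rep(seq_len(n), nc)
  ntot <- n * nc
  tf <- function(ci, cj) {
    if (ci %in% c("sticker", "hydrophobic_spacer") &&
        cj %in% c("sticker", "hydrophobic_spacer"))
      1 + model$alpha * (temperature - model$reference_temperature) /
        model$reference_temperature
    else 1
  }
  sig_bb <- 2 * topology$bead_radii[["backbone"]]
  sig_sc <- 2 * topology$bead_radii[["sidechain"]]
  e <- 0
  nb <- 2 * ntot
  for (a in seq_len(nb - 1)) for (b in (a + 1):nb) {
    ra <- ceiling(a / 2); rb <- ceiling(b / 2)
    if (ra == rb) next
    bbA <- a %% 2 == 1; bbB <- b %% 2 == 1
    same <- chain_of[ra] == chain_of[rb]
    if (bbA && bbB && same && abs(within[ra] - within[rb]) == 1) next
    r <- dist_pbc(coords[a, ], coords[b, ], box)
    sig <- 0.5 * ((if (bbA) sig_bb else sig_sc) +
                  (if (bbB) sig_bb else sig_sc))
    att <- !bbA && !bbB && (!same || abs(within[ra] - within[rb]) >= 2)
    eps <- if (att) sqrt(eps_sc[ra] * eps_sc[rb]) * tf(cats[ra], cats[rb])
           else 0
    if (r >= model$attraction_cutoff) next
    if (eps > 0) {
      lj <- function(rr) 4 * eps * ((sig / rr)^12 - (sig / rr)^6)
      e <- e + lj(r) - lj(model$attraction_cutoff)
    } else if (r < sig * 2^(1 / 6)) {
      e <- e + 4 * model$eps_rep * ((sig / r)^12 - (sig / r)^6) +
        model$eps_rep
    }
  }
  amide_axis <- function(r) {
    w_i <- within[r]
    rprev <- if (w_i > 1) r - 1 else r
    rnext <- if (w_i < n) r + 1 else r
    t <- coords[bb_idx(rnext), ] - coords[bb_idx(rprev), ]
    sd <- coords[sc_idx(r), ] - coords[bb_idx(r), ]
    u <- c(t[2] * sd[3] - t[3] * sd[2], t[3] * sd[1] - t[1] * sd[3],
           t[1] * sd[2] - t[2] * sd[1])
    nrm <- sqrt(sum(u^2))
    if (nrm < 1e-9) return(c(1, 0, 0))
    u / nrm
  }
  pairwell <- function(ra, rb, eps, r0, w) {
    v <- min_image(coords[bb_idx(rb), ] - coords[bb_idx(ra), ], box)
    r <- sqrt(sum(v^2))
    if (r >= r0 + 4 * w) return(0)
    if (r < 1e-9) return(-eps)
    ca <- sum(amide_axis(ra) * v) / r
    cb <- sum(amide_axis(rb) * v) / r
    -eps * exp(-0.5 * ((r - r0) / w)^2) * ca^2 * cb^2
  }
  # isotropic temperature-scaled backbone amide well
  eps_hb_T <- model$hbond_strength *
    (1 + model$alpha * (temperature - model$reference_temperature) /
       model$reference_temperature)
  if (model$hbond_strength > 0 && eps_hb_T > 0)
    for (ra in seq_len(ntot - 1)) for (rb in (ra + 1):ntot)
      if (chain_of[ra] != chain_of[rb] ||
          abs(within[ra] - within[rb]) >= 3) {
        r <- dist_pbc(coords[bb_idx(ra), ], coords[bb_idx(rb), ], box)
        if (r < 0.5)
          e <- e - eps_hb_T * exp(-0.5 * ((r - 0.30) / 0.06)^2)
      }
  lk <- topology$lock
  if (!is.null(lk) && lk$epsilon_lock > 0) {
    reg <- lk$registry
    for (c in seq_len(nc) - 1) {
      for (k in seq_len(nrow(reg)))
        e <- e + pairwell(reg[k, 1] + c * n, reg[k, 2] + c * n,
                          lk$epsilon_lock, lk$r_lock, lk$w_lock)
      eps_ext_T <- lk$epsilon_ext *
        (1 - model$enthalpic_alpha *
           (temperature - model$reference_temperature) /
           model$reference_temperature)
      if (!is.null(lk$extension) && lk$epsilon_ext > 0 && eps_ext_T > 0)
        for (k in seq_len(nrow(lk$extension)))
          e <- e + pairwell(lk$extension[k, 1] + c * n,
                            lk$extension[k, 2] + c * n,
                            eps_ext_T, lk$r_lock, lk$w_lock)
      eps_pack_T <- lk$epsilon_pack *
        (1 - model$enthalpic_alpha *
           (temperature - model$reference_temperature) /
           model$reference_temperature)
      if (lk$epsilon_pack > 0 && eps_pack_T > 0) {
        pp <- rbind(reg, cbind(reg[-nrow(reg), 1], reg[-1, 2]),
                    cbind(reg[-1, 1], reg[-nrow(reg), 2]))
        for (k in seq_len(nrow(pp))) {
          r <- dist_pbc(coords[sc_idx(pp[k, 1] + c * n), ],
                        coords[sc_idx(pp[k, 2] + c * n), ], box)
          e <- e - eps_pack_T *
            exp(-0.5 * ((r - lk$r_pack) / lk$w_pack)^2)
        }
      }
    }
  }
  for (c in seq_len(nc) - 1) for (i in seq_len(n)) {
    r <- c * n + i
    dsc <- dist_pbc(coords[bb_idx(r), ], coords[sc_idx(r), ], box)
    e <- e + 0.5 * model$k_bond *
      (dsc - topology$sidechain_bond_length)^2
    if (i < n) {
      dbb <- dist_pbc(coords[bb_idx(r), ], coords[bb_idx(r + 1), ], box)
      e <- e + 0.5 * model$k_bond *
        (dbb - topology$backbone_bond_length)^2
    }
    if (i > 1 && i < n) {
      v1 <- min_image(coords[bb_idx(r - 1), ] - coords[bb_idx(r), ], box)
      v2 <- min_image(coords[bb_idx(r + 1), ] - coords[bb_idx(r), ], box)
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      e <- e + 0.5 * model$k_angle *
        (acos(max(-1, min(1, cth))) - model$theta0)^2
    }
  }
  e
}

# brute-force residue-residue contact set
oracle_contacts <- function(coords, selection, cutoff, adjacency, scope,
                            box) {
  n <- selection$n_res
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- selection$res_chain[i] == selection$res_chain[j]
    if (scope == "intramolecular") {
      if (!same) next
      if (abs(selection$res_index[i] - selection$res_index[j]) <=
          adjacency) next
    } else if (same) next
    ai <- selection$atom_index[selection$atom_res == i]
    aj <- selection$atom_index[selection$atom_res == j]
    if (length(ai) == 0 || length(aj) == 0) next
    hit <- FALSE
    for (a in ai) for (b in aj)
      if (dist_pbc(coords[a, ], coords[b, ], box) < cutoff) hit <- TRUE
    out[i, j] <- out[j, i] <- hit
  }
  out
}

# per-triple hydrogen-bond oracle (loop, no vectorisation)
oracle_hbonds <- function(sites, config, scope, box) {
  bonds <- 0L
  for (d in seq_len(nrow(sites$donor_xyz)))
    for (a in seq_len(nrow(sites$acceptor_xyz))) {
      if (sites$donor_res[d] == sites$acceptor_res[a]) next
      same <- sites$donor_chain[d] == sites$acceptor_chain[a]
      sep <- abs(sites$donor_res[d] - sites$acceptor_res[a])
      if (scope == "intramolecular") {
        if (!same || sep < config$hbond_min_separation) next
      } else if (same) next
      da <- min_image(sites$acceptor_xyz[a, ] - sites$donor_xyz[d, ], box)
      if (sqrt(sum(da^2)) > config$hbond_distance_cutoff) next
      dh <- sites$hydrogen_xyz[d, ] - sites$donor_xyz[d, ]
      ang <- acos(max(-1, min(1, sum(da * dh) /
                                sqrt(sum(da^2) * sum(dh^2))))) * 180 / pi
      if (ang < config$hbond_angle_cutoff) bonds <- bonds + 1L
    }
  bonds
}

# straight-line moderated-t oracle (no shared code with the package)
oracle_moderated_t <- function(bait_log2, ctrl_log2) {
  n1 <- ncol(bait_log2); n2 <- ncol(ctrl_log2)
  d <- n1 + n2 - 2
  diff <- rowMeans(bait_log2) - rowMeans(ctrl_log2)
  s2 <- (apply(bait_log2, 1, function(z) sum((z - mean(z))^2)) +
         apply(ctrl_log2, 1, function(z) sum((z - mean(z))^2))) / d
  z <- log(s2)
  ez <- mean(z) - digamma(d / 2) + log(d / 2)
  vz <- var(z) - trigamma(d / 2)
  inv_trigamma <- function(y) {
    x <- 0.5 + 1 / y
    for (i in 1:100) x <- x + trigamma(x) * (1 - trigamma(x) / y) /
        psigamma(x, 2)
    x
  }
  if (vz > 0) {
    d0 <- 2 * inv_trigamma(vz)
    s02 <- exp(ez + digamma(d0 / 2) - log(d0 / 2))
    s2t <- (d0 * s02 + d * s2) / (d0 + d)
    dft <- d0 + d
  } else {
    s2t <- rep(exp(ez), length(s2))
    dft <- Inf
  }
  t <- diff / sqrt(s2t * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), dft), d0 = if (vz > 0) d0 else Inf)
}

# fabricated ensemble_set around hand-built frames (for deterministic
# analysis-module fixtures)
fake_ensemble <- function(topology, frame_list, temperature,
                          equilibration_fraction = 0) {
  arr <- array(0, c(nrow(frame_list[[1]]), 3, length(frame_list)))
  for (f in seq_along(frame_list)) arr[, , f] <- frame_list[[f]]
  structure(list(topology = topology, model = energy_model(),
                 temperatures = temperature, frames = list(arr),
                 energies = matrix(NA, length(frame_list), 1),
                 sweeps = seq_along(frame_list),
                 exchange_log = data.frame(pair = character(0),
                                           attempts = numeric(0),
                                           accepts = numeric(0)),
                 replica_walk = matrix(integer(0), 0, 1),
                 move_accept_rate = NA,
                 equilibration_fraction = equilibration_fraction,
                 stride = 1L, n_sweeps = length(frame_list),
                 exchange_interval = 0L, seed = NA,
                 config_digest = "fixture"),
            class = "ensemble_set")
}

random_cg_frame <- function(topology, spread = 1.2) {
  nb <- 2 * nrow(topology$residues) * topology$n_chains
  matrix(runif(nb * 3, 0, spread), nb, 3)
}
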