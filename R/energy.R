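# Coarse-grained energy model: bonded terms, excluded volume,
# temperature-scaled side-chain attractions (LCST encoding) and the lock
# pseudo hydrogen-bond wells.

#' Coarse-grained energy model
#'
#' Defines every energy term of the two-bead polymer.  Side-chain beads
#' of residues at sequence separation >= 2 (or on different chains)
#' attract through a truncated-shifted Lennard-Jones well whose depth is
#' the geometric mean of the two residues' `sidechain_epsilon`.  For
#' sticker and hydrophobic pairs the depth is additionally scaled by
#' `1 + alpha * (T - reference_temperature) / reference_temperature`,
#' which makes the attraction grow with temperature: the explicit LCST
#' encoding of a solvent-entropy-driven interaction in a model without
#' explicit water.  All other bead pairs are purely repulsive (WCA).
#' Registry pairs of a lock attract through a Gaussian well of depth
#' `epsilon_lock` between their backbone beads; this term is
#' temperature independent (enthalpic), so lock opening with heat
#' emerges from chain entropy and the competing sticker attractions.
#'
#' @param alpha temperature coefficient of the sticker/hydrophobic
#'   attraction (>= 0; 0 switches the LCST behaviour off).
#' @param reference_temperature K; the attraction equals its nominal
#'   depth at this temperature.
#' @param k_bond harmonic bond constant, kJ/mol/nm^2.
#' @param k_angle,theta0 harmonic backbone angle constant (kJ/mol/rad^2)
#'   and rest angle (rad).
#' @param eps_rep repulsive (WCA) energy scale, kJ/mol.
#' @param attraction_cutoff side-chain attraction cutoff, nm.
#' @param enthalpic_alpha temperature coefficient of the enthalpic
#'   lock-flank terms (zipper extension and sheet packing), whose
#'   strength falls on heating: `eps(T) = eps0 (1 - enthalpic_alpha
#'   (T - T_ref)/T_ref)`, floored at zero.  These polar, hydrogen-bonded
#'   contacts melt out well before the entropic sticker attractions
#'   peak, which is what lets heat open the lock.
#' @param hbond_strength nominal depth (kJ/mol, at the reference
#'   temperature) of a weak isotropic backbone-backbone well between
#'   residues at sequence separation >= 3 (or on different chains),
#'   producing transient crowding hydrogen bonds.  The depth carries
#'   the same LCST temperature factor as the sticker attractions, so
#'   the counted bond number grows with heating both through
#'   compaction and through the well itself.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(alpha = 5, reference_temperature = 298,
                         k_bond = 500, k_angle = 2.0,
                         theta0 = 2 * pi / 3, eps_rep = 1,
                         attraction_cutoff = 1.2, hbond_strength = 3.5,
                         enthalpic_alpha = 16) {
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha,
                 reference_temperature = reference_temperature,
                 k_bond = k_bond, k_angle = k_angle, theta0 = theta0,
                 eps_rep = eps_rep,
                 attraction_cutoff = attraction_cutoff,
                 hbond_strength = hbond_strength,
                 enthalpic_alpha = enthalpic_alpha),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("energy_model: alpha=%.2f (T_ref %.0f K), k_bond=%.0f,",
                     " k_angle=%.1f, cutoff %.2f nm\n"),
              x$alpha, x$reference_temperature, x$k_bond, x$k_angle,
              x$attraction_cutoff), sep = "")
  invisible(x)
}

# Flatten topology + model into the parameter list consumed by the C++
# kernels.  Residue/lock indices are 0-based there; the lock registry is
# replicated for each chain (it is intramolecular).
cg_system <- function(topology, model, restraints = NULL) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  cat_codes <- match(topology$residues$category, residue_categories) - 1L
  lock_a <- integer(0); lock_b <- integer(0)
  ext_a <- integer(0); ext_b <- integer(0)
  pack_a <- integer(0); pack_b <- integer(0)
  eps_lock <- 0; r_lock <- 0.34; w_lock <- 0.05
  eps_ext <- 0; eps_pack <- 0; r_pack <- 0.5; w_pack <- 0.1
  lk <- topology$lock
  if (!is.null(lk)) {
    reg <- lk$registry
    pp <- lock_packing_pairs(lk)
    for (c in seq_len(nc) - 1L) {
      lock_a <- c(lock_a, reg[, 1] - 1L + c * n)
      lock_b <- c(lock_b, reg[, 2] - 1L + c * n)
      if (!is.null(lk$extension)) {
        ext_a <- c(ext_a, lk$extension[, 1] - 1L + c * n)
        ext_b <- c(ext_b, lk$extension[, 2] - 1L + c * n)
      }
      pack_a <- c(pack_a, pp[, 1] - 1L + c * n)
      pack_b <- c(pack_b, pp[, 2] - 1L + c * n)
    }
    eps_lock <- lk$epsilon_lock
    r_lock <- lk$r_lock
    w_lock <- lk$w_lock
    eps_ext <- if (is.null(lk$epsilon_ext)) 0 else lk$epsilon_ext
    # packing and zipper act only while the core lock exists
    if (eps_lock > 0) {
      eps_pack <- lk$epsilon_pack
    } else {
      eps_ext <- 0
    }
    r_pack <- lk$r_pack
    w_pack <- lk$w_pack
  }
  sys <- list(
    n_res = n, n_chains = nc, box = topology$box_edge,
    cat = rep(cat_codes, nc),
    eps_sc = rep(topology$residues$sidechain_epsilon, nc),
    lock_a = lock_a, lock_b = lock_b, eps_lock = eps_lock,
    r_lock = r_lock, w_lock = w_lock,
    ext_a = ext_a, ext_b = ext_b, eps_ext = eps_ext,
    pack_a = pack_a, pack_b = pack_b, eps_pack = eps_pack,
    r_pack = r_pack, w_pack = w_pack,
    k_bond = model$k_bond, r0_bb = topology$backbone_bond_length,
    r0_sc = topology$sidechain_bond_length,
    k_angle = model$k_angle, theta0 = model$theta0,
    sigma_bb = 2 * topology$bead_radii[["backbone"]],
    sigma_sc = 2 * topology$bead_radii[["sidechain"]],
    eps_rep = model$eps_rep, rc_att = model$attraction_cutoff,
    eps_hb = model$hbond_strength, r_hb = 0.30, w_hb = 0.06,
    alpha = model$alpha, t_ref = model$reference_temperature,
    alpha_enth = model$enthalpic_alpha)
  if (!is.null(restraints)) {
    sys$restr_a <- as.integer(restraints$a)
    sys$restr_b <- as.integer(restraints$b)
    sys$restr_k <- restraints$k
    sys$restr_r0 <- restraints$r0
  }
  sys
}

#' Potential energy of a frame
#'
#' Deterministic sum of bonded, excluded-volume, side-chain attraction
#' and lock terms under the minimum-image convention in the periodic
#' box.  The attraction depends on temperature through the LCST scaling
#' of [energy_model()].
#'
#' @param topology a [chain_topology()].
#' @param model an [energy_model()].
#' @param coords numeric matrix (n_beads x 3), nm.
#' @param temperature K (> 0).
#' @return scalar energy, kJ/mol.
#' @export
potential_energy <- function(topology, model, coords, temperature) {
  stopifnot(temperature > 0)
  coords <- as.matrix(coords)
  if (nrow(coords) != n_beads(topology) || ncol(coords) != 3)
    stop(sprintf("coordinates must be %d x 3 for this topology",
                 n_beads(topology)))
  .cpp_total_energy(coords, cg_system(topology, model), temperature)
}
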