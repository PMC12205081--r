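# Metropolis Monte Carlo sampling and the replica-exchange driver.

#' Monte Carlo move set
#'
#' Relative weights and amplitudes of the three move types: local
#' single-bead displacement, crankshaft rotation of an internal backbone
#' segment, and pivot rotation of a chain end.
#'
#' @param p_local,p_crank,p_pivot move probabilities (must sum to 1).
#' @param step_local Gaussian displacement scale, nm.
#' @param amax_crank,amax_pivot maximum rotation angles, rad.
#' @param crank_span maximum crankshaft segment span, residues.
#' @return an object of class `move_set`.
#' @export
move_set <- function(p_local = 0.8, p_crank = 0.1, p_pivot = 0.1,
                     step_local = 0.06, amax_crank = pi / 2,
                     amax_pivot = pi / 3, crank_span = 8L) {
  if (abs(p_local + p_crank + p_pivot - 1) > 1e-9)
    stop("move probabilities must sum to 1")
  structure(list(p_local = p_local, p_crank = p_crank, p_pivot = p_pivot,
                 step_local = step_local, amax_crank = amax_crank,
                 amax_pivot = amax_pivot, crank_span = as.integer(crank_span)),
            class = "move_set")
}

new_frame <- function(coords, temperature, sweep_index, potential_energy) {
  structure(list(coords = coords, temperature = temperature,
                 sweep_index = sweep_index,
                 potential_energy = potential_energy),
            class = "cg_frame")
}

# Deterministic serpentine layout: rows of 9 residues along x, 5 rows
# per layer stacked in y, layers stacked in z; side-chain beads offset
# in z.  Compact enough that the minimum image never folds real
# neighbour interactions.
serpentine_coords <- function(topology) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  b <- topology$backbone_bond_length
  coords <- matrix(0, n_beads(topology), 3)
  row_len <- 9L; rows_per_layer <- 5L
  dy <- 0.55; dz <- 1.1
  for (ch in seq_len(nc) - 1L) {
    zoff <- if (nc == 2) (ch - 0.5) * topology$box_edge / 2 else 0
    for (i in seq_len(n) - 1L) {
      row <- i %/% row_len
      colp <- i %% row_len
      if (row %% 2L == 1L) colp <- row_len - 1L - colp
      layer <- row %/% rows_per_layer
      rowl <- row %% rows_per_layer
      bb <- c(colp * b, rowl * dy, layer * dz + zoff)
      r <- ch * n + i
      coords[2 * r + 1, ] <- bb
      coords[2 * r + 2, ] <- bb + c(0, 0.18, 0.24 * (-1)^i) *
        topology$sidechain_bond_length / 0.3
    }
  }
  coords
}

#' Initial conformation
#'
#' Builds a starting frame for sampling.  The chain is laid out as a
#' compact serpentine and, when the topology carries a lock geometry
#' (also for the lock-dead mutants, mimicking a folded predicted
#' starting structure), relaxed under temporary harmonic restraints that
#' bring the registry pairs into contact, then briefly relaxed without
#' restraints.  Uses the current RNG state; call `set.seed()` for
#' reproducibility.
#'
#' @param topology a [chain_topology()].
#' @param model an [energy_model()].
#' @param temperature K used during preparation.
#' @param prepare logical; skip the restrained relaxation if `FALSE`.
#' @param n_prep_sweeps sweeps of restrained relaxation.
#' @return a `cg_frame`.
#' @export
initial_frame <- function(topology, model, temperature = 280,
                          prepare = TRUE, n_prep_sweeps = 800L) {
  coords <- serpentine_coords(topology)
  mv <- move_set()
  if (prepare) {
    restr <- NULL
    if (!is.null(topology$lock)) {
      n <- n_residues(topology)
      # restrain the full hairpin (core registry plus any zipper
      # extension), mimicking a fully folded predicted start
      reg <- rbind(topology$lock$registry, topology$lock$extension)
      a <- integer(0); b <- integer(0)
      for (ch in seq_len(topology$n_chains) - 1L) {
        a <- c(a, 2L * (reg[, 1] - 1L + ch * n))     # backbone beads
        b <- c(b, 2L * (reg[, 2] - 1L + ch * n))
      }
      restr <- list(a = a, b = b, k = rep(100, length(a)),
                    r0 = rep(topology$lock$r_lock, length(a)))
    }
    sys <- cg_system(topology, model, restraints = restr)
    out <- .cpp_run_mc(coords, sys, unclass(mv), temperature,
                       as.integer(n_prep_sweeps))
    coords <- out$coords
    sys <- cg_system(topology, model)
    out <- .cpp_run_mc(coords, sys, unclass(mv), temperature, 200L)
    coords <- out$coords
  }
  e <- potential_energy(topology, model, coords, temperature)
  new_frame(coords, temperature, 0L, e)
}

#' Run Metropolis sweeps on a frame
#'
#' One sweep attempts `n_beads` moves, each accepted with the Metropolis
#' probability `min(1, exp(-dE/kT))`.  Proposals with non-finite energy
#' change are rejected.
#'
#' @param frame a `cg_frame` (see [initial_frame()]).
#' @param topology,model system definition.
#' @param temperature K.
#' @param n_sweeps number of sweeps.
#' @param moves a [move_set()].
#' @return updated `cg_frame` with attribute `acceptance_rate`.
#' @export
mc_sweep <- function(frame, topology, model, temperature,
                     n_sweeps = 1L, moves = move_set()) {
  out <- .cpp_run_mc(frame$coords, cg_system(topology, model),
                     unclass(moves), temperature, as.integer(n_sweeps))
  f <- new_frame(out$coords, temperature,
                 frame$sweep_index + as.integer(n_sweeps), out$energy)
  attr(f, "acceptance_rate") <- out$accepted / out$attempted
  f
}

#' Replica-swap acceptance probability
#'
#' The standard replica-exchange criterion
#' `min(1, exp((beta_i - beta_j) * (E_i - E_j)))`, symmetric under
#' swapping the two replicas.  (The sampler itself uses the generalised
#' two-sided evaluation because the LCST Hamiltonian depends on
#' temperature; for a temperature-independent Hamiltonian the two
#' coincide.)
#'
#' @param beta_i,beta_j inverse temperatures, 1/(kJ/mol).
#' @param E_i,E_j potential energies, kJ/mol.
#' @return acceptance probability in `[0, 1]`.
#' @export
exchange_probability <- function(beta_i, beta_j, E_i, E_j) {
  pmin(1, exp((beta_i - beta_j) * (E_i - E_j)))
}

#' Temperature ladder for replica exchange
#'
#' @param t_min,t_max ladder end points, K (guarded to 250-400 K).
#' @param n_replicas number of rungs.
#' @param spacing `"geometric"` or `"explicit"` (then supply
#'   `temperatures`).
#' @param temperatures explicit strictly increasing rung temperatures.
#' @param exchange_interval sweeps between swap attempts.
#' @return an object of class `replica_ladder`.
#' @export
replica_ladder <- function(t_min = 280, t_max = 316, n_replicas = 8L,
                           spacing = c("geometric", "explicit"),
                           temperatures = NULL, exchange_interval = 20L) {
  spacing <- match.arg(spacing)
  if (spacing == "geometric") {
    temperatures <- exp(seq(log(t_min), log(t_max),
                            length.out = n_replicas))
  } else if (is.null(temperatures)) {
    stop("explicit spacing needs `temperatures`")
  }
  if (length(temperatures) >= 2 && any(diff(temperatures) <= 0))
    stop("ladder temperatures must be strictly increasing")
  if (min(temperatures) < 250 || max(temperatures) > 400)
    stop("ladder temperatures must lie in [250, 400] K")
  structure(list(temperatures = temperatures, spacing_rule = spacing,
                 exchange_interval = as.integer(exchange_interval)),
            class = "replica_ladder")
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

new_ensemble_set <- function(topology, model, temperatures, res, seed,
                             equilibration_fraction, stride, n_sweeps,
                             exchange_interval) {
  nr <- length(temperatures)
  frames <- lapply(seq_len(nr), function(r) res$frames[[r]])
  pairs <- if (nr > 1 && exchange_interval > 0)
    sprintf("%d-%d", seq_len(nr - 1), 2:nr) else character(0)
  exchange_log <- data.frame(
    pair = pairs,
    attempts = if (length(pairs)) as.numeric(res$exch_attempts) else numeric(0),
    accepts = if (length(pairs)) as.numeric(res$exch_accepts) else numeric(0),
    stringsAsFactors = FALSE)
  cfg <- list(topology = unclass(topology), model = unclass(model),
              temperatures = temperatures, n_sweeps = n_sweeps,
              stride = stride, exchange_interval = exchange_interval,
              seed = seed)
  structure(list(topology = topology, model = model,
                 temperatures = temperatures, frames = frames,
                 energies = res$energies, sweeps = as.integer(res$sweeps),
                 exchange_log = exchange_log,
                 replica_walk = res$replica_walk,
                 move_accept_rate = res$move_accept_rate,
                 equilibration_fraction = equilibration_fraction,
                 stride = stride, n_sweeps = n_sweeps,
                 exchange_interval = exchange_interval, seed = seed,
                 config_digest = config_digest(cfg)),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf(
    "ensemble_set: %d rung(s) %s K, %d frames/rung (stride %d), seed %s\n",
    length(x$temperatures),
    paste(sprintf("%.1f", range(x$temperatures)), collapse = "-"),
    dim(x$frames[[1]])[3], x$stride,
    if (is.null(x$seed)) "<none>" else x$seed))
  if (nrow(x$exchange_log) > 0)
    cat(sprintf("  mean swap acceptance: %.2f\n",
                sum(x$exchange_log$accepts) /
                  max(1, sum(x$exchange_log$attempts))))
  cat(sprintf("  move acceptance: %.2f; equilibration discard: %.0f%%\n",
              x$move_accept_rate, 100 * x$equilibration_fraction))
  invisible(x)
}

#' Frames of one temperature rung
#'
#' @param ensemble an `ensemble_set`.
#' @param temperature rung temperature (matched to the nearest rung).
#' @param retained_only drop the equilibration fraction if `TRUE`.
#' @return array `n_beads x 3 x n_frames`.
#' @export
ensemble_frames <- function(ensemble, temperature = NULL,
                            retained_only = FALSE) {
  r <- rung_index(ensemble, temperature)
  fr <- ensemble$frames[[r]]
  if (retained_only) {
    keep <- retained_frames(dim(fr)[3], ensemble$equilibration_fraction)
    fr <- fr[, , keep, drop = FALSE]
  }
  fr
}

rung_index <- function(ensemble, temperature = NULL) {
  if (is.null(temperature)) {
    if (length(ensemble$temperatures) > 1)
      stop("specify `temperature` for a multi-rung ensemble")
    return(1L)
  }
  which.min(abs(ensemble$temperatures - temperature))
}

retained_frames <- function(n, fraction) {
  seq.int(floor(n * fraction) + 1L, n)
}

#' Replica-exchange Monte Carlo run
#'
#' Runs one replica per ladder rung, attempting nearest-neighbour
#' configuration swaps every `exchange_interval` sweeps with alternating
#' even/odd pair parity, and recording temperature-indexed frames every
#' `stride` sweeps.  The leading `equilibration_fraction` of frames is
#' marked for exclusion from ensemble averages (mirroring the usual
#' discard of the initial part of a sampling run).
#'
#' @param topology,model system definition.
#' @param ladder a [replica_ladder()] (>= 1 rung; a single rung degrades
#'   to a plain Metropolis run with an empty exchange log).
#' @param n_sweeps sweeps per replica (>= exchange interval).
#' @param stride sweeps between recorded frames.
#' @param equilibration_fraction fraction of frames to discard in
#'   averages (default 0.2).
#' @param seed RNG seed (mandatory for reproducible ensembles).
#' @param moves a [move_set()].
#' @param prepare build a lock-paired starting structure (see
#'   [initial_frame()]).
#' @return an `ensemble_set`.
#' @export
run_remd <- function(topology, model, ladder, n_sweeps, stride = 10L,
                     equilibration_fraction = 0.2, seed = 1L,
                     moves = move_set(), prepare = TRUE) {
  stopifnot(inherits(ladder, "replica_ladder"))
  n_sweeps <- as.integer(n_sweeps)
  if (n_sweeps <= 0) stop("n_sweeps must be positive")
  if (length(ladder$temperatures) >= 2 &&
      n_sweeps < ladder$exchange_interval)
    stop("n_sweeps must be >= exchange_interval")
  set.seed(seed)
  f0 <- initial_frame(topology, model,
                      temperature = min(ladder$temperatures),
                      prepare = prepare)
  init <- lapply(ladder$temperatures, function(t) f0$coords)
  res <- .cpp_run_remd(init, cg_system(topology, model), unclass(moves),
                       ladder$temperatures, n_sweeps,
                       as.integer(ladder$exchange_interval),
                       as.integer(stride))
  new_ensemble_set(topology, model, ladder$temperatures, res, seed,
                   equilibration_fraction, as.integer(stride), n_sweeps,
                   as.integer(ladder$exchange_interval))
}

#' Single-temperature Metropolis run
#'
#' @inheritParams run_remd
#' @param temperature K.
#' @return an `ensemble_set` with one rung.
#' @export
simulate_ensemble <- function(topology, model, temperature, n_sweeps,
                              stride = 10L, equilibration_fraction = 0.2,
                              seed = 1L, moves = move_set(),
                              prepare = TRUE) {
  ladder <- structure(list(temperatures = temperature,
                           spacing_rule = "explicit",
                           exchange_interval = 0L),
                      class = "replica_ladder")
  run_remd(topology, model, ladder, n_sweeps, stride,
           equilibration_fraction, seed, moves, prepare)
}

#' Two-chain runs at two temperatures
#'
#' Independent (non-exchanging) Metropolis runs of a two-chain system at
#' a low and a high temperature, for intermolecular contact analysis.
#' The two chains are prepared apart in the shared periodic box and the
#' frames retain chain identity.
#'
#' @inheritParams run_remd
#' @param temperatures two temperatures, K (default 280 and 310).
#' @return an `ensemble_set` with one rung per temperature and an empty
#'   exchange log.
#' @export
simulate_two_chain <- function(topology, model,
                               temperatures = c(280, 310), n_sweeps,
                               stride = 10L, equilibration_fraction = 0.2,
                               seed = 1L, moves = move_set(),
                               prepare = TRUE) {
  if (topology$n_chains != 2)
    stop("simulate_two_chain needs a topology with n_chains = 2")
  set.seed(seed)
  f0 <- initial_frame(topology, model, temperature = min(temperatures),
                      prepare = prepare)
  init <- lapply(temperatures, function(t) f0$coords)
  res <- .cpp_run_remd(init, cg_system(topology, model), unclass(moves),
                       temperatures, as.integer(n_sweeps), 0L,
                       as.integer(stride))
  new_ensemble_set(topology, model, temperatures, res, seed,
                   equilibration_fraction, as.integer(stride),
                   as.integer(n_sweeps), 0L)
}
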