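# Trajectory metric suite: Rg, Shrake-Rupley SASA, side-chain contact
# maps, distance/angle hydrogen bonds and beta-strand probability.
# Works on coarse-grained ensembles and on externally supplied
# structures through generic atom selections.

#' Analysis configuration
#'
#' Cutoffs and conventions of the metric suite.  Defaults: side-chain
#' contact below 0.6 nm with intramolecular pairs at sequence separation
#' `|i - j| <= 3` excluded; hydrogen bond when the acceptor-donor
#' distance is within 0.35 nm and the acceptor-donor-hydrogen angle
#' (vertex at the donor, between the D->A and D->H directions) is below
#' 30 degrees; Shrake-Rupley SASA with a 0.14 nm probe and 960 sphere
#' points; the leading 20% of frames excluded from ensemble averages.
#'
#' @param contact_cutoff nm.
#' @param adjacency_exclusion residue separation excluded from
#'   intramolecular contacts.
#' @param hbond_distance_cutoff nm.
#' @param hbond_angle_cutoff degrees, in (0, 90).
#' @param sasa_probe_radius nm.
#' @param sasa_points sphere sample count (>= 60).
#' @param equilibration_fraction leading fraction of frames excluded
#'   from averages.
#' @param extended_angle_min degrees; minimum backbone pseudo-angle for
#'   a residue to count as locally extended in strand assignment.
#' @param hbond_min_separation smallest intramolecular residue
#'   separation counted as a hydrogen bond (pseudo-site convention).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(contact_cutoff = 0.6, adjacency_exclusion = 3L,
                            hbond_distance_cutoff = 0.35,
                            hbond_angle_cutoff = 30,
                            sasa_probe_radius = 0.14, sasa_points = 960L,
                            equilibration_fraction = 0.2,
                            extended_angle_min = 100,
                            hbond_min_separation = 3L) {
  if (contact_cutoff <= 0 || hbond_distance_cutoff <= 0 ||
      sasa_probe_radius <= 0)
    stop("cutoffs must be positive")
  if (hbond_angle_cutoff <= 0 || hbond_angle_cutoff >= 90)
    stop("hbond_angle_cutoff must lie in (0, 90) degrees")
  if (sasa_points < 60) stop("sasa_points must be >= 60")
  structure(list(contact_cutoff = contact_cutoff,
                 adjacency_exclusion = as.integer(adjacency_exclusion),
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 sasa_probe_radius = sasa_probe_radius,
                 sasa_points = as.integer(sasa_points),
                 equilibration_fraction = equilibration_fraction,
                 extended_angle_min = extended_angle_min,
                 hbond_min_separation = as.integer(hbond_min_separation)),
            class = "analysis_config")
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of the particles from their centre of
#' mass: `sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i))`.
#'
#' @param coords numeric matrix (n x 3), nm.
#' @param masses optional positive weights (default equal).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral point sampling on each expanded sphere
#' (radius + probe); a point is accessible when inside no neighbouring
#' expanded sphere.
#'
#' @param coords numeric matrix (n x 3), nm.
#' @param radii per-particle radii, nm.
#' @param config an [analysis_config()] (probe radius and point count).
#' @return list with `per_atom` (nm^2) and `total`.
#' @export
sasa <- function(coords, radii, config = analysis_config()) {
  coords <- as.matrix(coords)
  if (length(radii) == 1) radii <- rep(radii, nrow(coords))
  if (length(radii) != nrow(coords)) stop("radii/coords length mismatch")
  if (any(radii <= 0)) stop("radii must be positive")
  per <- .cpp_sasa(coords, radii, config$sasa_probe_radius,
                   config$sasa_points)
  list(per_atom = per, total = sum(per))
}

#' Atom selection for residue-level metrics
#'
#' Maps atoms to residues and chains for the contact metric.  For the
#' coarse-grained model use [cg_selection()]; for all-atom structures
#' build one from any atom table (e.g. a bio3d PDB) with side-chain
#' heavy atoms selected.
#'
#' @param atom_index indices (rows of the coordinate matrix) of the
#'   selected side-chain atoms.
#' @param atom_res global residue id (1-based, unique across chains) of
#'   each selected atom.
#' @param res_chain,res_index per global residue: chain id and residue
#'   index within its chain.
#' @param n_res total number of residues (across chains).
#' @param bead_radii optional per-atom radii for SASA.
#' @return an object of class `structure_selection`.
#' @export
structure_selection <- function(atom_index, atom_res, res_chain, res_index,
                                n_res, bead_radii = NULL) {
  stopifnot(length(atom_index) == length(atom_res),
            length(res_chain) == n_res, length(res_index) == n_res)
  structure(list(atom_index = as.integer(atom_index),
                 atom_res = as.integer(atom_res),
                 res_chain = as.integer(res_chain),
                 res_index = as.integer(res_index),
                 n_res = as.integer(n_res), bead_radii = bead_radii),
            class = "structure_selection")
}

#' @describeIn structure_selection selection for a coarse-grained
#'   topology: the side-chain bead of every residue.
#' @param topology a [chain_topology()].
#' @export
cg_selection <- function(topology) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  res <- seq_len(n * nc)
  structure_selection(atom_index = 2L * res, atom_res = res,
                      res_chain = rep(seq_len(nc), each = n),
                      res_index = rep(seq_len(n), nc), n_res = n * nc)
}

#' Side-chain contacts of one frame
#'
#' Residue pair (i, j) is in contact when the minimum distance over
#' their selected side-chain atoms is below the cutoff.  Intramolecular
#' scope excludes pairs at sequence separation
#' `|i - j| <= adjacency_exclusion` (same chain); intermolecular scope
#' keeps only pairs on different chains with no adjacency exclusion.
#' Distances respect the minimum image in a periodic box.
#'
#' @param coords full frame coordinates (n_atoms x 3), nm.
#' @param selection a [structure_selection()].
#' @param config an [analysis_config()].
#' @param scope `"intramolecular"` or `"intermolecular"`.
#' @param box periodic cube edge, nm (`NA` or <= 0 for none).
#' @return logical symmetric matrix n_res x n_res.
#' @export
side_chain_contacts <- function(coords, selection,
                                config = analysis_config(),
                                scope = c("intramolecular",
                                          "intermolecular"),
                                box = NA) {
  scope <- match.arg(scope)
  coords <- as.matrix(coords)
  sub <- coords[selection$atom_index, , drop = FALSE]
  m <- .cpp_contact_frame(sub, selection$atom_res, selection$res_chain,
                          selection$res_index, selection$n_res,
                          config$contact_cutoff,
                          config$adjacency_exclusion,
                          if (scope == "intramolecular") 0L else 1L,
                          if (is.na(box) || box <= 0) -1 else box)
  dimnames(m) <- NULL
  m
}

#' Contact frequency map of an ensemble rung
#'
#' Per-pair contact frequency over the retained frames of one
#' temperature rung.
#'
#' @param ensemble an `ensemble_set`.
#' @param temperature rung temperature.
#' @param scope `"intramolecular"` or `"intermolecular"`.
#' @param config an [analysis_config()].
#' @param selection selection (default [cg_selection()] of the
#'   ensemble's topology).
#' @return object of class `contact_map` with fields `matrix`,
#'   `n_frames`, `scope`, `temperature`.
#' @export
contact_map <- function(ensemble, temperature = NULL,
                        scope = c("intramolecular", "intermolecular"),
                        config = analysis_config(), selection = NULL) {
  scope <- match.arg(scope)
  if (is.null(selection)) selection <- cg_selection(ensemble$topology)
  fr <- ensemble_frames(ensemble, temperature, retained_only = TRUE)
  nf <- dim(fr)[3]
  acc <- matrix(0, selection$n_res, selection$n_res)
  for (f in seq_len(nf))
    acc <- acc + side_chain_contacts(fr[, , f], selection, config, scope,
                                     box = ensemble$topology$box_edge)
  structure(list(matrix = acc / nf, n_frames = nf, scope = scope,
                 temperature = ensemble$temperatures[
                   rung_index(ensemble, temperature)]),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map (%s, %.1f K): %d residues, %d frames, %d pairs with freq > 0.5\n",
              x$scope, x$temperature, nrow(x$matrix), x$n_frames,
              sum(x$matrix[upper.tri(x$matrix)] > 0.5)))
  invisible(x)
}

#' Hydrogen-bond site set
#'
#' Donor, hydrogen and acceptor coordinates with residue and chain ids.
#' For the coarse-grained model, [cg_hbond_sites()] derives pseudo-sites
#' from the lock geometry convention: every backbone bead is both donor
#' and acceptor, with a pseudo-hydrogen placed 0.1 nm from the backbone
#' bead opposite the side chain (the direction a backbone amide points
#' away from the side chain).
#'
#' @param donor_xyz,hydrogen_xyz,acceptor_xyz coordinate matrices, nm.
#' @param donor_res,acceptor_res global residue ids.
#' @param donor_chain,acceptor_chain chain ids.
#' @return object of class `hbond_sites`.
#' @export
hbond_sites <- function(donor_xyz, hydrogen_xyz, acceptor_xyz,
                        donor_res, acceptor_res, donor_chain,
                        acceptor_chain) {
  if (nrow(donor_xyz) != nrow(hydrogen_xyz))
    stop("every donor needs an attached hydrogen")
  structure(list(donor_xyz = donor_xyz, hydrogen_xyz = hydrogen_xyz,
                 acceptor_xyz = acceptor_xyz,
                 donor_res = as.integer(donor_res),
                 acceptor_res = as.integer(acceptor_res),
                 donor_chain = as.integer(donor_chain),
                 acceptor_chain = as.integer(acceptor_chain)),
            class = "hbond_sites")
}

#' @describeIn hbond_sites pseudo-sites of a coarse-grained frame.
#'   Donor and acceptor sit on the backbone bead; each residue carries
#'   two pseudo-hydrogens 0.1 nm out along its amide axis, the cross
#'   product of the local backbone tangent and the side-chain
#'   direction.  In a beta-strand with side chains perpendicular to
#'   the sheet this axis lies in the sheet plane pointing at the
#'   partner strand on either side, mimicking how backbone N-H and
#'   C=O point both ways out of the strand.  The lock energy aligns
#'   the same axis, so a formed registry pair is a detectable
#'   hydrogen bond.
#' @param topology a [chain_topology()].
#' @param coords frame coordinates (n_beads x 3), nm.
#' @export
cg_hbond_sites <- function(topology, coords) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  res <- seq_len(n * nc)
  bb <- coords[2L * res - 1L, , drop = FALSE]
  sc <- coords[2L * res, , drop = FALSE]
  prev <- res - 1L; nxt <- res + 1L
  within <- rep(seq_len(n), nc)
  prev[within == 1L] <- res[within == 1L]
  nxt[within == n] <- res[within == n]
  tang <- coords[2L * nxt - 1L, , drop = FALSE] -
    coords[2L * prev - 1L, , drop = FALSE]
  sdir <- sc - bb
  u <- cbind(tang[, 2] * sdir[, 3] - tang[, 3] * sdir[, 2],
             tang[, 3] * sdir[, 1] - tang[, 1] * sdir[, 3],
             tang[, 1] * sdir[, 2] - tang[, 2] * sdir[, 1])
  nrm <- sqrt(rowSums(u^2))
  bad <- nrm < 1e-9
  if (any(bad)) {
    u[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    nrm[bad] <- 1
  }
  u <- u / nrm
  ch <- rep(seq_len(nc), each = n)
  # two donor entries per residue: hydrogens along +axis and -axis
  hbond_sites(rbind(bb, bb), rbind(bb + 0.1 * u, bb - 0.1 * u),
              bb, c(res, res), res, c(ch, ch), ch)
}

#' Count hydrogen bonds in a frame
#'
#' A bond is a donor-hydrogen-acceptor triple with donor-acceptor
#' distance within the cutoff and the acceptor-donor-hydrogen angle
#' (vertex at the donor) strictly below the angle cutoff.  Each triple
#' is counted once; intramolecular bonds between residues closer in
#' sequence than `hbond_min_separation` are excluded (self included).
#'
#' @param sites an [hbond_sites()].
#' @param config an [analysis_config()].
#' @param scope `"intramolecular"` or `"intermolecular"`.
#' @param box periodic cube edge (nm) or `NA`.
#' @return list with `count` and data.frame `bonds` (donor_res,
#'   acceptor_res, distance, angle).
#' @export
count_hbonds <- function(sites, config = analysis_config(),
                         scope = c("intramolecular", "intermolecular"),
                         box = NA) {
  scope <- match.arg(scope)
  nd <- nrow(sites$donor_xyz)
  na_ <- nrow(sites$acceptor_xyz)
  if (nd == 0 || na_ == 0) stop("site set is empty")
  mi <- function(d) {
    if (is.na(box) || box <= 0) return(d)
    d - box * round(d / box)
  }
  # donor-acceptor displacement components (nd x na matrices)
  dax <- mi(outer(sites$donor_xyz[, 1], sites$acceptor_xyz[, 1], "-"))
  day <- mi(outer(sites$donor_xyz[, 2], sites$acceptor_xyz[, 2], "-"))
  daz <- mi(outer(sites$donor_xyz[, 3], sites$acceptor_xyz[, 3], "-"))
  dist <- sqrt(dax^2 + day^2 + daz^2)
  same_res <- outer(sites$donor_res, sites$acceptor_res, "==")
  same_chain <- outer(sites$donor_chain, sites$acceptor_chain, "==")
  sep <- abs(outer(sites$donor_res, sites$acceptor_res, "-"))
  ok <- dist <= config$hbond_distance_cutoff & !same_res
  ok <- ok & if (scope == "intramolecular")
    same_chain & sep >= config$hbond_min_separation else !same_chain
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(count = 0L,
                bonds = data.frame(donor_res = integer(0),
                                   acceptor_res = integer(0),
                                   distance = numeric(0),
                                   angle = numeric(0))))
  dh <- sites$hydrogen_xyz - sites$donor_xyz   # D -> H, no image needed
  d_i <- idx[, 1]; a_i <- idx[, 2]
  vax <- -dax[idx]; vay <- -day[idx]; vaz <- -daz[idx]  # D -> A
  hx <- dh[d_i, 1]; hy <- dh[d_i, 2]; hz <- dh[d_i, 3]
  cosang <- (vax * hx + vay * hy + vaz * hz) /
    (sqrt(vax^2 + vay^2 + vaz^2) * sqrt(hx^2 + hy^2 + hz^2))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang < config$hbond_angle_cutoff
  bonds <- data.frame(donor_res = sites$donor_res[d_i[keep]],
                      acceptor_res = sites$acceptor_res[a_i[keep]],
                      distance = dist[idx][keep], angle = ang[keep])
  list(count = nrow(bonds), bonds = bonds)
}

# backbone pseudo-angle (degrees) at each residue of each chain; NA at
# chain ends
backbone_angles <- function(topology, coords) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  out <- rep(NA_real_, n * nc)
  for (ch in seq_len(nc) - 1L) {
    bb <- coords[2L * (ch * n + seq_len(n)) - 1L, , drop = FALSE]
    v1 <- bb[1:(n - 2), , drop = FALSE] - bb[2:(n - 1), , drop = FALSE]
    v2 <- bb[3:n, , drop = FALSE] - bb[2:(n - 1), , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    out[ch * n + 2:(n - 1)] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  out
}

# strand assignment of one frame from a hydrogen-bond list: residue i is
# strand iff it takes part in a ladder (two consecutive inter-segment
# bonds, parallel or antiparallel) and is locally extended
strand_assignment <- function(bonds, angles, n_res, extended_min,
                              min_sep = 3L) {
  strand <- rep(FALSE, n_res)
  if (nrow(bonds) == 0) return(strand)
  pairs <- unique(rbind(cbind(bonds$donor_res, bonds$acceptor_res),
                        cbind(bonds$acceptor_res, bonds$donor_res)))
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) > min_sep, , drop = FALSE]
  if (nrow(pairs) == 0) return(strand)
  key <- paste(pairs[, 1], pairs[, 2])
  has <- function(i, j) paste(i, j) %in% key
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ladder <- has(i + 1, j - 1) || has(i - 1, j + 1) ||
      has(i + 1, j + 1) || has(i - 1, j - 1)
    if (ladder && !is.na(angles[i]) && angles[i] >= extended_min)
      strand[i] <- TRUE
  }
  strand
}

#' Beta-strand probability per residue
#'
#' Per retained frame, a residue is assigned strand when it participates
#' in at least two consecutive inter-segment hydrogen bonds (a ladder,
#' parallel or antiparallel) and its local backbone is extended (the
#' backbone pseudo-angle at the residue exceeds
#' `extended_angle_min`).  The probability is the strand-frame fraction
#' after the equilibration discard.
#'
#' @param ensemble an `ensemble_set`.
#' @param temperature rung temperature.
#' @param config an [analysis_config()].
#' @return numeric vector of per-residue probabilities in `[0, 1]`.
#' @export
beta_strand_probability <- function(ensemble, temperature = NULL,
                                    config = analysis_config()) {
  topology <- ensemble$topology
  if (n_residues(topology) < 5) stop("chains shorter than 5 residues")
  fr <- ensemble_frames(ensemble, temperature, retained_only = TRUE)
  nf <- dim(fr)[3]
  n <- n_residues(topology) * topology$n_chains
  acc <- numeric(n)
  for (f in seq_len(nf)) {
    coords <- fr[, , f]
    sites <- cg_hbond_sites(topology, coords)
    hb <- count_hbonds(sites, config, "intramolecular",
                       box = topology$box_edge)
    angles <- backbone_angles(topology, coords)
    acc <- acc + strand_assignment(hb$bonds, angles, n,
                                   config$extended_angle_min,
                                   config$hbond_min_separation)
  }
  acc / nf
}

#' Ensemble average with block-bootstrap error
#'
#' Discards the leading `equilibration_fraction` of the series, then
#' reports the mean and a block-bootstrap standard error over
#' `block_count` contiguous blocks (bootstrap of block means, 200
#' resamples).
#'
#' @param values per-frame metric values.
#' @param equilibration_fraction leading fraction to discard.
#' @param block_count number of blocks (default 10).
#' @param n_boot bootstrap resamples.
#' @return object of class `metric_series` with fields `values`,
#'   `retained`, `mean`, `se`, `blocks`.
#' @export
ensemble_average <- function(values, equilibration_fraction = 0.2,
                             block_count = 10L, n_boot = 200L) {
  n <- length(values)
  keep <- retained_frames(n, equilibration_fraction)
  if (length(keep) < 2) stop("need at least 2 retained frames")
  if (length(keep) < block_count)
    stop("fewer retained frames than blocks")
  v <- values[keep]
  blocks <- split(v, cut(seq_along(v), block_count, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  boots <- vapply(seq_len(n_boot), function(b)
    mean(bm[sample.int(block_count, replace = TRUE)]), numeric(1))
  structure(list(values = values, retained = keep, mean = mean(v),
                 se = stats::sd(boots), blocks = bm),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("metric_series: mean %.4g +/- %.2g (SE), %d/%d frames retained\n",
              x$mean, x$se, length(x$retained), length(x$values)))
  invisible(x)
}

# per-frame metric values for one rung of a CG ensemble
frame_metric_values <- function(ensemble, metric, temperature = NULL,
                                config = analysis_config(),
                                scope = "intramolecular",
                                sasa_max_frames = 150L) {
  topology <- ensemble$topology
  fr <- ensemble_frames(ensemble, temperature)
  nf <- dim(fr)[3]
  sel <- cg_selection(topology)
  idx <- seq_len(nf)
  if (metric == "sasa" && nf > sasa_max_frames)
    idx <- unique(round(seq(1, nf, length.out = sasa_max_frames)))
  radii <- rep(rep(topology$bead_radii, n_residues(topology)),
               topology$n_chains)
  vals <- vapply(idx, function(f) {
    coords <- fr[, , f]
    switch(metric,
      rg = radius_of_gyration(coords),
      sasa = sasa(coords, radii, config)$total,
      contacts = {
        m <- side_chain_contacts(coords, sel, config, scope,
                                 box = topology$box_edge)
        sum(m[upper.tri(m)])
      },
      hbonds = count_hbonds(cg_hbond_sites(topology, coords), config,
                            scope, box = topology$box_edge)$count,
      stop("unknown metric"))
  }, numeric(1))
  list(values = vals, frame_index = idx)
}

#' Per-frame metric series of an ensemble rung
#'
#' Computes Rg (nm), total SASA (nm^2), intramolecular (or
#' intermolecular) side-chain contact pair count, or hydrogen-bond
#' count per frame, and aggregates with [ensemble_average()].
#'
#' @param ensemble an `ensemble_set`.
#' @param metric one of `"rg"`, `"sasa"`, `"contacts"`, `"hbonds"`.
#' @param temperature rung temperature.
#' @param config an [analysis_config()].
#' @param scope contact/hbond scope.
#' @param block_count blocks for the bootstrap SE.
#' @return a `metric_series` (with `temperature` and `metric` fields).
#' @export
metric_series <- function(ensemble,
                          metric = c("rg", "sasa", "contacts", "hbonds"),
                          temperature = NULL, config = analysis_config(),
                          scope = c("intramolecular", "intermolecular"),
                          block_count = 10L) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  fv <- frame_metric_values(ensemble, metric, temperature, config, scope)
  ms <- ensemble_average(fv$values, ensemble$equilibration_fraction,
                         block_count)
  ms$metric <- metric
  ms$temperature <- ensemble$temperatures[rung_index(ensemble, temperature)]
  ms$frame_index <- fv$frame_index
  ms
}
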