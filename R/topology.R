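# Chain topology: residue-level two-bead sticker-spacer polymer with an
# optional two-segment beta-strand lock.

#' Residue category levels
#'
#' Categories used by the coarse-grained energy model, in decreasing
#' default attraction strength: aromatic stickers, hydrophobic spacers,
#' polar spacers and flexible (glycine-like) residues.
#'
#' @export
residue_categories <- c("sticker", "hydrophobic_spacer", "polar_spacer",
                        "flexible")

default_epsilons <- c(sticker = 5.0, hydrophobic_spacer = 2.8,
                      polar_spacer = 1.0, flexible = 0.5)

#' Lock specification
#'
#' Describes an intramolecular antiparallel strand pairing ("lock")
#' between two disjoint segment ranges.  The registry lists the paired
#' residues; `epsilon_lock` is the directional pseudo hydrogen-bond
#' well depth acting between the paired residues' oriented amide sites.
#' Two further ingredients model the structure of a real beta-hairpin:
#' cross-strand side-chain packing wells (depth `epsilon_pack`, minimum
#' `r_pack`) between registry pairs and their diagonals, which give the
#' paired segments the tight side-chain contacts a sheet shows; and an
#' optional weak zipper `extension` of the registry towards the chain
#' ends (depth `epsilon_ext`), through which the locked hairpin can
#' transiently zip beyond the core segments and tether the termini.
#'
#' @param segment_a,segment_b integer residue index ranges (1-based).
#' @param epsilon_lock well depth per registry pair, kJ/mol (>= 0).
#' @param registry optional two-column matrix of paired indices; default
#'   antiparallel pairing of the two segments.
#' @param r_lock,w_lock Gaussian well minimum (nm, between the paired
#'   residues' backbone beads) and width (nm).
#' @param extension optional two-column matrix of weak zipper pairs.
#' @param epsilon_ext well depth of the zipper pairs, kJ/mol.
#' @param epsilon_pack,r_pack,w_pack side-chain packing well depth
#'   (kJ/mol), minimum (nm) and width (nm).
#' @return an object of class `lock_spec`.
#' @export
lock_spec <- function(segment_a, segment_b, epsilon_lock,
                      registry = NULL, r_lock = 0.34, w_lock = 0.05,
                      extension = NULL, epsilon_ext = 0,
                      epsilon_pack = 5, r_pack = 0.5, w_pack = 0.1) {
  segment_a <- as.integer(segment_a)
  segment_b <- as.integer(segment_b)
  if (length(intersect(segment_a, segment_b)) > 0)
    stop("lock segments must be disjoint")
  if (is.null(registry)) {
    if (length(segment_a) != length(segment_b))
      stop("segments of unequal length need an explicit registry")
    registry <- cbind(segment_a, rev(segment_b)) # antiparallel
  }
  registry <- matrix(as.integer(registry), ncol = 2)
  if (nrow(registry) < 2) stop("lock registry needs at least 2 pairs")
  if (epsilon_lock < 0) stop("epsilon_lock must be >= 0")
  if (!is.null(extension))
    extension <- matrix(as.integer(extension), ncol = 2)
  structure(list(segment_a = segment_a, segment_b = segment_b,
                 registry = registry, epsilon_lock = epsilon_lock,
                 r_lock = r_lock, w_lock = w_lock,
                 extension = extension, epsilon_ext = epsilon_ext,
                 epsilon_pack = epsilon_pack, r_pack = r_pack,
                 w_pack = w_pack),
            class = "lock_spec")
}

# registry + diagonal side-chain packing pairs of a lock
lock_packing_pairs <- function(lock) {
  reg <- lock$registry
  out <- reg
  if (nrow(reg) >= 2)
    out <- rbind(out, cbind(reg[-nrow(reg), 1], reg[-1, 2]),
                 cbind(reg[-1, 1], reg[-nrow(reg), 2]))
  out
}

#' Chain topology for the coarse-grained polymer
#'
#' A residue-level two-bead (backbone + side-chain) polymer.  Residues
#' carry a category and a side-chain attraction well depth; an optional
#' [lock_spec()] plants an intramolecular strand pairing.  One or two
#' chains share a periodic cubic box.
#'
#' @param residues data.frame with columns `index`, `category`,
#'   `sidechain_epsilon`, `label`.
#' @param lock optional [lock_spec()].
#' @param n_chains 1 or 2.
#' @param box_edge periodic cube edge, nm.
#' @param backbone_bond_length,sidechain_bond_length bond lengths, nm.
#' @param bead_radii named radii (nm) of the backbone and side-chain
#'   beads, used for excluded volume and SASA.
#' @return an object of class `chain_topology`.
#' @export
chain_topology <- function(residues, lock = NULL, n_chains = 1L,
                           box_edge = 7, backbone_bond_length = 0.38,
                           sidechain_bond_length = 0.30,
                           bead_radii = c(backbone = 0.125,
                                          sidechain = 0.225)) {
  stopifnot(is.data.frame(residues),
            all(c("index", "category", "sidechain_epsilon", "label") %in%
                  names(residues)))
  n <- nrow(residues)
  if (n < 4) stop("chain length must be >= 4")
  if (!all(residues$index == seq_len(n)))
    stop("residue indices must be 1..n in order")
  if (any(residues$sidechain_epsilon < 0))
    stop("sidechain_epsilon must be >= 0")
  if (!all(residues$category %in% residue_categories))
    stop("unknown residue category")
  if (!n_chains %in% 1:2) stop("n_chains must be 1 or 2")
  if (!is.null(lock)) {
    stopifnot(inherits(lock, "lock_spec"))
    if (max(lock$segment_a, lock$segment_b) > n)
      stop("lock segments exceed chain length")
  }
  structure(list(residues = residues, lock = lock,
                 n_chains = as.integer(n_chains), box_edge = box_edge,
                 backbone_bond_length = backbone_bond_length,
                 sidechain_bond_length = sidechain_bond_length,
                 bead_radii = bead_radii),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  n <- nrow(x$residues)
  cat(sprintf("chain_topology: %d residues x %d chain(s), box %.1f nm\n",
              n, x$n_chains, x$box_edge))
  tb <- table(x$residues$category)
  cat("  composition:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (!is.null(x$lock))
    cat(sprintf("  lock: %d-%d vs %d-%d (epsilon_lock %.1f kJ/mol)\n",
                min(x$lock$segment_a), max(x$lock$segment_a),
                min(x$lock$segment_b), max(x$lock$segment_b),
                x$lock$epsilon_lock))
  invisible(x)
}

n_residues <- function(topology) nrow(topology$residues)
n_beads <- function(topology) 2L * n_residues(topology) * topology$n_chains

# sticker positions: a regular 6-residue grid inset from the termini
# (the terminal stretches around the fluorophore fusion points are
# spacer-like), locally adjusted so the two lock segments each contain
# one aromatic (positions 27 and 78)
sticker_positions <- function(length) {
  pos <- seq(9L, max(9L, length - 6L), by = 6L)
  if (length >= 84)
    pos <- sort(unique(c(setdiff(pos, c(75L, 81L)), 78L, 84L)))
  pos
}

base_residues <- function(length) {
  cat <- character(length)
  eps <- numeric(length)
  stick <- sticker_positions(length)
  for (i in seq_len(length)) {
    if (i %in% stick) {
      cat[i] <- "sticker"
    } else if (i %% 3L == 1L) {
      cat[i] <- "hydrophobic_spacer"
    } else if (i %% 3L == 2L) {
      cat[i] <- "polar_spacer"
    } else {
      cat[i] <- "flexible"
    }
    eps[i] <- default_epsilons[[cat[i]]]
  }
  letter <- c(sticker = "Y", hydrophobic_spacer = "L", polar_spacer = "S",
              flexible = "G")
  data.frame(index = seq_len(length), category = cat,
             sidechain_epsilon = eps,
             label = paste0(letter[cat], seq_len(length)),
             stringsAsFactors = FALSE)
}

# residue identities inside the lock segments (serine/asparagine-like
# polar positions, glycines and a proline around the aromatics)
lock_segment_identities <- function(res) {
  seg_a <- list(`25` = "polar_spacer", `26` = "polar_spacer",
                `27` = "sticker", `28` = "hydrophobic_spacer",
                `29` = "polar_spacer", `30` = "polar_spacer")
  seg_b <- list(`77` = "flexible", `78` = "sticker", `79` = "flexible",
                `80` = "flexible", `81` = "polar_spacer",
                `82` = "polar_spacer")
  for (nm in names(c(seg_a, seg_b))) {
    i <- as.integer(nm)
    catg <- c(seg_a, seg_b)[[nm]]
    res$category[i] <- catg
    res$sidechain_epsilon[i] <- default_epsilons[[catg]]
  }
  special <- c(`27` = "Y27", `28` = "L28", `29` = "S29", `30` = "N30",
               `77` = "G77", `78` = "Y78", `79` = "G79", `80` = "P80")
  for (nm in names(special)) res$label[as.integer(nm)] <- special[[nm]]
  res
}

default_lock_segments <- list(a = 25:30, b = 77:82)

#' Build a preset chain topology
#'
#' Presets mirroring the constructs studied in heat-sensing prion-like
#' domains: the wild type carries regularly spaced aromatic stickers and
#' a two-segment beta-strand lock between residues 25-30 and 77-82;
#' `y_to_s` lowers every sticker well depth to the polar-spacer level
#' (tyrosine-to-serine substitution) while keeping the lock; `m1` and
#' `m2` remove the lock energy by mutating four residues of the first
#' (Y27A, L28A, S29A, N30A) or second (G77A, Y78A, G79A, P80A) segment
#' to alanine-like beads; `no_lock_homopolymer` is a uniform spacer
#' chain without a lock.
#'
#' @param name one of `"wt"`, `"y_to_s"`, `"m1"`, `"m2"`,
#'   `"no_lock_homopolymer"`.
#' @param length residue count (>= 84 for the lock-bearing presets).
#' @param epsilon_lock lock well depth per registry pair, kJ/mol.
#' @param n_chains,box_edge passed to [chain_topology()].
#' @return a [chain_topology()].
#' @examples
#' wt <- build_preset("wt", 90)
#' wt$lock$segment_a
#' @export
build_preset <- function(name = c("wt", "y_to_s", "m1", "m2",
                                  "no_lock_homopolymer"),
                         length = 90L, epsilon_lock = 15,
                         n_chains = 1L, box_edge = 7) {
  name <- match.arg(name)
  length <- as.integer(length)
  if (name == "no_lock_homopolymer") {
    if (length < 4) stop("length too short")
    res <- data.frame(index = seq_len(length), category = "polar_spacer",
                      sidechain_epsilon = default_epsilons[["polar_spacer"]],
                      label = paste0("S", seq_len(length)),
                      stringsAsFactors = FALSE)
    return(chain_topology(res, lock = NULL, n_chains = n_chains,
                          box_edge = box_edge))
  }
  if (length < 84)
    stop("length must be >= 84 for presets with the 25-30/77-82 lock")
  res <- lock_segment_identities(base_residues(length))
  # weak zipper extension of the antiparallel register (i, 107 - i)
  # towards the chain ends, as far as the chain allows
  ext_i <- (max(1L, 107L - length)):24L
  ext <- cbind(ext_i, 107L - ext_i)
  lock <- lock_spec(default_lock_segments$a, default_lock_segments$b,
                    epsilon_lock = epsilon_lock, extension = ext,
                    epsilon_ext = 0.65 * epsilon_lock)
  if (name == "y_to_s") {
    res$sidechain_epsilon[res$category == "sticker"] <-
      default_epsilons[["polar_spacer"]]
  } else if (name %in% c("m1", "m2")) {
    mut <- if (name == "m1") 27:30 else 77:80
    res$category[mut] <- "flexible"
    res$sidechain_epsilon[mut] <- default_epsilons[["flexible"]]
    res$label[mut] <- paste0("A", mut)
    lock <- lock_spec(default_lock_segments$a, default_lock_segments$b,
                      epsilon_lock = 0, extension = ext, epsilon_ext = 0,
                      epsilon_pack = 0)
  }
  topo <- chain_topology(res, lock = lock, n_chains = n_chains,
                         box_edge = box_edge)
  attr(topo, "preset") <- name
  topo
}
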