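# Formats: multi-model PDB interchange (written directly, read back
# through bio3d), optional DCD input, run metadata and manifests.

cg_atom_table <- function(topology) {
  n <- n_residues(topology)
  nc <- topology$n_chains
  lab3 <- toupper(substr(paste0(topology$residues$label, "XX"), 1, 3))
  data.frame(
    elety = rep(c("CA", "CB"), n * nc),
    resid = rep(rep(lab3, nc), each = 2),
    chain = rep(LETTERS[seq_len(nc)], each = 2 * n),
    resno = rep(rep(seq_len(n), nc), each = 2),
    stringsAsFactors = FALSE)
}

#' Write an ensemble as multi-model PDB files
#'
#' One PDB per temperature rung (one MODEL per stored frame; backbone
#' beads as CA, side-chain beads as CB; chains A/B), coordinates
#' converted from nm to Angstrom, plus a `meta.json` with temperatures,
#' seed, exchange log, run settings and the topology needed to rebuild
#' selections on reading.
#'
#' @param ensemble an `ensemble_set`.
#' @param dir output directory (created).
#' @return invisibly, the written file paths.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  at <- cg_atom_table(ensemble$topology)
  files <- character(0)
  for (r in seq_along(ensemble$temperatures)) {
    fr <- ensemble$frames[[r]]
    nf <- dim(fr)[3]
    path <- file.path(dir, sprintf("ensemble_T%07.2fK.pdb",
                                   ensemble$temperatures[r]))
    con <- file(path, "w")
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- fr[, , f] * 10  # nm -> Angstrom
      lines <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nrow(xyz)), sprintf(" %-3s", at$elety), at$resid,
        at$chain, at$resno, xyz[, 1], xyz[, 2], xyz[, 3])
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    close(con)
    files <- c(files, path)
  }
  topo <- ensemble$topology
  meta <- list(
    temperatures = ensemble$temperatures, seed = ensemble$seed,
    n_sweeps = ensemble$n_sweeps, stride = ensemble$stride,
    exchange_interval = ensemble$exchange_interval,
    equilibration_fraction = ensemble$equilibration_fraction,
    config_digest = ensemble$config_digest,
    exchange_log = ensemble$exchange_log,
    files = basename(files),
    topology = list(
      residues = topo$residues, n_chains = topo$n_chains,
      box_edge = topo$box_edge,
      backbone_bond_length = topo$backbone_bond_length,
      sidechain_bond_length = topo$sidechain_bond_length,
      bead_radii = as.list(topo$bead_radii),
      lock = if (is.null(topo$lock)) NULL else list(
        segment_a = topo$lock$segment_a, segment_b = topo$lock$segment_b,
        registry = topo$lock$registry,
        epsilon_lock = topo$lock$epsilon_lock,
        r_lock = topo$lock$r_lock, w_lock = topo$lock$w_lock)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, file.path(dir, "meta.json")))
}

topology_from_meta <- function(m) {
  lock <- NULL
  if (!is.null(m$lock) && length(m$lock) > 0)
    lock <- lock_spec(m$lock$segment_a, m$lock$segment_b,
                      epsilon_lock = m$lock$epsilon_lock,
                      registry = as.matrix(m$lock$registry),
                      r_lock = m$lock$r_lock, w_lock = m$lock$w_lock)
  chain_topology(as.data.frame(m$residues), lock = lock,
                 n_chains = m$n_chains, box_edge = m$box_edge,
                 backbone_bond_length = m$backbone_bond_length,
                 sidechain_bond_length = m$sidechain_bond_length,
                 bead_radii = unlist(m$bead_radii))
}

# diagnose truncated multi-model PDB files before handing to bio3d
scan_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_at <- grep("^MODEL", lines)
  end_at <- grep("^ENDMDL", lines)
  if (length(model_at) == 0) stop("no MODEL records in ", path)
  if (length(end_at) < length(model_at))
    stop(sprintf("truncated trajectory: frame %d of '%s' has no ENDMDL",
                 length(model_at), basename(path)))
  counts <- vapply(seq_along(model_at), function(i)
    sum(grepl("^ATOM", lines[model_at[i]:end_at[i]])), integer(1))
  if (length(unique(counts)) != 1)
    stop(sprintf("truncated trajectory: frame %d of '%s' has %d atoms, expected %d",
                 which(counts != counts[1])[1], basename(path),
                 counts[which(counts != counts[1])[1]], counts[1]))
  length(model_at)
}

read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading trajectories requires the bio3d package")
  scan_multimodel_pdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                      # models x 3N, Angstrom
  nf <- nrow(xyz)
  na_ <- ncol(xyz) / 3
  arr <- array(0, c(na_, 3, nf))
  for (f in seq_len(nf))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # -> nm
  list(frames = arr, atoms = pdb$atom)
}

#' Read an ensemble
#'
#' Reads a directory written by [write_ensemble()] (multi-model PDB per
#' rung plus `meta.json`), a single multi-model PDB file, or a DCD
#' trajectory paired with a PDB topology.  Coordinates are returned in
#' nm whatever the source convention (PDB/DCD Angstroms are converted);
#' XTC input is not supported.
#'
#' @param path ensemble directory, PDB file, or DCD file.
#' @param topology_pdb PDB file giving the atom table for DCD input.
#' @param temperature temperature label for single-file input.
#' @return an `ensemble_set` (directory input rebuilds the topology and
#'   run metadata; file input yields a single-rung set whose `atoms`
#'   attribute carries the source atom table).
#' @export
read_ensemble <- function(path, topology_pdb = NULL, temperature = NA) {
  if (grepl("[.]xtc$", path, ignore.case = TRUE))
    stop("XTC input is not supported; convert to DCD or multi-model PDB")
  if (dir.exists(path)) {
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
    topo <- topology_from_meta(meta$topology)
    frames <- lapply(meta$files, function(f)
      read_pdb_frames(file.path(path, f))$frames)
    res <- list(frames = frames,
                energies = matrix(NA_real_, dim(frames[[1]])[3],
                                  length(frames)),
                sweeps = seq_len(dim(frames[[1]])[3]) * meta$stride,
                exch_attempts = meta$exchange_log$attempts,
                exch_accepts = meta$exchange_log$accepts,
                replica_walk = matrix(integer(0), 0, length(frames)),
                move_accept_rate = NA_real_)
    ens <- new_ensemble_set(topo, energy_model(), meta$temperatures, res,
                            meta$seed, meta$equilibration_fraction,
                            meta$stride, meta$n_sweeps,
                            meta$exchange_interval)
    ens$config_digest <- meta$config_digest
    return(ens)
  }
  if (grepl("[.]dcd$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading trajectories requires the bio3d package")
    if (is.null(topology_pdb))
      stop("DCD input needs `topology_pdb`")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    pdb <- bio3d::read.pdb(topology_pdb)
    if (ncol(xyz) != length(pdb$xyz))
      stop("topology/trajectory atom-count mismatch")
    nf <- nrow(xyz)
    na_ <- ncol(xyz) / 3
    arr <- array(0, c(na_, 3, nf))
    for (f in seq_len(nf))
      arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    out <- list(frames = arr, atoms = pdb$atom)
  } else {
    out <- read_pdb_frames(path)
  }
  structure(list(frames = list(out$frames), temperatures = temperature,
                 equilibration_fraction = 0, atoms = out$atoms),
            class = "ensemble_view")
}

#' Selection of side-chain heavy atoms from a PDB atom table
#'
#' Builds the [structure_selection()] for externally supplied all-atom
#' structures: all heavy atoms that are not backbone (N, CA, C, O, OXT)
#' and not hydrogen, grouped into residues by chain + residue number.
#' Glycine-like residues without side-chain atoms are skipped (their
#' rows stay empty) with a message.
#'
#' @param atoms bio3d-style atom data.frame (`elety`, `chain`, `resno`,
#'   `elesy` optional).
#' @return a [structure_selection()].
#' @export
pdb_selection <- function(atoms) {
  rid <- paste(atoms$chain, atoms$resno)
  resu <- unique(rid)
  rmap <- match(rid, resu)
  backbone <- atoms$elety %in% c("N", "CA", "C", "O", "OXT")
  hydrogen <- grepl("^[0-9]*H", atoms$elety)
  side <- which(!backbone & !hydrogen)
  missing <- setdiff(seq_along(resu), unique(rmap[side]))
  if (length(missing) > 0)
    message(length(missing),
            " residue(s) without side-chain atoms skipped")
  res_chain <- match(sub(" .*", "", resu), unique(atoms$chain))
  res_index <- as.integer(sub(".* ", "", resu))
  structure_selection(atom_index = side, atom_res = rmap[side],
                      res_chain = res_chain, res_index = res_index,
                      n_res = length(resu))
}

#' Run manifest
#'
#' Writes a JSON manifest tying outputs to the configuration, seed and
#' inputs that produced them.
#'
#' @param path output JSON path.
#' @param config configuration list (digested).
#' @param seed RNG seed.
#' @param inputs,outputs character vectors of file paths.
#' @return invisibly, the manifest list.
#' @export
run_manifest <- function(path, config, seed, inputs = character(0),
                         outputs = character(0)) {
  manifest <- list(tool = "thermolock",
                   version = as.character(utils::packageVersion("thermolock")),
                   config_digest = config_digest(config), seed = seed,
                   inputs = inputs, outputs = outputs,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a YAML run configuration
#'
#' Sections `sequence`, `energy`, `ladder`, `run`; all fields optional
#' except `run$seed`.
#'
#' @param path YAML file.
#' @return named list with the four sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (s in c("sequence", "energy", "ladder", "run"))
    if (is.null(cfg[[s]])) cfg[[s]] <- list()
  if (is.null(cfg$run$seed))
    stop("config must set run$seed")
  cfg
}

#' Write metric tables as TSV
#'
#' Long-format metric table (frame, temperature, metric, value).
#'
#' @param series list of `metric_series`.
#' @param path output TSV.
#' @return invisibly, the data.frame written.
#' @export
write_metric_tsv <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(frame = if (!is.null(s$frame_index)) s$frame_index
               else seq_along(s$values),
               temperature = if (is.null(s$temperature)) NA
               else s$temperature,
               metric = if (is.null(s$metric)) "value" else s$metric,
               value = s$values))
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
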