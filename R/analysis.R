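# Thermo-switch inference: per-residue delta-contact profiles between a
# low and a high temperature, group contact heatmaps, and algorithmic
# detection of the beta-strand lock segments.

# per-retained-frame row sums of the intramolecular contact matrix
contact_rowsums <- function(ensemble, temperature = NULL,
                            config = analysis_config()) {
  sel <- cg_selection(ensemble$topology)
  fr <- ensemble_frames(ensemble, temperature, retained_only = TRUE)
  nf <- dim(fr)[3]
  out <- matrix(0, sel$n_res, nf)
  for (f in seq_len(nf)) {
    m <- side_chain_contacts(fr[, , f], sel, config, "intramolecular",
                             box = ensemble$topology$box_edge)
    out[, f] <- rowSums(m)
  }
  out
}

block_boot_mean <- function(mat, block_count = 10L, n_boot = 200L) {
  # bootstrap of per-frame column blocks; returns matrix rows x n_boot
  nf <- ncol(mat)
  blk <- cut(seq_len(nf), block_count, labels = FALSE)
  means <- vapply(seq_len(block_count), function(b)
    rowMeans(mat[, blk == b, drop = FALSE]), numeric(nrow(mat)))
  vapply(seq_len(n_boot), function(i)
    rowMeans(means[, sample.int(block_count, replace = TRUE),
                   drop = FALSE]),
    numeric(nrow(mat)))
}

#' Per-residue delta-contact profile
#'
#' For each residue, the change between two temperatures of its summed
#' intramolecular contact frequency,
#' `sum_j [freq(i, j; T_hi) - freq(i, j; T_lo)]`, over the retained
#' frames; positive values are contact gain on heating, negative values
#' contact loss.  Per-residue bootstrap confidence intervals come from
#' block-bootstrapping frames within each ensemble.
#'
#' @param ensemble_lo,ensemble_hi `ensemble_set`s sharing the chain
#'   definition (may be the same multi-rung set).
#' @param t_lo,t_hi rung temperatures (K) to compare.
#' @param config an [analysis_config()].
#' @param block_count,n_boot bootstrap settings.
#' @param ci confidence level.
#' @return object of class `delta_contact_profile` with fields `delta`,
#'   `ci_lo`, `ci_hi`, `t_lo`, `t_hi`.
#' @export
delta_contact_profile <- function(ensemble_lo, ensemble_hi = ensemble_lo,
                                  t_lo = NULL, t_hi = NULL,
                                  config = analysis_config(),
                                  block_count = 10L, n_boot = 200L,
                                  ci = 0.95) {
  if (n_residues(ensemble_lo$topology) != n_residues(ensemble_hi$topology))
    stop("ensembles have different chain lengths")
  lo <- contact_rowsums(ensemble_lo, t_lo, config)
  hi <- contact_rowsums(ensemble_hi, t_hi, config)
  delta <- rowMeans(hi) - rowMeans(lo)
  blo <- block_boot_mean(lo, block_count, n_boot)
  bhi <- block_boot_mean(hi, block_count, n_boot)
  bdelta <- bhi - blo
  a <- (1 - ci) / 2
  structure(list(
    delta = delta,
    ci_lo = apply(bdelta, 1, stats::quantile, probs = a),
    ci_hi = apply(bdelta, 1, stats::quantile, probs = 1 - a),
    t_lo = ensemble_lo$temperatures[rung_index(ensemble_lo, t_lo)],
    t_hi = ensemble_hi$temperatures[rung_index(ensemble_hi, t_hi)]),
    class = "delta_contact_profile")
}

#' @export
print.delta_contact_profile <- function(x, ...) {
  cat(sprintf(
    "delta_contact_profile %.1f -> %.1f K: mean %+.3f, %d residues negative\n",
    x$t_lo, x$t_hi, mean(x$delta), sum(x$delta < 0)))
  invisible(x)
}

#' Group contact heatmap
#'
#' Mean pairwise contact frequency between residue groups at each
#' requested temperature.
#'
#' @param ensembles a named list of `ensemble_set`s, or one multi-rung
#'   set (then `temperatures` selects rungs).
#' @param groups named list of residue index ranges.
#' @param temperatures rung temperatures (used with a single set).
#' @param config an [analysis_config()].
#' @return object of class `contact_heatmap`: list of group x group
#'   matrices, one per temperature.
#' @export
group_contact_heatmap <- function(ensembles, groups, temperatures = NULL,
                                  config = analysis_config()) {
  if (inherits(ensembles, "ensemble_set")) {
    if (is.null(temperatures)) temperatures <- ensembles$temperatures
    ensembles <- setNames(rep(list(ensembles), length(temperatures)),
                          sprintf("%.1fK", temperatures))
  } else temperatures <- vapply(ensembles, function(e)
    e$temperatures[1], numeric(1))
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  maps <- lapply(seq_along(ensembles), function(k) {
    cm <- contact_map(ensembles[[k]], temperatures[k],
                      "intramolecular", config)
    g <- length(groups)
    out <- matrix(0, g, g, dimnames = list(names(groups), names(groups)))
    for (i in seq_len(g)) for (j in seq_len(g))
      out[i, j] <- mean(cm$matrix[groups[[i]], groups[[j]]])
    out
  })
  names(maps) <- names(ensembles)
  structure(list(maps = maps, temperatures = temperatures,
                 groups = groups),
            class = "contact_heatmap")
}

# maximal runs of >= min_run consecutive residues with delta below
# -threshold
negative_runs <- function(delta, threshold, min_run) {
  neg <- delta < -threshold
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

segment_mean_strand <- function(strand, segment) mean(strand[segment])

#' Detect beta-strand lock segments
#'
#' Formalises the lock diagnosis as three criteria: (1) maximal runs of
#' at least `min_run` consecutive residues whose delta-contact value
#' (see [delta_contact_profile()]) lies below `-delta_threshold` while
#' the chain-wide mean delta is positive; (2) a candidate pair of such
#' runs must be in persistent contact at the low temperature: the
#' maximum cross-segment pair contact frequency must reach
#' `contact_floor` (the maximum rather than the cross-block mean,
#' because strand-paired segments touch through a few persistent
#' residue pairs); (3) the mean beta-strand probability of both
#' segments must drop by at least `strand_drop` from the low to the
#' high temperature.  The verdict is `lock_detected` when at least one
#' segment pair passes all three.  The thresholds are constants of the
#' detector, tuned once against the synthetic generator (whose
#' coarse-grained strand probabilities are lower than atomistic ones,
#' hence the small default `strand_drop`).
#'
#' @inheritParams delta_contact_profile
#' @param delta_threshold delta-contact threshold (default 0: any net
#'   loss).
#' @param min_run minimum run length, residues.
#' @param contact_floor minimum low-temperature cross-segment peak
#'   contact frequency.
#' @param strand_drop minimum strand-probability drop.
#' @return object of class `lock_call`.
#' @export
detect_lock <- function(ensemble_lo, ensemble_hi = ensemble_lo,
                        t_lo = NULL, t_hi = NULL,
                        config = analysis_config(),
                        delta_threshold = 0, min_run = 3L,
                        contact_floor = 0.3, strand_drop = 0.05) {
  profile <- delta_contact_profile(ensemble_lo, ensemble_hi, t_lo, t_hi,
                                   config, n_boot = 50L)
  global_mean <- mean(profile$delta)
  runs <- negative_runs(profile$delta, delta_threshold, min_run)
  thresholds <- list(delta_threshold = delta_threshold, min_run = min_run,
                     contact_floor = contact_floor,
                     strand_drop = strand_drop)
  no_lock <- function(evidence) {
    structure(list(segments = list(), pairs = list(),
                   verdict = "no_lock", profile = profile,
                   global_mean_delta = global_mean,
                   thresholds = thresholds, evidence = evidence),
              class = "lock_call")
  }
  if (global_mean <= 0 || length(runs) < 2)
    return(no_lock("no candidate runs under a positive global mean"))
  cm_lo <- contact_map(ensemble_lo, t_lo, "intramolecular", config)
  cm_hi <- contact_map(ensemble_hi, t_hi, "intramolecular", config)
  strand_lo <- beta_strand_probability(ensemble_lo, t_lo, config)
  strand_hi <- beta_strand_probability(ensemble_hi, t_hi, config)
  pairs <- list()
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (j <= i) next
    a <- runs[[i]]; b <- runs[[j]]
    inter_lo <- max(cm_lo$matrix[a, b])
    inter_hi <- max(cm_hi$matrix[a, b])
    if (inter_lo < contact_floor) next
    drop_a <- segment_mean_strand(strand_lo, a) -
      segment_mean_strand(strand_hi, a)
    drop_b <- segment_mean_strand(strand_lo, b) -
      segment_mean_strand(strand_hi, b)
    if (drop_a < strand_drop || drop_b < strand_drop) next
    pairs[[length(pairs) + 1L]] <- list(
      segment_a = a, segment_b = b,
      inter_segment_contact = c(t_lo = inter_lo, t_hi = inter_hi),
      strand_probability = rbind(
        t_lo = c(a = segment_mean_strand(strand_lo, a),
                 b = segment_mean_strand(strand_lo, b)),
        t_hi = c(a = segment_mean_strand(strand_hi, a),
                 b = segment_mean_strand(strand_hi, b))))
  }
  if (length(pairs) == 0)
    return(no_lock("candidate runs failed the contact or strand criteria"))
  segs <- unique(unlist(lapply(pairs, function(p)
    list(p$segment_a, p$segment_b)), recursive = FALSE))
  structure(list(segments = segs, pairs = pairs,
                 verdict = "lock_detected", profile = profile,
                 global_mean_delta = global_mean,
                 thresholds = thresholds, evidence = "all criteria met"),
            class = "lock_call")
}

#' @export
print.lock_call <- function(x, ...) {
  cat(sprintf("lock_call: %s (global mean delta %+.3f)\n", x$verdict,
              x$global_mean_delta))
  for (s in x$segments)
    cat(sprintf("  segment %d-%d\n", min(s), max(s)))
  invisible(x)
}

#' Monotone trend of per-rung means
#'
#' Spearman correlation of per-rung ensemble means against temperature
#' with a block-bootstrap confidence interval, classified as
#' `decreasing` (CI entirely below 0), `increasing` (entirely above) or
#' `flat`.
#'
#' @param values_by_rung list of per-frame value vectors, one per rung
#'   (already restricted to retained frames).
#' @param temperatures rung temperatures.
#' @param block_count,n_boot,ci bootstrap settings.
#' @return object of class `trend_report` with `means`, `rho`, `ci`,
#'   `classification`.
#' @export
trend_report <- function(values_by_rung, temperatures, block_count = 10L,
                         n_boot = 400L, ci = 0.95) {
  if (length(values_by_rung) < 3) stop("need >= 3 rungs")
  safe_rho <- function(m) {
    r <- suppressWarnings(stats::cor(m, temperatures, method = "spearman"))
    if (is.na(r)) 0 else r
  }
  means <- vapply(values_by_rung, mean, numeric(1))
  boot_rho <- vapply(seq_len(n_boot), function(b) {
    bm <- vapply(values_by_rung, function(v) {
      blk <- cut(seq_along(v), block_count, labels = FALSE)
      pick <- sample.int(block_count, replace = TRUE)
      mean(unlist(lapply(pick, function(k) v[blk == k])))
    }, numeric(1))
    safe_rho(bm)
  }, numeric(1))
  a <- (1 - ci) / 2
  lo <- stats::quantile(boot_rho, a)
  hi <- stats::quantile(boot_rho, 1 - a)
  cls <- if (hi < 0) "decreasing" else if (lo > 0) "increasing" else "flat"
  structure(list(means = means, temperatures = temperatures,
                 rho = safe_rho(means), ci = c(lo, hi),
                 classification = cls),
            class = "trend_report")
}

#' Radius-of-gyration trend over a ladder
#'
#' Per-rung mean Rg against temperature (see [trend_report()]).
#'
#' @param ensemble a multi-rung `ensemble_set` (>= 3 rungs).
#' @param config an [analysis_config()].
#' @param block_count,n_boot bootstrap settings.
#' @return a `trend_report`.
#' @export
rg_trend <- function(ensemble, config = analysis_config(),
                     block_count = 10L, n_boot = 400L) {
  temps <- ensemble$temperatures
  if (length(temps) < 3) stop("need >= 3 ladder rungs")
  vals <- lapply(temps, function(t) {
    fr <- ensemble_frames(ensemble, t, retained_only = TRUE)
    vapply(seq_len(dim(fr)[3]), function(f)
      radius_of_gyration(fr[, , f]), numeric(1))
  })
  trend_report(vals, temps, block_count, n_boot)
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("trend_report: %s (rho %+.2f, CI [%+.2f, %+.2f])\n",
              x$classification, x$rho, x$ci[1], x$ci[2]))
  invisible(x)
}
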