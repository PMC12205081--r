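# Forward FRET model: donor lifetime predicted from conformational
# ensembles of a chain with terminal donor/acceptor fusions.

#' FRET parameters
#'
#' Donor/acceptor photophysics and attachment sites.  Defaults are
#' representative literature constants for a GFP-mCherry pair
#' (Forster radius 5.4 nm, unquenched donor lifetime 2.6 ns); sites
#' default to the chain termini.
#'
#' @param forster_radius_R0 nm (> 0).
#' @param donor_lifetime_tau_D ns (> 0).
#' @param donor_site,acceptor_site residue indices of the fluorophore
#'   attachment points.
#' @return object of class `fret_params`.
#' @export
fret_params <- function(forster_radius_R0 = 5.4,
                        donor_lifetime_tau_D = 2.6,
                        donor_site = 1L, acceptor_site = NULL) {
  if (forster_radius_R0 <= 0 || donor_lifetime_tau_D <= 0)
    stop("R0 and tau_D must be positive")
  structure(list(forster_radius_R0 = forster_radius_R0,
                 donor_lifetime_tau_D = donor_lifetime_tau_D,
                 donor_site = as.integer(donor_site),
                 acceptor_site = if (is.null(acceptor_site)) NULL
                 else as.integer(acceptor_site)),
            class = "fret_params")
}

#' Forster transfer efficiency
#'
#' `E = 1 / (1 + (r / R0)^6)`, strictly decreasing in the
#' donor-acceptor distance `r`.
#'
#' @param r distance, nm (> 0).
#' @param R0 Forster radius, nm.
#' @return efficiency in (0, 1).
#' @export
fret_efficiency <- function(r, R0) {
  if (any(r <= 0)) stop("distance must be positive")
  1 / (1 + (r / R0)^6)
}

#' Predict donor lifetime from an ensemble
#'
#' Per retained frame, the transfer efficiency follows from the
#' donor-site to acceptor-site backbone distance; the predicted mean
#' donor lifetime is `tau_D * (1 - <E>)` under the static-frame
#' assumption (each frame contributes a fully quenched or unquenched
#' sub-population in proportion to its efficiency).  The confidence
#' interval is a block bootstrap over frames.
#'
#' @param ensemble an `ensemble_set`.
#' @param params a [fret_params()].
#' @param temperature rung temperature (default: all rungs).
#' @param block_count,n_boot,ci bootstrap settings.
#' @return object of class `fret_prediction`: data.frame with one row
#'   per rung (temperature, mean_efficiency, lifetime, ci_lo, ci_hi)
#'   plus per-frame efficiencies in `attr(, "per_frame")`.
#' @export
predict_lifetime <- function(ensemble, params = fret_params(),
                             temperature = NULL, block_count = 10L,
                             n_boot = 400L, ci = 0.95) {
  topo <- ensemble$topology
  n <- n_residues(topo)
  acceptor <- if (is.null(params$acceptor_site)) n else params$acceptor_site
  if (params$donor_site < 1 || params$donor_site > n ||
      acceptor < 1 || acceptor > n)
    stop("fluorophore sites outside the chain")
  temps <- if (is.null(temperature)) ensemble$temperatures else temperature
  per_frame <- list()
  rows <- lapply(temps, function(t) {
    fr <- ensemble_frames(ensemble, t, retained_only = TRUE)
    d_bead <- 2L * params$donor_site - 1L      # backbone beads
    a_bead <- 2L * acceptor - 1L
    r <- sqrt(colSums((fr[d_bead, , ] - fr[a_bead, , ])^2))
    eff <- fret_efficiency(r, params$forster_radius_R0)
    per_frame[[sprintf("%.1f", t)]] <<- eff
    nb <- max(1L, min(block_count, length(eff)))
    blk <- cut(seq_along(eff), nb, labels = FALSE)
    bm <- vapply(seq_len(nb), function(k)
      mean(eff[blk == k]), numeric(1))
    boots <- vapply(seq_len(n_boot), function(b)
      mean(bm[sample.int(nb, replace = TRUE)]), numeric(1))
    a2 <- (1 - ci) / 2
    tau <- params$donor_lifetime_tau_D
    data.frame(temperature = ensemble$temperatures[rung_index(ensemble, t)],
               mean_efficiency = mean(eff),
               lifetime = tau * (1 - mean(eff)),
               ci_lo = tau * (1 - stats::quantile(boots, 1 - a2)),
               ci_hi = tau * (1 - stats::quantile(boots, a2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_frame") <- per_frame
  attr(out, "params") <- params
  class(out) <- c("fret_prediction", "data.frame")
  out
}

#' @export
print.fret_prediction <- function(x, ...) {
  cat("fret_prediction (tau_D =",
      attr(x, "params")$donor_lifetime_tau_D, "ns):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
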