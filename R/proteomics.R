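# Label-free proteomics enrichment statistics: top-3 quantification,
# replicate-minimum imputation, fold-change calls and an empirical-Bayes
# moderated t-test, plus a planted-truth synthetic generator.

#' Synthetic proteome with planted enrichment
#'
#' Generates a peptide-level area table emulating a bait-vs-control
#' label-free experiment: per-protein log-normal base abundances,
#' per-peptide response factors, replicate-level multiplicative noise, a
#' planted enriched subset with a fixed log2 effect in the bait
#' condition, and missingness that is either intensity-dependent
#' (`"MNAR-low"`: low-abundance measurements are preferentially lost)
#' or completely at random (`"MCAR"`).
#'
#' @param n_proteins number of proteins.
#' @param n_enriched number of planted enriched proteins.
#' @param log2_effect true log2 fold change of the planted set.
#' @param n_replicates replicates per condition (default 4).
#' @param sigma replicate-level noise SD on the log2 scale (> 0).
#' @param missing_rate overall fraction of missing peptide measurements.
#' @param missing_mechanism `"MNAR-low"` or `"MCAR"`.
#' @param peptides_per_protein range of peptide counts per protein.
#' @param seed optional RNG seed.
#' @return list with `peptides` (data.frame: protein, peptide,
#'   replicate, condition, area) and `truth` (the planted protein ids).
#' @export
simulate_proteome <- function(n_proteins = 1000L, n_enriched = 100L,
                              log2_effect = 2, n_replicates = 4L,
                              sigma = 0.5, missing_rate = 0.15,
                              missing_mechanism = c("MNAR-low", "MCAR"),
                              peptides_per_protein = 3:8, seed = NULL) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (n_enriched > n_proteins) stop("n_enriched must be <= n_proteins")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  prot <- sprintf("P%04d", seq_len(n_proteins))
  enriched <- prot[seq_len(n_enriched)]
  npep <- sample(peptides_per_protein, n_proteins, replace = TRUE)
  base_log2 <- rnorm(n_proteins, mean = 20, sd = 1.5)
  # one row per (protein, peptide, replicate, condition)
  n_cells <- 2L * n_replicates
  pep_protein <- rep(seq_len(n_proteins), npep)
  pep_within <- sequence(npep)
  pep_off <- rnorm(length(pep_protein), 0, 1)  # peptide response factors
  row_pep <- rep(seq_along(pep_protein), each = n_cells)
  row_prot <- pep_protein[row_pep]
  condition <- rep(rep(c("bait", "control"), each = n_replicates),
                   length(pep_protein))
  replicate <- rep(seq_len(n_replicates), 2L * length(pep_protein))
  eff <- ifelse(condition == "bait" & row_prot <= n_enriched,
                log2_effect, 0)
  l2 <- base_log2[row_prot] + pep_off[row_pep] + eff +
    rnorm(length(row_pep), 0, sigma)
  tab <- data.frame(protein = prot[row_prot],
                    peptide = sprintf("%s_pep%d", prot[row_prot],
                                      pep_within[row_pep]),
                    replicate = replicate, condition = condition,
                    area = 2^l2, stringsAsFactors = FALSE)
  n <- nrow(tab)
  if (missing_rate > 0) {
    if (missing_mechanism == "MCAR") {
      drop <- runif(n) < missing_rate
    } else {
      # logistic in the within-table abundance rank: low areas lost more
      z <- scale(rank(tab$area) / n)[, 1]
      lin <- -z * 1.5
      p0 <- stats::uniroot(function(b)
        mean(stats::plogis(lin + b)) - missing_rate, c(-20, 20))$root
      drop <- runif(n) < stats::plogis(lin + p0)
    }
    tab$area[drop] <- NA_real_
  }
  list(peptides = tab, truth = enriched)
}

sample_key <- function(condition, replicate)
  paste(condition, replicate, sep = "_")

new_protein_quant <- function(areas, condition, replicate, provenance,
                              imputed = NULL) {
  structure(list(areas = areas, condition = condition,
                 replicate = replicate, provenance = provenance,
                 imputed = imputed),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins x %d samples (%s), %d missing\n",
              nrow(x$areas), ncol(x$areas), x$provenance,
              sum(is.na(x$areas))))
  invisible(x)
}

#' Top-3 protein quantification
#'
#' Per protein and replicate, the protein area is the mean of its three
#' largest peptide areas within that replicate (all observed peptides
#' when fewer than three); a replicate cell with no observed peptide
#' stays missing.
#'
#' @param peptides data.frame with columns `protein`, `peptide`,
#'   `replicate`, `condition` (`"bait"`/`"control"`), `area` (positive
#'   or `NA`).
#' @return a `protein_quant` (protein x sample area matrix with a
#'   missing mask).
#' @export
top3_protein_area <- function(peptides) {
  need <- c("protein", "peptide", "replicate", "condition", "area")
  if (!all(need %in% names(peptides)))
    stop("peptide table must have columns ",
         paste(need, collapse = ", "))
  if (any(peptides$area <= 0, na.rm = TRUE))
    stop("peptide areas must be positive")
  prot <- sort(unique(peptides$protein))
  cond <- c("bait", "control")
  reps <- sort(unique(peptides$replicate))
  samples <- as.vector(outer(cond, reps, sample_key))
  areas <- matrix(NA_real_, length(prot), length(samples),
                  dimnames = list(prot, samples))
  key <- sample_key(peptides$condition, peptides$replicate)
  grp <- split(peptides$area, list(peptides$protein, key), drop = FALSE,
               sep = "\r")
  for (g in names(grp)) {
    v <- grp[[g]]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    pk <- strsplit(g, "\r", fixed = TRUE)[[1]]
    areas[pk[1], pk[2]] <- mean(sort(v, decreasing = TRUE)[
      seq_len(min(3L, length(v)))])
  }
  new_protein_quant(areas,
                    condition = sub("_.*", "", samples),
                    replicate = as.integer(sub(".*_", "", samples)),
                    provenance = "from_peptides")
}

#' Protein-level quant table from a wide matrix
#'
#' @param areas protein x sample matrix (columns `bait_1`, ...,
#'   `control_1`, ...).
#' @return a `protein_quant` with provenance `"direct"`.
#' @export
protein_quant <- function(areas) {
  cn <- colnames(areas)
  if (is.null(cn) || !all(grepl("^(bait|control)_\\d+$", cn)))
    stop("columns must be named bait_<r> / control_<r>")
  if (any(areas <= 0, na.rm = TRUE)) stop("areas must be positive")
  new_protein_quant(as.matrix(areas), condition = sub("_.*", "", cn),
                    replicate = as.integer(sub(".*_", "", cn)),
                    provenance = "direct")
}

#' Replicate-minimum imputation
#'
#' Replaces every missing protein-level cell by a single constant: the
#' mean over replicate columns of the minimum observed area in that
#' column.
#'
#' @param quant a `protein_quant`.
#' @return the imputed `protein_quant`; `$imputed` holds the logical
#'   mask and `attr(, "imputation")` the constant and count.
#' @export
impute_missing <- function(quant) {
  stopifnot(inherits(quant, "protein_quant"))
  a <- quant$areas
  col_min <- apply(a, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("a replicate column is entirely missing")
    min(x)
  })
  value <- mean(col_min)
  mask <- is.na(a)
  a[mask] <- value
  out <- new_protein_quant(a, quant$condition, quant$replicate,
                           quant$provenance, imputed = mask)
  attr(out, "imputation") <- list(value = value, count = sum(mask),
                                  column_minima = col_min)
  out
}

enrichment_frame <- function(quant, arm) {
  bait <- quant$areas[, quant$condition == "bait", drop = FALSE]
  ctrl <- quant$areas[, quant$condition == "control", drop = FALSE]
  mb <- rowMeans(bait)
  mc <- rowMeans(ctrl)
  data.frame(protein = rownames(quant$areas), mean_bait = mb,
             mean_control = mc, log2_fold_change = log2(mb / mc),
             moderated_t = NA_real_, p_value = NA_real_,
             adjusted_p = NA_real_, enriched = NA, arm = arm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change enrichment call (proximity-labeling arm)
#'
#' Fold change is the mean bait area over the mean control area; a
#' protein is enriched when `log2FC >= 1` (at least two-fold).
#'
#' @param quant an imputed `protein_quant` (no missing cells).
#' @return an `enrichment_table` data.frame.
#' @export
fold_change_call <- function(quant) {
  stopifnot(inherits(quant, "protein_quant"))
  if (any(is.na(quant$areas)))
    stop("impute missing values first (see impute_missing)")
  out <- enrichment_frame(quant, arm = "turboid")
  out$enriched <- out$log2_fold_change >= 1
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# Inverse of trigamma by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (it in 1:75) {
      tri <- psigamma(x, 1)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the scaled inverse-chi-square prior on
# per-protein variances: matches mean and variance of log s^2 using
# digamma/trigamma moments of the log F distribution.
fit_variance_prior <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2)
    return(list(d0 = Inf, s02 = if (length(z)) exp(mean(z)) else 0))
  e_z <- mean(z) - digamma(df / 2) + log(df / 2)
  v_z <- var(z) - psigamma(df / 2, 1)
  if (v_z <= 0) return(list(d0 = Inf, s02 = exp(e_z)))
  d0 <- 2 * trigamma_inverse(v_z)
  s02 <- exp(e_z + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test enrichment call (IP-MS arm)
#'
#' Two-condition empirical-Bayes moderated t-test on log2 areas: the
#' per-protein pooled variance is shrunk towards a prior fitted by the
#' method of moments on the log sample variances (scaled
#' inverse-chi-square with `d0` prior degrees of freedom and scale
#' `s0^2`), giving `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` and a t
#' statistic with `d + d0` degrees of freedom.  P values are
#' Benjamini-Hochberg adjusted; a protein is enriched when the adjusted
#' p is below 0.05 and `log2FC >= 1`.
#'
#' @param quant an imputed `protein_quant` with >= 2 replicates per
#'   condition.
#' @return an `enrichment_table` data.frame (includes `moderated_t`,
#'   `p_value`, `adjusted_p`; prior in `attr(, "prior")`).
#' @export
moderated_test <- function(quant) {
  stopifnot(inherits(quant, "protein_quant"))
  if (any(is.na(quant$areas)))
    stop("impute missing values first (see impute_missing)")
  bait <- log2(quant$areas[, quant$condition == "bait", drop = FALSE])
  ctrl <- log2(quant$areas[, quant$condition == "control", drop = FALSE])
  n1 <- ncol(bait); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")
  d <- n1 + n2 - 2
  diff <- rowMeans(bait) - rowMeans(ctrl)
  s2 <- ((n1 - 1) * apply(bait, 1, var) +
           (n2 - 1) * apply(ctrl, 1, var)) / d
  prior <- fit_variance_prior(s2, d)
  if (is.finite(prior$d0)) {
    s2_tilde <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
    df_total <- d + prior$d0
  } else {
    s2_tilde <- rep(prior$s02, length(s2))
    df_total <- Inf
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- 2 * pt(-abs(t), df = df_total)
  out <- enrichment_frame(quant, arm = "ipms")
  out$moderated_t <- t
  out$p_value <- p
  out$adjusted_p <- p.adjust(p, method = "BH")
  out$enriched <- out$adjusted_p < 0.05 & out$log2_fold_change >= 1
  attr(out, "prior") <- prior
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table (%s arm): %d proteins, %d enriched\n",
              x$arm[1], nrow(x), sum(x$enriched)))
  invisible(x)
}

#' Full enrichment pipeline from a table
#'
#' Convenience wrapper: quantify (if peptide-level), impute, then call
#' enrichment for the requested arm.  Returns the `enrichment_table`.
#'
#' @param table peptide-level data.frame (see [top3_protein_area()]) or
#'   protein x sample matrix (see [protein_quant()]).
#' @param arm `"turboid"` (fold-change call) or `"ipms"` (moderated
#'   test).
#' @return an `enrichment_table`.
#' @export
enrichment_pipeline <- function(table, arm = c("turboid", "ipms")) {
  arm <- match.arg(arm)
  quant <- if (is.data.frame(table) && "peptide" %in% names(table))
    top3_protein_area(table) else protein_quant(as.matrix(table))
  quant <- impute_missing(quant)
  if (arm == "turboid") fold_change_call(quant) else moderated_test(quant)
}

#' Read a peptide- or protein-level TSV
#'
#' Peptide dialect: columns protein, peptide, replicate, condition,
#' area (missing as empty or NA).  Protein dialect: first column
#' protein id, remaining columns `bait_<r>` / `control_<r>`.
#'
#' @param path TSV file.
#' @return data.frame (peptide dialect) or matrix (protein dialect).
#' @export
read_quant_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
  if ("peptide" %in% names(tab)) return(tab)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
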