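pep_row <- function(protein, peptide, replicate, condition, area) {
  data.frame(protein = protein, peptide = peptide, replicate = replicate,
             condition = condition, area = area,
             stringsAsFactors = FALSE)
}

test_that("top-3 quantification follows the stated rule", {
  tab <- rbind(
    pep_row("P1", paste0("a", 1:4), 1, "bait", c(10, 20, 30, 40)),
    pep_row("P1", paste0("a", 1:2), 1, "control", c(10, 20)),
    pep_row("P2", "b1", 1, "bait", 7))
  q <- top3_protein_area(tab)
  expect_equal(q$areas["P1", "bait_1"], mean(c(40, 30, 20)))
  expect_equal(q$areas["P1", "control_1"], 15)  # fewer than three
  expect_equal(q$areas["P2", "bait_1"], 7)
  expect_true(is.na(q$areas["P2", "control_1"]))
  expect_error(top3_protein_area(transform(tab, area = -area)),
               "positive")

  # random tables against an exhaustive sort-and-average oracle
  set.seed(5)
  sim <- simulate_proteome(n_proteins = 50, n_enriched = 5,
                           missing_rate = 0.2, seed = 5)
  q <- top3_protein_area(sim$peptides)
  with_key <- split(sim$peptides,
                    list(sim$peptides$protein,
                         paste(sim$peptides$condition,
                               sim$peptides$replicate, sep = "_")))
  for (g in sample(names(with_key), 40)) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    v <- sort(with_key[[g]]$area[!is.na(with_key[[g]]$area)],
              decreasing = TRUE)
    want <- if (length(v) == 0) NA_real_
            else mean(v[seq_len(min(3, length(v)))])
    expect_equal(q$areas[parts[1], parts[2]], want)
  }
})

test_that("imputation uses the mean of per-replicate minima", {
  a <- matrix(c(1, 10, NA, 2, 20, 5, 3, NA, 7, 4, 6, 8), nrow = 3)
  colnames(a) <- c("bait_1", "bait_2", "control_1", "control_2")
  rownames(a) <- paste0("P", 1:3)
  q <- impute_missing(protein_quant(a))
  expect_equal(attr(q, "imputation")$value, mean(c(1, 2, 3, 4)))
  expect_equal(attr(q, "imputation")$count, 2L)
  expect_false(any(is.na(q$areas)))
  # observed cells untouched
  expect_equal(q$areas["P2", "bait_1"], 10)
  # no-missing table passes through unchanged
  full <- protein_quant(matrix(as.numeric(1:12), 3, 4,
                                dimnames = dimnames(a)))
  q2 <- impute_missing(full)
  expect_identical(q2$areas, full$areas)
  expect_equal(attr(q2, "imputation")$count, 0L)
  # entirely missing replicate column is an error
  bad <- a; bad[, 2] <- NA
  expect_error(impute_missing(protein_quant(bad)), "entirely missing")
})

test_that("imputation leaves no missing cells on random patterns", {
  set.seed(8)
  for (i in 1:5) {
    sim <- simulate_proteome(n_proteins = 80, n_enriched = 10,
                             missing_rate = 0.25,
                             missing_mechanism = "MCAR", seed = i)
    q <- impute_missing(top3_protein_area(sim$peptides))
    expect_false(any(is.na(q$areas)))
  }
})

test_that("fold-change calls implement the two-fold rule", {
  a <- matrix(c(400, 190, 400, 190, 400, 190, 400, 190,
                100, 100, 100, 100, 100, 100, 100, 100),
              nrow = 2,
              dimnames = list(c("P1", "P2"),
                              c(paste0("bait_", 1:4),
                                paste0("control_", 1:4))))
  et <- fold_change_call(impute_missing(protein_quant(a)))
  expect_equal(et$log2_fold_change[et$protein == "P1"], 2)
  expect_true(et$enriched[et$protein == "P1"])
  expect_equal(et$log2_fold_change[et$protein == "P2"],
               log2(1.9), tolerance = 1e-12)
  expect_false(et$enriched[et$protein == "P2"])
})

test_that("planted four-fold proteins are recovered by the fold-change arm", {
  sim <- simulate_proteome(n_proteins = 400, n_enriched = 50,
                           log2_effect = 2, sigma = 0.5, seed = 17)
  et <- enrichment_pipeline(sim$peptides, arm = "turboid")
  recall <- mean(sim$truth %in% et$protein[et$enriched])
  expect_gte(recall, 0.9)
})

test_that("moderated test matches the straight-line shrinkage oracle", {
  set.seed(21)
  n <- 20
  a <- matrix(2^(rnorm(8 * n, mean = 20, sd = 1)), n, 8,
              dimnames = list(sprintf("P%02d", 1:n),
                              c(paste0("bait_", 1:4),
                                paste0("control_", 1:4))))
  q <- impute_missing(protein_quant(a))
  et <- moderated_test(q)
  orc <- oracle_moderated_t(log2(a[, 1:4]), log2(a[, 5:8]))
  expect_equal(et$moderated_t, unname(orc$t), tolerance = 1e-8)
  expect_equal(et$p_value, unname(orc$p), tolerance = 1e-8)
  expect_equal(et$adjusted_p, unname(p.adjust(orc$p, "BH")),
               tolerance = 1e-8)
})

test_that("moderated test agrees with limma as an independent cross-check", {
  skip_if_not_installed("limma")
  set.seed(22)
  n <- 300
  a <- matrix(2^(rnorm(8 * n, mean = 18, sd = 1.2)), n, 8,
              dimnames = list(sprintf("P%03d", 1:n),
                              c(paste0("bait_", 1:4),
                                paste0("control_", 1:4))))
  a[1:20, 1:4] <- a[1:20, 1:4] * 8  # planted effects
  et <- moderated_test(impute_missing(protein_quant(a)))
  design <- cbind(1, c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- limma::eBayes(limma::lmFit(log2(a), design))
  expect_gt(cor(et$moderated_t, fit$t[, 2]), 0.999)
  expect_equal(unname(fit$df.prior), attr(et, "prior")$d0,
               tolerance = 0.05 * max(1, attr(et, "prior")$d0))
})

test_that("degenerate null table yields no enrichment", {
  a <- matrix(100, 5, 8,
              dimnames = list(paste0("P", 1:5),
                              c(paste0("bait_", 1:4),
                                paste0("control_", 1:4))))
  et <- moderated_test(impute_missing(protein_quant(a)))
  expect_true(all(!et$enriched))
  expect_true(all(et$p_value == 1))
})

test_that("pipeline is deterministic and scale-equivariant", {
  sim <- simulate_proteome(n_proteins = 120, n_enriched = 15, seed = 9)
  e1 <- enrichment_pipeline(sim$peptides, "ipms")
  e2 <- enrichment_pipeline(sim$peptides, "ipms")
  expect_identical(e1, e2)
  scaled <- transform(sim$peptides, area = area * 1000)
  e3 <- enrichment_pipeline(scaled, "ipms")
  expect_equal(e3$log2_fold_change, e1$log2_fold_change,
               tolerance = 1e-9)
  expect_equal(e3$moderated_t, e1$moderated_t, tolerance = 1e-6)
  expect_equal(e3$adjusted_p, e1$adjusted_p, tolerance = 1e-6)
})

test_that("proteins observed only in bait are retained with finite calls", {
  sim <- simulate_proteome(n_proteins = 30, n_enriched = 3, seed = 3,
                           missing_rate = 0)
  pep <- sim$peptides
  pep$area[pep$protein == "P0005" & pep$condition == "control"] <- NA
  et <- enrichment_pipeline(pep, "turboid")
  row <- et[et$protein == "P0005", ]
  expect_true(is.finite(row$log2_fold_change))
})
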