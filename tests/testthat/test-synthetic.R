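test_that("noiseless basal simulation gives unit ratios and fixed-seed determinism", {
  cfg0 <- sim_config(n_proteins = 50, sigma_basal = 0, sigma_rep = 0,
                     missing_rate = 0, seed = 3)
  b0 <- simulate_basal_experiment(cfg0)
  ratio_cols <- grep("^ratio_", names(b0), value = TRUE)
  expect_true(all(as.matrix(b0[, ratio_cols]) == 1))

  cfg <- sim_config(n_proteins = 80, seed = 7)
  expect_identical(simulate_basal_experiment(cfg), simulate_basal_experiment(cfg))
  sim1 <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
  sim2 <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
  expect_identical(sim1, sim2)
  # different conditions draw from different streams
  expect_false(identical(sim1$table,
                         simulate_stimulated_experiment(cfg, "P3C", "proteome")$table))
})

test_that("basal log2 ratios match the stated Normal model", {
  # independent moment check: per-timepoint log2 ratios ~ N(0, sigma_basal)
  cfg <- sim_config(n_proteins = 2000, sigma_basal = 0.227, sigma_rep = 0,
                    missing_rate = 0, seed = 11)
  b <- simulate_basal_experiment(cfg)
  s <- sd(log2(b$ratio_ML_rep1))
  expect_gte(s, 0.217)
  expect_lte(s, 0.237)
  expect_equal(s, sd(log2(b$ratio_ML_rep2)))  # shared per-protein fluctuation
})

test_that("planted responder and discordant sets have the configured sizes", {
  cfg <- sim_config(n_proteins = 500, responder_fraction = 0.1,
                    discordant_protein_only_n = 20,
                    discordant_transcript_only_n = 30, seed = 5)
  sim <- simulate_stimulated_experiment(cfg, "R848", "secretome")
  truth <- sim$truth
  expect_length(truth$responders, 50)
  expect_length(truth$protein_only, 20)
  expect_length(truth$transcript_only, 30)
  expect_length(intersect(truth$protein_only, truth$transcript_only), 0)
  # protein-only genes are responders; transcript-only genes are not
  resp_genes <- truth$gene_symbol[match(truth$responders, truth$protein_id)]
  expect_true(all(truth$protein_only %in% resp_genes))
  expect_false(any(truth$transcript_only %in% resp_genes))
})

test_that("noiseless stimulated effects are exact and halved at the early timepoint", {
  cfg <- sim_config(n_proteins = 100, sigma_basal = 0, sigma_rep = 0,
                    missing_rate = 0, responder_fraction = 0.2,
                    effect_size_mean = 2, effect_size_sd = 0, seed = 9)
  sim <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
  resp <- sim$table$protein_id %in% sim$truth$responders
  expect_true(all(sim$table$ratio_HL_rep1[resp] == 4))   # 2^2
  expect_true(all(sim$table$ratio_ML_rep1[resp] == 2))   # 2^(2/2)
  expect_true(all(sim$table$ratio_HL_rep1[!resp] == 1))
  expect_equal(sim$truth$protein_effect$early, sim$truth$protein_effect$late / 2)
})

test_that("null stimulated run reproduces the basal model statistics", {
  cfg <- sim_config(n_proteins = 3000, responder_fraction = 0,
                    sigma_basal = 0.3, sigma_rep = 0.1, missing_rate = 0.1,
                    seed = 13)
  sim <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
  expect_length(sim$truth$responders, 0)
  v <- log2(sim$table$ratio_HL_rep1)
  expect_lt(abs(mean(v, na.rm = TRUE)), 0.02)
  expect_lt(abs(sd(v, na.rm = TRUE) - sqrt(0.3^2 + 0.1^2)), 0.015)
  expect_lt(abs(mean(is.na(v)) - 0.1), 0.015)
})

test_that("transcriptome carries planted effects with the configured noise", {
  cfg <- sim_config(n_proteins = 200, responder_fraction = 0.25,
                    discordant_protein_only_n = 40, transcript_sigma = 0,
                    sigma_basal = 0, sigma_rep = 0, missing_rate = 0,
                    effect_size_mean = 1.5, effect_size_sd = 0.2, seed = 21)
  sim <- simulate_stimulated_experiment(cfg, "P3C", "proteome")
  expr <- simulate_transcriptome(sim$truth, cfg)
  expect_equal(names(expr), c("gene_symbol", "P3C_1h", "P3C_2h", "P3C_4h"))
  fc <- as.matrix(expr[, -1])
  rownames(fc) <- expr$gene_symbol
  truth <- sim$truth
  concordant <- setdiff(truth$gene_symbol[match(truth$responders, truth$protein_id)],
                        truth$protein_only)
  late <- truth$protein_effect$late[match(concordant, truth$protein_effect$gene_symbol)]
  # zero transcript noise: concordant transcript FC equals the protein effect
  expect_equal(unname(fc[concordant, "P3C_1h"]), late)
  # exactly the protein-only genes are flat with a nonzero protein effect
  flat <- rownames(fc)[rowSums(fc != 0) == 0]
  with_protein_effect <- truth$protein_effect$gene_symbol[truth$protein_effect$late != 0]
  expect_setequal(intersect(flat, with_protein_effect), truth$protein_only)
  expect_length(truth$protein_only, 40)
  expect_error(simulate_transcriptome(list(), cfg), "gene universe")
})

test_that("peptide evidence respects counts, noise and protein ratios", {
  cfg <- sim_config(n_proteins = 40, sigma_rep = 0, missing_rate = 0.2,
                    peptide_lambda = 3, seed = 17)
  tbl <- simulate_basal_experiment(cfg)
  ev <- simulate_peptide_evidence(cfg, tbl)
  expect_identical(ev, simulate_peptide_evidence(cfg, tbl))  # determinism
  # zero peptide noise: every peptide equals its protein log2 ratio
  sub <- ev[ev$replicate == 2 & ev$timepoint == "late", ]
  per_prot <- tapply(sub$log2_ratio, sub$protein_id, median)
  expect_equal(as.numeric(per_prot[tbl$protein_id]),
               unname(log2(tbl$ratio_HL_rep2)))
  # lambda 0 -> exactly one unique peptide each
  cfg1 <- sim_config(n_proteins = 25, peptide_lambda = 0, seed = 17)
  ev1 <- simulate_peptide_evidence(cfg1, simulate_basal_experiment(cfg1))
  expect_true(all(tapply(ev1$peptide_id, ev1$protein_id,
                         function(x) length(unique(x))) == 1))
})

test_that("basal quantile coverage is exact by construction at large n", {
  cfg <- sim_config(n_proteins = 10000, sigma_rep = 0, missing_rate = 0,
                    seed = 23)
  b <- simulate_basal_experiment(cfg)
  m <- cbind(log2(b$ratio_ML_rep1), log2(b$ratio_HL_rep1))
  rownames(m) <- b$protein_id
  for (q in c(0.88, 0.99)) {
    thr <- derive_basal_threshold(m, q)
    inside <- mean(apply(abs(m), 1, max) <= log2(thr$fold_change_threshold))
    expect_equal(inside, thr$coverage_achieved)
    expect_lte(abs(inside - q), 0.01)
  }
})
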