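make_id_map <- function(ids, symbols) {
  data.frame(protein_id = ids, gene_symbol = symbols, stringsAsFactors = FALSE)
}

test_that("symbol merge inner-joins and averages duplicates on both sides", {
  protein <- rbind(iso1 = c(1.0, 0.5), iso2 = c(2.0, 1.5), solo = c(0.2, 0.1),
                   orphan = c(9, 9))
  colnames(protein) <- c("proteome_LPS_6h", "proteome_LPS_12h")
  id_map <- make_id_map(c("iso1", "iso2", "solo", "orphan"),
                        c("GENE1", "GENE1", "GENE2", ""))
  expr <- data.frame(gene_symbol = c("GENE1", "GENE2", "GENE2", "GENE3"),
                     LPS_1h = c(0.9, 0.4, 0.6, 5),
                     stringsAsFactors = FALSE)
  join <- suppressMessages(merge_by_symbol(protein, expr, id_map))
  expect_equal(join$genes, c("GENE1", "GENE2"))          # GENE3 transcript-only
  expect_equal(unname(join$protein["GENE1", ]), c(1.5, 1.0))  # isoform mean
  expect_equal(unname(join$transcript["GENE2", 1]), 0.5)      # probe mean
  expect_equal(join$n_unmapped, 1)
  # join size is symmetric in the two gene universes
  expect_length(join$genes,
                length(intersect(c("GENE1", "GENE1", "GENE2"),
                                 unique(expr$gene_symbol))))
  bad_map <- make_id_map(rownames(protein), c("X1", "X2", "X3", "X4"))
  expect_error(merge_by_symbol(protein, expr, bad_map), "no common genes")
})

test_that("duplicate averaging before correlation equals correlating averages", {
  set.seed(101)
  for (i in 1:10) {
    sym <- sample(sprintf("G%02d", 1:8), 20, replace = TRUE)
    m <- matrix(rnorm(40), 20, 2, dimnames = list(sym, c("a", "b")))
    avg <- silacint::expression_matrix(
      data.frame(gene_symbol = sym, LPS_1h = m[, 1], LPS_2h = m[, 2]))
    manual <- t(vapply(sort(unique(sym)), function(s) {
      colMeans(m[sym == s, , drop = FALSE])
    }, numeric(2)))
    expect_equal(unname(avg), unname(manual))
  }
})

test_that("correlation grid has the full design shape and exact closed forms", {
  genes <- sprintf("G%02d", 1:20)
  set.seed(111)
  base <- rnorm(20)
  prot_cols <- c(condition_key("proteome", rep(c("LPS", "P3C", "R848"), each = 2),
                               rep(c(6, 12), 3)),
                 condition_key("secretome", rep(c("LPS", "P3C", "R848"), each = 2),
                               rep(c(6, 24), 3)))
  protein <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(genes, prot_cols))
  protein[, 1] <- base
  expr <- data.frame(gene_symbol = genes)
  for (tr in c("LPS", "P3C", "R848")) {
    for (h in c(1, 2, 4)) expr[[sprintf("%s_%dh", tr, h)]] <- rnorm(20)
  }
  expr$LPS_1h <- base          # identical to the first protein condition
  expr$LPS_2h <- -base         # exactly anti-correlated
  grid <- correlation_grid(protein, expr, make_id_map(genes, genes))
  expect_equal(dim(grid$r), c(12, 9))
  expect_equal(grid$r["proteome_LPS_6h", "LPS_1h"], 1)
  expect_equal(grid$r["proteome_LPS_6h", "LPS_2h"], -1)
  expect_true(all(abs(grid$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(grid$n[!is.na(grid$r)] >= 3))
})

test_that("basal columns and sparse cells are excluded from the grid", {
  genes <- sprintf("G%02d", 1:10)
  protein <- matrix(rnorm(20), 10, 2,
                    dimnames = list(genes, condition_key("proteome",
                                                         c("LPS", "basal"),
                                                         c(6, 6))))
  expr <- data.frame(gene_symbol = genes, LPS_1h = rnorm(10), LPS_2h = rnorm(10))
  expr$LPS_2h[3:10] <- NA      # only 2 complete pairs
  grid <- correlation_grid(protein, expr, make_id_map(genes, genes))
  expect_false("proteome_basal_6h" %in% rownames(grid$r))
  expect_true(is.na(grid$r["proteome_LPS_6h", "LPS_2h"]))
  expect_equal(grid$n["proteome_LPS_6h", "LPS_2h"], 2L)
})

test_that("discordance classification applies the two-sided max criterion", {
  genes <- c("G1", "G2", "G3", "G4")
  protein <- matrix(c(1.0, 0.14, 0.1, 1.2), 4, 1,
                    dimnames = list(genes, "proteome_LPS_12h"))
  expr <- data.frame(gene_symbol = genes,
                     LPS_1h = c(log2(1.1), log2(1.2), 1.5, 1.1),
                     LPS_2h = c(log2(1.2), 0.1, 1.4, 1.3),
                     LPS_4h = c(log2(1.05), 0.05, 1.2, 1.0))
  rep <- classify_discordance(protein, expr, make_id_map(genes, genes),
                              protein_threshold = 1.5,
                              transcript_threshold = 1.5)
  sets <- rep$per_treatment$LPS
  expect_equal(sets$protein_only, "G1")       # 2-fold protein, quiet transcript
  expect_equal(sets$transcript_only, "G3")    # quiet protein, >1.5-fold transcript
  expect_equal(sets$concordant, "G4")
  expect_equal(sets$unclassified, "G2")       # both below both bounds
  expect_equal(rep$counts$protein_only, 1)
  expect_error(classify_discordance(protein, expr, make_id_map(genes, genes),
                                    protein_threshold = 0.9), "exceed 1")
})

test_that("infinite transcript bound reduces to a protein-side threshold call", {
  set.seed(121)
  genes <- sprintf("G%02d", 1:50)
  protein <- matrix(rnorm(50, 0, 0.8), 50, 1,
                    dimnames = list(genes, "proteome_LPS_12h"))
  expr <- data.frame(gene_symbol = genes, LPS_1h = rnorm(50))
  rep <- classify_discordance(protein, expr, make_id_map(genes, genes),
                              protein_threshold = 1.5,
                              transcript_threshold = Inf)
  direct <- apply_threshold(protein, 1.5, "proteome_LPS_12h")$protein_id
  expect_setequal(rep$per_treatment$LPS$protein_only, direct)
  expect_length(rep$per_treatment$LPS$transcript_only, 0)
})

test_that("planted discordance is recovered through the whole chain", {
  cfg <- sim_config(n_proteins = 400, responder_fraction = 0.2,
                    discordant_protein_only_n = 40,
                    discordant_transcript_only_n = 40,
                    sigma_basal = 0.15, sigma_rep = 0.1,
                    transcript_sigma = 0.05, effect_size_mean = 2,
                    effect_size_sd = 0, missing_rate = 0.1, seed = 131)
  sim <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
  q <- filter_reliable(normalize_median(as_protein_quant(sim$table)), 2, 2)
  m <- summarize_replicates(q, "proteome", "LPS")
  expr <- simulate_transcriptome(sim$truth, cfg)
  rep <- classify_discordance(m, expr, gene_map(q), protein_threshold = 1.5)
  rec <- evaluate_recovery(rep, sim$truth)
  expect_gte(min(rec$precision), 0.9)
  expect_gte(min(rec$recall), 0.9)
})

test_that("recovery metrics are exact set arithmetic", {
  truth <- structure(list(treatment = "LPS", gene_symbol = sprintf("G%d", 1:10),
                          protein_only = c("G1", "G2", "G3", "G4"),
                          transcript_only = character(0)),
                     class = "planted_truth")
  report <- structure(list(per_treatment = list(LPS = list(
    protein_only = c("G1", "G2", "G3", "G9"),
    transcript_only = character(0),
    concordant = character(0), unclassified = character(0)
  ))), class = "discordance_report")
  rec <- evaluate_recovery(report, truth)
  expect_equal(rec$precision[1], 0.75)
  expect_equal(rec$recall[1], 0.75)
  expect_true(is.na(rec$precision[2]))  # nothing called
  # perfect report
  report$per_treatment$LPS$protein_only <- truth$protein_only
  rec2 <- evaluate_recovery(report, truth)
  expect_equal(rec2$precision[1], 1)
  expect_equal(rec2$recall[1], 1)
  # alien genes in the report are a universe mismatch
  report$per_treatment$LPS$protein_only <- "NOT_A_GENE"
  expect_error(evaluate_recovery(report, truth), "gene universe")
})
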