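#' Run the full integration pipeline on a simulated experiment
#'
#' Orchestrates every stage end to end: simulate the basal and stimulated
#' SILAC experiments for both compartments (plus the matched transcriptome),
#' quantify (normalize, filter, summarize replicates), derive the basal-null
#' thresholds, compare conditions (overlap matrix, PCA, hierarchical
#' clustering, strong changers), and integrate with the transcriptome
#' (correlation grid, discordance classification, planted-truth recovery).
#' All artifacts are written to `config$output_dir` as plain tab-separated
#' tables, a Newick tree and a JSON manifest; identical configurations
#' produce byte-identical outputs.
#'
#' @param config An [analysis_config()].
#' @return A `run_manifest` (invisibly also written to
#'   `manifest.json`): config snapshot, per-stage counts, thresholds,
#'   discordance counts, output paths and file digests.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_stage <- function(...) message("[silacint] ", sprintf(...))
  paths <- character(0)
  counts <- list()

  # basal sigma per compartment: the secretome fluctuates more than the
  # lysate proteome (serum-free conditioned media, lower protein amounts)
  sigma_basal <- c(proteome = config$sim$sigma_basal,
                   secretome = config$sim$sigma_basal *
                     (0.643 / 0.227))
  compartment_cfg <- function(compartment) {
    cfg <- config$sim
    cfg$sigma_basal <- unname(sigma_basal[compartment])
    cfg
  }

  # --- simulate + quantify ------------------------------------------------
  log_stage("simulate: %d proteins, %d replicates, seed %d",
            config$sim$n_proteins, config$sim$n_replicates, config$seed)
  fc <- list()
  basal_fc <- list()
  truths <- list()
  for (compartment in COMPARTMENTS) {
    cfg <- compartment_cfg(compartment)
    basal_tbl <- simulate_basal_experiment(cfg)
    write_protein_groups(basal_tbl, out(sprintf("groups_%s_basal.tsv", compartment)))
    paths <- c(paths, out(sprintf("groups_%s_basal.tsv", compartment)))
    bq <- filter_reliable(normalize_median(as_protein_quant(basal_tbl, cfg$n_replicates)),
                          config$min_unique_peptides, config$min_replicates)
    basal_fc[[compartment]] <- summarize_replicates(bq, compartment, "basal")
    counts[[paste0(compartment, "_basal")]] <-
      c(simulated = nrow(basal_tbl), reliable = length(bq$protein_id))
    per_treatment <- list()
    for (treatment in STIM_TREATMENTS) {
      sim <- simulate_stimulated_experiment(cfg, treatment, compartment)
      truths[[paste(compartment, treatment, sep = "_")]] <- sim$truth
      f <- out(sprintf("groups_%s_%s.tsv", compartment, treatment))
      write_protein_groups(sim$table, f)
      paths <- c(paths, f)
      q <- as_protein_quant(sim$table, cfg$n_replicates)
      q <- filter_reliable(normalize_median(q),
                           config$min_unique_peptides, config$min_replicates)
      per_treatment[[treatment]] <- summarize_replicates(q, compartment, treatment)
      counts[[paste(compartment, treatment, sep = "_")]] <-
        c(simulated = nrow(sim$table), reliable = length(q$protein_id))
      log_stage("quantify %s %s: %d of %d proteins reliable", compartment,
                treatment, length(q$protein_id), nrow(sim$table))
    }
    fc[[compartment]] <- combine_fold_changes(per_treatment)
    f <- out(sprintf("fold_changes_%s.tsv", compartment))
    write_fold_change_table(fc[[compartment]], f)
    paths <- c(paths, f)
    f <- out(sprintf("fold_changes_%s_basal.tsv", compartment))
    write_fold_change_table(basal_fc[[compartment]], f)
    paths <- c(paths, f)
  }

  # --- thresholds ---------------------------------------------------------
  thresholds <- lapply(COMPARTMENTS, function(compartment) {
    derive_basal_threshold(basal_fc[[compartment]],
                           config$basal_coverage[[compartment]])
  })
  names(thresholds) <- COMPARTMENTS
  for (compartment in COMPARTMENTS) {
    log_stage("threshold %s: %.3g-fold at %.0f%% coverage", compartment,
              thresholds[[compartment]]$fold_change_threshold,
              100 * config$basal_coverage[[compartment]])
  }

  # --- compare ------------------------------------------------------------
  combined <- combine_fold_changes(fc)
  sig_sets <- list()
  for (cond in colnames(combined)) {
    compartment <- parse_condition(cond)$compartment
    sig_sets[[cond]] <- apply_threshold(combined, thresholds[[compartment]],
                                        cond)$protein_id
  }
  quantified_sets <- lapply(colnames(combined), function(cond) {
    rownames(combined)[!is.na(combined[, cond])]
  })
  names(quantified_sets) <- colnames(combined)
  overlap <- build_overlap_matrix(quantified_sets, config$overlap_denominator)
  f <- out("overlap_matrix.tsv")
  writeLines(c(
    "# diagonal: proteins per condition; upper triangle: intersection counts;",
    sprintf("# lower triangle: normalized %% overlap (denominator: %s)",
            config$overlap_denominator)), f)
  suppressWarnings(utils::write.table(
    data.frame(condition = rownames(overlap), unclass(overlap),
               check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  paths <- c(paths, f)

  common <- lapply(COMPARTMENTS, function(compartment) {
    select_common_proteins(lapply(STIM_TREATMENTS, function(tr) {
      rownames(fc[[compartment]])[
        rowSums(!is.na(fc[[compartment]][, grep(paste0("_", tr, "_"),
                                colnames(fc[[compartment]])), drop = FALSE])) > 0]
    }))
  })
  names(common) <- COMPARTMENTS
  pca <- lapply(COMPARTMENTS, function(compartment) {
    run_pca(fc[[compartment]][common[[compartment]], , drop = FALSE])
  })
  names(pca) <- COMPARTMENTS
  for (compartment in COMPARTMENTS) {
    f <- out(sprintf("pca_%s.tsv", compartment))
    write_tsv_precise(data.frame(sample = rownames(pca[[compartment]]$scores),
                                 pca[[compartment]]$scores[, 1:3, drop = FALSE],
                                 check.names = FALSE), f)
    paths <- c(paths, f)
  }
  cluster <- hierarchical_cluster(
    combined[stats::complete.cases(combined), , drop = FALSE],
    config$distance, config$linkage)
  f <- out("cluster_samples.nwk")
  write_cluster_newick(cluster, f)
  paths <- c(paths, f)
  strong <- select_strong_changers(combined, config$min_fold)
  f <- out("strong_changers.tsv")
  write_fold_change_table(strong, f)
  paths <- c(paths, f)
  log_stage("compare: %d common proteome, %d common secretome, %d strong changers",
            length(common$proteome), length(common$secretome), nrow(strong))

  # --- integrate ----------------------------------------------------------
  expr <- NULL
  for (treatment in STIM_TREATMENTS) {
    e <- simulate_transcriptome(truths[[paste("proteome", treatment, sep = "_")]],
                                compartment_cfg("proteome"))
    expr <- if (is.null(expr)) e else merge(expr, e, by = "gene_symbol",
                                            sort = TRUE)
  }
  f <- out("transcriptome.tsv")
  write_tsv_precise(expr, f)
  paths <- c(paths, f)
  id_map <- data.frame(protein_id = sim_protein_ids(config$sim$n_proteins),
                       gene_symbol = sim_gene_symbols(config$sim$n_proteins),
                       stringsAsFactors = FALSE)
  grid <- correlation_grid(combined, expr, id_map)
  f <- out("correlation_grid.tsv")
  write_tsv_precise(data.frame(condition = rownames(grid$r), grid$r,
                               check.names = FALSE), f)
  paths <- c(paths, f)
  pthr <- c(proteome = thresholds$proteome$fold_change_threshold,
            secretome = thresholds$secretome$fold_change_threshold)
  discordance <- lapply(COMPARTMENTS, function(compartment) {
    classify_discordance(fc[[compartment]], expr, id_map,
                         protein_threshold = unname(pthr[compartment]),
                         transcript_threshold = config$transcript_threshold)
  })
  names(discordance) <- COMPARTMENTS
  recovery <- do.call(rbind, lapply(STIM_TREATMENTS, function(treatment) {
    r <- evaluate_recovery(discordance$proteome,
                           truths[[paste("proteome", treatment, sep = "_")]])
    cbind(data.frame(treatment = treatment), r)
  }))
  for (compartment in COMPARTMENTS) {
    rep_df <- do.call(rbind, lapply(names(discordance[[compartment]]$per_treatment),
      function(tr) {
        sets <- discordance[[compartment]]$per_treatment[[tr]]
        do.call(rbind, lapply(c("protein_only", "transcript_only"), function(cat) {
          if (length(sets[[cat]]) == 0) return(NULL)
          data.frame(treatment = tr, category = cat, gene_symbol = sets[[cat]],
                     stringsAsFactors = FALSE)
        }))
      }))
    f <- out(sprintf("discordant_genes_%s.tsv", compartment))
    if (is.null(rep_df)) {
      rep_df <- data.frame(treatment = character(0), category = character(0),
                           gene_symbol = character(0))
    }
    write_tsv_precise(rep_df, f)
    paths <- c(paths, f)
  }
  log_stage("integrate: %d joined genes; discordant (proteome): %s",
            discordance$proteome$n_joined,
            paste(discordance$proteome$counts$protein_only, collapse = "/"))

  # --- manifest -----------------------------------------------------------
  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("silacint")),
      seed = config$seed,
      config = config[setdiff(names(config), "sim")],
      sim = unclass(config$sim),
      stage_counts = counts,
      thresholds = lapply(thresholds, function(t) {
        list(fold_change_threshold = t$fold_change_threshold,
             coverage_requested = t$coverage_requested,
             coverage_achieved = t$coverage_achieved,
             n_proteins = t$n_proteins)
      }),
      common_proteins = lapply(common, length),
      n_strong_changers = nrow(strong),
      pca_var_explained = lapply(pca, function(p) p$var_explained[1:3]),
      discordance_counts = lapply(discordance, function(d) d$counts),
      recovery = recovery,
      outputs = paths,
      digests = as.list(tools::md5sum(sort(paths)))
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  manifest
}

#' Human-readable summary of a pipeline run
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  required <- c("stage_counts", "thresholds", "discordance_counts",
                "recovery", "outputs")
  for (field in required) {
    if (is.null(manifest[[field]])) {
      stop("incomplete manifest: missing stage '", field, "'", call. = FALSE)
    }
  }
  lines <- c(
    sprintf("silacint run (seed %d)", manifest$seed),
    "",
    "Reliably quantified proteins per condition:"
  )
  for (key in names(manifest$stage_counts)) {
    ct <- manifest$stage_counts[[key]]
    lines <- c(lines, sprintf("  %-22s %d of %d simulated", key,
                              ct[["reliable"]], ct[["simulated"]]))
  }
  lines <- c(lines, "", "Basal-null fold-change thresholds:")
  for (compartment in names(manifest$thresholds)) {
    t <- manifest$thresholds[[compartment]]
    lines <- c(lines, sprintf(
      "  %-10s %.3g-fold (%.0f%% coverage requested, %.1f%% achieved, n = %d)",
      compartment, t$fold_change_threshold, 100 * t$coverage_requested,
      100 * t$coverage_achieved, t$n_proteins))
  }
  lines <- c(lines, "", sprintf(
    "Common proteins: %d proteome, %d secretome; strong changers: %d",
    manifest$common_proteins$proteome, manifest$common_proteins$secretome,
    manifest$n_strong_changers))
  for (compartment in names(manifest$pca_var_explained)) {
    ve <- manifest$pca_var_explained[[compartment]]
    lines <- c(lines, sprintf("PCA %s: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%",
                              compartment, 100 * ve[1], 100 * ve[2], 100 * ve[3]))
  }
  lines <- c(lines, "", "Discordance counts (protein-only / transcript-only):")
  for (compartment in names(manifest$discordance_counts)) {
    ct <- manifest$discordance_counts[[compartment]]
    for (i in seq_len(nrow(ct))) {
      lines <- c(lines, sprintf("  %-10s %-5s %d / %d", compartment,
                                ct$treatment[i], ct$protein_only[i],
                                ct$transcript_only[i]))
    }
  }
  lines <- c(lines, "", "Planted-truth recovery (proteome):")
  rec <- manifest$recovery
  for (i in seq_len(nrow(rec))) {
    lines <- c(lines, sprintf(
      "  %-5s %-16s precision %.2f recall %.2f", rec$treatment[i],
      rec$category[i], rec$precision[i], rec$recall[i]))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
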