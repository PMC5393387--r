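#' @section Random-number streams:
#' Every stochastic operation draws from its own stream, seeded by a hash of
#' the master seed and a stream name (e.g. `"proteome_LPS_effects"`). Adding
#' or reordering draws in one stage therefore never perturbs another, and
#' identical configurations give identical outputs.
#' @name silacint-rng
#' @keywords internal
NULL

# Deterministic 31-bit sub-seed from (master seed, stream name).
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# Evaluate `code` under the stream's seed, leaving the caller's RNG state
# untouched.
with_stream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  code
}

sim_protein_ids <- function(n) sprintf("P%05d", seq_len(n))
sim_gene_symbols <- function(n) sprintf("GENE%05d", seq_len(n))

# Basal generator core: log2 ratio = b_{p,t} + e_{p,r,t}, b ~ N(0, sigma_basal)
# shared across replicates, e ~ N(0, sigma_rep); cells dropped at missing_rate.
# Returns list(log2fc = n x R x 2 array with NA for missing, peptides = n x R).
simulate_basal_core <- function(cfg, prefix) {
  n <- cfg$n_proteins
  R <- cfg$n_replicates
  b <- with_stream(cfg$seed, paste0(prefix, "_profile"),
                   matrix(stats::rnorm(n * 2, 0, cfg$sigma_basal), n, 2))
  e <- with_stream(cfg$seed, paste0(prefix, "_rep"),
                   array(stats::rnorm(n * R * 2, 0, cfg$sigma_rep), c(n, R, 2)))
  log2fc <- array(NA_real_, c(n, R, 2))
  for (t in 1:2) log2fc[, , t] <- b[, t] + e[, , t]
  if (cfg$missing_rate > 0) {
    miss <- if (cfg$missing_mechanism == "uniform") {
      with_stream(cfg$seed, paste0(prefix, "_missing"),
                  array(stats::runif(n * R * 2) < cfg$missing_rate, c(n, R, 2)))
    } else {
      # Abundance-biased dropout: low latent abundance raises the dropout odds.
      a <- with_stream(cfg$seed, paste0(prefix, "_abundance"),
                       stats::rnorm(n))
      p <- stats::plogis(stats::qlogis(cfg$missing_rate) - a)
      with_stream(cfg$seed, paste0(prefix, "_missing"),
                  array(stats::runif(n * R * 2) < rep(p, R * 2), c(n, R, 2)))
    }
    log2fc[miss] <- NA_real_
  }
  peptides <- with_stream(cfg$seed, paste0(prefix, "_peptides"),
                          matrix(1L + stats::rpois(n * R, cfg$peptide_lambda),
                                 n, R))
  list(log2fc = log2fc, peptides = peptides)
}

groups_df_from_core <- function(core, cfg) {
  n <- cfg$n_proteins
  R <- cfg$n_replicates
  df <- data.frame(protein_id = sim_protein_ids(n),
                   gene_symbol = sim_gene_symbols(n),
                   stringsAsFactors = FALSE)
  for (r in seq_len(R)) df[[sprintf("unique_peptides_rep%d", r)]] <- core$peptides[, r]
  for (r in seq_len(R)) df[[sprintf("ratio_ML_rep%d", r)]] <- 2^core$log2fc[, r, 1]
  for (r in seq_len(R)) df[[sprintf("ratio_HL_rep%d", r)]] <- 2^core$log2fc[, r, 2]
  df[, protein_groups_columns(R)]
}

#' Simulate an unstimulated (basal) SILAC time course
#'
#' Emulates the basal-null experiment: a triple-label time course of
#' untreated cells whose medium/light and heavy/light ratios measure nothing
#' but biological and technical fluctuation. Per protein `p`, replicate `r`
#' and timepoint `t`, the log2 ratio is `b[p,t] + e[p,r,t]` with
#' `b ~ N(0, sigma_basal)` and `e ~ N(0, sigma_rep)`; cells are dropped
#' independently at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A protein-groups `data.frame` in the [read_protein_groups()]
#'   dialect (linear ratios).
#' @export
simulate_basal_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  groups_df_from_core(simulate_basal_core(cfg, "basal"), cfg)
}

#' Simulate a TLR-stimulated SILAC experiment with planted truth
#'
#' On top of the basal model, an exact count
#' `round(n_proteins * responder_fraction)` of responder proteins receive a
#' treatment effect `delta ~ N(effect_size_mean, effect_size_sd)` (log2
#' units) at the late timepoint and `delta/2` at the early timepoint.
#' `discordant_protein_only_n` responders are marked as protein-only
#' discordant (their transcript will stay flat), and
#' `discordant_transcript_only_n` non-responders as transcript-only
#' discordant (transcript effect, no protein effect). All random draws come
#' from streams keyed by `(compartment, treatment)`, so different conditions
#' are independent replicates of the same design.
#'
#' @param cfg A [sim_config()].
#' @param treatment `"LPS"`, `"P3C"` or `"R848"`.
#' @param compartment `"proteome"` or `"secretome"`.
#' @return A list with elements `table` (protein-groups `data.frame`) and
#'   `truth` (a `planted_truth` object recording the responder and discordant
#'   sets and every true effect).
#' @export
simulate_stimulated_experiment <- function(cfg, treatment, compartment) {
  stopifnot(inherits(cfg, "sim_config"))
  treatment <- match.arg(treatment, STIM_TREATMENTS)
  compartment <- match.arg(compartment, COMPARTMENTS)
  prefix <- paste(compartment, treatment, sep = "_")
  core <- simulate_basal_core(cfg, prefix)
  n <- cfg$n_proteins
  ids <- sim_protein_ids(n)
  genes <- sim_gene_symbols(n)

  n_resp <- round(n * cfg$responder_fraction)
  responders <- with_stream(cfg$seed, paste0(prefix, "_responders"),
                            sort(sample.int(n, n_resp)))
  protein_only <- with_stream(cfg$seed, paste0(prefix, "_protein_only"),
                              sort(responders[sample.int(length(responders),
                                              cfg$discordant_protein_only_n)]))
  non_resp <- setdiff(seq_len(n), responders)
  transcript_only <- with_stream(cfg$seed, paste0(prefix, "_transcript_only"),
                                 sort(non_resp[sample.int(length(non_resp),
                                               cfg$discordant_transcript_only_n)]))
  delta <- with_stream(cfg$seed, paste0(prefix, "_effects"),
                       stats::rnorm(n_resp, cfg$effect_size_mean,
                                    cfg$effect_size_sd))
  effect_late <- numeric(n)
  effect_late[responders] <- delta
  # NA cells stay NA: effects apply to the underlying signal, dropout wins.
  for (r in seq_len(cfg$n_replicates)) {
    core$log2fc[, r, 1] <- core$log2fc[, r, 1] + effect_late / 2
    core$log2fc[, r, 2] <- core$log2fc[, r, 2] + effect_late
  }
  delta_t <- with_stream(cfg$seed, paste0(prefix, "_transcript_effects"),
                         stats::rnorm(cfg$discordant_transcript_only_n,
                                      cfg$effect_size_mean,
                                      cfg$effect_size_sd))
  transcript_effect <- numeric(n)
  transcript_effect[responders] <- delta          # concordant by default
  transcript_effect[protein_only] <- 0            # flat transcript
  transcript_effect[transcript_only] <- delta_t   # transcript change only
  names(transcript_effect) <- genes

  truth <- structure(
    list(
      treatment = treatment,
      compartment = compartment,
      protein_id = ids,
      gene_symbol = genes,
      responders = ids[responders],
      protein_only = genes[protein_only],
      transcript_only = genes[transcript_only],
      protein_effect = data.frame(
        protein_id = ids, gene_symbol = genes,
        early = effect_late / 2, late = effect_late,
        stringsAsFactors = FALSE
      ),
      transcript_effect = transcript_effect
    ),
    class = "planted_truth"
  )
  list(table = groups_df_from_core(core, cfg), truth = truth)
}

#' Simulate a matched transcriptome table
#'
#' Generates microarray-style log2 fold changes at the transcript timepoints
#' (1, 2 and 4 h by default) for the gene universe of a planted truth:
#' each gene's fold change is its true transcript effect plus
#' `N(0, transcript_sigma)` noise, independently per timepoint. Concordant
#' responders carry their protein effect at the transcript level,
#' protein-only discordant genes are flat, transcript-only discordant genes
#' change with no protein counterpart.
#'
#' @param truth A `planted_truth` from [simulate_stimulated_experiment()].
#' @param cfg The same [sim_config()].
#' @param timepoints Transcript timepoints in hours.
#' @return An expression `data.frame` in the [read_expression_table()]
#'   dialect (`gene_symbol` + `{treatment}_{hours}h` columns).
#' @export
simulate_transcriptome <- function(truth, cfg, timepoints = c(1, 2, 4)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!inherits(truth, "planted_truth") ||
      !identical(names(truth$transcript_effect), truth$gene_symbol)) {
    stop("mismatched gene universe: 'truth' must come from ",
         "simulate_stimulated_experiment()", call. = FALSE)
  }
  n <- length(truth$gene_symbol)
  k <- length(timepoints)
  noise <- with_stream(cfg$seed,
                       paste(truth$compartment, truth$treatment,
                             "transcriptome", sep = "_"),
                       matrix(stats::rnorm(n * k, 0, cfg$transcript_sigma),
                              n, k))
  fc <- matrix(truth$transcript_effect, n, k) + noise
  df <- data.frame(gene_symbol = truth$gene_symbol, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    df[[sprintf("%s_%gh", truth$treatment, timepoints[j])]] <- fc[, j]
  }
  df
}

#' Simulate peptide-level SILAC evidence for a protein-groups table
#'
#' Each protein emits `1 + Poisson(peptide_lambda)` unique peptides; a
#' peptide's log2 ratio in a given replicate and timepoint is the protein's
#' log2 ratio plus `N(0, sigma_rep)` noise, and is missing wherever the
#' protein ratio is missing. The resulting long table feeds
#' [aggregate_peptides()].
#'
#' @param cfg A [sim_config()].
#' @param protein_table Protein-groups `data.frame` from either simulator.
#' @return A long `data.frame` with columns `protein_id`, `gene_symbol`,
#'   `peptide_id`, `replicate`, `timepoint` (`"early"`/`"late"`),
#'   `log2_ratio`.
#' @export
simulate_peptide_evidence <- function(cfg, protein_table) {
  stopifnot(inherits(cfg, "sim_config"))
  required <- protein_groups_columns(cfg$n_replicates)
  if (!all(required %in% names(protein_table))) {
    stop("protein_table does not match the protein-groups dialect for ",
         cfg$n_replicates, " replicates", call. = FALSE)
  }
  n <- nrow(protein_table)
  R <- cfg$n_replicates
  k <- with_stream(cfg$seed, "evidence_counts",
                   1L + stats::rpois(n, cfg$peptide_lambda))
  prot_idx <- rep.int(seq_len(n), k)
  pep_num <- sequence(k)
  K <- length(prot_idx)
  grid <- expand.grid(pep = seq_len(K), replicate = seq_len(R),
                      timepoint = c("early", "late"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ml <- as.matrix(protein_table[, sprintf("ratio_ML_rep%d", seq_len(R))])
  hl <- as.matrix(protein_table[, sprintf("ratio_HL_rep%d", seq_len(R))])
  idx <- cbind(prot_idx[grid$pep], grid$replicate)
  prot_log2 <- log2(ifelse(grid$timepoint == "early", ml[idx], hl[idx]))
  noise <- with_stream(cfg$seed, "evidence_noise",
                       stats::rnorm(nrow(grid), 0, cfg$sigma_rep))
  data.frame(
    protein_id = protein_table$protein_id[prot_idx[grid$pep]],
    gene_symbol = protein_table$gene_symbol[prot_idx[grid$pep]],
    peptide_id = sprintf("%s_pep%d", protein_table$protein_id[prot_idx[grid$pep]],
                         pep_num[grid$pep]),
    replicate = grid$replicate,
    timepoint = grid$timepoint,
    log2_ratio = prot_log2 + noise,
    stringsAsFactors = FALSE
  )
}

#' Write / read the planted-truth sidecar
#'
#' Serializes a `planted_truth` as a tab-separated table (one row per gene:
#' id, symbol, role, true early/late protein effects, true transcript
#' effect) so simulated datasets can be shipped alongside their answer key.
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  role <- rep("background", length(truth$protein_id))
  role[truth$protein_id %in% truth$responders] <- "responder"
  role[truth$gene_symbol %in% truth$protein_only] <- "protein_only"
  role[truth$gene_symbol %in% truth$transcript_only] <- "transcript_only"
  df <- data.frame(
    protein_id = truth$protein_id,
    gene_symbol = truth$gene_symbol,
    treatment = truth$treatment,
    compartment = truth$compartment,
    role = role,
    protein_effect_early = truth$protein_effect$early,
    protein_effect_late = truth$protein_effect$late,
    transcript_effect = unname(truth$transcript_effect),
    stringsAsFactors = FALSE
  )
  write_tsv_precise(df, path)
}
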