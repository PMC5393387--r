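#' Simulation configuration
#'
#' Parameters of the synthetic SILAC + microarray experiment. The defaults
#' encode the study design being emulated: four biological replicates, basal
#' log2-ratio noise whose 99% two-sided quantile sits at a 1.5-fold change
#' (sd 0.227; the matching secretome value, sd 0.643, puts 88% of proteins
#' inside 2-fold), and moderate per-cell missingness.
#'
#' @param n_proteins Number of protein groups to simulate.
#' @param n_replicates Biological replicates per condition (default 4).
#' @param sigma_basal Sd (log2 units) of the per-protein, per-timepoint basal
#'   fluctuation shared across replicates.
#' @param sigma_rep Sd (log2 units) of replicate-level measurement noise; also
#'   the peptide-level noise sd in [simulate_peptide_evidence()].
#' @param responder_fraction Fraction of proteins given a treatment effect;
#'   responders are drawn as an exact count `round(n_proteins * fraction)`
#'   without replacement so planted set sizes are testable.
#' @param effect_size_mean,effect_size_sd Normal parameters (log2 units) of
#'   the planted late-timepoint effect; the early effect is half the late one.
#' @param discordant_protein_only_n Number of responders whose transcript is
#'   flat (post-transcriptionally regulated in the simulation).
#' @param discordant_transcript_only_n Number of non-responders given a
#'   transcript-level effect with no protein effect.
#' @param missing_rate Per-cell probability that a ratio is unquantified.
#' @param missing_mechanism `"uniform"` (independent per cell) or
#'   `"intensity"` (logistic in a latent per-protein abundance, emulating the
#'   abundance bias of SILAC missingness).
#' @param peptide_lambda Unique peptides per protein are `1 + Poisson(lambda)`.
#' @param transcript_sigma Sd (log2 units) of transcript fold-change noise.
#' @param seed Non-negative integer master seed; every stochastic operation
#'   draws from its own stream derived from this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins,
                       n_replicates = 4,
                       sigma_basal = 0.227,
                       sigma_rep = 0.1,
                       responder_fraction = 0.1,
                       effect_size_mean = 2,
                       effect_size_sd = 0.5,
                       discordant_protein_only_n = 0,
                       discordant_transcript_only_n = 0,
                       missing_rate = 0.1,
                       missing_mechanism = c("uniform", "intensity"),
                       peptide_lambda = 4,
                       transcript_sigma = 0.25,
                       seed = 1) {
  missing_mechanism <- match.arg(missing_mechanism)
  check_count <- function(x, name, min = 0) {
    if (length(x) != 1 || is.na(x) || x < min || x != round(x)) {
      stop("'", name, "' must be an integer >= ", min, call. = FALSE)
    }
  }
  check_count(n_proteins, "n_proteins", 1)
  check_count(n_replicates, "n_replicates", 1)
  check_count(discordant_protein_only_n, "discordant_protein_only_n")
  check_count(discordant_transcript_only_n, "discordant_transcript_only_n")
  check_count(seed, "seed")
  for (nm in c("sigma_basal", "sigma_rep", "effect_size_sd",
               "transcript_sigma", "peptide_lambda")) {
    v <- get(nm)
    if (length(v) != 1 || is.na(v) || v < 0) {
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
    }
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("'responder_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)", call. = FALSE)
  }
  n_responders <- round(n_proteins * responder_fraction)
  if (discordant_protein_only_n + discordant_transcript_only_n > n_proteins) {
    stop("discordant set sizes exceed n_proteins", call. = FALSE)
  }
  if (discordant_protein_only_n > n_responders) {
    stop("discordant_protein_only_n exceeds the responder count (",
         n_responders, ")", call. = FALSE)
  }
  if (discordant_transcript_only_n > n_proteins - n_responders) {
    stop("discordant_transcript_only_n exceeds the non-responder count",
         call. = FALSE)
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_replicates = as.integer(n_replicates),
      sigma_basal = sigma_basal,
      sigma_rep = sigma_rep,
      responder_fraction = responder_fraction,
      effect_size_mean = effect_size_mean,
      effect_size_sd = effect_size_sd,
      discordant_protein_only_n = as.integer(discordant_protein_only_n),
      discordant_transcript_only_n = as.integer(discordant_transcript_only_n),
      missing_rate = missing_rate,
      missing_mechanism = missing_mechanism,
      peptide_lambda = peptide_lambda,
      transcript_sigma = transcript_sigma,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: reliability-filter thresholds,
#' basal-null coverage fractions per compartment, fold-change thresholds,
#' clustering choices, and the master seed.
#'
#' @param min_unique_peptides Minimum unique peptides for a reliable
#'   identification (default 2).
#' @param min_replicates Minimum quantified replicates (default 2 of 4).
#' @param basal_coverage Named fractions in (0, 1): the basal-null coverage
#'   at which each compartment's significance threshold is read off
#'   (defaults: 99% proteome, 88% secretome).
#' @param transcript_threshold Linear fold-change bound for a transcript to
#'   count as changed (default 1.5).
#' @param min_fold Strong-changer selection bound (default 2).
#' @param distance,linkage Hierarchical clustering choices.
#' @param overlap_denominator `"union"` (Jaccard) or `"total"` (sum of sizes)
#'   for the normalized overlap percentage.
#' @param seed Non-negative integer master seed.
#' @param sim A [sim_config()] describing the synthetic experiment (the demo
#'   pipeline simulates its inputs).
#' @param output_dir Directory where [run_pipeline()] writes its artifacts.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(min_unique_peptides = 2,
                            min_replicates = 2,
                            basal_coverage = c(proteome = 0.99, secretome = 0.88),
                            transcript_threshold = 1.5,
                            min_fold = 2,
                            distance = c("pearson", "euclidean"),
                            linkage = c("average", "complete"),
                            overlap_denominator = c("union", "total"),
                            seed = 1,
                            sim = sim_config(n_proteins = 300, seed = seed),
                            output_dir = tempfile("silacint_run_")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  overlap_denominator <- match.arg(overlap_denominator)
  if (min_unique_peptides < 1 || min_replicates < 1) {
    stop("filter thresholds must be >= 1", call. = FALSE)
  }
  if (!all(COMPARTMENTS %in% names(basal_coverage))) {
    stop("'basal_coverage' must name both compartments", call. = FALSE)
  }
  if (any(basal_coverage <= 0 | basal_coverage >= 1)) {
    stop("coverage fractions must lie strictly between 0 and 1", call. = FALSE)
  }
  if (transcript_threshold <= 1 || min_fold <= 1) {
    stop("fold-change thresholds must exceed 1", call. = FALSE)
  }
  if (length(seed) != 1 || is.na(seed) || seed < 0 || seed != round(seed)) {
    stop("'seed' must be a non-negative integer", call. = FALSE)
  }
  stopifnot(inherits(sim, "sim_config"))
  structure(
    list(
      min_unique_peptides = min_unique_peptides,
      min_replicates = min_replicates,
      basal_coverage = basal_coverage[COMPARTMENTS],
      transcript_threshold = transcript_threshold,
      min_fold = min_fold,
      distance = distance,
      linkage = linkage,
      overlap_denominator = overlap_denominator,
      seed = as.integer(seed),
      sim = sim,
      output_dir = output_dir
    ),
    class = "analysis_config"
  )
}
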