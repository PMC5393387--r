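# silacint

Quantitative integration of SILAC proteome and secretome time courses with
matched transcriptome profiles, for studies of stimulus-response regulation
in cell culture — the motivating system is the macrophage response to
Toll-like-receptor (TLR) ligands (LPS, Pam3CSK4, R848).

## What it does

In a triple-label SILAC design the light channel is the untreated 0 h
reference, so the medium/light and heavy/light ratios of each protein group
are its fold changes at an early and a late timepoint (proteome 6/12 h,
secretome 6/24 h, four biological replicates). `silacint` provides the
downstream statistics:

* **Quantification** — log2 transform, per-column median normalization,
  the ≥2-unique-peptides / ≥2-of-4-replicates reliability filter, and
  missing-aware median summarization into a proteins × conditions
  fold-change matrix.
* **Empirical significance thresholds** — from an unstimulated basal time
  course. With per-protein basal summaries
  `m_p = max_c |log2 FC_(p,c)|`, the bound at coverage `q` is the order
  statistic `T = 2^(m_(k))`, `k = ceil(q·n)`: the fold change that `q` of
  all proteins never exceed without stimulation (≈1.5-fold at 99% for a
  lysate proteome, ≈2-fold at 88% for a noisier secretome).
* **Cross-condition structure** — overlap matrices (counts on the
  diagonal, intersections above, Jaccard percentages below), PCA of
  condition profiles, hierarchical clustering with correlation or
  Euclidean distance, and 2-fold "strong changer" selection ordered for
  heatmaps.
* **Transcriptome integration** — gene-symbol inner join with duplicate
  averaging, a Pearson correlation grid between all protein-side and
  transcript-side conditions, and classification of **discordant** genes:
  `protein_only` (changed at the protein but quiet at every transcript
  timepoint — candidate post-transcriptional regulation) and its
  `transcript_only` mirror.
* **Synthetic data with planted truth** — a simulator of the whole design
  (basal noise, treatment effects, discordant subsets, missingness,
  peptide-level evidence) so every stage is testable against a known
  answer key, plus `evaluate_recovery()` for precision/recall against the
  planted sets.

## Worked example

Simulate a basal and an LPS-stimulated proteome with 40 planted
protein-only and 40 transcript-only discordant genes, derive the basal
threshold, and screen for discordance:

```r
library(silacint)

cfg <- sim_config(n_proteins = 1000, seed = 42, responder_fraction = 0.2,
                  discordant_protein_only_n = 40, discordant_transcript_only_n = 40,
                  sigma_basal = 0.227, sigma_rep = 0.1, transcript_sigma = 0.05,
                  effect_size_mean = 2, effect_size_sd = 0)

basal <- simulate_basal_experiment(cfg)
bq  <- filter_reliable(normalize_median(as_protein_quant(basal)))
thr <- derive_basal_threshold(summarize_replicates(bq, "proteome", "basal"), 0.99)
thr
#> basal fold-change threshold: 1.537-fold (coverage 99.0% requested, 99.0% achieved, n = 1000, max summary)

sim <- simulate_stimulated_experiment(cfg, "LPS", "proteome")
q   <- filter_reliable(normalize_median(as_protein_quant(sim$table)))
fc  <- summarize_replicates(q, "proteome", "LPS")
nrow(apply_threshold(fc, thr, "proteome_LPS_12h"))
#> [1] 205

expr   <- simulate_transcriptome(sim$truth, cfg)
report <- classify_discordance(fc, expr, gene_map(q), protein_threshold = thr)
report
#> discordance report (1000 joined genes; protein threshold 1.54-fold, transcript 1.5-fold)
#>  treatment protein_only transcript_only concordant unclassified
#>        LPS           64              40        160          736

evaluate_recovery(report, sim$truth)
#>          category n_true n_called n_correct precision recall
#> 1    protein_only     40       64        40     0.625      1
#> 2 transcript_only     40       40        40     1.000      1
```

Reading the numbers: the basal null puts the 99% bound at 1.54-fold, close
to its analytic value `2^(2.576·0.227) ≈ 1.5`. At 12 h, 205 proteins exceed
the bound (200 planted responders plus a few basal fluctuations). The
screen recovers all 40 planted discordant genes in both directions; the
extra `protein_only` calls are null proteins whose basal fluctuation lands
just beyond the bound while their transcript is quiet — the expected cost
of a 99% empirical threshold, which is a screen, not a test.

`run_pipeline(analysis_config(...))` chains all of the above for both
compartments and all three treatments, writes every table as
tab-separated text plus a JSON manifest, and is byte-reproducible for a
fixed seed; `make_report()` prints the per-stage counts, thresholds, PCA
variance fractions and discordance counts.

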