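#' Build a transcript fold-change matrix
#'
#' Converts an expression table (possibly with duplicate gene symbols from
#' multiple probes) into a genes-by-conditions matrix of log2 fold changes,
#' averaging duplicate symbols per column with missing values ignored.
#'
#' @param expr Expression `data.frame` from [read_expression_table()] or
#'   [simulate_transcriptome()] (first column `gene_symbol`).
#' @return Numeric matrix, rows unique gene symbols (sorted), columns the
#'   `{treatment}_{hours}h` keys.
#' @export
expression_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "gene_symbol")
  parse_expression_keys(names(expr)[-1])   # validates column names
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_symbol
  average_by_symbol(m)
}

# Average rows sharing a symbol, ignoring NA; all-NA groups stay NA.
average_by_symbol <- function(m) {
  sym <- rownames(m)
  if (!anyDuplicated(sym)) return(m[order(sym), , drop = FALSE])
  g <- factor(sym)
  vals <- rowsum(ifelse(is.na(m), 0, m), g)
  cnts <- rowsum((!is.na(m)) * 1, g)
  out <- vals / cnts
  out[cnts == 0] <- NA_real_
  out[order(rownames(out)), , drop = FALSE]
}

#' Merge protein and transcript fold changes by gene symbol
#'
#' Maps protein rows to gene symbols through an explicit id map, averages
#' multiple measurements per symbol on each side (protein isoforms,
#' microarray probes), and inner-joins: only genes present on both sides
#' survive. Unmapped proteins are dropped with a tally, never silently.
#'
#' @param protein_fc Fold-change matrix (log2), rows protein ids.
#' @param transcript_fc Transcript matrix from [expression_matrix()] (or an
#'   expression `data.frame`, converted on the fly).
#' @param id_map `data.frame` with columns `protein_id`, `gene_symbol`.
#' @return A `symbol_join`: list with matrices `protein` and `transcript`
#'   over the identical joined gene set, plus `n_unmapped`.
#' @export
merge_by_symbol <- function(protein_fc, transcript_fc, id_map) {
  stopifnot(is.matrix(protein_fc),
            all(c("protein_id", "gene_symbol") %in% names(id_map)))
  if (is.data.frame(transcript_fc)) {
    transcript_fc <- expression_matrix(transcript_fc)
  }
  sym <- id_map$gene_symbol[match(rownames(protein_fc), id_map$protein_id)]
  unmapped <- is.na(sym) | sym == ""
  n_unmapped <- sum(unmapped)
  if (n_unmapped > 0) {
    message(n_unmapped, " protein(s) without a gene symbol dropped from the join")
  }
  p <- protein_fc[!unmapped, , drop = FALSE]
  rownames(p) <- sym[!unmapped]
  p <- average_by_symbol(p)
  t_avg <- average_by_symbol(transcript_fc)
  genes <- intersect(rownames(p), rownames(t_avg))
  if (length(genes) == 0) stop("no common genes", call. = FALSE)
  genes <- sort(genes)
  structure(
    list(protein = p[genes, , drop = FALSE],
         transcript = t_avg[genes, , drop = FALSE],
         genes = genes,
         n_unmapped = n_unmapped),
    class = "symbol_join"
  )
}

#' Pearson correlation grid between protein and transcript conditions
#'
#' For every (protein-side condition, transcript-side condition) pair the
#' Pearson correlation of the inner-joined, duplicate-averaged log2
#' fold-change vectors, over pairwise-complete genes. Basal / untreated
#' columns are excluded on both sides (their fold changes define the
#' references). Cells with fewer than `min_genes` complete pairs are
#' reported as missing, not zero.
#'
#' @inheritParams merge_by_symbol
#' @param min_genes Minimum complete pairs for a defined correlation
#'   (default 3).
#' @return A `correlation_grid`: matrices `r` and `n` with protein-side
#'   conditions as rows and transcript-side conditions as columns.
#' @export
correlation_grid <- function(protein_fc, transcript_fc, id_map, min_genes = 3) {
  if (is.data.frame(transcript_fc)) {
    transcript_fc <- expression_matrix(transcript_fc)
  }
  pc <- parse_condition(colnames(protein_fc))
  keep_p <- pc$treatment != "basal"
  tc <- parse_expression_keys(colnames(transcript_fc))
  keep_t <- !tolower(tc$treatment) %in% c("basal", "untreated")
  join <- merge_by_symbol(protein_fc[, keep_p, drop = FALSE],
                          transcript_fc[, keep_t, drop = FALSE], id_map)
  P <- join$protein
  T_ <- join$transcript
  r <- matrix(NA_real_, ncol(P), ncol(T_),
              dimnames = list(colnames(P), colnames(T_)))
  n <- matrix(0L, ncol(P), ncol(T_), dimnames = dimnames(r))
  for (i in seq_len(ncol(P))) {
    for (j in seq_len(ncol(T_))) {
      ok <- !is.na(P[, i]) & !is.na(T_[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] >= min_genes &&
          stats::sd(P[ok, i]) > 0 && stats::sd(T_[ok, j]) > 0) {
        r[i, j] <- stats::cor(P[ok, i], T_[ok, j])
      }
    }
  }
  structure(list(r = r, n = n), class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation grid: %d protein-side x %d transcript-side conditions\n",
              nrow(x$r), ncol(x$r)))
  print(round(x$r, digits))
  invisible(x)
}

#' Classify transcript-protein discordance per treatment
#'
#' Identifies candidate post-transcriptionally regulated genes. Per
#' treatment, a joined gene is `protein_only` when its largest absolute
#' protein log2 fold change over the treatment's protein conditions meets
#' the protein threshold while every observed transcript timepoint stays
#' strictly below the transcript threshold; `transcript_only` is the mirror
#' image. Genes significant on both sides are `concordant`; the rest are
#' `unclassified`. The "quiet" side must have at least one observed value —
#' absence of evidence is not evidence of absence.
#'
#' @inheritParams merge_by_symbol
#' @param protein_threshold Linear fold change > 1: a single value, a named
#'   vector by compartment (e.g. `c(proteome = 1.5, secretome = 2)`), or a
#'   `threshold_result` from [derive_basal_threshold()].
#' @param transcript_threshold Linear fold change > 1 (default 1.5);
#'   `Inf` disables the transcript criterion, reducing `protein_only` to a
#'   plain protein-side threshold call.
#' @param treatments Treatments to classify (default: all stimulation
#'   treatments present on both sides).
#' @return A `discordance_report`: per treatment the `protein_only`,
#'   `transcript_only`, `concordant` and `unclassified` gene sets, the
#'   thresholds used, and a counts table.
#' @export
classify_discordance <- function(protein_fc, transcript_fc, id_map,
                                 protein_threshold = c(proteome = 1.5,
                                                       secretome = 2),
                                 transcript_threshold = 1.5,
                                 treatments = NULL) {
  if (inherits(protein_threshold, "threshold_result")) {
    protein_threshold <- protein_threshold$fold_change_threshold
  }
  if (any(protein_threshold <= 1) || transcript_threshold <= 1) {
    stop("fold-change thresholds must exceed 1", call. = FALSE)
  }
  if (is.data.frame(transcript_fc)) {
    transcript_fc <- expression_matrix(transcript_fc)
  }
  pc <- parse_condition(colnames(protein_fc))
  tc <- parse_expression_keys(colnames(transcript_fc))
  if (is.null(treatments)) {
    treatments <- intersect(intersect(unique(pc$treatment), STIM_TREATMENTS),
                            unique(tc$treatment))
  }
  if (length(treatments) == 0) stop("no shared treatments", call. = FALSE)
  # per-column protein bound (log2), resolved by compartment
  pbound <- if (length(protein_threshold) == 1 && is.null(names(protein_threshold))) {
    rep(log2(protein_threshold), nrow(pc))
  } else {
    if (!all(pc$compartment %in% names(protein_threshold))) {
      stop("'protein_threshold' must name every compartment present",
           call. = FALSE)
    }
    log2(unname(protein_threshold[pc$compartment]))
  }
  tbound <- log2(transcript_threshold)
  join <- merge_by_symbol(protein_fc, transcript_fc, id_map)
  per_treatment <- list()
  counts <- NULL
  for (tr in treatments) {
    pi <- which(pc$treatment == tr)
    ti <- which(tc$treatment == tr)
    P <- join$protein[, pi, drop = FALSE]
    T_ <- join$transcript[, ti, drop = FALSE]
    p_obs <- rowSums(!is.na(P)) > 0
    t_obs <- rowSums(!is.na(T_)) > 0
    p_sig <- rowSums(sweep(abs(P), 2, pbound[pi], ">="), na.rm = TRUE) > 0
    t_sig <- rowSums(abs(T_) >= tbound, na.rm = TRUE) > 0
    protein_only <- p_sig & !t_sig & t_obs
    transcript_only <- t_sig & !p_sig & p_obs
    concordant <- p_sig & t_sig
    unclassified <- !(protein_only | transcript_only | concordant)
    per_treatment[[tr]] <- list(
      protein_only = join$genes[protein_only],
      transcript_only = join$genes[transcript_only],
      concordant = join$genes[concordant],
      unclassified = join$genes[unclassified]
    )
    counts <- rbind(counts, data.frame(
      treatment = tr,
      protein_only = sum(protein_only),
      transcript_only = sum(transcript_only),
      concordant = sum(concordant),
      unclassified = sum(unclassified),
      stringsAsFactors = FALSE
    ))
  }
  structure(
    list(per_treatment = per_treatment,
         counts = counts,
         protein_threshold = protein_threshold,
         transcript_threshold = transcript_threshold,
         n_joined = length(join$genes),
         n_unmapped = join$n_unmapped),
    class = "discordance_report"
  )
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf(
    "discordance report (%d joined genes; protein threshold %s-fold, transcript %s-fold)\n",
    x$n_joined, paste(signif(x$protein_threshold, 3), collapse = "/"),
    signif(x$transcript_threshold, 3)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Evaluate discordance calls against a planted truth
#'
#' Set-arithmetic precision and recall of the `protein_only` and
#' `transcript_only` calls for the truth's treatment. Precision is reported
#' as missing when no call was made.
#'
#' @param report A `discordance_report`.
#' @param truth A `planted_truth` from [simulate_stimulated_experiment()].
#' @return `data.frame` with one row per category: `n_true`, `n_called`,
#'   `n_correct`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(report, truth) {
  stopifnot(inherits(report, "discordance_report"),
            inherits(truth, "planted_truth"))
  tr <- truth$treatment
  if (!tr %in% names(report$per_treatment)) {
    stop("report does not cover treatment '", tr, "'", call. = FALSE)
  }
  called <- report$per_treatment[[tr]]
  universe <- unique(unlist(called))
  if (!all(universe %in% truth$gene_symbol)) {
    stop("mismatched gene universe between report and truth", call. = FALSE)
  }
  one <- function(pred, true) {
    tp <- length(intersect(pred, true))
    data.frame(
      n_true = length(true), n_called = length(pred), n_correct = tp,
      precision = if (length(pred) == 0) NA_real_ else tp / length(pred),
      recall = if (length(true) == 0) NA_real_ else tp / length(true)
    )
  }
  out <- rbind(one(called$protein_only, truth$protein_only),
               one(called$transcript_only, truth$transcript_only))
  cbind(data.frame(category = c("protein_only", "transcript_only"),
                   stringsAsFactors = FALSE), out)
}
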