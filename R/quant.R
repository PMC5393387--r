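#' Protein quantification tables
#'
#' A `protein_quant` holds per-protein, per-replicate log2 fold changes
#' versus the 0 h reference channel for the two stimulation timepoints
#' (`early` = medium/light, `late` = heavy/light) together with
#' per-replicate unique-peptide counts. It is the unit every quantification
#' operation consumes and produces.
#'
#' @param protein_id Character vector of unique accessions.
#' @param gene_symbol Character vector (may contain empty strings).
#' @param log2fc Named list of two proteins-by-replicates matrices,
#'   `early` and `late`, `NA` for unquantified cells.
#' @param unique_peptides Proteins-by-replicates integer matrix.
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(protein_id, gene_symbol, log2fc, unique_peptides) {
  stopifnot(is.list(log2fc), identical(names(log2fc), c("early", "late")))
  n <- length(protein_id)
  if (anyDuplicated(protein_id)) stop("duplicate protein_id", call. = FALSE)
  for (tp in names(log2fc)) {
    m <- log2fc[[tp]]
    stopifnot(is.matrix(m), nrow(m) == n)
    if (any(!is.na(m) & !is.finite(m))) {
      stop("non-finite log2 fold change in '", tp, "'", call. = FALSE)
    }
    rownames(log2fc[[tp]]) <- protein_id
  }
  stopifnot(is.matrix(unique_peptides), nrow(unique_peptides) == n,
            ncol(unique_peptides) == ncol(log2fc$early))
  rownames(unique_peptides) <- protein_id
  structure(
    list(protein_id = protein_id,
         gene_symbol = as.character(gene_symbol),
         log2fc = log2fc,
         unique_peptides = unique_peptides),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins x %d replicates x 2 timepoints\n",
              length(x$protein_id), ncol(x$log2fc$early)))
  for (tp in names(x$log2fc)) {
    m <- x$log2fc[[tp]]
    cat(sprintf("  %s: %d/%d cells quantified\n", tp,
                sum(!is.na(m)), length(m)))
  }
  invisible(x)
}

#' @export
`[.protein_quant` <- function(x, i, ...) {
  protein_quant(x$protein_id[i], x$gene_symbol[i],
                lapply(x$log2fc, function(m) m[i, , drop = FALSE]),
                x$unique_peptides[i, , drop = FALSE])
}

#' Convert a protein-groups table to log2 quantifications
#'
#' Takes the linear medium/light and heavy/light ratios of a protein-groups
#' table (each already referenced to the 0 h light channel) into log2 space.
#'
#' @param groups Protein-groups `data.frame` from [read_protein_groups()] or
#'   a simulator.
#' @param n_replicates Number of replicate column triples to expect.
#' @return A [protein_quant()].
#' @export
as_protein_quant <- function(groups, n_replicates = 4) {
  required <- protein_groups_columns(n_replicates)
  miss <- setdiff(required, names(groups))
  if (length(miss) > 0) {
    stop("missing mandatory column '", miss[1], "'", call. = FALSE)
  }
  reps <- seq_len(n_replicates)
  ml <- log2(as.matrix(groups[, sprintf("ratio_ML_rep%d", reps), drop = FALSE]))
  hl <- log2(as.matrix(groups[, sprintf("ratio_HL_rep%d", reps), drop = FALSE]))
  up <- as.matrix(groups[, sprintf("unique_peptides_rep%d", reps), drop = FALSE])
  colnames(ml) <- colnames(hl) <- colnames(up) <- sprintf("rep%d", reps)
  protein_quant(groups$protein_id, groups$gene_symbol,
                list(early = ml, late = hl), up)
}

#' Protein-to-gene-symbol map of a quantification table
#'
#' @param x A [protein_quant()] or protein-groups `data.frame`.
#' @return A `data.frame` with columns `protein_id`, `gene_symbol`.
#' @export
gene_map <- function(x) {
  if (inherits(x, "protein_quant")) {
    data.frame(protein_id = x$protein_id, gene_symbol = x$gene_symbol,
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = x$protein_id, gene_symbol = x$gene_symbol,
               stringsAsFactors = FALSE)
  }
}

#' Aggregate peptide evidence to protein quantifications
#'
#' Per protein, replicate and timepoint the protein log2 ratio is the median
#' of its peptides' log2 ratios (even-length medians average the central
#' pair); the unique-peptide count per replicate is the number of distinct
#' peptide ids with any observed ratio in that replicate.
#'
#' @param evidence Long peptide table as produced by
#'   [simulate_peptide_evidence()] (columns `protein_id`, `gene_symbol`
#'   optional, `peptide_id`, `replicate`, `timepoint`, `log2_ratio`).
#' @param n_replicates Replicate count of the design.
#' @return A [protein_quant()]; empty evidence gives an empty table.
#' @export
aggregate_peptides <- function(evidence, n_replicates = 4) {
  needed <- c("protein_id", "peptide_id", "replicate", "timepoint", "log2_ratio")
  miss <- setdiff(needed, names(evidence))
  if (length(miss) > 0) {
    stop("evidence is missing column '", miss[1], "'", call. = FALSE)
  }
  ids <- sort(unique(evidence$protein_id))
  n <- length(ids)
  reps <- seq_len(n_replicates)
  empty <- matrix(NA_real_, n, n_replicates,
                  dimnames = list(ids, sprintf("rep%d", reps)))
  log2fc <- list(early = empty, late = empty)
  up <- matrix(0L, n, n_replicates, dimnames = dimnames(empty))
  obs <- evidence[!is.na(evidence$log2_ratio), , drop = FALSE]
  if (nrow(obs) > 0) {
    for (tp in c("early", "late")) {
      sub <- obs[obs$timepoint == tp, , drop = FALSE]
      if (nrow(sub) == 0) next
      med <- tapply(sub$log2_ratio,
                    list(factor(sub$protein_id, levels = ids),
                         factor(sub$replicate, levels = reps)),
                    stats::median)
      log2fc[[tp]][] <- med
    }
    # distinct peptides with any ratio in the replicate (either timepoint)
    key <- paste(obs$protein_id, obs$replicate, obs$peptide_id, sep = "\r")
    dd <- obs[!duplicated(key), c("protein_id", "replicate")]
    cnt <- table(factor(dd$protein_id, levels = ids),
                 factor(dd$replicate, levels = reps))
    up[] <- as.integer(cnt)
  }
  gene <- if ("gene_symbol" %in% names(evidence)) {
    evidence$gene_symbol[match(ids, evidence$protein_id)]
  } else {
    rep("", n)
  }
  protein_quant(ids, gene, log2fc, up)
}

#' Median-center each replicate/timepoint column
#'
#' Corrects unequal channel mixing: within every (replicate, timepoint)
#' column the median log2 ratio is subtracted, equivalently the linear
#' ratios are divided by their median. Idempotent; the missing mask is
#' untouched.
#'
#' @param table A [protein_quant()].
#' @return The normalized [protein_quant()].
#' @export
normalize_median <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  for (tp in names(table$log2fc)) {
    m <- table$log2fc[[tp]]
    for (r in seq_len(ncol(m))) {
      v <- m[, r]
      if (all(is.na(v))) {
        cn <- if (is.null(colnames(m))) sprintf("rep%d", r) else colnames(m)[r]
        stop(sprintf("cannot normalize: column '%s %s' is entirely missing",
                     tp, cn), call. = FALSE)
      }
      m[, r] <- v - stats::median(v, na.rm = TRUE)
    }
    table$log2fc[[tp]] <- m
  }
  table
}

#' Reliability filter: unique peptides and quantified replicates
#'
#' Keeps proteins identified by at least `min_unique_peptides` unique
#' peptides (in any replicate by default, or summed across replicates) and
#' quantified in at least `min_replicates` biological replicates. The
#' replicate criterion is applied per timepoint: a protein may pass at 6 h
#' and fail at 12 h, in which case the failing timepoint's values are
#' blanked and the protein is retained only if some timepoint passes.
#'
#' @param table A [protein_quant()].
#' @param min_unique_peptides Minimum unique peptides (default 2).
#' @param min_replicates Minimum quantified replicates (default 2 of 4).
#' @param peptide_rule `"any"` (any single replicate reaches the count) or
#'   `"sum"` (counts summed across replicates).
#' @return The filtered [protein_quant()].
#' @export
filter_reliable <- function(table, min_unique_peptides = 2,
                            min_replicates = 2,
                            peptide_rule = c("any", "sum")) {
  stopifnot(inherits(table, "protein_quant"))
  peptide_rule <- match.arg(peptide_rule)
  if (min_unique_peptides < 1 || min_replicates < 1) {
    stop("filter thresholds must be >= 1", call. = FALSE)
  }
  if (length(table$protein_id) == 0) return(table)
  pep_ok <- if (peptide_rule == "any") {
    apply(table$unique_peptides, 1, max) >= min_unique_peptides
  } else {
    rowSums(table$unique_peptides) >= min_unique_peptides
  }
  tp_ok <- vapply(table$log2fc, function(m) {
    rowSums(!is.na(m)) >= min_replicates
  }, logical(length(table$protein_id)))
  tp_ok <- matrix(tp_ok, ncol = length(table$log2fc),
                  dimnames = list(NULL, names(table$log2fc)))
  keep <- pep_ok & rowSums(tp_ok) > 0
  out <- table[which(keep)]
  for (tp in names(out$log2fc)) {
    fail <- !tp_ok[keep, tp]
    out$log2fc[[tp]][fail, ] <- NA_real_
  }
  out
}

#' Summarize replicates into a fold-change matrix
#'
#' Per protein and timepoint, the median over the non-missing replicate
#' log2 values; a cell is missing only when all replicates are missing.
#' Columns are labelled with the full condition key, so the early column of
#' an LPS proteome table becomes `proteome_LPS_6h` and the late one
#' `proteome_LPS_12h` (24 h for the secretome).
#'
#' @param table A filtered [protein_quant()].
#' @param compartment `"proteome"` or `"secretome"`.
#' @param treatment Treatment label for the condition keys.
#' @return A proteins-by-2 fold-change matrix (log2, `NA` missing).
#' @export
summarize_replicates <- function(table, compartment, treatment) {
  stopifnot(inherits(table, "protein_quant"))
  hours <- compartment_hours(compartment)
  cols <- condition_key(compartment, treatment, hours)
  out <- matrix(NA_real_, length(table$protein_id), 2,
                dimnames = list(table$protein_id, cols))
  for (j in 1:2) {
    m <- table$log2fc[[c("early", "late")[j]]]
    out[, j] <- apply(m, 1, function(v) {
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
    })
  }
  out
}
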