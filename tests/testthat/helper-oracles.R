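# Independent brute-force oracles and fixture builders shared across tests.

# Order-statistic threshold by exhaustive scan: smallest candidate bound
# covering at least `coverage` of the per-protein summaries.
bf_threshold_scan <- function(basal, coverage) {
  m <- apply(abs(basal), 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  m <- m[!is.na(m)]
  for (cand in sort(unique(m))) {
    if (mean(m <= cand) >= coverage) return(2^cand)
  }
  stop("unreachable")
}

# Brute-force agglomerative clustering; returns the cophenetic distance
# matrix, which identifies the tree regardless of merge bookkeeping.
bf_agglom_cophenetic <- function(d, linkage) {
  n <- nrow(d)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  cl <- lapply(seq_len(n), identity)
  while (length(cl) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        dd <- if (linkage == "average") {
          mean(d[cl[[i]], cl[[j]]])
        } else {
          max(d[cl[[i]], cl[[j]]])
        }
        if (dd < bestd) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    coph[cl[[best[1]]], cl[[best[2]]]] <- bestd
    coph[cl[[best[2]]], cl[[best[1]]]] <- bestd
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl <- cl[-best[2]]
  }
  coph
}

# Random fold-change matrix with optional missingness.
random_fc_matrix <- function(n_proteins, n_samples, missing_rate = 0,
                             labels = NULL) {
  m <- matrix(rnorm(n_proteins * n_samples), n_proteins, n_samples)
  if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA
  rownames(m) <- sprintf("P%04d", seq_len(n_proteins))
  colnames(m) <- if (is.null(labels)) sprintf("S%02d", seq_len(n_samples)) else labels
  m
}

# Hand-built protein_quant from per-timepoint matrices.
quant_fixture <- function(early, late, peptides,
                          ids = sprintf("P%02d", seq_len(nrow(early)))) {
  protein_quant(ids, sprintf("G%02d", seq_len(nrow(early))),
                list(early = early, late = late), peptides)
}

# Protein-groups fixture file with 4 replicates; `rows` is a list of lists
# with protein_id, gene_symbol, up (4 counts), ml (4 ratios), hl (4 ratios).
write_groups_fixture <- function(rows, path) {
  cells <- lapply(rows, function(r) {
    fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 15))
    c(r$protein_id, r$gene_symbol, fmt(r$up), fmt(r$ml), fmt(r$hl))
  })
  header <- c("protein_id", "gene_symbol",
              sprintf("unique_peptides_rep%d", 1:4),
              sprintf("ratio_ML_rep%d", 1:4),
              sprintf("ratio_HL_rep%d", 1:4))
  lines <- c(paste(header, collapse = "\t"),
             vapply(cells, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}
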