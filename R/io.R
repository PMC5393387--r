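#' Read a protein-groups table
#'
#' Reads the tab-separated protein-groups dialect consumed by the
#' quantification stage. The dialect mirrors MaxQuant `proteinGroups.txt`
#' semantics with normalized column names: `protein_id`, `gene_symbol`, and
#' per replicate `i` the columns `unique_peptides_rep{i}`, `ratio_ML_rep{i}`
#' (medium/light, i.e. early timepoint vs 0 h) and `ratio_HL_rep{i}`
#' (heavy/light, late timepoint vs 0 h). Ratios are stored on the linear
#' scale and must be strictly positive; missing cells are written as `"NA"`
#' and come back as `NA`, never as zero. A genuine MaxQuant table can be
#' adapted by renaming "Ratio M/L <exp>", "Ratio H/L <exp>" and
#' "Unique peptides <exp>" columns to this scheme.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param n_replicates Number of biological replicates expected (default 4,
#'   the quadruplicate design).
#' @return A `data.frame`, one row per protein group.
#' @export
read_protein_groups <- function(path, n_replicates = 4) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- protein_groups_columns(n_replicates)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("protein-groups file is missing mandatory column '",
         missing_cols[1], "'", call. = FALSE)
  }
  df <- df[, required]
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id: '",
         df$protein_id[duplicated(df$protein_id)][1], "'", call. = FALSE)
  }
  for (col in grep("^ratio_", required, value = TRUE)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v))) {
        stop("non-numeric value in column '", col, "'", call. = FALSE)
      }
      df[[col]] <- v
    }
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-positive ratio in column '%s', row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  for (col in grep("^unique_peptides_", required, value = TRUE)) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v != round(v)))) {
      stop("unique-peptide counts must be non-negative integers ('",
           col, "')", call. = FALSE)
    }
    df[[col]][is.na(v)] <- 0L
  }
  df
}

protein_groups_columns <- function(n_replicates) {
  reps <- seq_len(n_replicates)
  c("protein_id", "gene_symbol",
    sprintf("unique_peptides_rep%d", reps),
    sprintf("ratio_ML_rep%d", reps),
    sprintf("ratio_HL_rep%d", reps))
}

#' Write a protein-groups table
#'
#' Inverse of [read_protein_groups()]; missing ratios are serialized as
#' `"NA"`.
#'
#' @param df Protein-groups data frame.
#' @param path Output path.
#' @export
write_protein_groups <- function(df, path) {
  write_tsv_precise(df, path)
}

#' Read a transcript fold-change (expression) table
#'
#' Tab-separated, first column `gene_symbol`, remaining columns named
#' `{treatment}_{hours}h` (e.g. `LPS_1h`) holding log2 fold changes relative
#' to the matched untreated sample. Duplicate gene symbols (multiple probes)
#' are retained; they are averaged downstream when matrices are built.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with attribute `"keys"`, a data frame mapping each
#'   measurement column to its `(treatment, hours)` pair.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_symbol") {
    stop("first column must be 'gene_symbol'", call. = FALSE)
  }
  if (ncol(df) < 2) {
    stop("expression table needs at least one treatment column", call. = FALSE)
  }
  if (any(is.na(df$gene_symbol) | df$gene_symbol == "")) {
    stop("empty gene_symbol in expression table", call. = FALSE)
  }
  keys <- parse_expression_keys(names(df)[-1])
  attr(df, "keys") <- keys
  df
}

parse_expression_keys <- function(cols) {
  m <- regmatches(cols, regexec("^([A-Za-z0-9]+)_([0-9]+)h$", cols))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("unparseable expression column name: '", cols[bad][1],
         "' (expected '{treatment}_{hours}h')", call. = FALSE)
  }
  data.frame(
    column = cols,
    treatment = vapply(m, `[`, character(1), 2L),
    hours = as.numeric(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a fold-change matrix
#'
#' Fold-change matrices (proteins x conditions, log2 scale, `NA` for missing)
#' are exchanged as tab-separated tables with a leading `protein_id` column.
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces values and the missing mask exactly.
#'
#' @param matrix Numeric matrix with row names (protein or gene ids) and
#'   condition-label column names.
#' @param path Output path.
#' @export
write_fold_change_table <- function(matrix, path) {
  stopifnot(is.matrix(matrix))
  df <- data.frame(protein_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(protein_id = character(0))
    for (cn in colnames(matrix)) df[[cn]] <- numeric(0)
  }
  write_tsv_precise(df, path)
}

#' @rdname write_fold_change_table
#' @return `read_fold_change_table()` returns the numeric matrix.
#' @export
read_fold_change_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "protein_id") {
    stop("first column must be 'protein_id'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  m
}

# Tab-separated writer preserving full double precision; NA -> "NA".
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  ok <- try(utils::write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write '", path, "'", call. = FALSE)
  }
  invisible(path)
}
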