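#' Derive a fold-change significance threshold from basal data
#'
#' The unstimulated time course bounds how much a protein's abundance
#' fluctuates with no stimulus at all. Per protein the basal summary is the
#' maximum absolute log2 fold change over all basal conditions (so no single
#' timepoint may exceed the bound); the threshold is the `k`-th smallest
#' such summary with `k = ceiling(coverage * n)`, returned as a linear fold
#' change. In the emulated study this yields approximately 1.5-fold at 99%
#' coverage for the proteome and 2-fold at 88% coverage for the secretome.
#'
#' @param basal Fold-change matrix (log2) of the basal experiment.
#' @param coverage Requested fraction of basal proteins inside the bound,
#'   strictly between 0 and 1.
#' @param summary `"max"` (per-protein maximum across basal conditions,
#'   default) or `"pooled"` (every cell treated as an observation).
#' @return A `threshold_result`: `fold_change_threshold` (linear, >= 1),
#'   `coverage_requested`, `coverage_achieved` (the realized fraction inside
#'   the bound; equals `k/n` unless ties inflate it), and `n_proteins`.
#' @export
derive_basal_threshold <- function(basal, coverage, summary = c("max", "pooled")) {
  summary <- match.arg(summary)
  if (!is.matrix(basal) || length(basal) == 0) {
    stop("'basal' must be a non-empty fold-change matrix", call. = FALSE)
  }
  if (length(coverage) != 1 || is.na(coverage) || coverage <= 0 || coverage >= 1) {
    stop("'coverage' must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- if (summary == "max") {
    apply(abs(basal), 1, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  } else {
    as.vector(abs(basal))
  }
  m <- m[!is.na(m)]
  n <- length(m)
  if (n == 0) {
    stop("'basal' has no quantified protein", call. = FALSE)
  }
  k <- ceiling(coverage * n)
  bound_log2 <- unname(sort(m)[k])
  structure(
    list(
      fold_change_threshold = 2^bound_log2,
      coverage_requested = coverage,
      coverage_achieved = mean(m <= bound_log2),
      n_proteins = n,
      summary = summary
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "basal fold-change threshold: %.4g-fold (coverage %.1f%% requested, %.1f%% achieved, n = %d, %s summary)\n",
    x$fold_change_threshold, 100 * x$coverage_requested,
    100 * x$coverage_achieved, x$n_proteins, x$summary))
  invisible(x)
}

#' Coverage achieved by a pre-chosen fold-change bound
#'
#' The inverse direction of [derive_basal_threshold()]: given a bound (e.g.
#' 1.5-fold), report the fraction of basal proteins whose summary stays at
#' or below it.
#'
#' @param basal Fold-change matrix (log2) of the basal experiment.
#' @param fold_change Linear fold-change bound > 1.
#' @inheritParams derive_basal_threshold
#' @return A `threshold_result` with `coverage_requested = NA`.
#' @export
basal_coverage <- function(basal, fold_change, summary = c("max", "pooled")) {
  summary <- match.arg(summary)
  if (fold_change <= 1) stop("'fold_change' must exceed 1", call. = FALSE)
  m <- if (summary == "max") {
    apply(abs(basal), 1, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  } else {
    as.vector(abs(basal))
  }
  m <- m[!is.na(m)]
  if (length(m) == 0) stop("'basal' has no quantified protein", call. = FALSE)
  structure(
    list(
      fold_change_threshold = fold_change,
      coverage_requested = NA_real_,
      coverage_achieved = mean(m <= log2(fold_change)),
      n_proteins = length(m),
      summary = summary
    ),
    class = "threshold_result"
  )
}

#' Apply a significance threshold at one condition
#'
#' Returns the proteins whose absolute log2 fold change at the given
#' condition meets the bound, with the direction of change. By default a
#' protein exactly at the bound is significant (`strict = TRUE` uses `>`).
#' Missing cells are never significant.
#'
#' @param matrix Fold-change matrix (log2).
#' @param threshold A `threshold_result` or a linear fold change > 1.
#' @param condition Column label ([condition_key()]) to test.
#' @param strict Use a strict inequality.
#' @return A `data.frame` with columns `protein_id`, `log2_fc`, `direction`
#'   (`"up"`/`"down"`), ordered by protein id.
#' @export
apply_threshold <- function(matrix, threshold, condition, strict = FALSE) {
  if (inherits(threshold, "threshold_result")) {
    threshold <- threshold$fold_change_threshold
  }
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  if (!condition %in% colnames(matrix)) {
    stop("unknown condition: '", condition, "'", call. = FALSE)
  }
  v <- matrix[, condition]
  bound <- log2(threshold)
  sel <- !is.na(v) & if (strict) abs(v) > bound else abs(v) >= bound
  ids <- rownames(matrix)[sel]
  ord <- order(ids)
  out <- data.frame(
    protein_id = ids[ord],
    log2_fc = unname(v[sel][ord]),
    direction = ifelse(v[sel][ord] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
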