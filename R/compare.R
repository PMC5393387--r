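#' Pairwise overlap matrix of condition protein sets
#'
#' Summarizes how many proteins the experimental conditions share. The
#' diagonal holds per-condition protein counts, the upper triangle pairwise
#' intersection counts, and the lower triangle the normalized percentage
#' overlap: by default `100 * |intersection| / |union|` (Jaccard), which
#' weights for unequal set sizes; `denominator = "total"` divides by the sum
#' of the two set sizes instead.
#'
#' @param sets Named list of protein-id character vectors, one per
#'   condition; names must be unique.
#' @param denominator `"union"` or `"total"`.
#' @return An `overlap_matrix`: a numeric matrix with the triple semantics
#'   above and attribute `denominator`.
#' @export
build_overlap_matrix <- function(sets, denominator = c("union", "total")) {
  denominator <- match.arg(denominator)
  if (length(sets) < 2) stop("need at least two sets", call. = FALSE)
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("sets must carry unique non-empty labels", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  diag(m) <- vapply(sets, length, integer(1))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- if (denominator == "union") {
        length(union(sets[[i]], sets[[j]]))
      } else {
        length(sets[[i]]) + length(sets[[j]])
      }
      m[i, j] <- inter
      m[j, i] <- if (denom == 0) 0 else 100 * inter / denom
    }
  }
  structure(m, class = c("overlap_matrix", "matrix", "array"),
            denominator = denominator)
}

#' @export
print.overlap_matrix <- function(x, digits = 1, ...) {
  cat(sprintf(
    "overlap matrix (diagonal: counts; upper: intersections; lower: %% of %s)\n",
    attr(x, "denominator")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Proteins common to every matrix
#'
#' @param matrices List of fold-change matrices (or character vectors of
#'   protein ids).
#' @return Sorted character vector: the intersection of the row sets.
#' @export
select_common_proteins <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  ids <- lapply(matrices, function(m) {
    if (is.character(m)) m else rownames(m)
  })
  sort(Reduce(intersect, ids))
}

#' Principal component analysis of condition profiles
#'
#' Samples (conditions) are the observations and proteins the variables,
#' so the score plot places similar stimulation conditions near each other.
#' Only proteins quantified in every sample enter; each protein is
#' mean-centered across samples and components come from the singular value
#' decomposition of the centered matrix (equivalently the eigendecomposition
#' of the sample covariance).
#'
#' @param matrix Fold-change matrix (log2), proteins x samples.
#' @return A `pca_result`: `scores` (samples x components), `rotation`,
#'   `center`, `var_explained` (non-increasing fractions summing to 1 over
#'   all components), `proteins_used`.
#' @export
run_pca <- function(matrix) {
  stopifnot(is.matrix(matrix))
  complete <- matrix[stats::complete.cases(matrix), , drop = FALSE]
  if (nrow(complete) < 2 || ncol(complete) < 2) {
    stop("PCA needs at least 2 complete proteins and 2 samples", call. = FALSE)
  }
  p <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      scores = p$x,
      rotation = p$rotation,
      center = p$center,
      var_explained = ve,
      proteins_used = rownames(complete)
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$var_explained))
  cat(sprintf("PCA on %d complete proteins, %d samples\n",
              length(x$proteins_used), nrow(x$scores)))
  cat("variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the condition columns. Pairwise distances are
#' computed on the positions both samples quantify: Pearson-correlation
#' distance `1 - r` (the default, insensitive to response magnitude) or
#' Euclidean distance over the shared positions. Columns are ordered
#' lexicographically before clustering so ties break deterministically by
#' label.
#'
#' @param matrix Fold-change matrix (log2), proteins x samples.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return A `cluster_result`: `merge`, `height`, `order`, `labels` (as in
#'   [stats::hclust()]), the `distance` and `linkage` used, and the
#'   underlying `hclust` object.
#' @export
hierarchical_cluster <- function(matrix, distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2) stop("need at least two samples", call. = FALSE)
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  d <- sample_distances(matrix, distance)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels, distance = distance, linkage = linkage,
         hclust = hc),
    class = "cluster_result"
  )
}

sample_distances <- function(matrix, distance) {
  k <- ncol(matrix)
  d <- matrix(0, k, k, dimnames = list(colnames(matrix), colnames(matrix)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- matrix[, i]
      y <- matrix[, j]
      shared <- !is.na(x) & !is.na(y)
      if (sum(shared) < 3) {
        stop(sprintf(
          "samples '%s' and '%s' share fewer than 3 quantified proteins",
          colnames(matrix)[i], colnames(matrix)[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- if (distance == "pearson") {
        1 - stats::cor(x[shared], y[shared])
      } else {
        sqrt(sum((x[shared] - y[shared])^2))
      }
    }
  }
  d
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering of %d samples (%s distance, %s linkage)\n",
              length(x$labels), x$distance, x$linkage))
  cat("leaf order:", paste(x$labels[x$order], collapse = ", "), "\n")
  invisible(x)
}

#' Export a cluster tree as Newick
#'
#' @param cluster A `cluster_result`.
#' @param path Output path.
#' @export
write_cluster_newick <- function(cluster, path) {
  stopifnot(inherits(cluster, "cluster_result"))
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Select and order strong changers for heatmap display
#'
#' Retains proteins whose absolute log2 fold change reaches
#' `log2(min_fold)` in at least one condition (either direction) and orders
#' them by decreasing mean log2 fold change over their non-missing
#' conditions; ties break by protein id. Missing cells are kept as `NA` for
#' display (gray cells in a heatmap).
#'
#' @param matrix Fold-change matrix (log2).
#' @param min_fold Linear fold-change bound, > 1 (default 2).
#' @return The ordered submatrix of retained proteins.
#' @export
select_strong_changers <- function(matrix, min_fold = 2) {
  stopifnot(is.matrix(matrix))
  if (min_fold <= 1) stop("'min_fold' must exceed 1", call. = FALSE)
  bound <- log2(min_fold)
  hit <- apply(matrix, 1, function(v) any(!is.na(v) & abs(v) >= bound))
  sub <- matrix[hit, , drop = FALSE]
  means <- rowMeans(sub, na.rm = TRUE)
  sub[order(-means, rownames(sub)), , drop = FALSE]
}
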