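test_that("overlap matrix encodes counts, intersections and Jaccard percentages", {
  sets <- list(x = c("a", "b", "c"), y = c("b", "c", "d"))
  om <- build_overlap_matrix(sets)
  expect_equal(diag(unclass(om)), c(x = 3, y = 3))
  expect_equal(om["x", "y"], 2)          # intersection
  expect_equal(om["y", "x"], 50)         # 100 * 2 / 4
  # identity and disjoint cases
  om2 <- build_overlap_matrix(list(s = c("a", "b"), t = c("a", "b"),
                                   u = c("z1", "z2")))
  expect_equal(om2["t", "s"], 100)
  expect_equal(om2["u", "s"], 0)
  # sum-of-sizes denominator variant
  om3 <- build_overlap_matrix(sets, denominator = "total")
  expect_equal(om3["y", "x"], 100 * 2 / 6)
  expect_error(build_overlap_matrix(list(a = "x")), "at least two")
  expect_error(build_overlap_matrix(setNames(list("x", "y"), c("a", "a"))),
               "unique")
})

test_that("overlap invariants hold on random set families", {
  set.seed(51)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    sets <- lapply(seq_len(k), function(j) {
      sample(sprintf("p%02d", 1:30), sample(0:20, 1))
    })
    names(sets) <- sprintf("S%d", seq_len(k))
    om <- unclass(build_overlap_matrix(sets))
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        expect_lte(om[a, b], min(om[a, a], om[b, b]))
        expect_gte(om[b, a], 0)
        expect_lte(om[b, a], 100)
        # symmetry of the normalized overlap
        expect_equal(om[b, a],
                     unclass(build_overlap_matrix(sets[c(b, a)]))[2, 1])
      }
    }
  }
})

test_that("common-protein selection is the row-set intersection", {
  m <- function(ids) matrix(0, length(ids), 1, dimnames = list(ids, "c"))
  expect_equal(select_common_proteins(list(m(c("A", "B", "C")), m(c("B", "C")),
                                           m(c("B", "D", "C")))),
               c("B", "C"))
  expect_equal(select_common_proteins(list(m(c("A", "B")), m(c("A", "B")))),
               c("A", "B"))
  expect_length(select_common_proteins(list(m(character(0)), m("A"))), 0)
})

test_that("PCA matches closed-form variance splits and reconstructs its input", {
  # rank-1: every sample a multiple of one profile
  u <- c(1, 2, -1, 0.5)
  rank1 <- outer(u, c(1, 2, 3, 4))
  dimnames(rank1) <- list(sprintf("P%d", 1:4), sprintf("S%d", 1:4))
  p1 <- run_pca(rank1)
  expect_equal(p1$var_explained[1], 1.0)

  # two orthogonal profiles with sample variances 4 and 1 -> 0.8 / 0.2
  m <- rbind(c(2, -2, 2, -2), c(1, -1, -1, 1))
  dimnames(m) <- list(c("P1", "P2"), sprintf("S%d", 1:4))
  p2 <- run_pca(m)
  expect_equal(p2$var_explained[1:2], c(0.8, 0.2))

  # reconstruction identity and general properties
  set.seed(61)
  x <- random_fc_matrix(30, 6)
  p <- run_pca(x)
  recon <- p$scores %*% t(p$rotation)
  recon <- sweep(recon, 2, p$center, "+")
  expect_equal(unname(recon), unname(t(x)), tolerance = 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)

  expect_error(run_pca(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("sample clustering is deterministic and merges the closest pair first", {
  # identical samples merge at height zero
  x <- random_fc_matrix(10, 2, labels = c("A", "B"))
  x[, 2] <- x[, 1]
  cl <- hierarchical_cluster(x, "euclidean", "average")
  expect_equal(cl$height[1], 0)
  # A and B highly correlated, C anti-correlated: first merge is (A, B)
  set.seed(71)
  base <- rnorm(20)
  y <- cbind(A = base + rnorm(20, 0, 0.05), B = base + rnorm(20, 0, 0.05),
             C = -base + rnorm(20, 0, 0.05))
  rownames(y) <- sprintf("P%02d", 1:20)
  cl2 <- hierarchical_cluster(y, "pearson", "average")
  expect_setequal(cl2$merge[1, ], c(-1, -2))
  expect_setequal(sort(cl2$labels[cl2$order]), c("A", "B", "C"))
  # provenance is recorded
  expect_equal(cl2$distance, "pearson")
  expect_equal(cl2$linkage, "average")
  # too few shared quantified proteins is an error
  z <- matrix(c(1, 2, NA, NA, NA, NA, 3, 4), 4, 2,
              dimnames = list(sprintf("P%d", 1:4), c("A", "B")))
  expect_error(hierarchical_cluster(z, "euclidean"), "fewer than 3")
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(81)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    x <- random_fc_matrix(15, k)
    for (linkage in c("average", "complete")) {
      cl <- hierarchical_cluster(x, "euclidean", linkage)
      d <- as.matrix(dist(t(x[, sort(colnames(x))])))
      expect_equal(as.matrix(cophenetic(cl$hclust))[colnames(d), colnames(d)],
                   bf_agglom_cophenetic(d, linkage), tolerance = 1e-10)
    }
  }
})

test_that("strong-changer selection filters on max fold and orders by mean", {
  m <- rbind(P1 = c(1.1, 0.2), P2 = c(0.8, 0.1), P3 = c(2.3, 1.7),
             P4 = c(NA, NA))
  colnames(m) <- c("proteome_LPS_6h", "proteome_LPS_12h")
  sel <- select_strong_changers(m, min_fold = 2)
  expect_identical(rownames(sel), c("P3", "P1"))  # ordered by mean log2 FC
  expect_true(is.na(select_strong_changers(rbind(m, P5 = c(3, NA)), 2)["P5", 2]))
  # subset property: a stricter bound never adds proteins
  set.seed(91)
  x <- random_fc_matrix(40, 5, missing_rate = 0.2)
  s2 <- rownames(select_strong_changers(x, 2))
  s15 <- rownames(select_strong_changers(x, 1.5))
  expect_true(all(s2 %in% s15))
  expect_error(select_strong_changers(x, 1), "exceed 1")
})
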