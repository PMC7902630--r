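test_that("confusion counts match a brute-force voxel tally", {
  set.seed(31)
  for (case in 1:25) {
    p <- random_mask_volume(c(6, 6, 6), runif(1, 0.1, 0.9))
    g <- random_mask_volume(c(6, 6, 6), runif(1, 0.1, 0.9))
    cc <- confusion(p, g)
    tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      a <- p$data[i, j, k]; b <- g$data[i, j, k]
      if (a == 1 && b == 1) tp <- tp + 1L
      else if (a == 1) fp <- fp + 1L
      else if (b == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(tp, fp, fn, tn))
  }
  expect_error(confusion(random_mask_volume(c(2, 2, 2)),
                         random_mask_volume(c(3, 3, 3))), "shapes")
})

test_that("overlap metrics evaluate the set formulas exactly", {
  # |X| = 4, |Y| = 6, |X n Y| = 3
  p <- array(0, c(2, 2, 3)); p[1:4] <- 1
  g <- array(0, c(2, 2, 3)); g[2:7] <- 1
  om <- overlap_metrics(confusion(label_volume(p), label_volume(g)))
  expect_equal(om$dice, 2 * 3 / 10)
  expect_equal(om$jaccard, 3 / 7)
  expect_equal(om$precision, 3 / 4)
  expect_equal(om$recall, 3 / 6)

  eq <- random_mask_volume(c(4, 4, 4), 0.5)
  om2 <- overlap_metrics(confusion(eq, eq))
  expect_true(all(unlist(om2[c("dice", "jaccard", "precision", "recall")]) == 1))

  a <- label_volume(array(c(1, 0), c(2, 1, 1)))
  b <- label_volume(array(c(0, 1), c(2, 1, 1)))
  om3 <- overlap_metrics(confusion(a, b))
  expect_true(all(unlist(om3[c("dice", "jaccard", "precision", "recall")]) == 0))

  # both-empty convention: 1.0 with a flag
  z <- label_volume(array(0, c(2, 2, 2)))
  om4 <- overlap_metrics(confusion(z, z))
  expect_equal(om4$dice, 1)
  expect_true("dice" %in% attr(om4, "degenerate"))
})

test_that("dice identities with jaccard and precision/recall hold", {
  set.seed(41)
  for (case in 1:300) {
    p <- random_mask_volume(c(5, 5, 5), runif(1, 0.05, 0.95))
    g <- random_mask_volume(c(5, 5, 5), runif(1, 0.05, 0.95))
    om <- overlap_metrics(confusion(p, g))
    expect_equal(om$dice, 2 * om$jaccard / (1 + om$jaccard), tolerance = 1e-9)
    if (om$precision + om$recall > 0)
      expect_equal(om$dice,
                   2 * om$precision * om$recall / (om$precision + om$recall),
                   tolerance = 1e-9)
  }
})

test_that("AUC equals the pairwise rank oracle, with tie credit one half", {
  gt <- label_volume(array(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1), c(10, 1, 1)))
  sc <- volume(array(c(0.9, 0.8, 0.5, 0.5, 0.3, 0.9, 0.1, 0.2, 0.4, 0.6),
                     c(10, 1, 1)))
  expect_equal(roc_auc(sc, gt), auc_bruteforce(sc$data, gt$data))

  set.seed(51)
  for (case in 1:30) {
    gt <- random_mask_volume(c(5, 5, 5), runif(1, 0.2, 0.8))
    if (sum(gt$data) == 0 || sum(gt$data) == length(gt$data)) next
    sc <- volume(array(round(runif(125), 2), c(5, 5, 5)))  # rounded -> ties
    expect_equal(roc_auc(sc, gt), auc_bruteforce(sc$data, gt$data),
                 tolerance = 1e-12)
  }
  # perfect scores and all-ties
  g <- random_mask_volume(c(4, 4, 4), 0.4)
  expect_equal(roc_auc(volume(g$data), g), 1)
  expect_equal(roc_auc(volume(array(0.5, c(4, 4, 4))), g), 0.5)
  expect_error(roc_auc(volume(array(1, c(2, 2, 2))),
                       label_volume(array(1, c(2, 2, 2)))), "single class")
})

test_that("Hausdorff distance matches the pair-loop oracle and its axioms", {
  a <- array(0, c(8, 8, 8)); a[2, 3, 1] <- 1
  b <- array(0, c(8, 8, 8)); b[2, 3, 4] <- 1
  expect_equal(hausdorff_3d(label_volume(a), label_volume(b),
                            c(0.1, 0.1, 0.1)), 0.3)
  m <- random_mask_volume(c(6, 6, 6), 0.3)
  expect_equal(hausdorff_3d(m, m), 0)

  set.seed(61)
  for (case in 1:40) {
    x <- random_mask_volume(c(8, 8, 8), runif(1, 0.05, 0.5))
    y <- random_mask_volume(c(8, 8, 8), runif(1, 0.05, 0.5))
    if (sum(x$data) == 0 || sum(y$data) == 0) next
    sp <- runif(3, 0.05, 2)
    hd <- hausdorff_3d(x, y, sp)
    expect_equal(hd, hausdorff_bruteforce(x$data, y$data, sp),
                 tolerance = 1e-9)
    expect_equal(hd, hausdorff_3d(y, x, sp), tolerance = 1e-12)  # symmetry
  }
  expect_error(hausdorff_3d(label_volume(array(0, c(6, 6, 6))), m), "empty")
})

test_that("Hausdorff grows when one mask dilates away from the other", {
  base <- array(0, c(12, 4, 4)); base[2, 2, 2] <- 1
  prev <- 0
  for (reach in c(4, 7, 10)) {
    far <- base; far[reach, 2, 2] <- 1
    hd <- hausdorff_3d(label_volume(far), label_volume(base))
    expect_gt(hd, prev)
    prev <- hd
  }
})

test_that("metrics are invariant under identical axis permutation of both masks", {
  set.seed(71)
  p <- random_mask_volume(c(5, 6, 7), 0.3)
  g <- random_mask_volume(c(5, 6, 7), 0.3)
  om <- overlap_metrics(confusion(p, g))
  hd <- hausdorff_3d(p, g, c(1, 1, 1))
  perm <- c(3, 1, 2)
  pp <- label_volume(aperm(p$data, perm))
  gp <- label_volume(aperm(g$data, perm))
  omp <- overlap_metrics(confusion(pp, gp))
  expect_equal(unlist(om), unlist(omp))
  expect_equal(hausdorff_3d(pp, gp, c(1, 1, 1)), hd, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank p-values are exact", {
  # constant positive shift at n = 8: the most extreme table, p = 2/2^8
  a <- 1:8 / 10 + 0.5
  b <- 1:8 / 10
  expect_equal(wilcoxon_paired(a, b), 2 / 256)

  # n = 6 hand-made pairs against full enumeration
  x <- c(0.84, 0.91, 0.77, 0.62, 0.95, 0.88)
  y <- c(0.80, 0.93, 0.70, 0.65, 0.90, 0.82)
  expect_equal(wilcoxon_paired(x, y), wilcoxon_enumerate(x, y))

  # random cases with ties in |d| against enumeration
  set.seed(81)
  for (case in 1:20) {
    n <- sample(5:9, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) / 10
    aa <- runif(n); bb <- aa - d
    expect_equal(wilcoxon_paired(aa, bb), wilcoxon_enumerate(aa, bb),
                 tolerance = 1e-12)
  }

  # agreement with stats::wilcox.test when its exact path applies
  set.seed(91)
  x1 <- rnorm(12); x2 <- x1 + rnorm(12)
  expect_equal(wilcoxon_paired(x1, x2),
               stats::wilcox.test(x1, x2, paired = TRUE, exact = TRUE,
                                  correct = FALSE)$p.value)

  expect_error(wilcoxon_paired(1:8, 1:8), "degenerate")
  expect_error(wilcoxon_paired(c(1, 2, 3, 4), c(0, 1, 2, 3)), "fewer than 5")
})

test_that("evaluate_pair reports NA for undefined metrics instead of zeros", {
  g <- random_mask_volume(c(6, 6, 6), 0.3)
  empty <- label_volume(array(0, c(6, 6, 6)))
  row <- evaluate_pair(empty, g)
  expect_true(is.na(row$hausdorff_mm))
  expect_true(is.na(row$auc))
  expect_identical(row$recall, 0)
  full <- evaluate_pair(g, g, prob = volume(g$data))
  expect_equal(full$dice, 1)
  expect_equal(full$auc, 1)
  expect_equal(full$hausdorff_mm, 0)
})
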