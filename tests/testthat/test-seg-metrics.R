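test_that("confusion counts partition the image", {
  t10 <- label_mask(array(c(rep(1L, 10), rep(0L, 90)), c(10, 10)))
  expect_equal(confusion(t10, t10), c(tp = 10, fp = 0, fn = 0, tn = 90))
  full <- label_mask(array(1L, c(2, 4)))
  half <- label_mask(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), c(2, 4)))
  expect_equal(confusion(full, half), c(tp = 4, fp = 4, fn = 0, tn = 0))
  set.seed(11)
  for (i in 1:20) {
    a <- random_mask(c(7, 9)); b <- random_mask(c(7, 9))
    expect_equal(sum(confusion(a, b)), 63)
  }
  expect_error(confusion(full, label_mask(array(0L, c(3, 3)))),
               "shape mismatch")
})

test_that("segmentation scores match hand-derived values and conventions", {
  full <- label_mask(array(1L, c(2, 4)))
  half <- label_mask(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), c(2, 4)))
  s <- segmentation_scores(full, half)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 1)
  expect_equal(s$iou, 0.5)
  # TP=2, FP=2, FN=2 in an 8-pixel frame
  a <- label_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 4)))
  b <- label_mask(array(c(1, 1, 0, 0, 1, 1, 0, 0), c(2, 4)))
  s2 <- segmentation_scores(a, b)
  expect_equal(s2$iou, 1 / 3)
  expect_equal(s2$dice, 1 / 2)
  # identity on a nonempty mask: everything 1
  id <- segmentation_scores(a, a)
  expect_true(all(unlist(id) == 1))
  # two empty masks agree perfectly by convention
  e <- label_mask(array(0L, c(3, 3)))
  expect_true(all(unlist(segmentation_scores(e, e)) == 1))
  # empty prediction against nonempty truth: P convention gives 0
  s3 <- segmentation_scores(e, label_mask(array(c(1L, rep(0L, 8)), c(3, 3))))
  expect_equal(s3$precision, 0)
  expect_equal(s3$recall, 0)
})

test_that("metric identities hold over random mask pairs", {
  set.seed(23)
  for (i in 1:200) {
    a <- random_mask(c(6, 8), p = runif(1, 0.05, 0.95))
    b <- random_mask(c(6, 8), p = runif(1, 0.05, 0.95))
    sab <- segmentation_scores(a, b)
    sba <- segmentation_scores(b, a)
    expect_gte(sab$dice, sab$iou)                       # dice >= IoU
    expect_equal(sab$precision, sba$recall)             # P/R swap symmetry
    expect_equal(sab$iou, sba$iou)
    expect_equal(sab$dice, sba$dice)
    if (sab$iou > 0 && sab$iou < 1) expect_gt(sab$dice, sab$iou)
    # invariance under a shared spatial permutation
    p <- sample(48)
    ap <- label_mask(array(as.vector(a)[p], c(6, 8)))
    bp <- label_mask(array(as.vector(b)[p], c(6, 8)))
    expect_equal(segmentation_scores(ap, bp), sab)
  }
})

test_that("pairwise agreement reproduces per-slice macro averages", {
  a <- label_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 4)))
  b <- label_mask(array(c(1, 1, 0, 0, 1, 1, 0, 0), c(2, 4)))
  sets <- list(DR = list(s1 = a), D1 = list(s1 = b))
  tab <- pairwise_agreement(sets)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$miou, 1 / 3)
  # a set against itself is perfect
  self <- pairwise_agreement(list(A = list(s1 = a, s2 = b),
                                  B = list(s1 = a, s2 = b)))
  expect_true(all(unlist(self[, c("precision", "recall", "miou", "mpa")]) == 1))
  # three sources -> three unordered pairs; four -> six
  set.seed(5)
  mk <- function() list(s1 = random_mask(c(4, 4)), s2 = random_mask(c(4, 4)))
  expect_equal(nrow(pairwise_agreement(list(D1 = mk(), D2 = mk(), D3 = mk()))), 3L)
  expect_equal(nrow(pairwise_agreement(list(DR = mk(), D1 = mk(), D2 = mk(),
                                            D3 = mk()))), 6L)
  expect_error(pairwise_agreement(list(A = list(s1 = a), B = list(s2 = b))),
               "mismatched")
})

test_that("macro and micro pooling differ when slice sizes of the problem differ", {
  # slice 1 perfect, slice 2 half-precision: macro averages the two ratios,
  # micro pools the counts
  a1 <- label_mask(array(c(1, rep(0, 15)), c(4, 4)))
  a2 <- label_mask(array(c(rep(1, 8), rep(0, 8)), c(4, 4)))
  b2 <- label_mask(array(c(rep(1, 4), rep(0, 12)), c(4, 4)))
  sets <- list(X = list(s1 = a1, s2 = a2), Y = list(s1 = a1, s2 = b2))
  macro <- pairwise_agreement(sets, pooling = "macro")
  micro <- pairwise_agreement(sets, pooling = "micro")
  expect_equal(macro$precision, (1 + 0.5) / 2)
  expect_equal(micro$precision, 5 / 9)
})

test_that("mean grayscale follows the unweighted per-slice convention", {
  g <- voxel_grid(array(100, c(2, 3, 3)), spacing = 1)
  m <- label_mask(array(1L, c(2, 3, 3)))
  expect_equal(mean_grayscale(g, m)$mgv, 100)
  # slice A holds {0, 200}, slice B holds 50: per-slice (100, 50), seq 75
  arr <- array(0, c(2, 1, 2))
  arr[1, 1, ] <- c(0, 200)
  arr[2, 1, ] <- c(50, 50)
  g2 <- voxel_grid(arr, spacing = 1)
  m2 <- label_mask(array(1L, c(2, 1, 2)))
  res <- mean_grayscale(g2, m2)
  expect_equal(res$per_slice$mgv, c(100, 50))
  expect_equal(res$mgv, 75)
  # voxel weighting pools all masked voxels instead
  expect_equal(mean_grayscale(g2, m2, weighting = "voxel")$mgv, 75)
  # slices with empty masks are skipped, all-empty masks error
  m3 <- label_mask(array(c(1L, 0L, 1L, 0L), c(2, 1, 2)))  # slice 2 empty
  expect_equal(mean_grayscale(g2, m3)$mgv, 100)
  expect_error(mean_grayscale(g2, label_mask(array(0L, c(2, 1, 2)))),
               "no tunnel voxels")
})
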