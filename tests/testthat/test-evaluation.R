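test_that("iou handles identity, disjoint, partial overlap and degenerate boxes", {
  a <- c(0, 0, 2, 2)
  expect_identical(iou(a, a), 1)
  expect_identical(iou(a, c(5, 5, 7, 7)), 0)
  expect_equal(iou(a, c(1, 0, 3, 2)), 2 / 6)
  expect_identical(iou(c(1, 1, 1, 1), c(1, 1, 1, 1)), 0)  # both degenerate
})

test_that("iou is symmetric, translation-invariant and 1 only for equal boxes", {
  set.seed(81)
  boxes <- random_boxes(60)
  for (i in seq(1, 59, by = 2)) {
    a <- boxes[[i]]; b <- boxes[[i + 1]]
    expect_equal(iou(a, b), iou(b, a))
    t <- stats::runif(2, -30, 30)
    at <- as_bbox(as.numeric(a) + t[c(1, 2, 1, 2)])
    bt <- as_bbox(as.numeric(b) + t[c(1, 2, 1, 2)])
    expect_equal(iou(at, bt), iou(a, b), tolerance = 1e-10)
    if (box_width(a) > 0 && iou(a, b) == 1) expect_equal(a, b)
  }
})

test_that("iou matches a brute-force area count on integer grids", {
  set.seed(82)
  grid <- 40L
  for (rep in 1:500) {
    b <- random_boxes(2, grid_size = grid, integer_coords = TRUE)
    a <- b[[1]]; bb <- b[[2]]
    # unit-cell membership: cell (i, j) covers [i-1, i] x [j-1, j]
    covers <- function(box, i, j)
      i > box[[1]] & i <= box[[3]] & j > box[[2]] & j <= box[[4]]
    cells <- expand.grid(i = seq_len(grid), j = seq_len(grid))
    in_a <- covers(a, cells$i, cells$j)
    in_b <- covers(bb, cells$i, cells$j)
    union <- sum(in_a | in_b)
    want <- if (union == 0) 0 else sum(in_a & in_b) / union
    expect_equal(iou(a, bb), want)
  }
})

test_that("confusion metrics reproduce the reference classification columns", {
  actual <- c(1, 0, 1, 1, 1, 1, 0, 1, 1)
  predicted <- c(1, 1, 1, 0, 1, 1, 0, 1, 1)
  cm <- confusion_metrics(actual, predicted)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(6L, 1L, 1L, 1L))
  expect_equal(cm$accuracy, 7 / 9)
  expect_equal(cm$sensitivity, 6 / 7)
  expect_equal(cm$specificity, 1 / 2)
  expect_identical(confusion_metrics(actual, actual)$accuracy, 1)
  expect_identical(confusion_metrics(c(1, 0, 1), c(1, 1, 1))$specificity, 0)
  # undefined denominators surface as NA, never as 0/0
  expect_true(is.na(confusion_metrics(c(1, 1), c(1, 0))$specificity))
  expect_error(confusion_metrics(c(1, 0), c(1)), "equal length")
  expect_error(confusion_metrics(c(2, 0), c(1, 0)), "binary")
})

test_that("roc_curve: separation, symmetry, label-independence, tie grouping", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(perfect$auc, 1)
  rev <- roc_curve(-c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(rev$auc, 1 - perfect$auc)
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "single class")
  set.seed(83)
  scores <- stats::runif(10000)
  labels <- stats::rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.02)
  # curve endpoints
  pts <- perfect$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
})

test_that("AUC equals the normalized Mann-Whitney pairwise count", {
  set.seed(84)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    # coarse scores to force ties
    scores <- round(stats::runif(n), 1)
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, FUN = function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_curve(scores, labels)$auc,
                 mean(cmp), tolerance = 1e-12)
  }
})

test_that("pr_curve: perfect ranking, tie collapse, rank monotonicity", {
  expect_identical(pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$average_precision, 1)
  # all-identical scores collapse to one step at precision = prevalence
  flat <- pr_curve(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(flat$average_precision, 0.3)
  expect_identical(nrow(flat$points), 1L)
  expect_error(pr_curve(c(0.1, 0.2), c(0, 0)), "no positive")
  # improving one positive's rank never lowers AP
  set.seed(85)
  for (rep in 1:20) {
    n <- 30
    scores <- stats::runif(n)
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    ap0 <- pr_curve(scores, labels)$average_precision
    i <- sample(which(labels == 1), 1)
    better <- scores
    better[i] <- better[i] + stats::runif(1, 0, 1)
    expect_gte(pr_curve(better, labels)$average_precision, ap0 - 1e-12)
  }
})

test_that("evaluation reports assemble and serialise", {
  set.seed(86)
  actual <- c(1, 0, 1, 0, 1)
  pred <- c(1, 0, 0, 0, 1)
  scores <- c(0.8, 0.4, 0.55, 0.3, 0.9)
  gt <- random_boxes(5)
  pb <- lapply(gt, function(b) as_bbox(as.numeric(b) + c(1, 1, 1, 1)))
  rep <- evaluation_report(actual, pred, scores, pred_boxes = pb, gt_boxes = gt)
  expect_s3_class(rep, "eval_report")
  expect_identical(length(rep$iou), 5L)
  expect_true(rep$roc$auc >= 0 && rep$roc$auc <= 1)
  expect_true(rep$pr$average_precision >= 0 && rep$pr$average_precision <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path, curves_csv = TRUE)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$confusion$accuracy)
  expect_equal(back$auc, rep$roc$auc)
  roc_csv <- utils::read.csv(sub("\\.json$", "_roc.csv", path))
  expect_identical(names(roc_csv), c("fpr", "tpr"))
})
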