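grid10 <- grid_spec(2, 5, 30)
mask10 <- function(bits) burn_mask(matrix(as.integer(bits), 2, 5), grid10)

test_that("confusion counts match manual enumeration", {
  # identical masks: all positives are tp, rest tn
  set.seed(4)
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  g <- grid_spec(10, 10, 30)
  cc <- confusion(burn_mask(m, g), burn_mask(m, g))
  expect_equal(cc$tp, sum(m))
  expect_equal(cc$tn, 100 - sum(m))
  expect_equal(cc$fp + cc$fn, 0)
  # complement: no agreement at all
  cc2 <- confusion(burn_mask(1L - m, g), burn_mask(m, g))
  expect_equal(cc2$tp + cc2$tn, 0)
  # hand 10-pixel case
  cc3 <- confusion(mask10(c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)),
                   mask10(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(unlist(cc3[, c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(2, 1, 1, 6))
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "match")
})

test_that("metrics from counts reproduce hand arithmetic", {
  m <- metrics_from_counts(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$iou, 0.5)
  expect_equal(m$dice, 2 / 3)
  perfect <- metrics_from_counts(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(perfect) == 1))
  # degenerate conventions: no predicted/actual positives
  none <- metrics_from_counts(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(none$precision, 0)
  expect_equal(none$f1, 0)
  all_clear <- metrics_from_counts(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(all_clear$iou, 1)
  expect_equal(all_clear$dice, 1)
})

test_that("F1 is the harmonic mean and rounds to the published values", {
  expect_equal(f1_from_precision_recall(1, 1), 1)
  expect_equal(f1_from_precision_recall(0, 0.7), 0)
  expect_equal(round(f1_from_precision_recall(0.49, 0.87), 2), 0.63)
  expect_equal(round(f1_from_precision_recall(0.18, 0.81), 2), 0.29)
})

test_that("Dice follows the single-class identity 2.IoU/(1+IoU)", {
  expect_equal(dice_from_iou(0), 0)
  expect_equal(dice_from_iou(1), 1)
  expect_equal(dice_from_iou(0.60), 0.75)
  expect_equal(round(dice_from_iou(0.17), 2), 0.29)
  expect_equal(round(dice_from_iou(0.46), 2), 0.63)
})

test_that("pixel accounting reports counts and half-even percentages", {
  pred <- mask10(c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0))
  truth <- mask10(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  rep10 <- pixel_report(pred, truth)
  mis <- rep10[rep10$quantity == "misclassified", ]
  expect_equal(mis$pixels, 2)
  expect_equal(mis$percent, 20.00)
  perfect <- pixel_report(truth, truth)
  expect_equal(perfect$pixels[perfect$quantity == "misclassified"], 0)
  expect_equal(perfect$percent[perfect$quantity == "misclassified"], 0)
})

test_that("metric identities hold for random confusion tables", {
  set.seed(6)
  for (i in 1:50) {
    cc <- as.list(stats::setNames(rpois(4, 40), c("tp", "fp", "fn", "tn")))
    if (sum(unlist(cc)) == 0) next
    m <- metrics_from_counts(cc)
    expect_equal(m$f1, m$dice)
    expect_equal(m$dice, dice_from_iou(m$iou))
    total <- with(cc, tp + fp + fn + tn)
    expect_equal(m$accuracy, 1 - (cc$fp + cc$fn) / total)
    # swapping pred and truth swaps precision/recall, keeps overlap metrics
    sw <- metrics_from_counts(list(tp = cc$tp, fp = cc$fn, fn = cc$fp, tn = cc$tn))
    expect_equal(sw$precision, m$recall)
    expect_equal(sw$recall, m$precision)
    expect_equal(sw$accuracy, m$accuracy)
    expect_equal(sw$iou, m$iou)
    expect_equal(sw$dice, m$dice)
  }
})

test_that("reclassifying a false positive as true negative never hurts", {
  set.seed(7)
  for (i in 1:20) {
    cc <- as.list(stats::setNames(rpois(4, 20) + c(1, 1, 0, 0), c("tp", "fp", "fn", "tn")))
    m1 <- metrics_from_counts(cc)
    m2 <- metrics_from_counts(list(tp = cc$tp, fp = cc$fp - 1, fn = cc$fn,
                                   tn = cc$tn + 1))
    expect_gte(m2$precision, m1$precision)
    expect_gte(m2$accuracy, m1$accuracy)
    expect_gte(m2$iou, m1$iou)
    expect_gte(m2$dice, m1$dice)
  }
})

test_that("macro-averaged IoU/Dice differ from burnt-class values as expected", {
  cc <- list(tp = 10, fp = 5, fn = 5, tn = 80)
  b <- metrics_from_counts(cc)
  m <- metrics_from_counts(cc, average = "macro")
  iou_un <- 80 / 90
  expect_equal(m$iou, (0.5 + iou_un) / 2)
  expect_gt(m$iou, b$iou)
})

test_that("masked evaluation only counts valid pixels", {
  pred <- mask10(c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0))
  truth <- mask10(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  valid <- forest_mask(matrix(as.integer(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)), 2, 5),
                       grid10)
  cc <- confusion(pred, truth, valid)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 3)
  expect_equal(cc$tp, 2)
  expect_equal(cc$fn, 1)
})

test_that("rank-based AUC separates and degenerates correctly", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(roc_auc(matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2), t), 1)
  expect_equal(roc_auc(matrix(c(0.1, 0.2, 0.9, 0.8), 2, 2), t), 0)
  expect_true(is.na(roc_auc(matrix(0.5, 2, 2), matrix(1, 2, 2))))
})
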