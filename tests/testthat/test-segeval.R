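# hand-constructed fixtures shared across the metric tests
fix_dice <- function() {
  pred <- matrix(0L, 8, 8); ref <- matrix(0L, 8, 8)
  pred[1:2, 1:2] <- 1L           # 4 px
  ref[2:3, 1:2] <- 1L            # 4 px, 2 px overlap
  list(pred = pred, ref = ref)
}
fix_iou06 <- function() {
  pred <- matrix(0L, 10, 10); ref <- matrix(0L, 10, 10)
  pred[1:8, 1] <- 1L             # 8 px
  ref[3:10, 1] <- 1L             # 8 px, 6 px overlap -> IoU 6/10
  list(pred = pred, ref = ref)
}

test_that("Dice fixtures including the empty conventions", {
  f <- fix_dice()
  expect_equal(diceScore(f$pred, f$ref), 0.5)   # 2*2/8
  expect_equal(diceScore(f$ref, f$ref), 1.0)
  disj <- f$pred * 0L; disj[8, 8] <- 1L
  expect_equal(diceScore(f$pred, disj), 0.0)
  empty <- matrix(0L, 8, 8)
  expect_equal(diceScore(empty, empty), 1.0)
})

test_that("instance matching honours the IoU threshold", {
  f <- fix_iou06()
  m5 <- matchInstances(f$pred, f$ref, 0.5)
  expect_equal(nrow(m5$matches), 1L)
  expect_equal(m5$matches$iou, 0.6)
  expect_length(m5$fp_ids, 0L)
  m65 <- matchInstances(f$pred, f$ref, 0.65)
  expect_equal(nrow(m65$matches), 0L)
  expect_equal(m65$fp_ids, 1L)
  expect_equal(m65$fn_ids, 1L)
  expect_error(matchInstances(f$pred, matrix(0L, 3, 3)), "shapes differ")
})

test_that("hard-threshold matching is the unique IoU>0.5 assignment", {
  set.seed(51)
  for (i in 1:50) {
    mp <- random_mask_pair()
    mt <- matchInstances(mp$pred, mp$ref, 0.5)
    ot <- wellcal:::.overlap_table(mp$pred, mp$ref)
    want <- ot$overlaps[ot$overlaps$iou > 0.5, ]
    # every >0.5 pair is matched, and ids are used at most once
    expect_equal(nrow(mt$matches), nrow(want))
    expect_setequal(paste(mt$matches$pred_id, mt$matches$ref_id),
                    paste(want$pred_id, want$ref_id))
    expect_false(anyDuplicated(mt$matches$pred_id) > 0)
    expect_false(anyDuplicated(mt$matches$ref_id) > 0)
  }
})

test_that("PQ fixtures: single TP, added FP, perfect and empty masks", {
  f <- fix_iou06()
  expect_equal(panopticQuality(f$pred, f$ref)$pq, 0.6)  # 0.6/(1+0+0)
  pred_fp <- f$pred; pred_fp[1:2, 5] <- 2L
  expect_equal(panopticQuality(pred_fp, f$ref)$pq, 0.4) # 0.6/(1+0.5)
  perf <- matrix(0L, 6, 6); perf[1:2, 1:2] <- 1L; perf[5:6, 5:6] <- 2L
  q <- panopticQuality(perf, perf)
  expect_equal(q$pq, 1.0)
  expect_equal(q$sq * q$rq, q$pq)
  empty <- matrix(0L, 6, 6)
  expect_equal(panopticQuality(empty, empty)$pq, 1.0)
})

test_that("SoftPQ reduces to PQ at 0.5/0.5 and rewards partial overlaps", {
  f <- fix_iou06()
  expect_identical(softPQ(f$pred, f$ref, 0.5, 0.5),
                   panopticQuality(f$pred, f$ref)$pq)
  # one reference split into two predictions with sub-threshold IoUs
  ref <- matrix(0L, 10, 10); ref[1:10, 1:2] <- 1L
  pred <- matrix(0L, 10, 10)
  pred[1:5, 1:2] <- 1L; pred[6:10, 1:2] <- 2L   # IoU 0.5 each
  expect_equal(panopticQuality(pred, ref)$pq, 0)
  expect_gt(softPQ(pred, ref), panopticQuality(pred, ref)$pq)
  expect_identical(softPQ(pred, ref, 0.5, 0.5), panopticQuality(pred, ref)$pq)
  expect_equal(softPQ(ref, ref), 1.0)
})

test_that("mAP fixtures over the 0.50:0.05:0.95 sweep", {
  # single pair with IoU 0.55 clears only the 0.50 threshold
  pred <- matrix(0L, 25, 4); ref <- matrix(0L, 25, 4)
  pred[1:11, 1] <- 1L; ref[1:20, 1] <- 1L     # IoU 11/20
  expect_equal(meanAveragePrecision(pred, ref), 0.1)
  expect_equal(meanAveragePrecision(ref, ref), 1.0)
  empty <- matrix(0L, 25, 4)
  expect_equal(meanAveragePrecision(empty, ref), 0.0)
  expect_equal(meanAveragePrecision(empty, empty), 1.0)
})

test_that("scores are invariant under instance relabeling", {
  set.seed(52)
  mp <- random_mask_pair(n_obj = 4)
  relab <- mp$pred
  perm <- c(7L, 3L, 9L, 1L)
  for (k in 1:4) relab[mp$pred == k] <- perm[k]
  for (fn in list(diceScore, function(a, b) panopticQuality(a, b)$pq,
                  softPQ, meanAveragePrecision))
    expect_equal(fn(relab, mp$ref), fn(mp$pred, mp$ref))
})

test_that("set evaluation reports mean and population SD per metric", {
  perf <- matrix(0L, 6, 6); perf[2:4, 2:4] <- 1L
  f <- fix_iou06()
  sc <- evaluateSegSet(list(a = list(pred = perf, ref = perf),
                            b = list(pred = f$pred, ref = f$ref)))
  expect_equal(sc$dice, c(1.0, 0.75))
  s <- attr(sc, "summary")
  expect_equal(unname(s$mean["dice"]), 0.875)
  expect_equal(unname(s$sd["dice"]), 0.125)      # population SD
  expect_false(s$sd_degenerate)
  one <- evaluateSegSet(list(list(pred = perf, ref = perf)))
  expect_true(attr(one, "summary")$sd_degenerate)
  expect_equal(unname(attr(one, "summary")$sd["pq"]), 0)
})
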