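test_that("precision/recall/F1 follow their definitions and guard zero denominators", {
  m <- precision_recall_f1(tp = 9, fp = 1, fn = 1)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_error(precision_recall_f1(0, 0, 5), class = "mushgrade_undefined_metric")

  # stalk confusion: 335 of 336 correct, 1 missed into the cap class
  s <- precision_recall_f1(tp = 335, fp = 1, fn = 0)
  expect_equal(s$recall, 1)
  expect_equal(round_half_up(100 * s$precision, 2), 99.70)
  expect_equal(round_half_up(100 * 335 / 336, 2), 99.70)  # per-class rate
})

test_that("MIoU, MPA, PA agree with hand arithmetic and brute-force set IoU", {
  perfect <- diag(c(100, 50, 30))
  expect_equal(miou(perfect), 1)
  expect_equal(mpa(perfect), 1)
  expect_equal(pa(perfect), 1)

  p <- matrix(c(50, 0, 10, 40), 2, 2, byrow = TRUE)  # true rows, pred cols
  expect_equal(miou(p), mean(c(50 / 60, 40 / 50)))
  expect_equal(pa(p), 0.9)
  expect_equal(mpa(p), mean(c(1, 0.8)))

  # brute-force set IoU on constructed masks must match the formula route
  truth <- matrix(0L, 20, 20); truth[1:10, 1:10] <- 1L
  pred <- matrix(0L, 20, 20); pred[3:12, 1:10] <- 1L
  conf <- pixel_confusion(truth, pred, classes = 0:1)
  a <- which(truth == 1L); b <- which(pred == 1L)
  set_iou <- length(intersect(a, b)) / length(union(a, b))
  iou_fg <- conf[2, 2] / (sum(conf[2, ]) + sum(conf[, 2]) - conf[2, 2])
  expect_equal(iou_fg, set_iou)

  degenerate <- diag(c(10, 0, 5))
  expect_error(miou(degenerate), class = "mushgrade_undefined_metric")
  expect_error(mpa(degenerate), class = "mushgrade_undefined_metric")
})

test_that("MIoU never exceeds MPA and both sit in [0, 1] on random confusions", {
  set.seed(10)
  for (i in 1:200) {
    p <- matrix(rpois(9, 40) + 1, 3, 3)
    expect_lte(miou(p), mpa(p) + 1e-12)
    expect_gte(miou(p), 0); expect_lte(miou(p), 1)
    expect_gte(pa(p), 0); expect_lte(pa(p), 1)
  }
})

test_that("grading accuracy is the plain mean of per-grade correct rates", {
  acc <- grading_accuracy(c(50, 50, 50), c(49, 47, 46))
  expect_equal(as.numeric(acc), 94.67)
  expect_equal(attr(acc, "rates"), c(98, 94, 92))

  expect_equal(as.numeric(grading_accuracy(c(50, 50, 50), c(45, 42, 38))), 83.33)
  expect_equal(as.numeric(grading_accuracy(c(10, 10, 10), c(10, 10, 10))), 100)
  expect_error(grading_accuracy(c(50, 0, 50), c(10, 0, 10)))
})

test_that("rounding is half-up at two decimals", {
  expect_equal(round_half_up(94.665, 2), 94.67)   # base round() would give .66
  expect_equal(round_half_up(80.663333, 2), 80.66)
  expect_equal(round_half_up(-2.5, 0), -3)     # away from zero, not to even
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("mask evaluation pools pixels (micro) or averages images (macro)", {
  fx1 <- render_mushroom(fixture_spec(D1 = 60, H = 30, L = 40, D2 = 20,
                                      canvas = c(192, 192)))
  fx2 <- render_mushroom(fixture_spec(D1 = 80, H = 40, L = 60, D2 = 24,
                                      rotation_deg = 45, canvas = c(256, 256)))
  # predictions: ground truth for fx1, segmentation of a blurred render for fx2
  blur <- render_mushroom(fixture_spec(D1 = 80, H = 40, L = 60, D2 = 24,
                                       rotation_deg = 45, canvas = c(256, 256),
                                       blur_sigma = 1))
  pred2 <- reference_segment(blur$image)
  micro <- evaluate_masks(list(fx1$mask, fx2$mask), list(fx1$mask, pred2))
  macro <- evaluate_masks(list(fx1$mask, fx2$mask), list(fx1$mask, pred2),
                          macro = TRUE)
  expect_gt(micro$miou, 0.95)
  expect_gte(macro$miou, micro$miou - 0.05)
  expect_lte(micro$miou, micro$mpa)
})
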