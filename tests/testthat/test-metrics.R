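test_that("iou follows the half-open area arithmetic", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 5, 5)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 50 / 150)
  # against the independent implementation on random pairs
  set.seed(1)
  for (i in 1:50) {
    a <- c(runif(2, 0, 30), runif(2, 1, 20))
    b <- c(runif(2, 0, 30), runif(2, 1, 20))
    expect_equal(iou(a, b), ref_iou(a, b))
  }
})

test_that("matching identity and one-to-one behaviour", {
  gt <- data.frame(id = 1:3, image_id = 1L, x = c(0, 30, 60), y = 0,
                   w = 10, h = 10, category = c("DO", "E", "ES"))
  det <- gt
  det$confidence <- c(0.9, 0.8, 0.7)
  m <- match_detections(gt, det)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unmatched_detections, 0)
  expect_length(m$unmatched_ground_truths, 0)

  # two detections over one GT: higher confidence wins, other is FP
  det2 <- rbind(det[1, ], det[1, ])
  det2$id <- 1:2
  det2$confidence <- c(0.6, 0.95)
  m2 <- match_detections(gt[1, ], det2)
  expect_equal(m2$pairs$det_id, 2L)
  expect_equal(m2$unmatched_detections, 1L)

  # class-aware matching refuses cross-category pairs
  det3 <- det[1, ]
  det3$category <- "R"
  m3 <- match_detections(gt[1, ], det3)
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(nrow(match_detections(gt[1, ], det3,
                                     class_agnostic = TRUE)$pairs), 1)
})

test_that("matching is invariant to ground-truth order", {
  set.seed(5)
  gt <- random_boxes(5)
  det <- random_boxes(5, with_conf = TRUE)
  m1 <- match_detections(gt, det, 0.3, class_agnostic = TRUE)
  perm <- sample(nrow(gt))
  m2 <- match_detections(gt[perm, ], det, 0.3, class_agnostic = TRUE)
  expect_equal(nrow(m1$pairs), nrow(m2$pairs))
  expect_equal(sort(m1$pairs$gt_id), sort(m2$pairs$gt_id))
})

test_that("detection P/R/F1 reproduce the two-step detection row", {
  m <- detection_prf(6303, 81, 361)
  expect_equal(round(m$precision, 4), 0.9873)
  expect_equal(round(m$recall, 4), 0.9458)
  expect_equal(round(m$f1, 4), 0.9661)
  z <- detection_prf(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)
})

test_that("classification metrics match the one-vs-rest formulas", {
  cats <- c("A", "B", "C")
  true <- c("A", "A", "B", "B", "C", "C")
  pred <- true
  cm <- classification_metrics(true, pred, cats)
  expect_equal(cm$accuracy, 1)
  expect_true(all(cm$per_class$f1 == 1))

  pred2 <- c("A", "B", "B", "B", "C", "A")
  cm2 <- classification_metrics(true, pred2, cats)
  ref <- ref_class_metrics(true, pred2, cats)
  expect_equal(cm2$per_class$precision, unname(ref[, "precision"]))
  expect_equal(cm2$per_class$recall, unname(ref[, "recall"]))
  expect_equal(cm2$per_class$f1, unname(ref[, "f1"]))
  expect_equal(cm2$accuracy, mean(true == pred2))
  expect_error(classification_metrics(c("A", "Z"), c("A", "A"), cats),
               "outside")
})

test_that("macro is support-invariant; weighted equals macro when equal", {
  f1 <- c(0.9, 0.5, 0.7)
  expect_equal(macro_average(f1), mean(f1))
  expect_equal(weighted_average(f1, c(10, 10, 10)), mean(f1))
  expect_gt(weighted_average(f1, c(100, 1, 1)), macro_average(f1))
})

test_that("support-weighted recall equals accuracy on single-label data", {
  set.seed(9)
  cats <- c("A", "B", "C", "D")
  for (i in 1:20) {
    n <- sample(20:60, 1)
    true <- sample(cats, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, true, sample(cats, n, replace = TRUE))
    cm <- classification_metrics(true, pred, cats)
    expect_equal(cm$weighted$recall, cm$accuracy, tolerance = 1e-12)
  }
})

test_that("recall at IoU thresholds behaves across the tau range", {
  gt <- data.frame(id = 1:4, image_id = 1L, x = c(0, 20, 40, 60), y = 0,
                   w = 10, h = 10, category = "DO")
  det <- gt[1:3, ]
  det$confidence <- 1
  det$x <- det$x + 2  # IoU = 8/12 ~ 0.667
  r <- recall_at_iou(gt, det, tau = 0.75)
  expect_equal(r$recall, 0)
  r2 <- recall_at_iou(gt, det, tau = 0.5)
  expect_equal(r2$matched, 3)
  expect_equal(r2$recall, 0.75)
  expect_equal(recall_at_iou(gt, det[0, ], tau = 0.5)$recall, 0)
  # tau = 0 with any overlap recalls everything overlapped
  expect_equal(recall_at_iou(gt[1:3, ], det, tau = 1e-9)$recall, 1)
})

test_that("AP is 1 for perfect detections and 0 without true positives", {
  gt <- data.frame(id = 1:3, image_id = 1L, x = c(0, 30, 60), y = 0,
                   w = 10, h = 10, category = "DO")
  det <- gt
  det$confidence <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(gt, det, "DO", 0.5), 1)
  wrong <- det
  wrong$category <- "E"
  expect_equal(average_precision(gt, wrong, "DO", 0.5), 0)
  expect_true(is.na(average_precision(gt, det, "R", 0.5)))
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(13)
  gt <- random_boxes(5, cats = "A")
  det <- random_boxes(6, cats = "A", with_conf = TRUE)
  aps <- vapply(seq(0.3, 0.9, by = 0.1), function(t) {
    average_precision(gt, det, "A", t)
  }, 0)
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("map_range excludes categories absent from ground truth", {
  gt <- data.frame(id = 1:2, image_id = 1L, x = c(0, 30), y = 0,
                   w = 10, h = 10, category = c("DO", "E"))
  det <- gt
  det$confidence <- 1
  out <- map_range(gt, det)
  expect_setequal(out$excluded, c("ES", "G", "R"))
  expect_equal(out$map50, 1)
  expect_equal(out$map5095, 1)
})

test_that("the assembled report reproduces the aggregate-table layout", {
  img <- small_scene()
  det <- oracle_detector(img, oracle_noise(), seed = 1)
  det$category <- img$annotations$category
  rep_ <- build_report(img$annotations, det, compute_map = TRUE)
  expect_equal(rep_$detection$f1, 1)
  expect_equal(rep_$recall_at_tau$recall, 1)
  expect_equal(rep_$classification$accuracy, 1)
  expect_equal(rep_$ap$map5095, 1)

  td <- withr::local_tempdir()
  write_report(rep_, td)
  expect_true(file.exists(file.path(td, "report.json")))
  expect_true(file.exists(file.path(td, "per_class.csv")))
  js <- jsonlite::fromJSON(file.path(td, "report.json"))
  expect_equal(js$detection$f1, 1)
})

test_that("weighted aggregates reconstruct from per-class values", {
  f1 <- c(0.9841, 0.9355, 0.9499, 0.9370, 0.8789)
  support <- c(4421, 91, 1009, 646, 136)
  expect_equal(round(macro_average(f1), 4), 0.9371)
  expect_equal(round(weighted_average(f1, support), 4), 0.9708)
})
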