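det <- function(conf, x = 0, y = 0, w = 10, h = 10) {
  list(box = bbox(x, y, w, h), confidence = conf, label = "cyst")
}

test_that("greedy matching honours the one-match rule", {
  gt <- list(bbox(0, 0, 10, 10))
  m <- match_detections(list(det(0.9)), gt, iou_threshold = 1)
  expect_true(m$det_tp)
  expect_equal(m$det_match, 1L)
  expect_true(m$gt_matched)
  # two detections on one ground truth: only the more confident one matches
  m2 <- match_detections(list(det(0.7, x = 1), det(0.9)), gt, 0.5)
  expect_equal(m2$det_tp, c(TRUE, FALSE))
  expect_equal(m2$det_conf, c(0.9, 0.7))            # sorted internally
  # below-threshold overlap is a false positive
  m3 <- match_detections(list(det(0.9, x = 9)), gt, 0.5)
  expect_false(any(m3$det_tp))
  # detections cap
  m4 <- match_detections(list(det(0.9), det(0.8), det(0.7)), gt, 0.5,
                         max_detections = 2L)
  expect_length(m4$det_tp, 2)
})

test_that("greedy matching agrees with explicit confidence-order assignment", {
  # oracle: walk detections in confidence order, assign the unmatched ground
  # truth with max IoU when above threshold
  oracle_match <- function(dets, gts, thr) {
    ord <- order(-vapply(dets, `[[`, numeric(1), "confidence"))
    taken <- logical(length(gts))
    tp <- logical(length(dets))
    for (i in ord) {
      ious <- vapply(gts, function(g) iou(dets[[i]]$box, g), numeric(1))
      ious[taken] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= thr) { tp[i] <- TRUE; taken[j] <- TRUE }
    }
    tp[ord]
  }
  set.seed(62)
  for (rep in 1:60) {
    n_d <- sample(1:3, 1); n_g <- sample(1:2, 1)
    dets <- lapply(seq_len(n_d), function(i) {
      det(runif(1), x = sample(0:20, 1), y = sample(0:20, 1),
          w = sample(4:12, 1), h = sample(4:12, 1))
    })
    gts <- lapply(seq_len(n_g), function(i) {
      bbox(sample(0:20, 1), sample(0:20, 1), sample(4:12, 1), sample(4:12, 1))
    })
    thr <- sample(c(0.1, 0.3, 0.5), 1)
    m <- match_detections(dets, gts, thr)
    expect_equal(m$det_tp, oracle_match(dets, gts, thr))
  }
})

test_that("average precision reproduces hand-worked rankings", {
  expect_equal(average_precision(TRUE, 0.9, 1), 1)            # single clean TP
  expect_equal(average_precision(logical(0), numeric(0), 3), 0)
  expect_equal(average_precision(c(FALSE, FALSE), c(0.9, 0.8), 2), 0)
  # ranked [FP 0.9, TP 0.8] on one ground truth: precision 0.5 at recall 1
  expect_equal(average_precision(c(FALSE, TRUE), c(0.9, 0.8), 1), 0.5)
  expect_error(average_precision(TRUE, 0.9, 0), "ground truths")
})

test_that("average precision equals the all-cutoffs oracle on small instances", {
  set.seed(83)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    tp <- runif(n) < 0.5
    conf <- round(runif(n), 3)
    n_gt <- max(1, sum(tp) + sample(0:2, 1))
    expect_equal(average_precision(tp, conf, n_gt), oracle_ap(tp, conf, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("AP/AR over the IoU range count thresholds correctly", {
  # perfect detections: all metrics 1 at every threshold
  ds <- list(list(detections = list(det(0.9)),
                  ground_truths = list(bbox(0, 0, 10, 10))))
  m <- ap_ar_over_range(ds)
  expect_true(all(m$ap_at_iou == 1))
  expect_true(all(m$ar_at_iou == 1))
  expect_equal(m$mean_ap_range, 1)
  expect_equal(m$ar_range, 1)

  # detections with IoU exactly 0.6 against truth match at IoU thresholds
  # 0.50, 0.55, 0.60 only: AP and AR both 3/10 over the range
  truth <- bbox(0, 0, 10, 10)
  shifted <- det(0.9, x = 0, y = 0, w = 10, h = 10)
  shifted$box <- bbox(2.5, 0, 10, 10)   # intersection 75, union 125
  expect_equal(iou(shifted$box, truth), 0.6)
  ds2 <- list(list(detections = list(shifted), ground_truths = list(truth)))
  m2 <- ap_ar_over_range(ds2)
  expect_equal(m2$mean_ap_range, 3 / 10)
  expect_equal(m2$ar_range, 3 / 10)

  # empty detections
  m3 <- ap_ar_over_range(list(list(detections = list(),
                                   ground_truths = list(truth))))
  expect_equal(m3$mean_ap_range, 0)
  expect_equal(m3$ar_range, 0)
  expect_error(ap_ar_over_range(list(list(detections = list(),
                                          ground_truths = list()))),
               "no ground truths")
})

test_that("AP and AR are non-increasing in the IoU threshold", {
  set.seed(29)
  scenes <- lapply(1:15, function(i) generate_scene(tiny_scene_config(), 210 + i))
  ds <- lapply(seq_along(scenes), function(i) {
    list(detections = simulate_detections(scenes[[i]], noise_config(jitter_sd = 5),
                                          seed = 310 + i),
         ground_truths = lapply(scenes[[i]]$lesions, `[[`, "box"))
  })
  m <- ap_ar_over_range(ds)
  expect_true(all(diff(m$ap_at_iou) <= 1e-12))
  expect_true(all(diff(m$ar_at_iou) <= 1e-12))
})

test_that("image-level sweep reproduces a hand-counted 10-image set", {
  # 6 positives, 4 negatives; detector hits 5 positives at conf 0.8, misses
  # one, and false-alarms on one negative at conf 0.6
  gt_box <- bbox(0, 0, 10, 10)
  imgs <- c(
    lapply(1:5, function(i) list(detections = list(det(0.8)),
                                 ground_truths = list(gt_box))),
    list(list(detections = list(), ground_truths = list(gt_box))),
    list(list(detections = list(det(0.6)), ground_truths = list())),
    lapply(1:3, function(i) list(detections = list(), ground_truths = list()))
  )
  sw <- image_level_sweep(imgs, thresholds = 0.5)
  expect_equal(sw$sensitivity, 5 / 6)
  expect_equal(sw$specificity, 3 / 4)
  expect_equal(sw$accuracy, 8 / 10)
  expect_equal(sw$precision, 5 / 6)
  # above every confidence: sensitivity 0, specificity 1
  hi <- image_level_sweep(imgs, thresholds = 0.95)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  # positive-prediction count is non-increasing along the sweep
  sw2 <- image_level_sweep(imgs, thresholds = seq(0, 1, 0.25))
  expect_true(all(diff(sw2$n_predicted_positive) <= 0))
  # perfect detector below all TP confidences scores 1 everywhere
  perfect <- imgs[c(1:5, 8:10)]
  p <- image_level_sweep(perfect, thresholds = 0.5)
  expect_true(all(unlist(p[, c("accuracy", "precision", "sensitivity",
                               "specificity", "f1")]) == 1))
  expect_warning(image_level_sweep(imgs[1:5], 0.5), "no negative")
})

test_that("zero-noise simulator output yields perfect detection metrics", {
  scenes <- lapply(1:10, function(i) generate_scene(tiny_scene_config(), 150 + i))
  ds <- lapply(seq_along(scenes), function(i) {
    list(detections = simulate_detections(scenes[[i]],
                                          noise_config(jitter_sd = 0, fn_rate = 0,
                                                       fp_rate = 0),
                                          seed = 80 + i),
         ground_truths = lapply(scenes[[i]]$lesions, `[[`, "box"))
  })
  m <- ap_ar_over_range(ds)
  expect_equal(m$mean_ap_range, 1)
  expect_equal(m$ar_range, 1)
})
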