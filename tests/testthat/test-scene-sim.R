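test_that("scene generation is deterministic and respects class placement rules", {
  cfg <- tiny_scene_config()
  scenes <- lapply(1:20, function(i) generate_scene(cfg, seed = 100 + i))
  again <- lapply(1:20, function(i) generate_scene(cfg, seed = 100 + i))
  expect_identical(scenes, again)

  for (s in scenes) {
    expect_identical(dim(s$masks$maxilla), c(cfg$height, cfg$width))
    # dentition is the union of the present individual teeth
    union_teeth <- Reduce(`|`, s$masks[tooth_keys()])
    expect_identical(s$masks$dentition, union_teeth)
    for (lesion in s$lesions) {
      b <- lesion$box
      expect_gte(b$x, 0); expect_gte(b$y, 0)
      expect_lte(b$x + b$w, cfg$width); expect_lte(b$y + b$h, cfg$height)
      tooth_shares <- vapply(tooth_keys(),
                             function(k) overlap_share(b, s$masks[[k]]),
                             numeric(1))
      if (lesion$class == "odontogenic") {
        expect_gt(max(tooth_shares), 0)
      } else {
        expect_equal(max(tooth_shares), 0)
      }
    }
  }
})

test_that("absent teeth have empty masks and zero-lesion scenes are supported", {
  cfg <- tiny_scene_config(n_lesions = 0L, missing_rate = 0.5)
  s <- generate_scene(cfg, seed = 9)
  expect_length(s$lesions, 0)
  absent <- setdiff(as.integer(sub("tooth_", "", tooth_keys())),
                    s$present_teeth)
  expect_gt(length(absent), 0)
  for (fdi in absent) {
    expect_equal(sum(s$masks[[paste0("tooth_", fdi)]]), 0)
  }
})

test_that("zero-noise detections reproduce ground truth; fn_rate 1 drops all", {
  s <- generate_scene(tiny_scene_config(), seed = 31)
  d0 <- simulate_detections(s, noise_config(jitter_sd = 0, fn_rate = 0,
                                            fp_rate = 0), seed = 5)
  expect_length(d0, length(s$lesions))
  for (i in seq_along(d0)) {
    expect_equal(iou(d0[[i]]$box, s$lesions[[i]]$box), 1)
    expect_gte(d0[[i]]$confidence, 0)
    expect_lte(d0[[i]]$confidence, 1)
  }
  expect_length(simulate_detections(s, noise_config(fn_rate = 1, fp_rate = 0),
                                    seed = 5), 0)
  # output sorted by descending confidence
  dn <- simulate_detections(generate_scene(tiny_scene_config(n_lesions = 3L), 77),
                            noise_config(fp_rate = 1), seed = 8)
  conf <- vapply(dn, `[[`, numeric(1), "confidence")
  expect_true(all(diff(conf) <= 0))
})

test_that("jittered detections match the pixel-IoU oracle and its frozen band", {
  # 100x80 ground-truth box, corner jitter sd 4, replicated; the closed-form
  # IoU must agree with brute-force pixel rasterisation on every replicate,
  # and the replicate mean must sit in the band the oracle establishes
  truth <- bbox(160, 60, 100, 80)
  s <- structure(list(scene_id = "jit", width = 440, height = 220,
                      lesions = list(list(box = truth, class = "odontogenic"))),
                 class = "scene")
  nz <- noise_config(jitter_sd = 4, fn_rate = 0, fp_rate = 0)
  closed <- oracle <- numeric(300)
  for (i in 1:300) {
    d <- simulate_detections(s, nz, seed = i)[[1]]
    closed[i] <- iou(d$box, truth)
    oracle[i] <- pixel_iou(d$box, truth)
  }
  expect_equal(closed, oracle, tolerance = 1e-12)
  expect_equal(mean(closed), mean(oracle), tolerance = 1e-12)
  # frozen band from a 1000-replicate oracle run (mean 0.868, sd 0.047)
  expect_gt(mean(closed), 0.84)
  expect_lt(mean(closed), 0.90)
})

test_that("degrade_mask hits its Dice target and is deterministic", {
  sq <- matrix(FALSE, 60, 60); sq[11:50, 11:50] <- TRUE
  expect_identical(degrade_mask(sq, 1.0, seed = 3), sq)
  d8 <- degrade_mask(sq, 0.8, seed = 3)
  expect_gte(dice(d8, sq), 0.75)
  expect_lte(dice(d8, sq), 0.85)
  expect_identical(degrade_mask(sq, 0.8, seed = 3), d8)

  # maxilla-shaped mask down to the hardest published segmentation level
  s <- generate_scene(tiny_scene_config(), seed = 12)
  dm <- degrade_mask(s$masks$maxilla, 0.465, seed = 4)
  expect_gte(dice(dm, s$masks$maxilla), 0.415)
  expect_lte(dice(dm, s$masks$maxilla), 0.515)

  expect_error(degrade_mask(matrix(FALSE, 5, 5), 0.8), "empty")
  expect_error(degrade_mask(sq, 0.1), "target_dice")
})

test_that("degrade_mask_set hits every per-structure target", {
  s <- generate_scene(tiny_scene_config(), seed = 21)
  nz <- noise_config()
  deg <- degrade_mask_set(s, nz, seed = 6)
  for (key in c("maxilla", "mandible", "mandibular_canal", "maxillary_sinus",
                "dentition")) {
    expect_equal(dice(deg[[key]], s$masks[[key]]),
                 nz$dice_targets[[key]], tolerance = 0.05)
  }
  present <- paste0("tooth_", s$present_teeth)
  tooth_dice <- vapply(present, function(k) dice(deg[[k]], s$masks[[k]]),
                       numeric(1))
  expect_true(all(abs(tooth_dice - nz$dice_targets[["tooth"]]) <= 0.05))
})

test_that("annotation files round-trip and malformed lines are rejected", {
  s <- generate_scene(tiny_scene_config(), seed = 55)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_file(s, path)
  rec <- read_annotation_file(path)
  expect_equal(nrow(rec), length(s$lesions))
  b <- s$lesions[[1]]$box
  expect_equal(rec$x[1], b$x); expect_equal(rec$y[1], b$y)
  expect_equal(rec$w[1], b$w); expect_equal(rec$h[1], b$h)
  expect_equal(rec$age[1], s$demographics$age)
  expect_equal(rec$sex[1], s$demographics$sex)
  expect_equal(rec$diagnosis[1], s$lesions[[1]]$class)

  s0 <- generate_scene(tiny_scene_config(n_lesions = 0L), seed = 56)
  write_annotation_file(s0, path)
  expect_equal(nrow(read_annotation_file(path)), 0)

  writeLines(c("scene_id\tx\ty\tw\th\tage\tsex\tdiagnosis",
               "s1\t10\t20\t0\t40\t50\tF\todontogenic"), path)
  expect_error(read_annotation_file(path), "line 2.*positive")
  writeLines(c("scene_id\tx\ty\tw\th\tage\tsex\tdiagnosis",
               "s1\t10\t20\t30"), path)
  expect_error(read_annotation_file(path), "line 2.*8 fields")
  writeLines("not a header", path)
  expect_error(read_annotation_file(path), "line 1")
})

test_that("detection-count attrition is monotone in the confidence threshold", {
  scenes <- lapply(1:30, function(i) generate_scene(tiny_scene_config(), 300 + i))
  dets <- lapply(seq_along(scenes), function(i) {
    simulate_detections(scenes[[i]], noise_config(), seed = 400 + i)
  })
  thresholds <- seq(0, 1, by = 0.1)
  n_retained <- vapply(thresholds, function(t) {
    sum(vapply(dets, function(d) !is.null(select_top_box(d, t)), logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_retained) <= 0))
})

test_that("mask PNGs and COCO JSON round-trip", {
  s <- generate_scene(tiny_scene_config(), seed = 61)
  dir <- withr::local_tempdir()
  write_mask_pngs(s, dir, keys = c("mandible", "tooth_31"))
  m <- read_mask_png(file.path(dir, paste0(s$scene_id, "__mandible.png")))
  expect_identical(m, s$masks$mandible)

  path <- file.path(dir, "gt.json")
  write_coco_json(list(s), path)
  gt <- read_coco_json(path)
  expect_equal(gt$images$width[1], s$width)
  expect_equal(nrow(gt$annotations), length(s$lesions))
  expect_equal(gt$annotations$x[1], s$lesions[[1]]$box$x)

  dets <- simulate_detections(s, noise_config(fp_rate = 1), seed = 3)
  write_coco_json(list(s), path, detections = list(dets))
  dd <- read_coco_json(path)
  expect_equal(nrow(dd$annotations), length(dets))
  expect_equal(dd$annotations$score[1], dets[[1]]$confidence)
})
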