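#' Canonical anatomical structure keys
#'
#' The fixed, canonical ordering of structure masks and overlap features:
#' five region structures (maxilla, mandible, mandibular canal, maxillary
#' sinus, dentition — canal and sinus masks hold the union of the left and
#' right structures) followed by the 32 permanent tooth positions in FDI
#' order (quadrants 1-4, positions 1-8). Classifier feature vectors always
#' use this order, so absent teeth simply contribute zeros.
#'
#' @return Character vector of 37 structure keys.
#' @export
structure_keys <- function() {
  c("maxilla", "mandible", "mandibular_canal", "maxillary_sinus", "dentition",
    tooth_keys())
}

#' @rdname structure_keys
#' @export
tooth_keys <- function() {
  paste0("tooth_", as.vector(outer(1:8, c(10L, 20L, 30L, 40L), `+`)))
}

#' Scene configuration
#'
#' Parameters of the synthetic jaw-scene generator. The generator draws a
#' stylised 2-D panoramic projection: two jaw bands (maxilla above,
#' mandible below), 32 tooth slots along the arches, two mandibular-canal
#' bands, two elliptical maxillary sinuses. Only the spatial-overlap
#' topology of these structures matters to the downstream classifier, not
#' radiographic realism.
#'
#' Lesion placement encodes the clinical class definitions: an odontogenic
#' cyst is centred near the apex of a uniformly chosen present tooth and
#' must cover at least `min_tooth_share` of its own area with that tooth's
#' mask; a non-odontogenic cyst is rejection-sampled inside jaw bone or
#' sinus with zero overlap with every tooth mask.
#'
#' @param width,height image size in pixels.
#' @param n_lesions number of lesions (0 gives a negative, cyst-free scene).
#' @param class_mix named probabilities for lesion classes
#'   (`odontogenic`, `non_odontogenic`); a scene's lesions are drawn i.i.d.
#' @param missing_rate probability that each tooth position is absent.
#' @param lesion_size integer range (min, max) of lesion box side lengths.
#' @param min_tooth_share minimum fraction of an odontogenic lesion box
#'   covered by its anchor tooth.
#' @param max_attempts rejection-sampling budget per lesion.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 440L, height = 220L,
                         n_lesions = 1L,
                         class_mix = c(odontogenic = 0.72,
                                       non_odontogenic = 0.28),
                         missing_rate = 0.1,
                         lesion_size = c(30L, 60L),
                         min_tooth_share = 0.10,
                         max_attempts = 200L) {
  stopifnot(width >= 200, height >= 120, n_lesions >= 0,
            missing_rate >= 0, missing_rate < 1,
            lesion_size[1] >= 10, lesion_size[2] >= lesion_size[1],
            min_tooth_share > 0, min_tooth_share < 1)
  class_mix <- class_mix / sum(class_mix)
  if (!setequal(names(class_mix), cyst_classes())) {
    stop("class_mix must be named over: ", paste(cyst_classes(), collapse = ", "))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_lesions = as.integer(n_lesions), class_mix = class_mix,
                 missing_rate = missing_rate,
                 lesion_size = as.integer(lesion_size),
                 min_tooth_share = min_tooth_share,
                 max_attempts = as.integer(max_attempts)),
            class = "scene_config")
}

#' The two cyst classes
#'
#' Odontogenic cysts show clear radiological signs of an underlying dental
#' pathology (e.g. a tooth apex protruding into the radiolucency);
#' non-odontogenic cysts show no such signs in their proximity.
#'
#' @return `c("odontogenic", "non_odontogenic")` (odontogenic first; this
#'   order is also the classifier's class order and tie-break winner).
#' @export
cyst_classes <- function() c("odontogenic", "non_odontogenic")

# ---- anatomy layout ---------------------------------------------------------
# All layout constants are expressed as fractions of the image so the cartoon
# scales with (width, height). Rows/columns are 1-based matrix indices.

scene_layout <- function(width, height) {
  fx <- function(f) as.integer(round(f * width))
  fy <- function(f) as.integer(round(f * height))
  tw <- max(4L, fx(0.05))                # tooth slot width (16 slots per arch)
  mid <- fx(0.5)
  list(
    width = width, height = height, mid = mid, tooth_w = tw,
    maxilla_rows  = c(fy(0.11), fy(0.43)),
    mandible_rows = c(fy(0.64), fy(0.95)),
    jaw_cols      = c(fx(0.05), fx(0.95)),
    upper_tooth_rows = c(fy(0.32), fy(0.57)),
    lower_tooth_rows = c(fy(0.57), fy(0.82)),
    canal_rows    = c(fy(0.84), fy(0.90)),
    canal_cols_l  = c(fx(0.09), fx(0.41)),
    canal_cols_r  = c(fx(0.59), fx(0.91)),
    sinus_center  = list(l = c(fx(0.27), fy(0.23)), r = c(fx(0.73), fy(0.23))),
    sinus_radii   = c(fx(0.125), fy(0.09))
  )
}

blank_mask <- function(width, height) {
  matrix(FALSE, nrow = height, ncol = width)
}

fill_rect <- function(mask, rows, cols) {
  rows <- rows[rows >= 1 & rows <= nrow(mask)]
  cols <- cols[cols >= 1 & cols <= ncol(mask)]
  mask[rows, cols] <- TRUE
  mask
}

fill_ellipse <- function(mask, cx, cy, rx, ry) {
  # cx, cy in 0-based pixel coordinates; pixel centres at index - 0.5
  xs <- (seq_len(ncol(mask)) - 0.5 - cx) / rx
  ys <- (seq_len(nrow(mask)) - 0.5 - cy) / ry
  mask | (outer(ys^2, xs^2, `+`) <= 1)
}

# Column range of a tooth slot. FDI quadrants on a panoramic image:
# quadrant 1 (upper right) appears on the image left of the midline,
# quadrant 2 (upper left) on the image right; 4 and 3 mirror them below.
tooth_slot_cols <- function(layout, quadrant, pos) {
  tw <- layout$tooth_w
  inset <- max(1L, tw %/% 8L)            # small gap between neighbours
  if (quadrant %in% c(1L, 4L)) {         # image-left, counted from midline out
    x1 <- layout$mid - pos * tw
  } else {                               # image-right
    x1 <- layout$mid + (pos - 1L) * tw
  }
  seq.int(x1 + 1L + inset, x1 + tw - inset)
}

tooth_mask <- function(layout, fdi) {
  quadrant <- fdi %/% 10L
  pos <- fdi %% 10L
  cols <- tooth_slot_cols(layout, quadrant, pos)
  rows <- if (quadrant <= 2L) {
    seq.int(layout$upper_tooth_rows[1] + 1L, layout$upper_tooth_rows[2])
  } else {
    seq.int(layout$lower_tooth_rows[1] + 1L, layout$lower_tooth_rows[2])
  }
  m <- blank_mask(layout$width, layout$height)
  # taper the root third to a narrower trapezoid (roots are thinner than crowns)
  root_rows <- if (quadrant <= 2L) {
    rows[seq_len(ceiling(length(rows) / 3))]
  } else {
    rows[seq.int(length(rows) - ceiling(length(rows) / 3) + 1L, length(rows))]
  }
  crown_rows <- setdiff(rows, root_rows)
  narrow <- cols[-c(1L, length(cols))]
  m <- fill_rect(m, crown_rows, cols)
  fill_rect(m, root_rows, narrow)
}

# Apex anchor point (0-based x, y) of a tooth: root tip end of the slot.
tooth_apex <- function(layout, fdi) {
  quadrant <- fdi %/% 10L
  cols <- tooth_slot_cols(layout, quadrant, fdi %% 10L)
  cx <- mean(cols) - 0.5
  cy <- if (quadrant <= 2L) layout$upper_tooth_rows[1] + 2 else
    layout$lower_tooth_rows[2] - 2
  c(cx, cy)
}

build_mask_set <- function(layout, present_teeth) {
  W <- layout$width; H <- layout$height
  masks <- list()
  masks$maxilla <- fill_rect(blank_mask(W, H),
                             seq.int(layout$maxilla_rows[1] + 1L, layout$maxilla_rows[2]),
                             seq.int(layout$jaw_cols[1] + 1L, layout$jaw_cols[2]))
  masks$mandible <- fill_rect(blank_mask(W, H),
                              seq.int(layout$mandible_rows[1] + 1L, layout$mandible_rows[2]),
                              seq.int(layout$jaw_cols[1] + 1L, layout$jaw_cols[2]))
  canal <- blank_mask(W, H)
  canal_rows <- seq.int(layout$canal_rows[1] + 1L, layout$canal_rows[2])
  canal <- fill_rect(canal, canal_rows,
                     seq.int(layout$canal_cols_l[1] + 1L, layout$canal_cols_l[2]))
  canal <- fill_rect(canal, canal_rows,
                     seq.int(layout$canal_cols_r[1] + 1L, layout$canal_cols_r[2]))
  masks$mandibular_canal <- canal
  sinus <- blank_mask(W, H)
  sinus <- fill_ellipse(sinus, layout$sinus_center$l[1], layout$sinus_center$l[2],
                        layout$sinus_radii[1], layout$sinus_radii[2])
  sinus <- fill_ellipse(sinus, layout$sinus_center$r[1], layout$sinus_center$r[2],
                        layout$sinus_radii[1], layout$sinus_radii[2])
  masks$maxillary_sinus <- sinus
  dentition <- blank_mask(W, H)
  for (key in tooth_keys()) {
    fdi <- as.integer(sub("tooth_", "", key))
    m <- if (fdi %in% present_teeth) tooth_mask(layout, fdi) else blank_mask(W, H)
    masks[[key]] <- m
    dentition <- dentition | m
  }
  masks$dentition <- dentition
  masks[structure_keys()]
}

# ---- lesion placement -------------------------------------------------------

sample_box_size <- function(config) {
  c(w = sample(seq.int(config$lesion_size[1], config$lesion_size[2]), 1L),
    h = sample(seq.int(config$lesion_size[1], config$lesion_size[2]), 1L))
}

clamp_box <- function(x, y, w, h, width, height) {
  x <- max(0L, min(as.integer(round(x)), width - w))
  y <- max(0L, min(as.integer(round(y)), height - h))
  bbox(x, y, w, h)
}

place_odontogenic <- function(config, layout, masks, present_teeth, scene_id) {
  for (i in seq_len(config$max_attempts)) {
    fdi <- present_teeth[sample.int(length(present_teeth), 1L)]
    apex <- tooth_apex(layout, fdi)
    sz <- sample_box_size(config)
    jit <- stats::runif(2, -layout$tooth_w / 3, layout$tooth_w / 3)
    box <- clamp_box(apex[1] - sz["w"] / 2 + jit[1], apex[2] - sz["h"] / 2 + jit[2],
                     sz["w"], sz["h"], config$width, config$height)
    key <- paste0("tooth_", fdi)
    if (overlap_share(box, masks[[key]]) >= config$min_tooth_share) return(box)
  }
  stop("generate_scene: could not place odontogenic lesion in scene '",
       scene_id, "' within ", config$max_attempts, " attempts")
}

place_non_odontogenic <- function(config, layout, masks, scene_id) {
  dent <- masks$dentition
  for (i in seq_len(config$max_attempts)) {
    sz <- sample_box_size(config)
    if (stats::runif(1) < 0.5) {
      # sinus / upper jaw zone, above the upper tooth apices
      max_h <- layout$upper_tooth_rows[1] - layout$maxilla_rows[1] - 2L
      h <- min(sz["h"], max_h)
      cy <- stats::runif(1, layout$maxilla_rows[1] + h / 2,
                         layout$upper_tooth_rows[1] - h / 2 - 1)
    } else {
      # deep mandible zone, below the lower tooth apices
      max_h <- layout$mandible_rows[2] - layout$lower_tooth_rows[2] - 2L
      h <- min(sz["h"], max_h)
      cy <- stats::runif(1, layout$lower_tooth_rows[2] + h / 2 + 1,
                         layout$mandible_rows[2] - h / 2)
    }
    if (h < 8) next
    cx <- stats::runif(1, layout$jaw_cols[1] + sz["w"] / 2,
                       layout$jaw_cols[2] - sz["w"] / 2)
    box <- clamp_box(cx - sz["w"] / 2, cy - h / 2, sz["w"], as.integer(h),
                     config$width, config$height)
    if (overlap_share(box, dent) == 0) return(box)
  }
  stop("generate_scene: could not place non-odontogenic lesion in scene '",
       scene_id, "' within ", config$max_attempts, " attempts")
}

#' Generate a synthetic jaw scene
#'
#' Draws a complete ground-truth scene: the anatomical mask set, zero or
#' more cyst lesions with class labels, and demographics used only by the
#' plain-text annotation format. Deterministic: the same `(config, seed)`
#' always yields a bit-identical scene.
#'
#' @param config a [scene_config()].
#' @param seed integer RNG seed.
#' @param scene_id identifier recorded in annotation and mask files.
#' @return A list of class `scene` with fields `scene_id`, `width`,
#'   `height`, `masks` (named list of logical matrices over
#'   [structure_keys()]), `lesions` (list of `list(box, class)`),
#'   `present_teeth` (FDI integers), and `demographics` (`age`, `sex`).
#' @export
generate_scene <- function(config = scene_config(), seed = 1L,
                           scene_id = sprintf("scene_%06d", seed)) {
  with_seed(seed, {
    layout <- scene_layout(config$width, config$height)
    all_fdi <- as.integer(sub("tooth_", "", tooth_keys()))
    present <- all_fdi[stats::runif(32) >= config$missing_rate]
    if (length(present) == 0) present <- sample(all_fdi, 1L)
    masks <- build_mask_set(layout, present)
    lesions <- list()
    if (config$n_lesions > 0) {
      classes <- sample(names(config$class_mix), config$n_lesions,
                        replace = TRUE, prob = config$class_mix)
      for (cl in classes) {
        box <- if (cl == "odontogenic") {
          place_odontogenic(config, layout, masks, present, scene_id)
        } else {
          place_non_odontogenic(config, layout, masks, scene_id)
        }
        lesions[[length(lesions) + 1L]] <- list(box = box, class = cl)
      }
    }
    age <- max(18L, min(90L, as.integer(round(stats::rnorm(1, 53.5, 13)))))
    sex <- sample(c("F", "M"), 1L, prob = c(0.41, 0.59))
    structure(list(scene_id = scene_id, width = config$width,
                   height = config$height, masks = masks, lesions = lesions,
                   present_teeth = present,
                   demographics = list(age = age, sex = sex)),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s %dx%d, %d lesion(s), %d teeth present>\n",
              x$scene_id, x$width, x$height, length(x$lesions),
              length(x$present_teeth)))
  invisible(x)
}

#' Detector / segmenter noise configuration
#'
#' Describes the imperfections of the simulated object detector and
#' segmentation models. A ground-truth lesion is dropped with probability
#' `fn_rate`; otherwise its corners are jittered by Gaussian noise with
#' standard deviation `jitter_sd` pixels (clipped to the image) and it is
#' emitted with a confidence drawn from `Beta(conf_tp[1], conf_tp[2])`.
#' False-positive boxes are added with per-image rate `fp_rate` (at most
#' `fp_max` per image) and confidence from `Beta(conf_fp[1], conf_fp[2])`.
#' The default confidence distributions make true positives stochastically
#' more confident but overlap substantially, as they do for a detector of
#' moderate precision, so a false positive occasionally outranks the true
#' detection. False-positive boxes mimic what such a detector confuses
#' with cysts — radiolucency look-alikes: half are centred near a random
#' tooth apex (follicles, periapical shadows), half fall anywhere in the
#' jaw bands (foramina, sinus recesses).
#' `dice_targets` gives the target Dice score per structure key that
#' [degrade_mask()] will impose on the "predicted" segmentation masks; the
#' defaults are the Dice levels of published dental segmentation models
#' (dentition 0.945, mandibular canal 0.794, maxillary sinus 0.644,
#' maxilla 0.465, mandible 0.978, individual tooth 0.870).
#'
#' @param jitter_sd corner jitter SD in pixels.
#' @param fn_rate,fp_rate false-negative / false-positive rates in `[0, 1]`.
#' @param fp_max maximum false positives per image.
#' @param conf_tp,conf_fp Beta shape pairs for confidence scores.
#' @param dice_targets named vector of target Dice values in `(0.2, 1]`;
#'   names are structure keys, with `tooth` applying to all 32 teeth.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(jitter_sd = 3, fn_rate = 0.1, fp_rate = 0.1,
                         fp_max = 2L,
                         conf_tp = c(5, 2), conf_fp = c(2, 4),
                         dice_targets = c(maxilla = 0.465, mandible = 0.978,
                                          mandibular_canal = 0.794,
                                          maxillary_sinus = 0.644,
                                          dentition = 0.945, tooth = 0.870)) {
  stopifnot(jitter_sd >= 0, fn_rate >= 0, fn_rate <= 1,
            fp_rate >= 0, fp_rate <= 1, fp_max >= 0,
            all(conf_tp > 0), all(conf_fp > 0),
            all(dice_targets > 0.2), all(dice_targets <= 1))
  structure(list(jitter_sd = jitter_sd, fn_rate = fn_rate, fp_rate = fp_rate,
                 fp_max = as.integer(fp_max), conf_tp = conf_tp,
                 conf_fp = conf_fp, dice_targets = dice_targets),
            class = "noise_config")
}

#' Simulate imperfect detector output for a scene
#'
#' Emulates the output contract of a lesion detector: each ground-truth
#' lesion is either missed (probability `fn_rate`) or emitted with jittered
#' integer corners and a confidence score; spurious boxes are added at rate
#' `fp_rate`. The result is sorted by descending confidence.
#'
#' @param scene a [generate_scene()] result.
#' @param noise a [noise_config()].
#' @param seed integer RNG seed.
#' @return A list of detections, each `list(box, confidence, label)` with
#'   `label = "cyst"`.
#' @export
simulate_detections <- function(scene, noise = noise_config(), seed = 1L) {
  with_seed(seed, {
    dets <- list()
    for (lesion in scene$lesions) {
      if (stats::runif(1) < noise$fn_rate) next
      b <- lesion$box
      d <- stats::rnorm(4, 0, noise$jitter_sd)
      x0 <- b$x + d[1]; y0 <- b$y + d[2]
      x1 <- b$x + b$w + d[3]; y1 <- b$y + b$h + d[4]
      x0 <- max(0, min(round(x0), scene$width - 1))
      y0 <- max(0, min(round(y0), scene$height - 1))
      x1 <- max(x0 + 1, min(round(x1), scene$width))
      y1 <- max(y0 + 1, min(round(y1), scene$height))
      conf <- stats::rbeta(1, noise$conf_tp[1], noise$conf_tp[2])
      dets[[length(dets) + 1L]] <- list(box = bbox(x0, y0, x1 - x0, y1 - y0),
                                        confidence = conf, label = "cyst")
    }
    n_fp <- if (noise$fp_max > 0) stats::rbinom(1, noise$fp_max, noise$fp_rate) else 0L
    if (n_fp > 0) {
      layout <- scene_layout(scene$width, scene$height)
      all_fdi <- as.integer(sub("tooth_", "", tooth_keys()))
      for (i in seq_len(n_fp)) {
        w <- sample(15:60, 1L); h <- sample(15:60, 1L)
        if (stats::runif(1) < 0.5) {
          # radiolucency mimic near a tooth apex
          apex <- tooth_apex(layout, all_fdi[sample.int(32L, 1L)])
          cx <- apex[1] + stats::runif(1, -10, 10)
          cy <- apex[2] + stats::runif(1, -10, 10)
        } else {
          # anywhere in the jaw bands
          cx <- stats::runif(1, layout$jaw_cols[1], layout$jaw_cols[2])
          cy <- stats::runif(1, layout$maxilla_rows[1], layout$mandible_rows[2])
        }
        box <- clamp_box(cx - w / 2, cy - h / 2, w, h,
                         scene$width, scene$height)
        conf <- stats::rbeta(1, noise$conf_fp[1], noise$conf_fp[2])
        dets[[length(dets) + 1L]] <- list(box = box,
                                          confidence = conf, label = "cyst")
      }
    }
    if (length(dets) > 1) {
      dets <- dets[order(-vapply(dets, `[[`, numeric(1), "confidence"))]
    }
    dets
  })
}

#' Degrade a binary mask to a target Dice score
#'
#' Emulates an imperfect segmentation model: removes `k = round(a (1 - d))`
#' randomly chosen foreground pixels (false negatives) and adds the same
#' number of pixels from successive border rings outside the mask (false
#' positives), where `a` is the original area and `d` the target Dice.
#' With equal removals and additions the Dice score of the degraded mask
#' against the original is exactly `1 - k/a` up to rounding, so the
#' achieved Dice is within the `±0.05` contract by construction.
#'
#' @param mask logical matrix; must contain at least one `TRUE` pixel.
#' @param target_dice target Dice in `(0.2, 1]`; `1` returns the mask
#'   unchanged.
#' @param seed integer RNG seed.
#' @return A logical matrix of the same dimensions.
#' @export
degrade_mask <- function(mask, target_dice, seed = 1L) {
  a <- sum(mask)
  if (a == 0) stop("degrade_mask: mask is empty")
  if (target_dice <= 0.2 || target_dice > 1) {
    stop("degrade_mask: target_dice must be in (0.2, 1]")
  }
  if (target_dice == 1) return(mask)
  k <- as.integer(round(a * (1 - target_dice)))
  if (k == 0) return(mask)
  with_seed(seed, {
    idx_in <- which(mask)
    drop <- sample(idx_in, min(k, a - 1L))
    out <- mask
    out[drop] <- FALSE
    # collect candidate additions from successive dilation rings of the
    # original mask until k pixels are available
    ring_src <- mask
    add <- integer(0)
    while (length(add) < k) {
      dil <- dilate_once(ring_src)
      cand <- which(dil & !ring_src & !mask)
      cand <- setdiff(cand, add)
      if (length(cand) == 0) break
      take <- min(k - length(add), length(cand))
      add <- c(add, if (length(cand) == take) cand else sample(cand, take))
      ring_src <- dil
    }
    out[add] <- TRUE
    out
  })
}

# 4-neighbour binary dilation by one pixel (matrix shifts, no dependencies)
dilate_once <- function(m) {
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  m | up | down | left | right
}

#' Degrade all masks of a scene to per-structure Dice targets
#'
#' @param scene a scene.
#' @param noise a [noise_config()]; `dice_targets` names either a structure
#'   key or `tooth` (applied to all 32 individual teeth).
#' @param seed integer RNG seed.
#' @return A named list of degraded masks over [structure_keys()]. The
#'   dentition mask is degraded independently, mirroring the use of one
#'   segmentation model per task.
#' @export
degrade_mask_set <- function(scene, noise = noise_config(), seed = 1L) {
  keys <- structure_keys()
  seeds <- derive_seeds(seed, length(keys))
  out <- scene$masks
  for (i in seq_along(keys)) {
    key <- keys[i]
    target <- if (key %in% names(noise$dice_targets)) {
      noise$dice_targets[[key]]
    } else if (startsWith(key, "tooth_") && "tooth" %in% names(noise$dice_targets)) {
      noise$dice_targets[["tooth"]]
    } else NA_real_
    if (is.na(target) || target >= 1) next
    if (sum(out[[key]]) == 0) next      # absent tooth: nothing to degrade
    out[[key]] <- degrade_mask(out[[key]], target, seeds[i])
  }
  out
}

#' Generate a labelled overlap-feature dataset by streaming scenes
#'
#' Draws `n` positive scenes with per-scene seeds derived from `seed`,
#' extracts the ground-truth-box overlap feature vector of each scene's
#' first lesion against its clean masks, and discards the masks
#' immediately, so memory stays flat in `n`. This is the noise-free
#' "planted rule" dataset: odontogenic exactly when some tooth feature is
#' positive.
#'
#' @param n number of scenes/samples.
#' @param config a [scene_config()] (must have `n_lesions >= 1`).
#' @param seed integer RNG seed.
#' @return A [feature_table()] data frame with one labelled row per scene.
#' @export
generate_feature_dataset <- function(n, config = scene_config(), seed = 1L) {
  stopifnot(n >= 1, config$n_lesions >= 1)
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_scene(config, seeds[i], scene_id = sprintf("scene_%06d", i))
    out[[i]] <- feature_table(list(list(
      box = s$lesions[[1]]$box, masks = s$masks, sample_id = s$scene_id,
      source = "annotated_box", label = s$lesions[[1]]$class,
      confidence = NA_real_)))
  }
  do.call(rbind, out)
}

#' Generate a dataset of scenes
#'
#' Draws `n` scenes with independent per-scene seeds derived from `seed`.
#' A fraction `prop_positive` of scenes carry lesions (per `config`); the
#' remainder are negative, cyst-free scenes. The default positive fraction
#' of 0.38 matches a clinically representative prevalence in a screening
#' sample.
#'
#' @param n number of scenes.
#' @param config a [scene_config()] used for positive scenes.
#' @param seed integer RNG seed.
#' @param prop_positive fraction of scenes containing lesions.
#' @return List of `scene` objects.
#' @export
generate_scenes <- function(n, config = scene_config(), seed = 1L,
                            prop_positive = 1) {
  stopifnot(n >= 1, prop_positive >= 0, prop_positive <= 1)
  seeds <- derive_seeds(seed, n)
  n_pos <- as.integer(round(n * prop_positive))
  neg_config <- config
  neg_config$n_lesions <- 0L
  lapply(seq_len(n), function(i) {
    cfg <- if (i <= n_pos) config else neg_config
    generate_scene(cfg, seeds[i], scene_id = sprintf("scene_%06d", i))
  })
}
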