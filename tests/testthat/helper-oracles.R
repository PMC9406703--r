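# Brute-force oracles, kept deliberately independent of the package's own
# implementations: everything here works by exhaustive pixel enumeration or
# exhaustive search on small instances.

# Rasterise an integer-coordinate box onto a width x height pixel grid.
rasterize_box <- function(b, width, height) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  xs <- seq.int(max(0, b$x), min(width, b$x + b$w) - 1)
  ys <- seq.int(max(0, b$y), min(height, b$y + b$h) - 1)
  if (length(xs) > 0 && length(ys) > 0 &&
      b$x < width && b$y < height && b$x + b$w > 0 && b$y + b$h > 0) {
    m[ys + 1, xs + 1] <- TRUE
  }
  m
}

# IoU by counting pixels on a grid large enough to hold both boxes.
pixel_iou <- function(a, b) {
  width <- max(a$x + a$w, b$x + b$w) + 2
  height <- max(a$y + a$h, b$y + b$h) + 2
  ma <- rasterize_box(a, width, height)
  mb <- rasterize_box(b, width, height)
  sum(ma & mb) / sum(ma | mb)
}

# Overlap share by pixel enumeration (box clipped to the grid).
pixel_overlap_share <- function(b, mask) {
  mb <- rasterize_box(b, ncol(mask), nrow(mask))
  sum(mb & mask) / sum(mb)
}

# Dice by direct counting.
pixel_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Exhaustive greedy CART: at every node enumerate ALL features and ALL
# midpoint thresholds, pick max Gini gain (ties: lowest feature, lowest
# threshold). Mirrors the textbook algorithm with no sampling.
oracle_cart <- function(X, y, min_samples_split = 2, max_depth = 0, depth = 0) {
  classes <- cystdx::cyst_classes()
  counts <- c(sum(y == classes[1]), sum(y == classes[2]))
  names(counts) <- classes
  leaf <- list(type = "leaf", counts = counts)
  if (any(counts == 0) || nrow(X) < min_samples_split) return(leaf)
  if (max_depth > 0 && depth >= max_depth) return(leaf)
  n <- nrow(X)
  g0 <- 1 - sum((counts / n)^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (t in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- X[, j] <= t
      nl <- sum(left); nr <- n - nl
      cl <- c(sum(y[left] == classes[1]), sum(y[left] == classes[2]))
      cr <- counts - cl
      gain <- g0 - (nl / n) * (1 - sum((cl / nl)^2)) -
        (nr / n) * (1 - sum((cr / nr)^2))
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(feature = j, threshold = t, gain = gain)
      }
    }
  }
  if (is.null(best)) return(leaf)
  left <- X[, best$feature] <= best$threshold
  list(type = "split", feature = best$feature, threshold = best$threshold,
       left = oracle_cart(X[left, , drop = FALSE], y[left],
                          min_samples_split, max_depth, depth + 1),
       right = oracle_cart(X[!left, , drop = FALSE], y[!left],
                           min_samples_split, max_depth, depth + 1))
}

oracle_cart_predict <- function(node, x) {
  while (node$type == "split") {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  names(node$counts)[which.max(node$counts)]
}

# Average precision by direct evaluation of every rank cutoff: precision and
# recall after the k highest-confidence detections, interpolated precision as
# the max precision at any recall >= r over the 101-point grid.
oracle_ap <- function(tp, conf, n_gt) {
  if (length(tp) == 0) return(0)
  tp <- tp[order(-conf)]
  prec <- rec <- numeric(length(tp))
  for (k in seq_along(tp)) {
    prec[k] <- sum(tp[seq_len(k)]) / k
    rec[k] <- sum(tp[seq_len(k)]) / n_gt
  }
  mean(sapply(seq(0, 1, 0.01), function(r) {
    ok <- rec >= r - 1e-12
    if (!any(ok)) 0 else max(prec[ok])
  }))
}

# Planted spatial rule the simulator guarantees on noise-free data:
# odontogenic iff any individual-tooth overlap feature is positive.
rule_classify <- function(X) {
  tooth_cols <- cystdx::tooth_keys()
  ifelse(rowSums(X[, tooth_cols, drop = FALSE] > 0) > 0,
         "odontogenic", "non_odontogenic")
}

# Feature table for a list of scenes using their ground-truth boxes and
# clean masks (first lesion per scene defines the sample).
scenes_to_features <- function(scenes, source = "annotated_box") {
  rows <- lapply(scenes, function(s) {
    list(box = s$lesions[[1]]$box, masks = s$masks, sample_id = s$scene_id,
         source = source, label = s$lesions[[1]]$class, confidence = NA_real_)
  })
  cystdx::feature_table(rows)
}

tiny_scene_config <- function(...) {
  cystdx::scene_config(width = 220L, height = 120L, lesion_size = c(16L, 30L), ...)
}
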