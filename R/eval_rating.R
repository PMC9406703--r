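#' One-vs-rest confusion counts
#'
#' Tallies true/false positives and negatives for `target_class` against
#' all other labels.
#'
#' @param truth,predicted equal-length label vectors.
#' @param target_class the class counted as positive.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`
#'   and `target_class`.
#' @export
confusion_counts <- function(truth, predicted, target_class) {
  if (length(truth) != length(predicted)) {
    stop("confusion_counts: truth and predicted have different lengths")
  }
  if (length(truth) == 0) stop("confusion_counts: empty input")
  tpos <- truth == target_class
  ppos <- predicted == target_class
  structure(list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                 tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos),
                 target_class = target_class),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive value, and F1 as the harmonic mean of PPV and
#' sensitivity. A metric whose denominator is zero is reported as `NA`
#' (flagged undefined), never as 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return A list of class `class_metrics`.
#' @export
class_metrics <- function(counts) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(counts$tp, counts$tp + counts$fn)
  spec <- safe(counts$tn, counts$tn + counts$fp)
  ppv <- safe(counts$tp, counts$tp + counts$fp)
  npv <- safe(counts$tn, counts$tn + counts$fn)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1_score(ppv, sens),
                 target_class = counts$target_class),
            class = "class_metrics")
}

#' F1 score from precision and sensitivity
#'
#' The harmonic mean `2 p s / (p + s)`; `NA` when either input is
#' undefined or both are zero. Useful to recompute a reported F1 from its
#' published precision/recall pair.
#'
#' @param ppv precision (positive predictive value).
#' @param sensitivity recall.
#' @return F1 in `[0, 1]` or `NA`.
#' @examples
#' f1_score(0.89, 0.84)
#' @export
f1_score <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity) || ppv + sensitivity == 0) {
    return(NA_real_)
  }
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Per-class diagnostic report for a two-class prediction set
#'
#' Computes [class_metrics()] with each cyst class as target. Because the
#' problem is binary, the two columns are linked by an exchange symmetry:
#' the sensitivity of one class equals the specificity of the other, and
#' the PPV of one equals the NPV of the other.
#'
#' @param truth,predicted label vectors over [cyst_classes()].
#' @return Named list of `class_metrics`, one per class.
#' @export
two_class_report <- function(truth, predicted) {
  present <- unique(truth)
  if (!all(present %in% cyst_classes()) || length(present) != 2) {
    stop("two_class_report: truth must contain exactly the two cyst classes")
  }
  out <- lapply(cyst_classes(), function(cl) {
    class_metrics(confusion_counts(truth, predicted, cl))
  })
  names(out) <- cyst_classes()
  out
}

#' Flatten a two-class report into a data frame
#'
#' @param report a [two_class_report()] result.
#' @return Data frame with one row per class.
#' @export
report_as_df <- function(report) {
  do.call(rbind, lapply(report, function(m) {
    data.frame(class = m$target_class, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               f1 = m$f1, stringsAsFactors = FALSE)
  }))
}

#' Fleiss' kappa for a subjects-by-categories rating matrix
#'
#' Chance-corrected agreement for `n_raters` raters assigning each subject
#' to one category. With `n_ij` votes for category `j` on subject `i`,
#' per-subject agreement is `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, the
#' chance agreement is `Pe = sum_j p_j^2` over the marginal category
#' shares, and `kappa = (mean(P_i) - Pe) / (1 - Pe)`. When every vote
#' falls in a single category `Pe = 1` and kappa is undefined (`NA` with a
#' warning). Invariant to subject and category order.
#'
#' @param ratings integer matrix, subjects x categories; every row must
#'   sum to the same number of raters (>= 2).
#' @return Kappa (<= 1), or `NA` when undefined.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2) stop("fleiss_kappa: need at least 2 subjects")
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1) {
    stop("fleiss_kappa: all subjects must have the same number of raters")
  }
  if (n_raters < 2) stop("fleiss_kappa: need at least 2 raters")
  n <- n_raters
  p_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  p_j <- colSums(ratings) / sum(ratings)
  pe <- sum(p_j^2)
  pbar <- mean(p_i)
  if (1 - pe < 1e-12) {
    # every vote in a single category: chance agreement is total and the
    # statistic is undefined
    warning("fleiss_kappa: all votes in one category; kappa undefined")
    return(NA_real_)
  }
  (pbar - pe) / (1 - pe)
}

#' Bootstrap confidence interval for Fleiss' kappa
#'
#' Percentile interval over subject-level resampling: subjects (matrix
#' rows) are drawn with replacement `n_boot` times and kappa is recomputed
#' on each resample. Resamples with undefined kappa are dropped.
#' Deterministic under a fixed seed.
#'
#' @param ratings subjects-by-categories matrix as in [fleiss_kappa()].
#' @param n_boot number of resamples (>= 100).
#' @param level confidence level.
#' @param seed integer RNG seed.
#' @return `c(low, high)` percentile bounds.
#' @export
kappa_bootstrap_ci <- function(ratings, n_boot = 2000L, level = 0.95,
                               seed = 1L) {
  stopifnot(n_boot >= 100)
  ratings <- as.matrix(ratings)
  with_seed(seed, {
    ks <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(ratings), nrow(ratings), replace = TRUE)
      suppressWarnings(fleiss_kappa(ratings[idx, , drop = FALSE]))
    }, numeric(1))
    ks <- ks[!is.na(ks)]
    alpha <- (1 - level) / 2
    stats::quantile(ks, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
}

#' Mean Dice per structure across paired mask sets
#'
#' Compares predicted and ground-truth segmentations scene by scene and
#' reports the mean Dice score per structure key — the segmentation-model
#' performance summary.
#'
#' @param predicted,truth lists (one element per scene) of named mask
#'   lists sharing structure keys.
#' @param keys structure keys to report; defaults to all present in the
#'   first truth set.
#' @return Named numeric vector of mean Dice scores.
#' @export
dice_report <- function(predicted, truth, keys = names(truth[[1]])) {
  if (length(predicted) != length(truth)) {
    stop("dice_report: predicted and truth have different lengths")
  }
  vapply(keys, function(k) {
    mean(vapply(seq_along(truth), function(i) {
      dice(predicted[[i]][[k]], truth[[i]][[k]])
    }, numeric(1)))
  }, numeric(1))
}

#' Dataset composition percentages
#'
#' Recomputes the percentage share of each diagnostic group from raw
#' counts, as printed in dataset-characteristics tables.
#'
#' @param counts named nonnegative counts.
#' @param digits rounding for the percentage column.
#' @return Data frame with `n` and `percent` per group.
#' @export
composition_report <- function(counts, digits = 1) {
  total <- sum(counts)
  if (total <= 0) stop("composition_report: counts sum to zero")
  data.frame(group = names(counts), n = as.integer(counts),
             percent = round(100 * counts / total, digits),
             row.names = NULL, stringsAsFactors = FALSE)
}
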