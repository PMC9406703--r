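#' Share of a bounding box covered by a mask
#'
#' The fraction of the box's pixels that are foreground in `mask`, the
#' feature underlying the spatial-context classifier: a value in `[0, 1]`
#' stating how much of the lesion box is covered by a specific anatomical
#' structure. Boxes are clipped to the image bounds first (jittered
#' detections can leave the frame); the clipped pixel area is the
#' denominator.
#'
#' @param box a [bbox()].
#' @param mask logical (or 0/1) matrix, rows = image rows.
#' @return Overlap share in `[0, 1]`.
#' @export
overlap_share <- function(box, mask) {
  if (is.numeric(mask)) mask <- mask > 0
  clipped <- bbox_clip(box, ncol(mask), nrow(mask))
  if (is.null(clipped)) {
    stop("overlap_share: box has zero area inside the image")
  }
  rows <- bbox_rows(clipped)
  cols <- bbox_cols(clipped)
  sum(mask[rows, cols]) / (length(rows) * length(cols))
}

#' Dice similarity of two binary masks
#'
#' `2|A . B| / (|A| + |B|)`. Symmetric; 1 for identical non-empty masks and
#' 0 for disjoint ones. Two empty masks score 1 by convention (a truly
#' absent structure that is also predicted absent is a perfect answer).
#'
#' @param a,b logical (or 0/1) matrices of identical dimensions.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is.numeric(a)) a <- a > 0
  if (is.numeric(b)) b <- b > 0
  if (!all(dim(a) == dim(b))) {
    stop("dice: masks have different dimensions")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Highest-confidence detection above a threshold
#'
#' Selects the detection whose box is passed on to feature extraction: the
#' highest-confidence box with confidence at or above `threshold`, or
#' `NULL` when no detection qualifies (the sample is then excluded
#' downstream, which is what shrinks the classified-sample count as the
#' threshold rises). Ties on confidence are broken by larger box area, then
#' by lowest `(x, y)` lexicographically.
#'
#' @param detections list of detections (`list(box, confidence, label)`).
#' @param threshold minimum confidence in `[0, 1]`.
#' @return The winning detection, or `NULL`.
#' @export
select_top_box <- function(detections, threshold = 0) {
  if (length(detections) == 0) return(NULL)
  conf <- vapply(detections, `[[`, numeric(1), "confidence")
  keep <- which(conf >= threshold)
  if (length(keep) == 0) return(NULL)
  area <- vapply(detections, function(d) bbox_area(d$box), numeric(1))
  xs <- vapply(detections, function(d) d$box$x, numeric(1))
  ys <- vapply(detections, function(d) d$box$y, numeric(1))
  o <- order(-conf[keep], -area[keep], xs[keep], ys[keep])
  detections[[keep[o[1]]]]
}

#' Overlap feature vector of a box against an anatomical mask set
#'
#' Computes the 37 overlap shares in the canonical [structure_keys()]
#' order: maxilla, mandible, mandibular canal, maxillary sinus, dentition,
#' then the 32 FDI tooth positions. Absent teeth have all-zero masks and
#' contribute a 0 feature, so the vector has fixed dimensionality. Since
#' the dentition mask is the union of the tooth masks, the dentition
#' feature is at least the maximum tooth feature (up to segmentation
#' degradation, when predicted masks are used).
#'
#' @param box a [bbox()].
#' @param masks named list of masks covering [structure_keys()].
#' @param sample_id identifier attached to the vector.
#' @param source `"predicted_box"` or `"annotated_box"`.
#' @return Named numeric vector of length 37 with attributes `sample_id`
#'   and `source`.
#' @export
feature_vector <- function(box, masks, sample_id = NA_character_,
                           source = c("annotated_box", "predicted_box")) {
  source <- match.arg(source)
  keys <- structure_keys()
  missing <- setdiff(keys, names(masks))
  if (length(missing) > 0) {
    stop("feature_vector: masks missing structures: ",
         paste(missing, collapse = ", "))
  }
  v <- vapply(keys, function(k) overlap_share(box, masks[[k]]), numeric(1))
  attr(v, "sample_id") <- sample_id
  attr(v, "source") <- source
  v
}

#' Assemble a feature table for a set of samples
#'
#' One row per sample: `sample_id`, `source`, the 37 feature columns in
#' canonical order, the class `label` when known and the `confidence` of
#' the chosen box. This is the CSV interchange format between feature
#' extraction and the Random Forest.
#'
#' @param rows list of entries `list(box, masks, sample_id, source, label,
#'   confidence)`; `label`/`confidence` may be `NA`.
#' @return A `data.frame`.
#' @export
feature_table <- function(rows) {
  keys <- structure_keys()
  out <- lapply(rows, function(r) {
    v <- feature_vector(r$box, r$masks, r$sample_id, r$source)
    df <- as.data.frame(as.list(v))
    names(df) <- keys
    cbind(data.frame(sample_id = r$sample_id, source = r$source,
                     stringsAsFactors = FALSE),
          df,
          data.frame(label = if (is.null(r$label)) NA_character_ else r$label,
                     confidence = if (is.null(r$confidence)) NA_real_ else r$confidence,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}

#' Extract the feature matrix from a feature table
#'
#' @param df a [feature_table()] data frame.
#' @return Numeric matrix with the 37 canonical feature columns.
#' @export
feature_matrix <- function(df) {
  as.matrix(df[, structure_keys(), drop = FALSE])
}
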