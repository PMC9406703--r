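#' Bounding box
#'
#' Axis-aligned rectangle in pixel coordinates. `x`, `y` give the upper-left
#' corner (0-based); the box covers columns `[x, x + w)` and rows
#' `[y, y + h)`, i.e. the extent is half-open and areas are whole pixel
#' counts. This is the convention used by the plain-text lesion annotation
#' format (upper-left corner plus width and height).
#'
#' @param x,y upper-left corner, 0-based pixels.
#' @param w,h width and height in pixels; both must be strictly positive.
#' @return An object of class `bbox`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)
#' @export
bbox <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (w <= 0 || h <= 0) {
    stop("bbox: width and height must be strictly positive (got w=", w,
         ", h=", h, ")")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' @rdname bbox
#' @param b a `bbox`.
#' @export
bbox_area <- function(b) b$w * b$h

#' Clip a box to image bounds
#'
#' Intersects a box with the image rectangle `[0, width) x [0, height)`.
#' Returns `NULL` when the intersection is empty.
#'
#' @param b a `bbox`.
#' @param width,height image dimensions in pixels.
#' @return A clipped `bbox`, or `NULL` if nothing remains.
#' @export
bbox_clip <- function(b, width, height) {
  x0 <- max(b$x, 0); y0 <- max(b$y, 0)
  x1 <- min(b$x + b$w, width); y1 <- min(b$y + b$h, height)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

#' Intersection over union of two boxes
#'
#' `|a intersect b| / |a union b|` with areas counted in whole pixels under
#' the half-open convention. Symmetric, in `[0, 1]`, and equal to 1 exactly
#' when the boxes coincide.
#'
#' @param a,b `bbox` objects.
#' @return IoU as a single number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 50 / 150
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- bbox_area(a) + bbox_area(b) - inter
  inter / union
}

# Integer pixel index sets of a box on a height x width grid (1-based matrix
# indices). Used for mask overlap; assumes the box was already clipped.
bbox_rows <- function(b) seq.int(floor(b$y) + 1L, ceiling(b$y + b$h))
bbox_cols <- function(b) seq.int(floor(b$x) + 1L, ceiling(b$x + b$w))

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (args, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive per-item child seeds from a parent seed, all below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
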