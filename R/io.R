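#' Write / read the plain-text lesion annotation format
#'
#' One tab-separated record per lesion with the fields `scene_id`, `x`,
#' `y`, `w`, `h` (upper-left corner plus width and height of the smallest
#' rectangle containing the radiolucent lesion), `age`, `sex` and
#' `diagnosis`. A scene without lesions produces a header-only file.
#' `read_annotation_file(write_annotation_file(scene))` reproduces every
#' recorded field exactly.
#'
#' @param scene a scene (or for `read_annotation_file`, a file path).
#' @param path output file path.
#' @return `write_annotation_file` returns `path` invisibly;
#'   `read_annotation_file` returns a `data.frame` with one row per lesion.
#' @export
write_annotation_file <- function(scene, path) {
  header <- c("scene_id", "x", "y", "w", "h", "age", "sex", "diagnosis")
  lines <- paste(header, collapse = "\t")
  for (lesion in scene$lesions) {
    b <- lesion$box
    lines <- c(lines, paste(c(scene$scene_id, b$x, b$y, b$w, b$h,
                              scene$demographics$age, scene$demographics$sex,
                              lesion$class), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_file
#' @export
read_annotation_file <- function(path) {
  lines <- readLines(path)
  header <- c("scene_id", "x", "y", "w", "h", "age", "sex", "diagnosis")
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]], header)) {
    stop("read_annotation_file: line 1: malformed or missing header")
  }
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 8) {
      stop("read_annotation_file: line ", i, ": expected 8 fields, got ",
           length(f))
    }
    num <- suppressWarnings(as.numeric(f[2:5]))
    if (anyNA(num)) {
      stop("read_annotation_file: line ", i, ": non-numeric box coordinates")
    }
    if (num[3] <= 0 || num[4] <= 0) {
      stop("read_annotation_file: line ", i,
           ": box width and height must be positive")
    }
    age <- suppressWarnings(as.integer(f[6]))
    if (is.na(age)) stop("read_annotation_file: line ", i, ": bad age")
    if (!f[8] %in% c(cyst_classes(), "negative")) {
      stop("read_annotation_file: line ", i, ": unknown diagnosis '", f[8], "'")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(scene_id = f[1], x = num[1], y = num[2], w = num[3],
                 h = num[4], age = age, sex = f[7], diagnosis = f[8],
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(scene_id = character(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), age = integer(),
                      sex = character(), diagnosis = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a scene's masks as PNG files
#'
#' One 0/255 grayscale PNG per structure, named
#' `<scene_id>__<structure>.png`.
#'
#' @param scene a scene.
#' @param dir output directory (created if needed).
#' @param keys structures to write; defaults to all 37.
#' @return Invisible character vector of file paths.
#' @export
write_mask_pngs <- function(scene, dir, keys = structure_keys()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (key in keys) {
    p <- file.path(dir, paste0(scene$scene_id, "__", key, ".png"))
    png::writePNG(scene$masks[[key]] * 1.0, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_mask_pngs
#' @param path a PNG path written by `write_mask_pngs`.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read detections and ground truth as COCO-style JSON
#'
#' The standard interchange layout: `images` (id, file_name, width,
#' height), `annotations` (id, image_id, category_id, `bbox = [x, y, w,
#' h]`, and `score` for detections), `categories`. Ground-truth
#' annotations carry the cyst class as their category; detections carry
#' the single `cyst` category plus a confidence score.
#'
#' @param scenes list of scenes.
#' @param detections optional list (parallel to `scenes`) of detection
#'   lists from [simulate_detections()]; when supplied, detections are
#'   written instead of ground truth.
#' @param path output JSON path.
#' @return `write_coco_json` returns `path` invisibly; `read_coco_json`
#'   returns a list with `images`, `annotations`, `categories` data frames.
#' @export
write_coco_json <- function(scenes, path, detections = NULL) {
  images <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    data.frame(id = i, file_name = paste0(s$scene_id, ".png"),
               width = s$width, height = s$height, stringsAsFactors = FALSE)
  }))
  if (is.null(detections)) {
    categories <- data.frame(id = c(1L, 2L), name = cyst_classes(),
                             stringsAsFactors = FALSE)
    ann <- list(); aid <- 0L
    for (i in seq_along(scenes)) {
      for (lesion in scenes[[i]]$lesions) {
        aid <- aid + 1L
        ann[[aid]] <- list(id = aid, image_id = i,
                           category_id = match(lesion$class, cyst_classes()),
                           bbox = c(lesion$box$x, lesion$box$y,
                                    lesion$box$w, lesion$box$h),
                           area = bbox_area(lesion$box))
      }
    }
  } else {
    categories <- data.frame(id = 1L, name = "cyst", stringsAsFactors = FALSE)
    ann <- list(); aid <- 0L
    for (i in seq_along(detections)) {
      for (d in detections[[i]]) {
        aid <- aid + 1L
        ann[[aid]] <- list(id = aid, image_id = i, category_id = 1L,
                           bbox = c(d$box$x, d$box$y, d$box$w, d$box$h),
                           score = d$confidence)
      }
    }
  }
  obj <- list(images = images, annotations = ann, categories = categories)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_coco_json
#' @export
read_coco_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  ann <- obj$annotations
  if (is.data.frame(ann) && nrow(ann) > 0) {
    bb <- do.call(rbind, ann$bbox)
    ann$x <- bb[, 1]; ann$y <- bb[, 2]; ann$w <- bb[, 3]; ann$h <- bb[, 4]
    ann$bbox <- NULL
  }
  list(images = obj$images, annotations = ann, categories = obj$categories)
}

#' Read / write a scene configuration as YAML
#'
#' @param config a [scene_config()] (or for reading, a file path).
#' @param path output path.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` returns a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  v <- yaml::read_yaml(path)
  scene_config(width = v$width, height = v$height, n_lesions = v$n_lesions,
               class_mix = unlist(v$class_mix), missing_rate = v$missing_rate,
               lesion_size = unlist(v$lesion_size),
               min_tooth_share = v$min_tooth_share,
               max_attempts = v$max_attempts)
}
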