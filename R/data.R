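# Synthetic dataset generation and label I/O.
#
# The generator emulates the structure of a single-class fallen-person
# dataset: one to a few boxed objects per image, an 80/16/4
# train/test/val split, YOLO-txt labels. Targets are bright geometric
# shapes (rectangles / ellipses with orientation jitter) on darker textured
# backgrounds -- deliberately not human figures: the contract is that a
# detector can learn them, which is what exercises the loss, decode and
# metric stack.

#' Read YOLO-format labels
#'
#' Each line is `class cx cy w h` with normalized floats in `[0, 1]`.
#'
#' @param path label file.
#' @return data.frame with columns `class`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 5L)
      stop(sprintf("%s:%d: expected 5 fields, got %d", path, i, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("%s:%d: non-numeric field", path, i), call. = FALSE)
    if (v[1] < 0 || v[1] != floor(v[1]))
      stop(sprintf("%s:%d: class id must be a non-negative integer", path, i), call. = FALSE)
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop(sprintf("%s:%d: coordinates out of [0, 1]", path, i), call. = FALSE)
    data.frame(class = as.integer(v[1]), cx = v[2], cy = v[3], w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' @rdname read_yolo_labels
#' @param boxes data.frame with `class`, `cx`, `cy`, `w`, `h` (normalized).
#' @param path destination file for the writer.
#' @export
write_yolo_labels <- function(boxes, path) {
  lines <- if (nrow(boxes) == 0L) character() else
    sprintf("%d %.6f %.6f %.6f %.6f", boxes$class, boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalized YOLO boxes to pixel corner coordinates
#'
#' Pixel boxes are 0-based and half-open: `"0 0.5 0.5 0.2 0.2"` at size 640
#' becomes `(256, 256, 384, 384)`.
#'
#' @param boxes data.frame from [read_yolo_labels()].
#' @param image_size side length in pixels.
#' @export
yolo_to_xyxy <- function(boxes, image_size) {
  data.frame(class = boxes$class,
             x1 = (boxes$cx - boxes$w / 2) * image_size,
             y1 = (boxes$cy - boxes$h / 2) * image_size,
             x2 = (boxes$cx + boxes$w / 2) * image_size,
             y2 = (boxes$cy + boxes$h / 2) * image_size)
}

#' Read a Pascal-VOC XML annotation
#'
#' VOC bounding boxes are 1-based inclusive pixel coordinates; they are
#' converted to the package's 0-based half-open convention (xmin 1, ymin 1,
#' xmax 10, ymax 10 becomes `(0, 0, 10, 10)`).
#'
#' @param path XML file.
#' @return data.frame with `name`, `x1`, `y1`, `x2`, `y2`.
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L)
    return(data.frame(name = character(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  rows <- lapply(objs, function(o) {
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (is.na(bb)) stop("VOC schema error in ", path, ": object without bndbox", call. = FALSE)
    get <- function(tag) {
      n <- xml2::xml_find_first(bb, paste0("./", tag))
      if (is.na(n)) stop("VOC schema error in ", path, ": missing ", tag, call. = FALSE)
      as.numeric(xml2::xml_text(n))
    }
    data.frame(name = xml2::xml_text(xml2::xml_find_first(o, "./name")),
               x1 = get("xmin") - 1, y1 = get("ymin") - 1,
               x2 = get("xmax"), y2 = get("ymax"))
  })
  do.call(rbind, rows)
}

#' @rdname read_voc_xml
#' @param boxes data.frame with `name`, `x1`, `y1`, `x2`, `y2` (internal
#'   convention); written back as 1-based inclusive VOC coordinates.
#' @param filename value of the `<filename>` element.
#' @export
write_voc_xml <- function(boxes, path, filename = "image.png") {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  for (i in seq_len(nrow(boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", as.character(boxes$name[i]))
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(boxes$x1[i] + 1))
    xml2::xml_add_child(bb, "ymin", format(boxes$y1[i] + 1))
    xml2::xml_add_child(bb, "xmax", format(boxes$x2[i]))
    xml2::xml_add_child(bb, "ymax", format(boxes$y2[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# draw one rotated shape into an image array; returns the updated image and
# the tight axis-aligned pixel box of the drawn mask
draw_shape <- function(img, size) {
  # box-dimension span mirrors the published fallen-person anchor range
  # (roughly 0.2 to 0.85 of the frame side)
  w <- stats::runif(1, 0.18, 0.65) * size
  h <- stats::runif(1, 0.18, 0.65) * size
  theta <- stats::runif(1, -25, 25) * pi / 180
  half_span <- (abs(cos(theta)) * w + abs(sin(theta)) * h) / 2 + 2
  half_span_y <- (abs(sin(theta)) * w + abs(cos(theta)) * h) / 2 + 2
  cx <- stats::runif(1, half_span, size - half_span)
  cy <- stats::runif(1, half_span_y, size - half_span_y)
  kind <- sample(c("rect", "ellipse"), 1L)
  color <- stats::runif(3, 0.75, 1.0)
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)   # x per column
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)  # y per row
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  mask <- if (kind == "rect") abs(u) <= w / 2 & abs(v) <= h / 2
          else (u / (w / 2))^2 + (v / (h / 2))^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
  list(img = img, box = c(x1 = cols[1] - 1, y1 = rows[1] - 1, x2 = cols[2], y2 = rows[2]))
}

textured_background <- function(size) {
  base <- stats::runif(1, 0.05, 0.25)
  coarse <- matrix(stats::runif(16 * 16, 0, 1), 16, 16)
  idx <- pmin(16L, pmax(1L, ceiling(seq_len(size) / (size / 16))))
  tex <- coarse[idx, idx]
  lvl <- pmin(0.40, base + 0.10 * tex)
  array(rep(lvl, 3L), c(size, size, 3L))
}

#' Generate a synthetic single-class detection dataset
#'
#' Writes `n_images` PNG images with matching YOLO-txt label files under
#' `out_dir/images` and `out_dir/labels`, deterministically under `seed`,
#' and splits them 80/16/4 into train/test/val (each split non-empty for
#' `n_images >= 5`).
#'
#' @param n_images number of scenes (>= 5).
#' @param image_size square image side (default 640).
#' @param boxes_per_image integer range `c(min, max)` of objects per scene;
#'   `c(0, 0)` produces background-only images with empty label files.
#' @param seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @return a `dataset_split`: list with data.frames `train`, `test`, `val`
#'   (columns `image`, `label`) and the realized `ratios`.
#' @export
generate_dataset <- function(n_images, image_size = 640L, boxes_per_image = c(1L, 3L),
                             seed = 0L, out_dir = tempfile("fpd_synth_")) {
  stopifnot(n_images >= 5L)
  if (length(boxes_per_image) == 1L) boxes_per_image <- rep(boxes_per_image, 2L)
  img_dir <- file.path(out_dir, "images"); lab_dir <- file.path(out_dir, "labels")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) | dir.exists(img_dir)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(lab_dir))
    stop("generate_dataset: cannot create output directory ", out_dir, call. = FALSE)
  set.seed(seed)
  imgs <- character(n_images); labs <- character(n_images)
  for (i in seq_len(n_images)) {
    img <- textured_background(image_size)
    k <- if (boxes_per_image[2] == 0L) 0L else
      sample(boxes_per_image[1]:boxes_per_image[2], 1L)
    boxes <- list()
    for (b in seq_len(k)) {
      sh <- draw_shape(img, image_size)
      img <- sh$img
      boxes[[b]] <- sh$box
    }
    imgs[i] <- file.path(img_dir, sprintf("img_%04d.png", i))
    labs[i] <- file.path(lab_dir, sprintf("img_%04d.txt", i))
    png::writePNG(img, imgs[i])
    lab <- if (k == 0L) data.frame(class = integer(), cx = numeric(), cy = numeric(),
                                   w = numeric(), h = numeric())
    else do.call(rbind, lapply(boxes, function(bx) data.frame(
      class = 0L,
      cx = (bx["x1"] + bx["x2"]) / 2 / image_size,
      cy = (bx["y1"] + bx["y2"]) / 2 / image_size,
      w = (bx["x2"] - bx["x1"]) / image_size,
      h = (bx["y2"] - bx["y1"]) / image_size)))
    write_yolo_labels(lab, labs[i])
  }
  split_dataset(imgs, labs, seed = seed, out_dir = out_dir)
}

#' Split image/label pairs 80/16/4
#'
#' Deterministic under `seed`; partitions are disjoint and exhaustive, the
#' test and val splits are never empty.
#'
#' @param images,labels parallel path vectors.
#' @param ratios train/test/val fractions (default `c(0.80, 0.16, 0.04)`).
#' @param seed RNG seed for the shuffle.
#' @param out_dir when non-NULL, `train.txt` / `test.txt` / `val.txt`
#'   manifests are written there.
#' @export
split_dataset <- function(images, labels, ratios = c(0.80, 0.16, 0.04),
                          seed = 0L, out_dir = NULL) {
  stopifnot(length(images) == length(labels), abs(sum(ratios) - 1) < 1e-8)
  n <- length(images)
  set.seed(seed + 1L)
  ord <- sample.int(n)
  n_val <- max(1L, round(ratios[3] * n))
  n_test <- max(1L, round(ratios[2] * n))
  n_train <- n - n_test - n_val
  if (n_train < 1L) stop("split_dataset: too few files for a train split", call. = FALSE)
  take <- function(idx) data.frame(image = images[ord[idx]], label = labels[ord[idx]],
                                   stringsAsFactors = FALSE)
  sp <- structure(list(train = take(seq_len(n_train)),
                       test = take(n_train + seq_len(n_test)),
                       val = take(n_train + n_test + seq_len(n_val)),
                       ratios = c(train = n_train, test = n_test, val = n_val) / n),
                  class = "dataset_split")
  if (!is.null(out_dir))
    for (s in c("train", "test", "val"))
      writeLines(sp[[s]]$image, file.path(out_dir, paste0(s, ".txt")))
  sp
}
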