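#' Read YOLO-format labels into a bundle
#'
#' Each image has one text label file (same stem, `.txt`) whose lines
#' read `class cx cy w h` with center/extent normalized to `[0, 1]`.
#' Conversion to absolute corner boxes is `x = (cx - w/2) * W`,
#' `y = (cy - h/2) * H`. Normalized values outside `[0, 1]` or class
#' indices outside the category map are errors.
#'
#' @param labels_dir Directory of `.txt` label files.
#' @param images_dir Directory of matching raster images (PNG/TIFF);
#'   used for frame dimensions and pixel data.
#' @param categories A [category_map()] giving the class-index order.
#' @param load_pixels Keep pixel data in memory (default `TRUE`).
#' @return A [dataset_bundle()]; image ids are assigned 1..n in sorted
#'   file order.
#' @export
read_yolo <- function(labels_dir, images_dir, categories = category_map(),
                      load_pixels = TRUE) {
  label_files <- sort(list.files(labels_dir, pattern = "\\.txt$",
                                 full.names = TRUE))
  if (!length(label_files)) stop("no .txt label files in ", labels_dir)
  next_id <- 1L
  images <- vector("list", length(label_files))
  for (i in seq_along(label_files)) {
    stem <- tools::file_path_sans_ext(basename(label_files[i]))
    img_path <- find_image_file(images_dir, stem)
    px <- load_image(img_path)
    W <- ncol(px); H <- nrow(px)
    lines <- readLines(label_files[i], warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    ann <- annotation_frame()
    if (length(lines)) {
      fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                                      as.numeric))
      if (ncol(fields) != 5L) {
        stop(label_files[i], ": each line must be 'class cx cy w h'")
      }
      norm <- fields[, 2:5, drop = FALSE]
      if (any(norm < 0 | norm > 1)) {
        stop(label_files[i], ": normalized values outside [0, 1]")
      }
      cls <- as.integer(fields[, 1])
      if (any(!(cls %in% categories$index))) {
        stop(label_files[i], ": class index outside the category map")
      }
      ann <- data.frame(
        id = seq.int(next_id, length.out = nrow(fields)),
        image_id = i,
        x = (fields[, 2] - fields[, 4] / 2) * W,
        y = (fields[, 3] - fields[, 5] / 2) * H,
        w = fields[, 4] * W,
        h = fields[, 5] * H,
        category = categories$name[match(cls, categories$index)],
        source = "manual",
        stringsAsFactors = FALSE
      )
      next_id <- next_id + nrow(fields)
    }
    clipped <- clip_annotations(ann, W, H)
    images[[i]] <- image_record(
      i, W, H, pixels = if (load_pixels) px else NULL,
      annotations = clipped$annotations, path = img_path)
  }
  dataset_bundle(images, categories,
                 provenance = sprintf("read_yolo: %s", labels_dir))
}

find_image_file <- function(images_dir, stem) {
  for (ext in c("png", "tif", "tiff", "jpg", "jpeg")) {
    p <- file.path(images_dir, paste0(stem, ".", ext))
    if (file.exists(p)) return(p)
  }
  stop("no raster image found for label stem '", stem, "' in ", images_dir)
}

#' Write a bundle as YOLO-format labels
#'
#' One `.txt` file per image under `dir/labels`, lines
#' `class cx cy w h` normalized to the frame and rounded to 6 decimal
#' places; images with pixel data are written as PNG under `dir/images`.
#'
#' @param bundle A valid [dataset_bundle()].
#' @param dir Output directory (created if needed).
#' @param write_images Also write PNG rasters (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_yolo <- function(bundle, dir, write_images = TRUE) {
  stop_if_invalid(bundle, "write_yolo")
  labels_dir <- file.path(dir, "labels")
  images_dir <- file.path(dir, "images")
  dir.create(labels_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images) {
    dir.create(images_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cat_index <- setNames(bundle$categories$index, bundle$categories$name)
  for (img in bundle$images) {
    stem <- sprintf("image_%06d", img$image_id)
    a <- img$annotations
    lines <- if (nrow(a)) {
      sprintf("%d %.6f %.6f %.6f %.6f",
              unname(cat_index[a$category]),
              (a$x + a$w / 2) / img$width,
              (a$y + a$h / 2) / img$height,
              a$w / img$width,
              a$h / img$height)
    } else character()
    writeLines(lines, file.path(labels_dir, paste0(stem, ".txt")))
    if (write_images && !is.null(img$pixels)) {
      save_image(img$pixels, file.path(images_dir, paste0(stem, ".png")))
    }
  }
  invisible(dir)
}
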