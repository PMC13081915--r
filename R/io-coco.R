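#' Read a COCO JSON annotation file
#'
#' Maps the COCO `images`/`annotations`/`categories` arrays onto the
#' package data model. COCO `bbox = [x, y, w, h]` is interpreted as
#' 0-based top-left origin with half-open pixel extent, stored in
#' absolute pixels. Boxes that overhang the frame are clipped to it with
#' a warning (edge-of-field cells do occur); an annotation referencing a
#' missing image or an unknown category is an error.
#'
#' @param path Path to a COCO JSON file.
#' @param categories Optional [category_map()] to enforce; by default the
#'   file's own categories are used (rare flags from the default map
#'   where the names match).
#' @param images_dir Optional directory of raster files; when given,
#'   each image's `file_name` is resolved against it and pixels loaded.
#' @return A [dataset_bundle()].
#' @export
read_coco <- function(path, categories = NULL, images_dir = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("images", "annotations", "categories")) {
    if (is.null(doc[[field]])) {
      stop("not a COCO file: missing '", field, "' array")
    }
  }
  cat_names <- vapply(doc$categories, function(x) as.character(x$name), "")
  cat_ids <- vapply(doc$categories, function(x) as.integer(x$id), 1L)
  if (is.null(categories)) {
    default <- category_map()
    categories <- category_map(
      cat_names,
      rare = intersect(cat_names, rare_names(default)))
  } else if (!all(cat_names %in% categories$name)) {
    stop("COCO file contains categories absent from the supplied map: ",
         paste(setdiff(cat_names, categories$name), collapse = ", "))
  }

  img_meta <- lapply(doc$images, function(im) {
    list(image_id = as.integer(im$id),
         width = as.integer(im$width), height = as.integer(im$height),
         file_name = im$file_name %||% NA_character_)
  })
  img_ids <- vapply(img_meta, `[[`, 1L, "image_id")

  ann_rows <- lapply(doc$annotations, function(a) {
    iid <- as.integer(a$image_id)
    k <- match(iid, img_ids)
    if (is.na(k)) {
      stop("annotation ", a$id, " references missing image ", iid)
    }
    bb <- as.numeric(a$bbox)
    if (length(bb) != 4L) stop("annotation ", a$id, ": bbox must have 4 values")
    ci <- match(as.integer(a$category_id), cat_ids)
    if (is.na(ci)) {
      stop("annotation ", a$id, " references unknown category id ",
           a$category_id)
    }
    data.frame(id = as.integer(a$id), image_id = iid,
               x = bb[1], y = bb[2], w = bb[3], h = bb[4],
               category = cat_names[ci],
               source = as.character(a$source %||% "manual"),
               stringsAsFactors = FALSE)
  })
  ann <- if (length(ann_rows)) {
    do.call(rbind, c(ann_rows, list(make.row.names = FALSE)))
  } else annotation_frame()

  images <- lapply(img_meta, function(im) {
    a <- ann[ann$image_id == im$image_id, , drop = FALSE]
    rownames(a) <- NULL
    clipped <- clip_annotations(a, im$width, im$height)
    if (clipped$n_clipped > 0L) {
      warning(sprintf("image %d: clipped %d box(es) to the frame",
                      im$image_id, clipped$n_clipped), call. = FALSE)
    }
    px <- NULL
    pth <- NULL
    if (!is.null(images_dir) && !is.na(im$file_name)) {
      pth <- file.path(images_dir, im$file_name)
      if (file.exists(pth)) px <- load_image(pth)
    }
    image_record(im$image_id, im$width, im$height, pixels = px,
                 annotations = clipped$annotations, path = pth)
  })
  dataset_bundle(images, categories,
                 provenance = sprintf("read_coco: %s", path))
}

# clip boxes to [0,W) x [0,H); degenerate boxes are left for validate_bundle
clip_annotations <- function(ann, width, height) {
  if (!nrow(ann)) return(list(annotations = ann, n_clipped = 0L))
  x2 <- pmin(ann$x + ann$w, width)
  y2 <- pmin(ann$y + ann$h, height)
  x1 <- pmax(ann$x, 0)
  y1 <- pmax(ann$y, 0)
  n_clipped <- sum(x1 != ann$x | y1 != ann$y |
                     x2 != ann$x + ann$w | y2 != ann$y + ann$h)
  ann$x <- x1; ann$y <- y1
  ann$w <- x2 - x1; ann$h <- y2 - y1
  list(annotations = ann, n_clipped = n_clipped)
}

#' Write a bundle as COCO JSON
#'
#' The bundle is validated first; nothing is written if any invariant is
#' violated. Ids are emitted exactly as stored.
#'
#' @param bundle A valid [dataset_bundle()].
#' @param path Output JSON path.
#' @param images_dir Optional directory; when given, images with pixel
#'   data are saved there as PNG and referenced by `file_name`.
#' @return `path`, invisibly.
#' @export
write_coco <- function(bundle, path, images_dir = NULL) {
  stop_if_invalid(bundle, "write_coco")
  cat_ids <- setNames(bundle$categories$index, bundle$categories$name)
  images <- lapply(bundle$images, function(img) {
    fn <- sprintf("image_%06d.png", img$image_id)
    if (!is.null(images_dir) && !is.null(img$pixels)) {
      if (!dir.exists(images_dir)) {
        dir.create(images_dir, recursive = TRUE)
      }
      save_image(img$pixels, file.path(images_dir, fn))
    }
    list(id = img$image_id, width = img$width, height = img$height,
         file_name = fn)
  })
  ann <- bundle_annotations(bundle)
  annotations <- lapply(seq_len(nrow(ann)), function(i) {
    list(id = ann$id[i], image_id = ann$image_id[i],
         bbox = c(ann$x[i], ann$y[i], ann$w[i], ann$h[i]),
         area = ann$w[i] * ann$h[i],
         category_id = unname(cat_ids[ann$category[i]]),
         iscrowd = 0L,
         source = ann$source[i])
  })
  categories <- lapply(seq_along(bundle$categories$name), function(i) {
    list(id = bundle$categories$index[i],
         name = bundle$categories$name[i],
         supercategory = "cell")
  })
  doc <- list(images = images, annotations = annotations,
              categories = categories)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
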