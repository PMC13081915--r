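#' Category map for RBC phenotypes
#'
#' An ordered set of category names with contiguous 0-based integer
#' indices (the COCO/YOLO class ids) and a flag set marking which
#' categories are treated as "rare" by the data-level imbalance
#' operators.
#'
#' The default five-phenotype map covers discocytes/ovalocytes (DO),
#' echinocytes (E), elongated/sickle cells (ES), granular cells (G) and
#' reticulocytes (R). The default rare set is `{E, ES, G, R}` — every
#' non-majority phenotype — but it is configurable because analyses may
#' instead treat only the scarcest classes (E, G, R) as minorities.
#'
#' @param names Character vector of unique category names, in index order.
#' @param rare Character vector, subset of `names`, flagged as rare.
#' @return An object of class `category_map` with elements `name`
#'   (character), `index` (0-based integer) and `rare` (logical).
#' @examples
#' cm <- category_map()
#' cm$name[cm$rare]
#' @export
category_map <- function(names = c("DO", "E", "ES", "G", "R"),
                         rare = c("E", "ES", "G", "R")) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("category names must be unique")
  if (!all(rare %in% names)) {
    stop("rare categories must be a subset of category names")
  }
  structure(
    list(name = names,
         index = seq_along(names) - 1L,
         rare = names %in% rare),
    class = "category_map"
  )
}

#' @export
print.category_map <- function(x, ...) {
  cat("<category_map> ", length(x$name), " categories\n", sep = "")
  cat(sprintf("  %d: %s%s\n", x$index, x$name,
              ifelse(x$rare, "  (rare)", "")), sep = "")
  invisible(x)
}

rare_names <- function(categories) categories$name[categories$rare]

category_index <- function(categories, name) {
  i <- match(name, categories$name)
  if (anyNA(i)) {
    stop("unknown category: ", paste(unique(name[is.na(i)]), collapse = ", "))
  }
  categories$index[i]
}

#' Empty annotation table
#'
#' Annotations are stored as a data frame with one row per cell box:
#' `id`, `image_id` (integers), `x`, `y`, `w`, `h` (absolute pixels,
#' 0-based top-left origin, half-open extent), `category` (name) and
#' `source` (one of `manual`, `pasted`, `cropped`, `predicted`).
#'
#' @param n Number of blank rows.
#' @return A zero- or `n`-row annotation data frame.
#' @export
annotation_frame <- function(n = 0L) {
  data.frame(
    id = integer(n), image_id = integer(n),
    x = numeric(n), y = numeric(n), w = numeric(n), h = numeric(n),
    category = character(n), source = character(n),
    stringsAsFactors = FALSE
  )
}

ANNOTATION_SOURCES <- c("manual", "pasted", "cropped", "predicted")

#' Construct a full-scope image record
#'
#' @param image_id Integer identifier, unique within a bundle.
#' @param width,height Frame size in pixels.
#' @param pixels Numeric matrix (`height` x `width`, grayscale in
#'   `[0, 1]`), or `NULL` when only geometry is needed.
#' @param annotations Annotation data frame (see [annotation_frame()]).
#' @param path Optional path of the raster file backing `pixels`.
#' @return An object of class `scope_image`.
#' @export
image_record <- function(image_id, width, height, pixels = NULL,
                         annotations = annotation_frame(), path = NULL) {
  if (!is.null(pixels)) {
    if (!is.matrix(pixels)) stop("pixels must be a matrix (grayscale)")
    if (nrow(pixels) != height || ncol(pixels) != width) {
      stop(sprintf("pixel dims %dx%d do not match declared %dx%d (h x w)",
                   nrow(pixels), ncol(pixels), height, width))
    }
  }
  annotations$image_id <- rep(as.integer(image_id), nrow(annotations))
  structure(
    list(image_id = as.integer(image_id),
         width = as.integer(width), height = as.integer(height),
         pixels = pixels, annotations = annotations, path = path),
    class = "scope_image"
  )
}

#' @export
print.scope_image <- function(x, ...) {
  cat(sprintf("<scope_image> id=%d  %dx%d px  %d annotations%s\n",
              x$image_id, x$width, x$height, nrow(x$annotations),
              if (is.null(x$pixels)) "  (pixels not loaded)" else ""))
  invisible(x)
}

#' Construct a dataset bundle
#'
#' The in-memory equivalent of a COCO dataset: a list of
#' [image_record()]s, a [category_map()], and a free-text provenance log
#' appended to by every transformation.
#'
#' @param images List of `scope_image` records.
#' @param categories A `category_map`.
#' @param provenance Character vector of log lines.
#' @return An object of class `scope_bundle`.
#' @export
dataset_bundle <- function(images, categories = category_map(),
                           provenance = character()) {
  structure(
    list(images = images, categories = categories, provenance = provenance),
    class = "scope_bundle"
  )
}

#' @export
print.scope_bundle <- function(x, ...) {
  ann <- bundle_annotations(x)
  cat(sprintf("<scope_bundle> %d images, %d annotations, %d categories\n",
              length(x$images), nrow(ann), length(x$categories$name)))
  if (nrow(ann)) {
    tab <- table(factor(ann$category, levels = x$categories$name))
    cat("  instances:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = " "), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance: ", length(x$provenance), " entries (last: ",
        utils::tail(x$provenance, 1), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.scope_bundle <- function(object, ...) {
  ann <- bundle_annotations(object)
  counts <- table(factor(ann$category, levels = object$categories$name))
  out <- data.frame(
    category = object$categories$name,
    index = object$categories$index,
    rare = object$categories$rare,
    instances = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out
}

#' Collect all annotations of a bundle into one data frame
#'
#' @param bundle A `scope_bundle`.
#' @return Annotation data frame over all images.
#' @export
bundle_annotations <- function(bundle) {
  anns <- lapply(bundle$images, `[[`, "annotations")
  anns <- anns[vapply(anns, nrow, 1L) > 0L]
  if (!length(anns)) return(annotation_frame())
  do.call(rbind, c(anns, list(make.row.names = FALSE)))
}

#' Per-category instance counts of a bundle
#'
#' @param bundle A `scope_bundle`.
#' @return Named integer vector in category order.
#' @export
class_counts <- function(bundle) {
  ann <- bundle_annotations(bundle)
  tab <- table(factor(ann$category, levels = bundle$categories$name))
  setNames(as.integer(tab), bundle$categories$name)
}

next_ids <- function(current_ids, n) {
  start <- if (length(current_ids)) max(current_ids) else 0L
  seq.int(start + 1L, length.out = n)
}

log_provenance <- function(bundle, line) {
  bundle$provenance <- c(bundle$provenance, line)
  bundle
}

#' Validate the internal consistency of a bundle
#'
#' Checks every type invariant of the data model: unique image ids,
#' globally unique annotation ids, positive box extents, boxes inside
#' their frame, categories present in the category map, annotation
#' `image_id` agreeing with the enclosing record, known `source` values,
#' and pixel dimensions matching the declared frame size.
#'
#' @param bundle A `scope_bundle`.
#' @return Character vector of violation messages (empty when the bundle
#'   is valid); each message names the offending id and the rule broken.
#' @examples
#' b <- generate_dataset(n_images = 1, spec = scene_spec(n_cells = 5), seed = 1)
#' validate_bundle(b)
#' @export
validate_bundle <- function(bundle) {
  v <- character()
  ids <- vapply(bundle$images, `[[`, 1L, "image_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    v <- c(v, sprintf("image id %d: duplicated image_id", dup))
  }
  ann <- bundle_annotations(bundle)
  if (nrow(ann)) {
    dup <- unique(ann$id[duplicated(ann$id)])
    if (length(dup)) {
      v <- c(v, sprintf("annotation id %d: duplicated annotation id", dup))
    }
    bad <- !(ann$category %in% bundle$categories$name)
    if (any(bad)) {
      v <- c(v, sprintf("annotation id %d: unknown category '%s'",
                        ann$id[bad], ann$category[bad]))
    }
    bad <- !(ann$source %in% ANNOTATION_SOURCES)
    if (any(bad)) {
      v <- c(v, sprintf("annotation id %d: unknown source '%s'",
                        ann$id[bad], ann$source[bad]))
    }
  }
  for (img in bundle$images) {
    a <- img$annotations
    if (!is.null(img$pixels) &&
        (nrow(img$pixels) != img$height || ncol(img$pixels) != img$width)) {
      v <- c(v, sprintf("image id %d: pixel dims do not match width/height",
                        img$image_id))
    }
    if (!nrow(a)) next
    bad <- a$image_id != img$image_id
    if (any(bad)) {
      v <- c(v, sprintf("annotation id %d: image_id mismatch", a$id[bad]))
    }
    bad <- a$w <= 0 | a$h <= 0
    if (any(bad)) {
      v <- c(v, sprintf("annotation id %d: non-positive box extent", a$id[bad]))
    }
    bad <- a$x < 0 | a$y < 0 | a$x + a$w > img$width | a$y + a$h > img$height
    if (any(bad)) {
      v <- c(v, sprintf("annotation id %d: box extends outside image bounds",
                        a$id[bad]))
    }
  }
  v
}

stop_if_invalid <- function(bundle, context) {
  v <- validate_bundle(bundle)
  if (length(v)) {
    stop(context, ": bundle fails validation:\n  ",
         paste(head(v, 5L), collapse = "\n  "), call. = FALSE)
  }
  invisible(bundle)
}

#' Randomly downsample one category to a target count
#'
#' Keeps exactly `n_keep` annotations of `category`, chosen by seeded
#' uniform sampling without replacement; every other category and all
#' pixel data are untouched. This mirrors the dataset-curation step that
#' thins grossly over-represented phenotypes (e.g. cutting 17,697
#' discocyte crops down to 1,000) before classifier training.
#'
#' @param bundle A `scope_bundle`.
#' @param category Category name to thin.
#' @param n_keep Number of annotations of that category to retain.
#' @param seed Integer seed for the sampling draw.
#' @return The thinned `scope_bundle`.
#' @export
downsample_class <- function(bundle, category, n_keep, seed = 1L) {
  if (!category %in% bundle$categories$name) {
    stop("unknown category: ", category)
  }
  ann <- bundle_annotations(bundle)
  pool <- ann$id[ann$category == category]
  if (n_keep > length(pool)) {
    stop(sprintf("n_keep (%d) exceeds available %s annotations (%d)",
                 n_keep, category, length(pool)))
  }
  keep <- local_seed(seed, pool[sample.int(length(pool), n_keep)])
  drop <- setdiff(pool, keep)
  bundle$images <- lapply(bundle$images, function(img) {
    a <- img$annotations
    img$annotations <- a[!(a$id %in% drop), , drop = FALSE]
    rownames(img$annotations) <- NULL
    img
  })
  log_provenance(bundle, sprintf(
    "downsample_class: %s %d -> %d (seed %d)",
    category, length(pool), n_keep, as.integer(seed)))
}
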