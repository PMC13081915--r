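#' Specification for rare-class cropping
#'
#' @param s Crop side in pixels (default 640).
#' @param k Crops per rare instance (default 2).
#' @param min_visible_fraction Keep an annotation intersecting the crop
#'   window only if at least this fraction of its box area is visible
#'   (default 0.5).
#' @return A `crop_spec` list. Centre offsets are drawn
#'   `Uniform(-s/4, s/4)` per crop.
#' @export
crop_spec <- function(s = 640, k = 2, min_visible_fraction = 0.5) {
  if (s <= 0 || k < 1) stop("s must be positive and k >= 1")
  structure(list(s = s, k = k, min_visible_fraction = min_visible_fraction),
            class = "crop_spec")
}

#' Generate crops centred on rare-class instances
#'
#' For each rare instance with centre `(c_x, c_y)`, produces `k` crops
#' of size `s x s` centred at `(c_x + dx, c_y + dy)` with offsets drawn
#' `Uniform(-s/4, s/4)`; crop windows are clamped to lie inside the
#' frame (never padded). Annotations intersecting a window are kept iff
#' their visible box area is at least `min_visible_fraction` of the
#' original, translated to crop coordinates and clipped, with
#' `source = "cropped"`. The original full-frame record is retained by
#' the caller; this function returns only the new crop records.
#'
#' @param record A `scope_image` with pixel data.
#' @param spec A [crop_spec()].
#' @param rare Rare category names.
#' @param seed Integer seed.
#' @return List of new `scope_image` crop records (image_id 0; assign
#'   bundle-unique ids via [rare_crop_bundle()]). Each crop carries a
#'   `crop_info` attribute with the source instance id, the drawn
#'   offset and the realized window.
#' @export
rare_crop <- function(record, spec = crop_spec(),
                      rare = c("E", "ES", "G", "R"), seed = 1L) {
  s <- spec$s
  if (s > record$width || s > record$height) {
    stop(sprintf("crop size %d exceeds frame %dx%d", s,
                 record$width, record$height))
  }
  a <- record$annotations
  targets <- which(a$category %in% rare)
  if (!length(targets)) stop("record contains no rare-class instance")
  local_seed(seed, {
    crops <- list()
    for (i in targets) {
      ccx <- a$x[i] + a$w[i] / 2
      ccy <- a$y[i] + a$h[i] / 2
      for (rep_i in seq_len(spec$k)) {
        dx <- runif(1, -s / 4, s / 4)
        dy <- runif(1, -s / 4, s / 4)
        x0 <- clamp(round(ccx + dx - s / 2), 0, record$width - s)
        y0 <- clamp(round(ccy + dy - s / 2), 0, record$height - s)
        kept <- crop_annotations(a, x0, y0, s, spec$min_visible_fraction)
        px <- NULL
        if (!is.null(record$pixels)) {
          px <- record$pixels[(y0 + 1):(y0 + s), (x0 + 1):(x0 + s),
                              drop = FALSE]
        }
        cr <- image_record(0L, s, s, pixels = px, annotations = kept)
        attr(cr, "crop_info") <- list(
          instance_id = a$id[i], offset = c(dx = dx, dy = dy),
          window = c(x = x0, y = y0, s = s))
        crops[[length(crops) + 1L]] <- cr
      }
    }
    crops
  })
}

# translate + clip annotations into an s x s window at (x0, y0);
# keep boxes whose visible area fraction meets the threshold
crop_annotations <- function(ann, x0, y0, s, min_visible_fraction) {
  if (!nrow(ann)) return(annotation_frame())
  vx1 <- pmax(ann$x, x0); vy1 <- pmax(ann$y, y0)
  vx2 <- pmin(ann$x + ann$w, x0 + s); vy2 <- pmin(ann$y + ann$h, y0 + s)
  vis <- pmax(0, vx2 - vx1) * pmax(0, vy2 - vy1)
  keep <- vis / (ann$w * ann$h) >= min_visible_fraction
  out <- data.frame(
    id = seq_len(sum(keep)), image_id = rep(0L, sum(keep)),
    x = vx1[keep] - x0, y = vy1[keep] - y0,
    w = (vx2 - vx1)[keep], h = (vy2 - vy1)[keep],
    category = ann$category[keep], source = rep("cropped", sum(keep)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rare-class cropping over a bundle
#'
#' Applies [rare_crop()] to every image holding a rare instance and
#' appends the crops with fresh, bundle-unique image and annotation
#' ids; original full-frame images are retained.
#'
#' @param bundle A `scope_bundle` with pixel data.
#' @param spec A [crop_spec()].
#' @param rare Rare category names (default: the bundle's rare flags).
#' @param seed Integer seed.
#' @return The extended bundle.
#' @export
rare_crop_bundle <- function(bundle, spec = crop_spec(), rare = NULL,
                             seed = 1L) {
  rare <- rare %||% rare_names(bundle$categories)
  seeds <- derive_seeds(seed, length(bundle$images))
  ann <- bundle_annotations(bundle)
  next_img <- max(vapply(bundle$images, `[[`, 1L, "image_id")) + 1L
  next_ann <- if (nrow(ann)) max(ann$id) + 1L else 1L
  new_images <- list()
  for (i in seq_along(bundle$images)) {
    img <- bundle$images[[i]]
    if (!any(img$annotations$category %in% rare)) next
    crops <- rare_crop(img, spec, rare, seed = seeds[i])
    for (cr in crops) {
      cr$image_id <- next_img
      if (nrow(cr$annotations)) {
        cr$annotations$image_id <- next_img
        cr$annotations$id <- seq.int(next_ann,
                                     length.out = nrow(cr$annotations))
        next_ann <- next_ann + nrow(cr$annotations)
      }
      next_img <- next_img + 1L
      new_images[[length(new_images) + 1L]] <- cr
    }
  }
  bundle$images <- c(bundle$images, new_images)
  log_provenance(bundle, sprintf(
    "rare_crop_bundle: added %d crops of %dx%d (k=%d, seed %d)",
    length(new_images), spec$s, spec$s, spec$k, as.integer(seed)))
}
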