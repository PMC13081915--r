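#' Extract a single-cell patch around an annotation
#'
#' The patch window is the annotation box expanded by `margin` pixels
#' on every side and clipped to the frame; the cell's box is recorded
#' in patch-local coordinates.
#'
#' @param record A `scope_image` with pixel data.
#' @param annotation One annotation row of `record`, or an annotation
#'   id.
#' @param margin Expansion in pixels (default 5).
#' @return Object of class `cell_patch`: `pixels`, `box_local`
#'   (`c(x, y, w, h)` relative to the patch origin), `category`,
#'   `origin` (patch top-left in frame coordinates).
#' @export
extract_patch <- function(record, annotation, margin = 5) {
  if (is.numeric(annotation) && length(annotation) == 1L) {
    annotation <- record$annotations[record$annotations$id == annotation, ]
    if (!nrow(annotation)) stop("annotation id not found in record")
  }
  if (is.null(record$pixels)) stop("record carries no pixel data")
  x0 <- max(annotation$x - margin, 0)
  y0 <- max(annotation$y - margin, 0)
  x1 <- min(annotation$x + annotation$w + margin, record$width)
  y1 <- min(annotation$y + annotation$h + margin, record$height)
  win <- box_window(x0, y0, x1 - x0, y1 - y0, record$width, record$height)
  if (is.null(win)) stop("degenerate patch window after clipping")
  structure(
    list(pixels = record$pixels[win$rows, win$cols, drop = FALSE],
         box_local = c(x = annotation$x - x0, y = annotation$y - y0,
                       w = annotation$w, h = annotation$h),
         category = annotation$category,
         origin = c(x = x0, y = y0)),
    class = "cell_patch"
  )
}

#' Constraints for targeted copy-paste augmentation
#'
#' @param patch_margin Margin used when patches were extracted
#'   (default 5 px).
#' @param field_radius_fraction Paste centres must fall inside the
#'   circle of this radius times `min(W, H)` about the frame centre
#'   (default 0.45, the approximate circular imaging region).
#' @param max_iou_with_existing Reject candidate boxes at or above this
#'   IoU against any existing or previously pasted box (default 0.3).
#' @param mask_smoothing_sd Gaussian sd (px) smoothing the elliptical
#'   blend mask (default 3).
#' @param max_attempts_per_paste Placement attempts before skipping a
#'   paste (default 50).
#' @param pastes_per_image Number of patches pasted per image; `NULL`
#'   (default) draws uniformly from 1--3 per image.
#' @param augment_ratio Fraction of images to augment when applied to a
#'   bundle (default 1.0).
#' @param mask_mode Blend mask: `"ellipse"` (smoothed elliptical soft
#'   mask, the default), `"box"` (mask identically 1 over the patch)
#'   or `"zero"` (mask identically 0); the latter two are unit-test
#'   hooks for the blending identity `I = I_crop * M + I_target * (1 - M)`.
#' @return A `paste_constraint` list.
#' @export
paste_constraint <- function(patch_margin = 5, field_radius_fraction = 0.45,
                             max_iou_with_existing = 0.3,
                             mask_smoothing_sd = 3,
                             max_attempts_per_paste = 50,
                             pastes_per_image = NULL,
                             augment_ratio = 1.0,
                             mask_mode = c("ellipse", "box", "zero")) {
  if (max_iou_with_existing < 0 || max_iou_with_existing >= 1) {
    stop("max_iou_with_existing must lie in [0, 1)")
  }
  structure(
    list(patch_margin = patch_margin,
         field_radius_fraction = field_radius_fraction,
         max_iou_with_existing = max_iou_with_existing,
         mask_smoothing_sd = mask_smoothing_sd,
         max_attempts_per_paste = max_attempts_per_paste,
         pastes_per_image = pastes_per_image,
         augment_ratio = augment_ratio,
         mask_mode = match.arg(mask_mode)),
    class = "paste_constraint"
  )
}

# elliptical soft mask for a ph x pw patch, optionally Gaussian-smoothed
paste_mask <- function(ph, pw, mode, smoothing_sd) {
  if (mode == "box") return(matrix(1, ph, pw))
  if (mode == "zero") return(matrix(0, ph, pw))
  cy <- (ph + 1) / 2; cx <- (pw + 1) / 2
  ry <- ph / 2; rx <- pw / 2
  yy <- ((seq_len(ph) - cy) / ry)^2
  xx <- ((seq_len(pw) - cx) / rx)^2
  M <- (outer(yy, xx, "+") <= 1) * 1
  if (smoothing_sd > 0) {
    M <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(M)),
                                             sigma = smoothing_sd)))
    M <- clamp(M, 0, 1)
  }
  M
}

#' Paste rare-cell patches into an image under feasibility constraints
#'
#' For each paste, a candidate centre is sampled uniformly inside the
#' circular imaging region (radius `field_radius_fraction * min(W, H)`
#' about the frame centre); the tentative cell box is rejected if its
#' IoU with any existing or previously pasted box reaches
#' `max_iou_with_existing`. After `max_attempts_per_paste` rejections
#' the paste is skipped (logged in the returned record's `paste_log`
#' attribute). Accepted patches are blended as
#' `I = I_crop * M + I_target * (1 - M)` with `M` the smoothed
#' elliptical mask, and a new annotation (`source = "pasted"`) is added;
#' original annotations and all pixels outside accepted paste windows
#' are untouched.
#'
#' @param record A `scope_image` with pixel data.
#' @param source_patches Non-empty list of [extract_patch()] results.
#' @param constraint A [paste_constraint()].
#' @param seed Integer seed.
#' @param id_start First id for new annotations (default: one past the
#'   record's own maximum, so use explicitly when bundle-wide
#'   uniqueness matters).
#' @return The augmented `scope_image`; attribute `paste_log` records
#'   accepted/skipped pastes.
#' @export
copy_paste_augment <- function(record, source_patches,
                               constraint = paste_constraint(), seed = 1L,
                               id_start = NULL) {
  if (!length(source_patches)) stop("empty source patch set")
  if (is.null(record$pixels)) stop("record carries no pixel data")
  id_start <- id_start %||%
    (if (nrow(record$annotations)) max(record$annotations$id) + 1L else 1L)
  W <- record$width; H <- record$height
  Rmax <- constraint$field_radius_fraction * min(W, H)
  cx0 <- W / 2; cy0 <- H / 2
  local_seed(seed, {
    n_pastes <- constraint$pastes_per_image %||% sample(1:3, 1)
    log_lines <- character()
    boxes <- record$annotations[, c("x", "y", "w", "h"), drop = FALSE]
    for (p in seq_len(n_pastes)) {
      patch <- source_patches[[sample(length(source_patches), 1)]]
      ph <- nrow(patch$pixels); pw <- ncol(patch$pixels)
      bl <- patch$box_local
      placed <- FALSE
      for (attempt in seq_len(constraint$max_attempts_per_paste)) {
        # uniform point in the circular field
        rr <- Rmax * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        cx <- cx0 + rr * cos(th)
        cy <- cy0 + rr * sin(th)
        # cell box centred at the candidate point
        bx <- cx - bl["w"] / 2
        by <- cy - bl["h"] / 2
        cand <- c(bx, by, bl["w"], bl["h"])
        ious <- if (nrow(boxes)) {
          apply(boxes, 1, function(b) iou(cand, as.numeric(b)))
        } else numeric()
        if (length(ious) && max(ious) >= constraint$max_iou_with_existing) {
          next
        }
        # patch window in the frame (patch origin from its local box)
        px0 <- round(bx - bl["x"])
        py0 <- round(by - bl["y"])
        rows <- (py0 + 1):(py0 + ph)
        cols <- (px0 + 1):(px0 + pw)
        ok_r <- rows >= 1 & rows <= H
        ok_c <- cols >= 1 & cols <= W
        if (!any(ok_r) || !any(ok_c)) next
        M <- paste_mask(ph, pw, constraint$mask_mode,
                        constraint$mask_smoothing_sd)
        tgt <- record$pixels[rows[ok_r], cols[ok_c], drop = FALSE]
        crop <- patch$pixels[ok_r, ok_c, drop = FALSE]
        m <- M[ok_r, ok_c, drop = FALSE]
        record$pixels[rows[ok_r], cols[ok_c]] <- crop * m + tgt * (1 - m)
        new_box <- clip_annotations(
          data.frame(id = id_start, image_id = record$image_id,
                     x = px0 + bl[["x"]], y = py0 + bl[["y"]],
                     w = bl[["w"]], h = bl[["h"]],
                     category = patch$category, source = "pasted",
                     stringsAsFactors = FALSE), W, H)$annotations
        record$annotations <- rbind(record$annotations, new_box)
        boxes <- rbind(boxes, new_box[, c("x", "y", "w", "h")])
        id_start <- id_start + 1L
        log_lines <- c(log_lines, sprintf(
          "pasted %s at (%.1f, %.1f) after %d attempt(s)",
          patch$category, cx, cy, attempt))
        placed <- TRUE
        break
      }
      if (!placed) {
        log_lines <- c(log_lines, sprintf(
          "skipped paste %d: no feasible location in %d attempts",
          p, constraint$max_attempts_per_paste))
      }
    }
    rownames(record$annotations) <- NULL
    attr(record, "paste_log") <- log_lines
    record
  })
}

#' Apply targeted copy-paste across a bundle
#'
#' Builds the rare-patch pool from every rare-category annotation in
#' the bundle (extracted with `patch_margin`), then pastes into a
#' seeded fraction `augment_ratio` of images with bundle-unique
#' annotation ids.
#'
#' @param bundle A `scope_bundle` whose images carry pixel data.
#' @param constraint A [paste_constraint()].
#' @param rare Rare category names (default: the bundle's rare flags).
#' @param seed Integer seed.
#' @return The augmented bundle.
#' @export
copy_paste_rare <- function(bundle, constraint = paste_constraint(),
                            rare = NULL, seed = 1L) {
  rare <- rare %||% rare_names(bundle$categories)
  pool <- list()
  for (img in bundle$images) {
    a <- img$annotations
    for (i in which(a$category %in% rare)) {
      pool[[length(pool) + 1L]] <-
        extract_patch(img, a[i, ], margin = constraint$patch_margin)
    }
  }
  if (!length(pool)) stop("bundle contains no rare-class instances")
  ann <- bundle_annotations(bundle)
  next_ann <- if (nrow(ann)) max(ann$id) + 1L else 1L
  seeds <- derive_seeds(seed, length(bundle$images) + 1L)
  augment <- local_seed(seeds[1], {
    runif(length(bundle$images)) <= constraint$augment_ratio
  })
  n_pasted <- 0L
  for (i in seq_along(bundle$images)) {
    if (!augment[i]) next
    out <- copy_paste_augment(bundle$images[[i]], pool, constraint,
                              seed = seeds[i + 1L], id_start = next_ann)
    added <- nrow(out$annotations) - nrow(bundle$images[[i]]$annotations)
    n_pasted <- n_pasted + added
    next_ann <- next_ann + added
    bundle$images[[i]] <- out
  }
  log_provenance(bundle, sprintf(
    "copy_paste_rare: %d patches pasted over %d images (seed %d)",
    n_pasted, sum(augment), as.integer(seed)))
}
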