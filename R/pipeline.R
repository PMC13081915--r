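# Two-step pipeline: detector -> crop/standardize -> (train-time
# geometric augmentation) -> per-fold classifiers -> confidence-weighted
# ensemble vote -> back-annotation.

#' Crop detections and standardize them for classification
#'
#' Each detection box (optionally expanded by `margin`) is extracted,
#' padded to a square with the median background intensity around the
#' cell (the median of the crop window's border pixels, so aspect
#' ratio — a key elongation cue — is preserved rather than distorted by
#' anisotropic resizing) and resized to `target_side x target_side`. Pad amounts, origin and
#' scale are recorded so patch coordinates map back to the frame.
#' Zero-area boxes are skipped with a log entry; order is preserved.
#'
#' @param record A `scope_image` with pixel data.
#' @param detections Detection data frame (`x, y, w, h`, plus
#'   `id`/`confidence` carried through).
#' @param target_side Output side length (default 224).
#' @param margin Box expansion in pixels before cropping (default 0).
#' @return List of `patch_record`s: `pixels`, `detection` (the input
#'   row), `origin`, `pad`, `scale`, `target_side`; attribute
#'   `skipped` lists skipped detection ids.
#' @export
crop_and_standardize <- function(record, detections, target_side = 224,
                                 margin = 0) {
  if (is.null(record$pixels)) stop("record carries no pixel data")
  detections <- ensure_det_ids(detections)
  out <- list()
  skipped <- integer()
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    x0 <- max(d$x - margin, 0)
    y0 <- max(d$y - margin, 0)
    x1 <- min(d$x + d$w + margin, record$width)
    y1 <- min(d$y + d$h + margin, record$height)
    win <- box_window(x0, y0, x1 - x0, y1 - y0, record$width, record$height)
    if (is.null(win) || length(win$rows) < 2 || length(win$cols) < 2) {
      skipped <- c(skipped, d$id)
      next
    }
    px <- record$pixels[win$rows, win$cols, drop = FALSE]
    hh <- nrow(px); ww <- ncol(px)
    # local background: median of the window border, so the padding
    # matches the illumination around this cell, not the frame median
    fill <- median(c(px[1, ], px[hh, ], px[, 1], px[, ww]))
    side <- max(hh, ww)
    pad_top <- (side - hh) %/% 2
    pad_left <- (side - ww) %/% 2
    sq <- matrix(fill, side, side)
    sq[pad_top + seq_len(hh), pad_left + seq_len(ww)] <- px
    std <- if (side == target_side) {
      sq
    } else {
      t(EBImage::imageData(EBImage::resize(EBImage::Image(t(sq)),
                                           w = target_side,
                                           h = target_side)))
    }
    out[[length(out) + 1L]] <- structure(
      list(pixels = std, detection = d,
           origin = c(x = win$cols[1] - 1, y = win$rows[1] - 1),
           pad = c(left = pad_left, top = pad_top),
           scale = side / target_side,
           target_side = target_side),
      class = "patch_record")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Map a standardized-patch coordinate back to frame coordinates
#'
#' Inverts the pad-and-resize transform of [crop_and_standardize()].
#'
#' @param patch A `patch_record`.
#' @param xy Length-2 coordinate `c(x, y)` in patch pixels (0-based).
#' @return Frame coordinate `c(x, y)`.
#' @export
patch_to_frame <- function(patch, xy) {
  c(x = unname(xy[1] * patch$scale - patch$pad[["left"]] +
                 patch$origin[["x"]]),
    y = unname(xy[2] * patch$scale - patch$pad[["top"]] +
                 patch$origin[["y"]]))
}

#' Geometric train-time augmentation policy
#'
#' Random horizontal/vertical flips, small-angle rotation, limited
#' translation and mild isotropic scaling; no photometric transform of
#' any kind, so intensity statistics carry morphology information only.
#' Applied to training patches only.
#'
#' @param p_hflip,p_vflip Flip probabilities (default 0.5 each).
#' @param rotation_limit Max |rotation| in degrees (default 12).
#' @param translation_limit Max |shift| as a fraction of the patch side
#'   (default 0.05).
#' @param scale_range Isotropic scale range (default `c(0.95, 1.05)`).
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(p_hflip = 0.5, p_vflip = 0.5,
                           rotation_limit = 12, translation_limit = 0.05,
                           scale_range = c(0.95, 1.05)) {
  structure(
    list(p_hflip = p_hflip, p_vflip = p_vflip,
         rotation_limit = rotation_limit,
         translation_limit = translation_limit,
         scale_range = scale_range),
    class = "augment_policy"
  )
}

#' Apply seeded geometric augmentation to one patch
#'
#' Draws flips, a rotation angle in `[-limit, +limit]`, translations
#' within the fraction limit and a scale from the range, then resamples
#' bilinearly about the patch centre (out-of-frame samples take the
#' patch border median). Output shape equals input shape. With an
#' identity policy (zero probabilities and limits, unit scale) the
#' patch is returned bit-unchanged.
#'
#' @param patch Numeric pixel matrix.
#' @param policy An [augment_policy()].
#' @param seed Integer seed.
#' @return Augmented pixel matrix, same dimensions.
#' @export
geometric_augment <- function(patch, policy = augment_policy(), seed = 1L) {
  local_seed(seed, {
    h <- nrow(patch); w <- ncol(patch)
    hflip <- runif(1) < policy$p_hflip
    vflip <- runif(1) < policy$p_vflip
    ang <- runif(1, -policy$rotation_limit, policy$rotation_limit) * pi / 180
    tx <- runif(1, -policy$translation_limit, policy$translation_limit) * w
    ty <- runif(1, -policy$translation_limit, policy$translation_limit) * h
    sc <- runif(1, policy$scale_range[1], policy$scale_range[2])
    if (hflip) patch <- patch[, rev(seq_len(w)), drop = FALSE]
    if (vflip) patch <- patch[rev(seq_len(h)), , drop = FALSE]
    if (ang == 0 && tx == 0 && ty == 0 && sc == 1) {
      return(patch)
    }
    fill <- median(c(patch[1, ], patch[h, ], patch[, 1], patch[, w]))
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    # inverse map: output pixel -> input location
    yy <- matrix(rep(seq_len(h), w), h, w) - cy - ty
    xx <- matrix(rep(seq_len(w), each = h), h, w) - cx - tx
    xi <- (cos(-ang) * xx - sin(-ang) * yy) / sc + cx
    yi <- (sin(-ang) * xx + cos(-ang) * yy) / sc + cy
    bilinear_sample(patch, xi, yi, fill)
  })
}

bilinear_sample <- function(img, xi, yi, fill) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, nrow(r), ncol(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its records cyclically
#' across folds from a random starting fold, so per-class counts
#' differ by at most one across folds and the folds partition the
#' input.
#'
#' @param labels Class label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per record.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop("class with fewer than k records: ", paste(small, collapse = ", "))
  }
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1)
      folds[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1
    }
  })
  folds
}

#' Confidence-weighted ensemble vote
#'
#' Each fold model contributes its maximum softmax confidence to the
#' score of its own argmax class; the class with the largest
#' accumulated score wins. Exact ties are broken toward the lowest
#' category index and flagged. `mode = "mean"` instead averages the
#' full probability vectors (an alternative accumulation rule).
#'
#' @param probs Matrix (models x categories) of probability vectors,
#'   or a list of such vectors; each row must be non-negative and sum
#'   to 1 within 1e-6.
#' @param mode `"max_confidence"` (default) or `"mean"`.
#' @return Object of class `ensemble_prediction`: `category` (winner),
#'   `scores`, `per_model` (argmax + max confidence per model), `tie`.
#' @export
ensemble_vote <- function(probs, mode = c("max_confidence", "mean")) {
  mode <- match.arg(mode)
  if (is.list(probs)) probs <- do.call(rbind, probs)
  if (is.null(colnames(probs))) {
    colnames(probs) <- paste0("class", seq_len(ncol(probs)))
  }
  if (any(probs < -1e-9)) stop("probability vectors must be non-negative")
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("probability vectors must sum to 1 (tolerance 1e-6)")
  }
  arg <- apply(probs, 1, which.max)
  conf <- probs[cbind(seq_len(nrow(probs)), arg)]
  scores <- setNames(numeric(ncol(probs)), colnames(probs))
  if (mode == "max_confidence") {
    for (m in seq_len(nrow(probs))) {
      scores[arg[m]] <- scores[arg[m]] + conf[m]
    }
  } else {
    scores[] <- colMeans(probs)
  }
  top <- which(abs(scores - max(scores)) < 1e-12)
  structure(
    list(category = colnames(probs)[top[1]],
         scores = scores,
         per_model = data.frame(model = seq_len(nrow(probs)),
                                argmax = colnames(probs)[arg],
                                confidence = conf),
         tie = length(top) > 1),
    class = "ensemble_prediction"
  )
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %s (score %.3f%s)\n", x$category,
              max(x$scores), if (x$tie) ", tie broken to lowest index" else ""))
  invisible(x)
}

#' Configuration of the two-step pipeline
#'
#' @param conf_threshold Minimum detector confidence kept
#'   (default 0.25).
#' @param target_side Standardized patch side (default 224).
#' @param crop_margin Box expansion before cropping (default 0).
#' @param vote_mode Ensemble accumulation rule (see [ensemble_vote()]).
#' @return A `two_step_config` list.
#' @export
two_step_config <- function(conf_threshold = 0.25, target_side = 224,
                            crop_margin = 0,
                            vote_mode = "max_confidence") {
  structure(
    list(conf_threshold = conf_threshold, target_side = target_side,
         crop_margin = crop_margin, vote_mode = vote_mode),
    class = "two_step_config"
  )
}

#' Run the decoupled detect-then-classify pipeline on one image
#'
#' Detect, filter by confidence, crop and standardize, classify every
#' patch with each fold model, vote, and back-annotate the image: the
#' returned record copy carries the predictions as annotations with
#' `source = "predicted"`. Deterministic whenever the supplied
#' components are.
#'
#' @param record A `scope_image` with pixel data.
#' @param detector Function `record -> detection data frame`
#'   (`x, y, w, h, confidence`, optional `category`).
#' @param classifiers List of functions `patch matrix -> named
#'   probability vector` (the fold models; one suffices).
#' @param config A [two_step_config()].
#' @return List: `record` (copy with predicted annotations),
#'   `predictions` (one row per kept detection with voted `category`,
#'   `vote_score`, `tie`, detector `confidence`), `label_lines`
#'   (overlay-ready YOLO-style text: `class cx cy w h conf`).
#' @export
run_two_step <- function(record, detector, classifiers,
                         config = two_step_config()) {
  stopifnot(is.function(detector), length(classifiers) >= 1)
  det <- detector(record)
  if (!is.data.frame(det) || !all(c("x", "y", "w", "h", "confidence")
                                  %in% names(det))) {
    stop("detector contract violated: must return a data frame with ",
         "x, y, w, h, confidence")
  }
  det <- det[det$confidence >= config$conf_threshold, , drop = FALSE]
  det <- ensure_det_ids(det)
  out <- record
  out$annotations <- annotation_frame()
  if (!nrow(det)) {
    return(list(record = out,
                predictions = cbind(annotation_frame(),
                                    confidence = numeric(),
                                    vote_score = numeric(),
                                    tie = logical()),
                label_lines = character()))
  }
  patches <- crop_and_standardize(record, det, config$target_side,
                                  config$crop_margin)
  preds <- list()
  for (p in patches) {
    probs <- lapply(seq_along(classifiers), function(m) {
      pr <- classifiers[[m]](p$pixels)
      if (is.null(pr) || abs(sum(pr) - 1) > 1e-6) {
        stop("classifier contract violated by fold model ", m)
      }
      pr
    })
    vote <- ensemble_vote(probs, mode = config$vote_mode)
    d <- p$detection
    preds[[length(preds) + 1L]] <- data.frame(
      id = d$id, image_id = record$image_id,
      x = d$x, y = d$y, w = d$w, h = d$h,
      category = vote$category, source = "predicted",
      confidence = d$confidence,
      vote_score = max(vote$scores), tie = vote$tie,
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  out$annotations <- preds[, c("id", "image_id", "x", "y", "w", "h",
                               "category", "source")]
  cm <- category_map(unique(c(category_map()$name, preds$category)))
  label_lines <- sprintf(
    "%d %.6f %.6f %.6f %.6f %.4f",
    category_index(cm, preds$category),
    (preds$x + preds$w / 2) / record$width,
    (preds$y + preds$h / 2) / record$height,
    preds$w / record$width, preds$h / record$height,
    preds$confidence)
  list(record = out, predictions = preds, label_lines = label_lines)
}
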