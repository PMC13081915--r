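# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive re-implementations (explicit loops, exhaustive
# search) kept separate from the package's code paths.

# small hand-built bundle: 2 images, known boxes, no pixels needed
tiny_bundle <- function(with_pixels = FALSE) {
  ann1 <- data.frame(
    id = 1:3, image_id = 1L,
    x = c(10, 40, 70), y = c(10, 40, 20), w = c(20, 18, 16),
    h = c(20, 18, 16),
    category = c("DO", "ES", "G"), source = "manual",
    stringsAsFactors = FALSE)
  ann2 <- data.frame(
    id = 4:5, image_id = 2L,
    x = c(15, 60), y = c(25, 55), w = c(22, 20), h = c(22, 20),
    category = c("DO", "R"), source = "manual",
    stringsAsFactors = FALSE)
  px <- if (with_pixels) matrix(0.8, 120, 120) else NULL
  dataset_bundle(
    list(image_record(1L, 120, 120, pixels = px, annotations = ann1),
         image_record(2L, 120, 120, pixels = px, annotations = ann2)),
    category_map())
}

# independent IoU (same half-open convention, written from the areas)
ref_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
  inter <- max(0, x2 - x1) * max(0, y2 - y1)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# exhaustive maximum bipartite matching: largest number of valid
# (detection, ground-truth) pairs; recursion over detections
brute_max_matching <- function(gt, det, thr, class_agnostic = TRUE) {
  n_gt <- nrow(gt)
  valid <- matrix(FALSE, nrow(det), n_gt)
  for (j in seq_len(nrow(det))) {
    for (i in seq_len(n_gt)) {
      same_img <- is.null(gt$image_id) ||
        gt$image_id[i] == det$image_id[j]
      same_cat <- class_agnostic || is.null(gt$category) ||
        gt$category[i] == det$category[j]
      if (same_img && same_cat &&
          ref_iou(as.numeric(det[j, c("x", "y", "w", "h")]),
                  as.numeric(gt[i, c("x", "y", "w", "h")])) >= thr) {
        valid[j, i] <- TRUE
      }
    }
  }
  recurse <- function(j, used) {
    if (j > nrow(det)) return(0L)
    best <- recurse(j + 1L, used)  # leave detection j unmatched
    for (i in which(valid[j, ] & !used)) {
      used[i] <- TRUE
      best <- max(best, 1L + recurse(j + 1L, used))
      used[i] <- FALSE
    }
    best
  }
  if (!nrow(det) || !n_gt) return(0L)
  recurse(1L, rep(FALSE, n_gt))
}

# independent per-class metrics via a confusion matrix
ref_class_metrics <- function(true, pred, cats) {
  cm <- table(factor(true, cats), factor(pred, cats))
  out <- lapply(cats, function(cc) {
    tp <- cm[cc, cc]
    fp <- sum(cm[, cc]) - tp
    fn <- sum(cm[cc, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
  })
  do.call(rbind, out)
}

# independent AP: explicit loops, own iou, own interpolation
ref_average_precision <- function(gt, det, category, thr) {
  g <- gt[gt$category == category, , drop = FALSE]
  d <- det[!is.na(det$category) & det$category == category, , drop = FALSE]
  if (!nrow(g)) return(NA_real_)
  if (!nrow(d)) return(0)
  d <- d[order(-d$confidence, d$id), , drop = FALSE]
  taken <- rep(FALSE, nrow(g))
  tp <- integer(nrow(d))
  for (j in seq_len(nrow(d))) {
    best_i <- 0L
    best_iou <- -1
    for (i in seq_len(nrow(g))) {
      if (taken[i]) next
      if (g$image_id[i] != d$image_id[j]) next
      ov <- ref_iou(as.numeric(d[j, c("x", "y", "w", "h")]),
                    as.numeric(g[i, c("x", "y", "w", "h")]))
      if (ov < thr) next
      if (ov > best_iou + 1e-12 ||
          (abs(ov - best_iou) <= 1e-12 && g$id[i] < g$id[best_i])) {
        best_iou <- ov
        best_i <- i
      }
    }
    if (best_i > 0L) {
      taken[best_i] <- TRUE
      tp[j] <- 1L
    }
  }
  rec <- cumsum(tp) / nrow(g)
  prec <- cumsum(tp) / seq_along(tp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pmax_r <- 0
    for (j in seq_along(rec)) {
      if (rec[j] >= r - 1e-12 && prec[j] > pmax_r) pmax_r <- prec[j]
    }
    total <- total + pmax_r
  }
  total / 101
}

# random micro-instance of boxes for matching/AP fuzzing
random_boxes <- function(n, cats = c("A", "B"), with_conf = FALSE,
                         frame = 60) {
  out <- data.frame(
    id = seq_len(n), image_id = sample(1:2, n, replace = TRUE),
    x = runif(n, 0, frame - 15), y = runif(n, 0, frame - 15),
    w = runif(n, 5, 15), h = runif(n, 5, 15),
    category = sample(cats, n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (with_conf) out$confidence <- round(runif(n), 3)
  out
}

# small synthetic scene shared across tests (cached per session)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene(scene_spec(width = 800, height = 600,
                                          n_cells = 25, seed = 42))
    }
    cache
  }
})
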