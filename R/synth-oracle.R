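# Oracle stand-ins for the two pluggable pipeline components: a
# detector that perturbs ground truth under a controlled noise model,
# and a classifier driven by handcrafted morphology features. They let
# the pipeline and the evaluation protocol be exercised end to end with
# known error rates and no trained weights.

#' Noise model for the oracle detector
#'
#' @param box_jitter_sd Gaussian sd (px) added to box corners.
#' @param miss_rate Probability of dropping each ground-truth box.
#' @param spurious_rate Expected number of false boxes per image
#'   (Poisson).
#' @return An `oracle_noise` list. All-zero (the default) makes the
#'   detector reproduce ground truth exactly with confidence 1.
#' @export
oracle_noise <- function(box_jitter_sd = 0, miss_rate = 0,
                         spurious_rate = 0) {
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must lie in [0, 1]")
  structure(list(box_jitter_sd = box_jitter_sd, miss_rate = miss_rate,
                 spurious_rate = spurious_rate),
            class = "oracle_noise")
}

#' Oracle detector: ground truth under a controlled noise model
#'
#' Emits each ground-truth box perturbed by Gaussian corner jitter,
#' dropped independently with probability `miss_rate`, plus
#' `Poisson(spurious_rate)` false boxes placed inside the circular
#' field. Reported confidence decays with the realized jitter
#' (exactly 1 when the noise model is all-zero); spurious boxes get
#' low-to-middling confidences.
#'
#' @param record A `scope_image` with ground-truth annotations.
#' @param noise An [oracle_noise()].
#' @param seed Integer seed.
#' @return Detection data frame: `id, image_id, x, y, w, h, confidence,
#'   category` (category of the underlying ground truth; `NA` for
#'   spurious boxes).
#' @export
oracle_detector <- function(record, noise = oracle_noise(), seed = 1L) {
  ann <- record$annotations
  local_seed(seed, {
    keep <- if (nrow(ann)) {
      runif(nrow(ann)) >= noise$miss_rate
    } else logical()
    det <- ann[keep, , drop = FALSE]
    n <- nrow(det)
    conf <- rep(1, n)
    if (n && noise$box_jitter_sd > 0) {
      j <- matrix(rnorm(4 * n, sd = noise$box_jitter_sd), n, 4)
      x2 <- det$x + det$w + j[, 3]
      y2 <- det$y + det$h + j[, 4]
      det$x <- det$x + j[, 1]
      det$y <- det$y + j[, 2]
      det$w <- pmax(x2 - det$x, 2)
      det$h <- pmax(y2 - det$y, 2)
      d <- rowMeans(abs(j))
      conf <- clamp(exp(-d / (2 * noise$box_jitter_sd)), 1e-3, 1)
    }
    out <- data.frame(
      id = seq_len(n), image_id = rep(record$image_id, n),
      x = det$x, y = det$y, w = det$w, h = det$h,
      confidence = conf, category = det$category,
      stringsAsFactors = FALSE)
    n_spur <- if (noise$spurious_rate > 0) rpois(1, noise$spurious_rate) else 0L
    if (n_spur > 0) {
      Rf <- 0.45 * min(record$width, record$height)
      rr <- Rf * sqrt(runif(n_spur))
      th <- runif(n_spur, 0, 2 * pi)
      sw <- runif(n_spur, 15, 40)
      sh <- runif(n_spur, 15, 40)
      spur <- data.frame(
        id = n + seq_len(n_spur), image_id = record$image_id,
        x = record$width / 2 + rr * cos(th) - sw / 2,
        y = record$height / 2 + rr * sin(th) - sh / 2,
        w = sw, h = sh,
        confidence = runif(n_spur, 0.3, 0.7),
        category = NA_character_, stringsAsFactors = FALSE)
      out <- rbind(out, spur)
    }
    if (nrow(out)) {
      cl <- clip_annotations(out, record$width, record$height)
      out <- cl$annotations
    }
    rownames(out) <- NULL
    out
  })
}

#' Handcrafted morphology features of a single-cell patch
#'
#' Segments the dark cell body (pixels below the border-estimated
#' background), keeps the connected component nearest the patch
#' centre, and measures: `elongation` (square root of the second-moment
#' eigenvalue ratio), `spike` (high-frequency coefficient of variation
#' of the boundary radius over angle, after removing the smooth
#' low-order trend so smooth elongation does not register as
#' spiculation), `dark_frac` / `bright_frac` (fraction of interior
#' pixels well below / above the body median — granular speckles and
#' reticular mesh respectively) and `ring_contrast` (centre minus rim
#' mean intensity, the central-pallor signature of a biconcave disc).
#' All five are invariant to patch rescaling.
#'
#' @param patch Numeric pixel matrix of one cell (any size).
#' @return Named numeric feature vector with attribute `blank = TRUE`
#'   when no cell body was found.
#' @export
patch_features <- function(patch) {
  blank <- c(elongation = 1, spike = 0, dark_frac = 0, bright_frac = 0,
             ring_contrast = 0)
  h <- nrow(patch); w <- ncol(patch)
  if (h < 5 || w < 5) {
    attr(blank, "blank") <- TRUE
    return(blank)
  }
  border <- c(patch[1, ], patch[h, ], patch[, 1], patch[, w])
  bg <- median(border)
  mask <- patch < bg - 0.1
  if (sum(mask) < 12) {
    attr(blank, "blank") <- TRUE
    return(blank)
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  lab <- t(EBImage::imageData(lab))
  # component nearest the patch centre (weighted toward large ones)
  comps <- sort(unique(lab[lab > 0]))
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  pick <- comps[1]; best <- Inf
  for (cc in comps) {
    idx <- which(lab == cc, arr.ind = TRUE)
    if (nrow(idx) < 12) next
    d <- sqrt((mean(idx[, 1]) - cy0)^2 + (mean(idx[, 2]) - cx0)^2)
    score <- d - 0.1 * sqrt(nrow(idx))
    if (score < best) {
      best <- score
      pick <- cc
    }
  }
  roi <- which(lab == pick, arr.ind = TRUE)
  if (nrow(roi) < 12) {
    attr(blank, "blank") <- TRUE
    return(blank)
  }
  ys <- roi[, 1]; xs <- roi[, 2]
  vals <- patch[roi]
  cy <- mean(ys); cx <- mean(xs)
  dy <- ys - cy; dx <- xs - cx
  # second-moment elongation
  C <- cov(cbind(dx, dy))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  elongation <- sqrt(max(ev) / max(min(ev), 1e-9))
  # boundary radius profile over 36 angle bins
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  bin <- pmin(floor((ang + pi) / (2 * pi) * 36) + 1, 36)
  rb <- vapply(1:36, function(b) {
    v <- r[bin == b]
    if (length(v)) max(v) else NA_real_
  }, 0)
  rb <- fill_circular(rb)
  smooth <- circular_ma(rb, 5)
  spike <- sd(rb - smooth) / max(mean(rb), 1e-9)
  # normalized radius per pixel (against the smoothed boundary)
  u <- r / pmax(smooth[bin], 1e-9)
  interior <- u < 0.55
  rim <- u >= 0.65 & u < 0.95
  int_med <- if (sum(interior) >= 5) median(vals[interior]) else median(vals)
  dark_frac <- if (sum(interior) >= 5) {
    mean(vals[interior] < int_med - 0.15)
  } else 0
  bright_frac <- if (sum(interior) >= 5) {
    mean(vals[interior] > int_med + 0.12)
  } else 0
  ring_contrast <- if (sum(interior) >= 5 && sum(rim) >= 5) {
    mean(vals[interior]) - mean(vals[rim])
  } else 0
  c(elongation = elongation, spike = spike, dark_frac = dark_frac,
    bright_frac = bright_frac, ring_contrast = ring_contrast)
}

fill_circular <- function(x) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  for (i in which(is.na(x))) {
    for (off in 1:n) {
      cand <- c(x[(i - 1 - off) %% n + 1], x[(i - 1 + off) %% n + 1])
      cand <- cand[!is.na(cand)]
      if (length(cand)) {
        x[i] <- mean(cand)
        break
      }
    }
  }
  x
}

circular_ma <- function(x, k) {
  n <- length(x)
  half <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    mean(x[((i - 1 + seq(-half, half)) %% n) + 1])
  }, 0)
}

# per-class feature centroids and scales for the oracle classifier;
# calibrated once against noiseless archetype renderings
ORACLE_CENTROIDS <- rbind(
  DO = c(1.00, 0.012, 0.00, 0.00, 0.25),
  E  = c(1.01, 0.170, 0.00, 0.00, 0.00),
  ES = c(3.00, 0.090, 0.00, 0.00, 0.00),
  G  = c(1.00, 0.013, 0.19, 0.00, -0.02),
  R  = c(1.01, 0.016, 0.00, 0.24, 0.00)
)
ORACLE_SCALES <- c(0.40, 0.040, 0.06, 0.06, 0.05)

#' Oracle classifier over handcrafted morphology features
#'
#' Scores a single-cell patch against per-archetype feature centroids
#' (Gaussian kernel on standardized feature distance) and returns a
#' normalized probability vector. On noiseless archetype renderings the
#' argmax equals the generating category; a blank patch yields a
#' uniform vector flagged with attribute `blank`.
#'
#' @param patch Numeric pixel matrix of one cell.
#' @param categories Category names (default the five phenotypes).
#' @return Named probability vector summing to 1; attribute `blank` set
#'   when no cell body was found.
#' @export
oracle_classifier <- function(patch, categories = rownames(ORACLE_CENTROIDS)) {
  f <- patch_features(patch)
  if (isTRUE(attr(f, "blank"))) {
    p <- setNames(rep(1 / length(categories), length(categories)),
                  categories)
    attr(p, "blank") <- TRUE
    return(p)
  }
  mu <- ORACLE_CENTROIDS[categories, , drop = FALSE]
  z2 <- rowSums(sweep(sweep(mu, 2, f), 2, ORACLE_SCALES, "/")^2)
  s <- exp(-(z2 - min(z2)) / 2)
  setNames(s / sum(s), categories)
}
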