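test_that("class weight schemes satisfy their algebraic identities", {
  # equal counts -> unit weights for inverse and sqrt_inverse
  eq <- rep(50, 5)
  expect_equal(unname(class_weights(eq, "inverse")), rep(1, 5))
  expect_equal(unname(class_weights(eq, "sqrt_inverse")), rep(1, 5))
  # inverse: sum n_i w_i = N exactly; sqrt scheme is its square root
  set.seed(2)
  for (rep_i in 1:20) {
    n <- sample(1:2000, sample(2:8, 1))
    w <- class_weights(n, "inverse")
    expect_equal(sum(n * w), sum(n))
    expect_equal(class_weights(n, "sqrt_inverse"), sqrt(w))
  }
  # effective number: n_i = 1 gives E_i = 1, w_i = 1 for any beta
  for (beta in c(0, 0.5, 0.99, 0.9999)) {
    expect_equal(unname(class_weights(c(1, 1), "effective_number",
                                      beta = beta)), c(1, 1))
  }
  expect_error(class_weights(c(A = 10, B = 0)), "class B")
})

test_that("inverse weights on the curated single-cell counts", {
  counts <- c(DO = 871, E = 264, ES = 799, G = 882, R = 263)
  w <- class_weights(counts, "inverse")
  expect_equal(sum(counts), 3079)
  expect_equal(unname(w["DO"]), 3079 / (5 * 871), tolerance = 1e-12)
  expect_equal(round(unname(w["DO"]), 5), 0.70700)
  expect_equal(round(unname(w["E"]), 5), 2.33258)
})

test_that("focal loss closed forms and monotonicity", {
  expect_equal(focal_loss(1), 0)
  p <- c(0.1, 0.3, 0.7, 0.95)
  expect_equal(focal_loss(p, alpha_t = 1, gamma = 0), -log(p))
  expect_equal(focal_loss(0.5), 0.25 * 0.25 * log(2), tolerance = 1e-12)
  # strictly decreasing in p_t for any fixed parameters
  for (gamma in c(0, 0.5, 2, 5)) {
    grid <- focal_loss(seq(0.05, 1, by = 0.05), gamma = gamma)
    expect_true(all(diff(grid) < 0))
  }
  expect_error(focal_loss(0), "0, 1")
  expect_error(focal_loss(0.5, gamma = -1), "gamma")
})

test_that("duplication factor follows the oversampling formula", {
  expect_equal(duplication_factor(1000, 100, 0.5), 5L)
  expect_equal(duplication_factor(100, 1000, 0.5), 1L)  # floors at 1
  expect_equal(duplication_factor(300, 100, 0.5), 2L)   # 1.5 rounds half-up
  expect_equal(duplication_factor(290, 100, 0.5), 1L)   # 1.45 rounds down
  expect_error(duplication_factor(100, 0), "positive")
})

test_that("oversample_rare duplicates rare images exactly k times", {
  # 10 DO on image 1 (no rares), 1 R + 1 DO on image 2 -> k = round(11*0.5/1)=6
  ann1 <- data.frame(id = 1:10, image_id = 1L, x = (0:9) * 10, y = 5,
                     w = 8, h = 8, category = "DO", source = "manual",
                     stringsAsFactors = FALSE)
  ann2 <- data.frame(id = 11:12, image_id = 2L, x = c(5, 30), y = 5,
                     w = 8, h = 8, category = c("R", "DO"),
                     source = "manual", stringsAsFactors = FALSE)
  b <- dataset_bundle(
    list(image_record(1L, 120, 40, annotations = ann1),
         image_record(2L, 120, 40, annotations = ann2)),
    category_map())
  out <- oversample_rare(b, ratio = 0.5)
  k <- attr(out, "duplication_factor")
  expect_equal(k, duplication_factor(11, 1, 0.5))
  # the rare image occurs k times (matched on annotation signature)
  sig <- vapply(out$images, function(img) {
    paste(img$annotations$x, img$annotations$category, collapse = ";")
  }, "")
  expect_equal(sum(sig == sig[2]), k)
  expect_equal(sum(sig == sig[1]), 1)
  expect_length(validate_bundle(out), 0)
  # annotation count bookkeeping: input + (k-1) * (rows on rare images)
  expect_equal(nrow(bundle_annotations(out)), 12 + (k - 1) * 2)
})

test_that("oversample with k = 1 is the identity", {
  b <- tiny_bundle()
  out <- oversample_rare(b, ratio = 0.01)
  expect_equal(attr(out, "duplication_factor"), 1L)
  expect_identical(bundle_annotations(out), bundle_annotations(b))
  expect_error(oversample_rare(b, rare = character(0)), "no rare")
})

test_that("extract_patch window arithmetic and pixel fidelity", {
  px <- matrix(runif(100 * 100), 100, 100)
  ann <- data.frame(id = 1L, image_id = 1L, x = 10, y = 10, w = 20, h = 20,
                    category = "E", source = "manual",
                    stringsAsFactors = FALSE)
  rec <- image_record(1L, 100, 100, pixels = px, annotations = ann)
  p <- extract_patch(rec, ann, margin = 5)
  expect_equal(dim(p$pixels), c(30, 30))
  expect_equal(unname(p$origin), c(5, 5))
  expect_equal(unname(p$box_local), c(5, 5, 20, 20))
  expect_identical(p$pixels, px[6:35, 6:35])
  # corner box clips to the frame without out-of-range reads
  ann2 <- transform(ann, x = 0, y = 0, w = 10, h = 10)
  p2 <- extract_patch(rec, ann2, margin = 5)
  expect_equal(dim(p2$pixels), c(15, 15))
  expect_equal(unname(p2$origin), c(0, 0))
})

test_that("copy-paste blending follows the mask identity", {
  img <- small_scene()
  a <- img$annotations[img$annotations$category != "DO", ][1, ]
  patch <- extract_patch(img, a, margin = 5)
  base <- paste_constraint(pastes_per_image = 1)

  # M == 0: output image equals input image bit for bit
  z <- copy_paste_augment(img, list(patch),
                          modifyList(base, list(mask_mode = "zero")),
                          seed = 3)
  expect_identical(z$pixels, img$pixels)
  expect_equal(nrow(z$annotations), nrow(img$annotations) + 1)

  # M == 1: pasted region equals the source patch exactly
  o <- copy_paste_augment(img, list(patch),
                          modifyList(base, list(mask_mode = "box")),
                          seed = 3)
  newb <- o$annotations[o$annotations$source == "pasted", ]
  ph <- nrow(patch$pixels); pw <- ncol(patch$pixels)
  px0 <- round(newb$x - patch$box_local[["x"]])
  py0 <- round(newb$y - patch$box_local[["y"]])
  region <- o$pixels[(py0 + 1):(py0 + ph), (px0 + 1):(px0 + pw)]
  expect_identical(region, patch$pixels)
})

test_that("blended pixels are convex combinations of source and target", {
  img <- small_scene()
  rare_ann <- img$annotations[img$annotations$category != "DO", ]
  pool <- lapply(seq_len(nrow(rare_ann)),
                 function(i) extract_patch(img, rare_ann[i, ], margin = 5))
  out <- copy_paste_augment(img, pool,
                            paste_constraint(pastes_per_image = 3), seed = 5)
  changed <- which(out$pixels != img$pixels, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # every changed pixel lies between the two source values; verify via
  # global bounds of the pools involved
  lo <- pmin(out$pixels, img$pixels)
  hi <- pmax(out$pixels, img$pixels)
  pool_rng <- range(vapply(pool, function(p) range(p$pixels), c(0, 0)))
  expect_true(all(out$pixels[changed] >=
                    pmin(img$pixels[changed], pool_rng[1]) - 1e-12))
  expect_true(all(out$pixels[changed] <=
                    pmax(img$pixels[changed], pool_rng[2]) + 1e-12))
})

test_that("copy-paste respects placement constraints and bookkeeping", {
  b <- generate_dataset(2, scene_spec(width = 800, height = 600,
                                      n_cells = 20), seed = 8)
  out <- copy_paste_rare(b, paste_constraint(), seed = 9)
  expect_length(validate_bundle(out), 0)
  for (i in seq_along(out$images)) {
    orig <- b$images[[i]]$annotations
    aug <- out$images[[i]]$annotations
    pasted <- aug[aug$source == "pasted", ]
    if (!nrow(pasted)) next
    W <- out$images[[i]]$width; H <- out$images[[i]]$height
    for (j in seq_len(nrow(pasted))) {
      cand <- as.numeric(pasted[j, c("x", "y", "w", "h")])
      # centre inside the 0.45 min-dimension circle
      d <- sqrt((cand[1] + cand[3] / 2 - W / 2)^2 +
                  (cand[2] + cand[4] / 2 - H / 2)^2)
      expect_lte(d, 0.45 * min(W, H) + 1)
      # IoU below 0.3 against all prior boxes (originals + earlier pastes)
      prior <- rbind(orig[, c("x", "y", "w", "h")],
                     pasted[seq_len(j - 1), c("x", "y", "w", "h")])
      ious <- apply(prior, 1, function(bx) ref_iou(cand, as.numeric(bx)))
      expect_lt(max(ious), 0.3)
    }
    # original annotations untouched
    expect_identical(aug[seq_len(nrow(orig)), ], orig)
  }
  expect_error(copy_paste_augment(b$images[[1]], list(), seed = 1), "empty")
})

test_that("rare crops have the exact size, offsets and annotation law", {
  b <- generate_dataset(1, scene_spec(n_cells = 40), seed = 12)
  img <- b$images[[1]]
  crops <- rare_crop(img, crop_spec(), rare = rare_names(b$categories),
                     seed = 13)
  a <- img$annotations
  n_rare <- sum(a$category %in% rare_names(b$categories))
  expect_equal(length(crops), 2 * n_rare)
  for (cr in crops) {
    expect_equal(c(cr$width, cr$height), c(640, 640))
    expect_equal(dim(cr$pixels), c(640, 640))
    info <- attr(cr, "crop_info")
    expect_true(all(abs(info$offset) <= 160))
    # window clamped inside the frame
    expect_true(info$window[["x"]] >= 0 &&
                  info$window[["x"]] + 640 <= img$width)
    expect_true(info$window[["y"]] >= 0 &&
                  info$window[["y"]] + 640 <= img$height)
    # kept annotations verified against a per-pixel membership oracle
    x0 <- info$window[["x"]]; y0 <- info$window[["y"]]
    for (i in seq_len(nrow(a))) {
      inter_w <- max(0, min(a$x[i] + a$w[i], x0 + 640) - max(a$x[i], x0))
      inter_h <- max(0, min(a$y[i] + a$h[i], y0 + 640) - max(a$y[i], y0))
      visible <- inter_w * inter_h / (a$w[i] * a$h[i])
      in_crop <- any(abs(cr$annotations$x - (max(a$x[i], x0) - x0)) < 1e-9 &
                       cr$annotations$category == a$category[i] &
                       abs(cr$annotations$w - inter_w) < 1e-9)
      expect_equal(in_crop, visible >= 0.5)
    }
  }
  expect_error(rare_crop(image_record(1L, 500, 500), crop_spec(s = 640),
                         seed = 1), "no rare|exceeds")
})

test_that("crop coordinate transform matches a brute-force membership oracle", {
  # 50x50 toy frame: verify translated/clipped boxes pixel by pixel
  set.seed(4)
  for (trial in 1:25) {
    ann <- data.frame(
      id = 1:3, image_id = 1L,
      x = runif(3, 0, 40), y = runif(3, 0, 40),
      w = runif(3, 4, 10), h = runif(3, 4, 10),
      category = "E", source = "manual", stringsAsFactors = FALSE)
    x0 <- sample(0:30, 1); y0 <- sample(0:30, 1); s <- 20
    kept <- rbcscope:::crop_annotations(ann, x0, y0, s, 0.5)
    for (i in 1:3) {
      # exhaustive pixel-membership count over the toy frame
      xs <- seq(ann$x[i] + 0.5, ann$x[i] + ann$w[i] - 0.5, by = 1)
      ys <- seq(ann$y[i] + 0.5, ann$y[i] + ann$h[i] - 0.5, by = 1)
      grid <- expand.grid(x = xs, y = ys)
      inside <- grid$x > x0 & grid$x < x0 + s & grid$y > y0 & grid$y < y0 + s
      frac_oracle <- mean(inside)
      retained <- any(kept$category == "E" &
                        abs(kept$x - (max(ann$x[i], x0) - x0)) < 1e-9 &
                        abs(kept$y - (max(ann$y[i], y0) - y0)) < 1e-9)
      exact <- (pmax(0, pmin(ann$x[i] + ann$w[i], x0 + s) -
                       pmax(ann$x[i], x0)) *
                  pmax(0, pmin(ann$y[i] + ann$h[i], y0 + s) -
                         pmax(ann$y[i], y0))) / (ann$w[i] * ann$h[i])
      expect_equal(retained, exact >= 0.5)
      # pixel-count oracle agrees with the analytic fraction within 1 px
      expect_lt(abs(frac_oracle - exact), 0.25)
    }
  }
})

test_that("data-level operators never modify pixels they should not", {
  b <- generate_dataset(1, scene_spec(width = 700, height = 500,
                                      n_cells = 15), seed = 17)
  po <- oversample_rare(b, ratio = 10)  # force k > 1
  expect_gt(attr(po, "duplication_factor"), 1)
  for (img in po$images) {
    expect_identical(img$pixels,
                     b$images[[1]]$pixels[seq_len(img$height),
                                          seq_len(img$width)])
  }
  crops <- rare_crop_bundle(b, crop_spec(s = 400), seed = 2)
  for (img in crops$images[-1]) {
    info <- attr(img, "crop_info")
    w <- info$window
    expect_identical(img$pixels,
                     b$images[[1]]$pixels[(w[["y"]] + 1):(w[["y"]] + 400),
                                          (w[["x"]] + 1):(w[["x"]] + 400)])
  }
})

test_that("data-level operators are deterministic under a fixed seed", {
  b <- generate_dataset(1, scene_spec(width = 700, height = 500,
                                      n_cells = 20), seed = 19)
  c1 <- copy_paste_rare(b, seed = 5)
  c2 <- copy_paste_rare(b, seed = 5)
  expect_identical(c1$images[[1]]$pixels, c2$images[[1]]$pixels)
  expect_identical(bundle_annotations(c1), bundle_annotations(c2))
  r1 <- rare_crop_bundle(b, crop_spec(s = 300), seed = 6)
  r2 <- rare_crop_bundle(b, crop_spec(s = 300), seed = 6)
  expect_identical(bundle_annotations(r1), bundle_annotations(r2))
})
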