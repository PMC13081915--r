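# Synthetic full-scope scene generator. Emulates the imaging regime of
# bright-field RBC microscopy at desk scale: a circular illuminated
# field inside a 1920x1080 frame, densely packed dark cells with a thin
# bright halo (the bright-field membrane highlight), five visually
# distinct phenotype archetypes, strong class imbalance, and exact
# ground-truth boxes. It is a test fixture, not a biophysical model:
# render parameters are chosen only to make the archetypes separable by
# handcrafted features.

#' Specification of a synthetic full-scope scene
#'
#' @param width,height Frame size in pixels (default 1920 x 1080, the
#'   acquisition resolution of the emulated microscope setup).
#' @param field_radius_fraction Radius of the circular illuminated
#'   field as a fraction of `min(width, height)` (default 0.45).
#' @param n_cells Number of cells to place (default 60, about the mean
#'   cell count per full-scope image in the emulated regime).
#' @param class_mixture Named probability vector over categories; the
#'   default mirrors the strong imbalance of the emulated data
#'   (majority DO about 78%, rarest R about 2%).
#' @param cell_radius_range Nominal cell radius range in pixels.
#' @param max_overlap_iou Cap on box IoU between placed cells
#'   (default 0.3).
#' @param illumination Relative amplitude of a linear illumination
#'   gradient across the field (default 0.04).
#' @param noise_sd Gaussian pixel noise sd in intensity units
#'   (default 0.02).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 1920, height = 1080,
                       field_radius_fraction = 0.45,
                       n_cells = 60,
                       class_mixture = c(DO = 0.777, E = 0.037,
                                         ES = 0.142, G = 0.025, R = 0.019),
                       cell_radius_range = c(12, 18),
                       max_overlap_iou = 0.3,
                       illumination = 0.04,
                       noise_sd = 0.02,
                       seed = 1L) {
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture must sum to 1")
  }
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (max_overlap_iou < 0 || max_overlap_iou >= 1) {
    stop("max_overlap_iou must lie in [0, 1)")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         field_radius_fraction = field_radius_fraction,
         n_cells = as.integer(n_cells), class_mixture = class_mixture,
         cell_radius_range = cell_radius_range,
         max_overlap_iou = max_overlap_iou,
         illumination = illumination, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# rendering constants shared with the feature extractor
RENDER <- list(
  bg_field = 0.85,      # illuminated background
  bg_outside = 0.22,    # outside the circular field
  body = 0.48,          # uniform cell body intensity
  do_center = 0.62,     # discocyte central pallor (brighter than rim)
  do_rim = 0.36,        # discocyte dark rim
  halo = 0.97,          # bright membrane halo
  halo_width = 2,       # px
  speckle_level = 0.18, # granular dark dots
  mesh_level = 0.74,    # reticular bright mesh
  mesh_period = 5       # px
)

# Render one cell archetype into a square window.
# Returns body intensity, body mask and halo mask; the tight ground
# truth box is the bbox of the body mask.
render_archetype <- function(category, r0, theta0) {
  ext <- ceiling(switch(category, ES = r0 * 1.9, E = r0 * 1.35, r0 * 1.1) +
                   RENDER$halo_width + 1)
  n <- 2L * ext + 1L
  cy <- cx <- ext + 1
  dy <- matrix(rep(seq_len(n) - cy, n), n, n)
  dx <- t(dy)
  # rotate into the cell frame
  xr <- cos(theta0) * dx + sin(theta0) * dy
  yr <- -sin(theta0) * dx + cos(theta0) * dy
  r <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  # boundary radius R(phi) per archetype
  Rb <- switch(category,
    DO = , G = , R = matrix(r0, n, n),
    E = r0 * (1 + 0.22 * cos(10 * phi)),
    ES = {
      a <- r0 * 1.8; b <- r0 * 0.6
      1 / sqrt((cos(phi) / a)^2 + (sin(phi) / b)^2)
    })
  body <- r <= Rb
  halo <- r > Rb & r <= Rb + RENDER$halo_width
  u <- r / Rb
  I <- matrix(RENDER$body, n, n)
  if (category == "DO") {
    # annular disc: dark rim, brighter central pallor
    I[] <- ifelse(u < 0.55, RENDER$do_center,
                  ifelse(u < 0.7,
                         RENDER$do_center + (u - 0.55) / 0.15 *
                           (RENDER$do_rim - RENDER$do_center),
                         RENDER$do_rim))
  } else if (category == "G") {
    # speckled interior: dark granular dots
    n_dots <- 14L
    du <- runif(n_dots, 0, 0.72)
    dphi <- runif(n_dots, -pi, pi)
    ddx <- sqrt(du) * r0 * cos(dphi)
    ddy <- sqrt(du) * r0 * sin(dphi)
    dot_r <- 0.1 * r0
    for (d in seq_len(n_dots)) {
      hit <- (xr - ddx[d])^2 + (yr - ddy[d])^2 <= dot_r^2
      I[hit] <- RENDER$speckle_level
    }
  } else if (category == "R") {
    # reticular bright mesh
    p <- RENDER$mesh_period
    mesh <- sin(2 * pi * xr / p) * sin(2 * pi * yr / p) > 0.25
    I[mesh] <- RENDER$mesh_level
  }
  list(intensity = I, body = body, halo = halo, ext = ext)
}

#' Render one synthetic full-scope scene
#'
#' The class of each cell is drawn from a single multinomial
#' (`rmultinom(1, n_cells, class_mixture)`) as the first random draw
#' after seeding, so the per-class counts of a scene can be reproduced
#' independently from the seed. Cells are placed by rejection sampling
#' inside the circular field: a candidate violating the box-IoU cap
#' against already placed cells is redrawn up to 100 times, after which
#' the cell is dropped and the shortfall reported as a warning.
#' Ground-truth boxes are the tight bounding boxes of the rendered cell
#' bodies.
#'
#' @param spec A [scene_spec()].
#' @return A `scope_image` with pixels and one annotation per rendered
#'   cell (`source = "manual"`); identical specs (including seed) give
#'   bit-identical results.
#' @export
generate_scene <- function(spec = scene_spec()) {
  W <- spec$width; H <- spec$height
  categories <- names(spec$class_mixture)
  local_seed(spec$seed, {
    counts <- as.integer(rmultinom(1, spec$n_cells, spec$class_mixture))
    # background with circular field and linear illumination gradient
    Rf <- spec$field_radius_fraction * min(W, H)
    cx0 <- W / 2; cy0 <- H / 2
    xs <- seq_len(W) - 0.5; ys <- seq_len(H) - 0.5
    d2 <- outer((ys - cy0)^2, (xs - cx0)^2, "+")
    grad <- 1 + spec$illumination * ((matrix(xs, H, W, byrow = TRUE) - cx0) / Rf)
    px <- ifelse(d2 <= Rf^2, RENDER$bg_field * grad, RENDER$bg_outside)
    ann <- annotation_frame()
    placed <- matrix(numeric(), 0, 4)
    occupied <- matrix(FALSE, H, W)  # cell bodies form a monolayer
    next_id <- 1L
    shortfall <- 0L
    for (ci in seq_along(categories)) {
      for (cell in seq_len(counts[ci])) {
        r0 <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        theta0 <- runif(1, 0, 2 * pi)
        shape <- render_archetype(categories[ci], r0, theta0)
        # tight bbox of the body mask, window-local (0-based)
        rows_any <- which(rowSums(shape$body) > 0)
        cols_any <- which(colSums(shape$body) > 0)
        bx0 <- cols_any[1] - 1L; bx1 <- cols_any[length(cols_any)]
        by0 <- rows_any[1] - 1L; by1 <- rows_any[length(rows_any)]
        bw <- bx1 - bx0; bh <- by1 - by0
        ok <- FALSE
        for (attempt in 1:100) {
          rr <- (Rf - shape$ext - 2) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          ox <- round(cx0 + rr * cos(th)) - shape$ext - 1L  # window origin, 0-based
          oy <- round(cy0 + rr * sin(th)) - shape$ext - 1L
          cand <- c(ox + bx0, oy + by0, bw, bh)
          if (nrow(placed)) {
            ious <- apply(placed, 1, function(b) iou(cand, b))
            if (max(ious) >= spec$max_overlap_iou) next
            # bodies must not interpenetrate and keep a halo-wide gap
            # (cells sit in a monolayer; boxes may still overlap up to
            # the IoU cap, but the bright membrane halo separates them)
            rows_c <- (oy + 1):(oy + nrow(shape$body))
            cols_c <- (ox + 1):(ox + ncol(shape$body))
            sr <- rows_c >= 1 & rows_c <= H
            sc <- cols_c >= 1 & cols_c <= W
            if (any(occupied[rows_c[sr], cols_c[sc]] &
                      (shape$body | shape$halo)[sr, sc])) next
          }
          ok <- TRUE
          break
        }
        if (!ok) {
          shortfall <- shortfall + 1L
          next
        }
        rows <- (oy + 1):(oy + nrow(shape$body))
        cols <- (ox + 1):(ox + ncol(shape$body))
        sel_r <- rows >= 1 & rows <= H
        sel_c <- cols >= 1 & cols <= W
        win <- px[rows[sel_r], cols[sel_c], drop = FALSE]
        body <- shape$body[sel_r, sel_c, drop = FALSE]
        halo <- shape$halo[sel_r, sel_c, drop = FALSE]
        inten <- shape$intensity[sel_r, sel_c, drop = FALSE]
        occ <- occupied[rows[sel_r], cols[sel_c], drop = FALSE]
        win[body] <- inten[body]
        win[halo & !occ] <- RENDER$halo  # halo never eats a neighbour body
        px[rows[sel_r], cols[sel_c]] <- win
        occupied[rows[sel_r], cols[sel_c]] <- occ | body
        ann <- rbind(ann, data.frame(
          id = next_id, image_id = 1L,
          x = cand[1], y = cand[2], w = cand[3], h = cand[4],
          category = categories[ci], source = "manual",
          stringsAsFactors = FALSE))
        placed <- rbind(placed, cand)
        next_id <- next_id + 1L
      }
    }
    if (shortfall > 0L) {
      warning(sprintf(
        "generate_scene: dropped %d of %d cells (no feasible placement)",
        shortfall, spec$n_cells), call. = FALSE)
    }
    if (spec$noise_sd > 0) {
      px <- px + matrix(rnorm(W * H, sd = spec$noise_sd), H, W)
    }
    px <- clamp(px, 0, 1)
    rownames(ann) <- NULL
    image_record(1L, W, H, pixels = px, annotations = ann)
  })
}

#' Generate a synthetic dataset bundle
#'
#' Renders `n_images` scenes from a template spec with per-image seeds
#' derived deterministically from the master seed, then reassigns image
#' and annotation ids to be bundle-unique. The result always passes
#' [validate_bundle()].
#'
#' @param n_images Number of scenes (>= 1).
#' @param spec Template [scene_spec()] (its own `seed` is ignored).
#' @param seed Master seed.
#' @param categories Optional [category_map()]; defaults to the
#'   mixture's names with the standard rare flags.
#' @return A `scope_bundle`.
#' @export
generate_dataset <- function(n_images, spec = scene_spec(), seed = 1L,
                             categories = NULL) {
  if (n_images < 1) stop("n_images must be >= 1")
  seeds <- derive_seeds(seed, n_images)
  cat_names <- names(spec$class_mixture)
  categories <- categories %||%
    category_map(cat_names,
                 rare = intersect(cat_names, rare_names(category_map())))
  images <- vector("list", n_images)
  next_ann <- 1L
  for (i in seq_len(n_images)) {
    s <- spec
    s$seed <- seeds[i]
    img <- generate_scene(s)
    img$image_id <- i
    if (nrow(img$annotations)) {
      img$annotations$image_id <- i
      img$annotations$id <- seq.int(next_ann,
                                    length.out = nrow(img$annotations))
      next_ann <- next_ann + nrow(img$annotations)
    }
    images[[i]] <- img
  }
  dataset_bundle(images, categories, provenance = sprintf(
    "generate_dataset: %d images, n_cells=%d, master seed %d",
    n_images, spec$n_cells, as.integer(seed)))
}
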