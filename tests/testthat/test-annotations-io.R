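test_that("COCO read maps records directly and tolerates empty annotations", {
  td <- withr::local_tempdir()
  doc <- list(
    images = list(list(id = 1, width = 100, height = 80,
                       file_name = "a.png")),
    annotations = list(
      list(id = 1, image_id = 1, bbox = c(10, 12, 20, 18),
           category_id = 0, iscrowd = 0),
      list(id = 2, image_id = 1, bbox = c(50, 30, 15, 15),
           category_id = 2, iscrowd = 0)),
    categories = list(list(id = 0, name = "DO"), list(id = 1, name = "E"),
                      list(id = 2, name = "ES"), list(id = 3, name = "G"),
                      list(id = 4, name = "R")))
  path <- file.path(td, "two.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  b <- read_coco(path)
  expect_length(b$images, 1)
  ann <- b$images[[1]]$annotations
  expect_equal(nrow(ann), 2)
  expect_equal(ann$x, c(10, 50))
  expect_equal(ann$category, c("DO", "ES"))

  doc$annotations <- list()
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  b0 <- read_coco(path)
  expect_equal(nrow(bundle_annotations(b0)), 0)
})

test_that("COCO read rejects missing images and unknown categories", {
  td <- withr::local_tempdir()
  doc <- list(
    images = list(list(id = 1, width = 100, height = 80)),
    annotations = list(list(id = 1, image_id = 9, bbox = c(1, 1, 5, 5),
                            category_id = 0)),
    categories = list(list(id = 0, name = "DO")))
  path <- file.path(td, "bad.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_coco(path), "missing image")

  doc$annotations[[1]]$image_id <- 1
  doc$annotations[[1]]$category_id <- 7
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_coco(path), "unknown category")
})

test_that("COCO write/read round trip preserves ids, boxes and categories", {
  td <- withr::local_tempdir()
  b <- tiny_bundle()
  path <- file.path(td, "rt.json")
  write_coco(b, path)
  b2 <- read_coco(path)
  a1 <- bundle_annotations(b)
  a2 <- bundle_annotations(b2)
  expect_identical(a2$id, a1$id)
  expect_identical(a2$category, a1$category)
  expect_equal(a2[, c("x", "y", "w", "h")], a1[, c("x", "y", "w", "h")])
})

test_that("write_coco refuses invalid bundles before writing", {
  td <- withr::local_tempdir()
  b <- tiny_bundle()
  b$images[[2]]$annotations$id <- c(1L, 5L)  # duplicates id 1 of image 1
  path <- file.path(td, "dup.json")
  expect_error(write_coco(b, path), "validation")
  expect_false(file.exists(path))
})

test_that("boxes overhanging the frame are clipped with a warning", {
  td <- withr::local_tempdir()
  doc <- list(
    images = list(list(id = 1, width = 50, height = 50)),
    annotations = list(list(id = 1, image_id = 1, bbox = c(40, 40, 20, 20),
                            category_id = 0)),
    categories = list(list(id = 0, name = "DO")))
  path <- file.path(td, "edge.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_warning(b <- read_coco(path), "clipped")
  a <- bundle_annotations(b)
  expect_equal(a$w, 10)
  expect_equal(a$h, 10)
  expect_length(validate_bundle(b), 0)
})

test_that("YOLO line arithmetic matches the format definition", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "labels"))
  dir.create(file.path(td, "images"))
  writeLines("0 0.5 0.5 0.5 0.5", file.path(td, "labels", "im.txt"))
  save_image(matrix(0.5, 100, 100), file.path(td, "images", "im.png"))
  b <- read_yolo(file.path(td, "labels"), file.path(td, "images"))
  a <- bundle_annotations(b)
  expect_equal(as.numeric(a[1, c("x", "y", "w", "h")]), c(25, 25, 50, 50))

  # full-frame box writes back as centred unit extents
  b$images[[1]]$annotations <- data.frame(
    id = 1L, image_id = 1L, x = 0, y = 0, w = 100, h = 100,
    category = "DO", source = "manual", stringsAsFactors = FALSE)
  write_yolo(b, file.path(td, "out"), write_images = TRUE)
  line <- readLines(file.path(td, "out", "labels", "image_000001.txt"))
  expect_equal(line, "0 0.500000 0.500000 1.000000 1.000000")
})

test_that("YOLO round trip reproduces random boxes within format tolerance", {
  td <- withr::local_tempdir()
  set.seed(7)
  n <- 12
  ann <- data.frame(
    id = 1:n, image_id = 1L,
    x = runif(n, 0, 150), y = runif(n, 0, 100),
    w = runif(n, 5, 40), h = runif(n, 5, 40),
    category = sample(category_map()$name, n, replace = TRUE),
    source = "manual", stringsAsFactors = FALSE)
  b <- dataset_bundle(
    list(image_record(1L, 200, 150, pixels = matrix(0.5, 150, 200),
                      annotations = ann)),
    category_map())
  write_yolo(b, file.path(td, "y"))
  b2 <- read_yolo(file.path(td, "y", "labels"), file.path(td, "y", "images"))
  a2 <- bundle_annotations(b2)
  expect_lt(max(abs(a2$x - ann$x)), 1e-4 * 200)
  expect_lt(max(abs(a2$h - ann$h)), 1e-4 * 150)
  expect_identical(a2$category, ann$category)
})

test_that("YOLO reader rejects out-of-range values and bad class indices", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "labels"))
  dir.create(file.path(td, "images"))
  save_image(matrix(0.5, 50, 50), file.path(td, "images", "im.png"))
  writeLines("0 1.5 0.5 0.2 0.2", file.path(td, "labels", "im.txt"))
  expect_error(read_yolo(file.path(td, "labels"), file.path(td, "images")),
               "outside \\[0, 1\\]")
  writeLines("9 0.5 0.5 0.2 0.2", file.path(td, "labels", "im.txt"))
  expect_error(read_yolo(file.path(td, "labels"), file.path(td, "images")),
               "class index")
})

test_that("validate_bundle reports constructed breaches by id and rule", {
  b <- tiny_bundle()
  expect_length(validate_bundle(b), 0)

  b_edge <- tiny_bundle()
  b_edge$images[[1]]$annotations$x[2] <- 115  # w = 18 overhangs 120
  v <- validate_bundle(b_edge)
  expect_length(v, 1)
  expect_match(v, "annotation id 2.*outside image bounds")

  b_dup <- tiny_bundle()
  b_dup$images[[2]]$annotations$id <- c(3L, 5L)
  v <- validate_bundle(b_dup)
  expect_length(v, 1)
  expect_match(v, "duplicated annotation id")
})

test_that("downsample_class keeps exactly n_keep, deterministically", {
  b <- tiny_bundle()
  same <- downsample_class(b, "DO", 2, seed = 11)
  expect_equal(unname(class_counts(same)["DO"]), 2L)
  expect_equal(bundle_annotations(downsample_class(b, "DO", 2, seed = 11)),
               bundle_annotations(same))
  # n_keep equal to the count is the identity
  expect_equal(bundle_annotations(downsample_class(b, "G", 1, seed = 3)),
               bundle_annotations(b)[, ])
  expect_error(downsample_class(b, "R", 5, seed = 1), "exceeds")
  # non-target categories untouched
  d <- downsample_class(b, "DO", 1, seed = 5)
  cc <- class_counts(d)
  expect_equal(unname(cc[c("ES", "G", "R")]), c(1L, 1L, 1L))
})

test_that("downsampling scales to the curation regime counts", {
  # thinning a majority class from many to few, as in dataset curation
  set.seed(1)
  n <- 500
  ann <- data.frame(
    id = 1:n, image_id = 1L,
    x = runif(n, 0, 1800), y = runif(n, 0, 1000), w = 30, h = 30,
    category = sample(c("DO", "E"), n, replace = TRUE, prob = c(0.9, 0.1)),
    source = "manual", stringsAsFactors = FALSE)
  b <- dataset_bundle(list(image_record(1L, 1920, 1080, annotations = ann)),
                      category_map())
  n_do <- unname(class_counts(b)["DO"])
  d <- downsample_class(b, "DO", 50, seed = 2)
  expect_equal(unname(class_counts(d)["DO"]), 50L)
  expect_equal(unname(class_counts(d)["E"]), unname(class_counts(b)["E"]))
  # kept ids are a subset of the originals; pixels untouched (none here)
  expect_true(all(bundle_annotations(d)$id %in% ann$id))
  expect_gt(n_do, 50)
})
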