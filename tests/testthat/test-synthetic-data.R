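# Synthetic capsule scenes and Pascal-VOC I/O: determinism, box invariants,
# target/background contrast, directory layout, and XML round-trips.

test_that("scene generation is deterministic and respects box invariants", {
  spec <- scene_spec(image_size = 96)
  s1 <- generate_scene(spec, seed = 42)
  s2 <- generate_scene(spec, seed = 42)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$boxes, s2$boxes)
  s3 <- generate_scene(spec, seed = 43)
  expect_false(identical(s1$image, s3$image))

  set.seed(0)
  for (seed in sample.int(10000, 100)) {
    sc <- generate_scene(spec, seed = seed)
    b <- sc$boxes
    expect_gte(nrow(b), 1)
    expect_true(all(b$xmin >= 0 & b$ymin >= 0 &
                      b$xmax <= 96 & b$ymax <= 96))
    expect_true(all((b$xmax - b$xmin) * (b$ymax - b$ymin) >= 0.02 * 96^2))
  }
})

test_that("zero-target scenes are background-only", {
  sc <- generate_scene(scene_spec(image_size = 64), seed = 5, n_targets = 0)
  expect_equal(nrow(sc$boxes), 0L)
  expect_equal(dim(sc$image), c(64, 64, 3))
})

test_that("capsules are lighter than the surrounding tissue by the configured offset", {
  spec <- scene_spec(image_size = 96, n_targets = c(1, 1))
  lum <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] +
    0.114 * img[, , 3]
  for (seed in 1:10) {
    sc <- generate_scene(spec, seed = seed)
    L <- lum(sc$image)
    b <- sc$boxes[1, ]
    inside <- L[(b$ymin + 1):b$ymax, (b$xmin + 1):b$xmax]
    mask <- matrix(TRUE, 96, 96)
    mask[(b$ymin + 1):b$ymax, (b$xmin + 1):b$xmax] <- FALSE
    expect_gt(mean(inside) - mean(L[mask]), spec$intensity_offset / 2)
  }
})

test_that("VOC XML round-trips losslessly with the 1-based convention", {
  boxes <- data.frame(xmin = c(0, 12), ymin = c(3, 40), xmax = c(20, 60),
                      ymax = c(18, 90), class = "capsule")
  f <- tempfile(fileext = ".xml")
  write_voc_annotation(f, "img1.png", c(96, 96), boxes)
  back <- read_voc_annotation(f)
  expect_equal(back$filename, "img1.png")
  expect_equal(back$size, c(96L, 96L))
  expect_equal(back$boxes$xmin, boxes$xmin)
  expect_equal(back$boxes$ymax, boxes$ymax)
  # xmin = 0 internally is stored as 1 in the XML
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//bndbox/xmin")), "1")
  # empty object list round-trips to zero boxes
  write_voc_annotation(f, "img2.png", c(64, 64), boxes[0, ])
  expect_equal(nrow(read_voc_annotation(f)$boxes), 0L)
  # second write of identical content is byte-identical
  f2 <- tempfile(fileext = ".xml")
  write_voc_annotation(f, "img1.png", c(96, 96), boxes)
  write_voc_annotation(f2, "img1.png", c(96, 96), boxes)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed annotations raise parse errors naming the element", {
  f <- tempfile(fileext = ".xml")
  writeLines("<annotation><object><bndbox><xmin>5</xmin>", f)
  expect_error(read_voc_annotation(f), "cannot parse")
  writeLines(paste0("<annotation><filename>x</filename>",
                    "<size><width>9</width><height>9</height></size>",
                    "<object><name>c</name><bndbox><xmin>1</xmin>",
                    "<ymin>1</ymin><xmax>5</xmax></bndbox></object>",
                    "</annotation>"), f)
  expect_error(read_voc_annotation(f), "bndbox/ymax")
})

test_that("dataset generation lays out VOC directories and reproduces exactly", {
  td1 <- tempfile(); td2 <- tempfile()
  spec <- scene_spec(image_size = 64)
  m1 <- generate_dataset(td1, n_train = 8, n_test = 2, spec = spec, seed = 9)
  m2 <- generate_dataset(td2, n_train = 8, n_test = 2, spec = spec, seed = 9)
  expect_length(m1$train, 8)
  expect_length(m1$test, 2)
  expect_length(list.files(file.path(td1, "Annotations")), 10L)
  expect_length(list.files(file.path(td1, "JPEGImages")), 10L)
  expect_equal(m1$classes, "capsule")
  expect_length(intersect(m1$train, m1$test), 0L)
  # byte-level reproducibility of annotations and images under a fixed seed
  for (f in list.files(file.path(td1, "Annotations"))) {
    expect_identical(readLines(file.path(td1, "Annotations", f)),
                     readLines(file.path(td2, "Annotations", f)))
  }
  for (f in list.files(file.path(td1, "JPEGImages"))) {
    a <- file.path(td1, "JPEGImages", f); b <- file.path(td2, "JPEGImages", f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
  # refuses to clobber an existing dataset unless asked
  expect_error(generate_dataset(td1, 2, 1, spec, seed = 1), "not empty")
  expect_silent(m3 <- generate_dataset(td1, 2, 1, spec, seed = 1,
                                       overwrite = TRUE))
  # every train split contains at least one target instance
  n_inst <- sum(vapply(m1$train, function(id)
    nrow(read_voc_annotation(file.path(td1, "Annotations",
                                       paste0(id, ".xml")))$boxes), 0))
  expect_gte(n_inst, 1)
})

test_that("manifest loading recovers images and pixel-space boxes", {
  mf <- tiny_manifest(n_train = 3, n_test = 1, image_size = 64)
  ex <- load_example(mf, mf$train[1])
  expect_equal(dim(ex$image), c(64, 64, 3))
  expect_true(all(ex$image >= 0 & ex$image <= 1))
  expect_gte(nrow(ex$boxes), 1)
  expect_equal(mf$image_size, 64L)
})
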