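# VOC evaluation, curve logging, and feature-map visualisation.

test_that("perfect detections score mAP 1 and no detections score 0", {
  gt <- data.frame(image = c("a", "a", "b"), class = c(1L, 1L, 2L),
                   xmin = c(10, 50, 5), ymin = c(10, 50, 5),
                   xmax = c(30, 80, 25), ymax = c(30, 80, 25))
  det <- cbind(gt, score = 1.0)
  res <- voc_average_precision(det, gt)
  expect_equal(res$map, 1.0)
  expect_equal(unname(res$per_class_ap), c(1, 1))
  empty <- det[0, ]
  expect_equal(voc_average_precision(empty, gt)$map, 0)
})

test_that("the 1-gt / TP+2FP example matches the hand-enumerated 11-point AP", {
  gt <- data.frame(image = "a", class = 1L, xmin = 0, ymin = 0,
                   xmax = 10, ymax = 10)
  det <- data.frame(image = "a", class = 1L, score = c(0.9, 0.8, 0.7),
                    xmin = c(0, 50, 70), ymin = c(0, 50, 70),
                    xmax = c(10, 60, 80), ymax = c(10, 60, 80))
  res <- voc_average_precision(det, gt, protocol = "voc07")
  # rank 1 is a TP at recall 1, precision 1; interpolated precision is 1 at
  # every recall level, so AP = 1
  expect_equal(unname(res$per_class_ap["1"]), 1.0)
  expect_equal(res$per_class_ap[["1"]],
               oracle_ap(det, gt))
})

test_that("AP agrees with the oracle on 100 randomised small scenes", {
  set.seed(55)
  for (i in 1:100) {
    ng <- sample(1:6, 1); nd <- sample(0:10, 1)
    gt <- data.frame(image = sample(c("a", "b"), ng, replace = TRUE),
                     class = 1L)
    gt <- cbind(gt, setNames(as.data.frame(random_corner_boxes(ng) * 100),
                             c("xmin", "ymin", "xmax", "ymax")))
    det <- if (nd > 0) {
      base <- gt[sample(ng, nd, replace = TRUE), ]
      jit <- matrix(rnorm(nd * 4, sd = 8), nd)
      data.frame(image = base$image, class = 1L, score = runif(nd),
                 xmin = base$xmin + jit[, 1], ymin = base$ymin + jit[, 2],
                 xmax = base$xmax + jit[, 3], ymax = base$ymax + jit[, 4])
    } else data.frame(image = character(), class = integer(),
                      score = numeric(), xmin = numeric(), ymin = numeric(),
                      xmax = numeric(), ymax = numeric())
    got <- voc_average_precision(det, gt)$per_class_ap[["1"]]
    want <- if (nd > 0) oracle_ap(det, gt) else 0
    expect_equal(got, want)
  }
})

test_that("appending a low-confidence false positive never increases AP", {
  set.seed(66)
  for (i in 1:20) {
    ng <- sample(2:5, 1)
    gt <- data.frame(image = "a", class = 1L)
    gt <- cbind(gt, setNames(as.data.frame(random_corner_boxes(ng) * 100),
                             c("xmin", "ymin", "xmax", "ymax")))
    det <- data.frame(image = "a", class = 1L, score = runif(ng, 0.5, 1),
                      xmin = gt$xmin, ymin = gt$ymin, xmax = gt$xmax,
                      ymax = gt$ymax)
    ap0 <- voc_average_precision(det, gt)$per_class_ap[["1"]]
    fp <- data.frame(image = "a", class = 1L, score = 0,
                     xmin = 900, ymin = 900, xmax = 910, ymax = 910)
    ap1 <- voc_average_precision(rbind(det, fp), gt)$per_class_ap[["1"]]
    expect_lte(ap1, ap0)
  }
})

test_that("difficult ground truths are excluded from the recall denominator", {
  gt <- data.frame(image = "a", class = 1L,
                   xmin = c(0, 50), ymin = c(0, 50),
                   xmax = c(10, 60), ymax = c(10, 60),
                   difficult = c(0L, 1L))
  det <- data.frame(image = "a", class = 1L, score = 0.9,
                    xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  expect_equal(voc_average_precision(det, gt)$per_class_ap[["1"]], 1.0)
})

test_that("unknown detection classes warn and do not enter the mAP", {
  gt <- data.frame(image = "a", class = 1L, xmin = 0, ymin = 0,
                   xmax = 10, ymax = 10)
  det <- data.frame(image = "a", class = c(1L, 9L), score = c(0.9, 0.8),
                    xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  expect_warning(res <- voc_average_precision(det, gt), "no ground truth")
  expect_equal(names(res$per_class_ap), "1")
})

test_that("curve logs round-trip through CSV and reject disorder", {
  h <- data.frame(iteration = c(1L, 5L, 9L), loss = c(3.2, 2.1, 1.4),
                  map = c(NA, 0.4, 0.6))
  f <- tempfile(fileext = ".csv")
  log_training_curves(h, f)
  back <- read_training_curves(f)
  expect_equal(back, h)
  empty <- data.frame(iteration = integer(), loss = numeric())
  log_training_curves(empty, f)
  expect_equal(nrow(read_training_curves(f)), 0L)
  bad <- data.frame(iteration = c(3L, 2L), loss = c(1, 2))
  expect_error(log_training_curves(bad, f), "increasing")
})

test_that("endpoint visualisation is deterministic and guards constant maps", {
  set.seed(10)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  visualize_endpoint(x, f1, reduce = "none")
  visualize_endpoint(x, f2, reduce = "none")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  expect_equal(dim(img), c(16, 16))        # 4 channels in a 2x2 grid
  fc <- tempfile(fileext = ".png")
  visualize_endpoint(array(2.5, c(6, 6, 1)), fc)
  const <- png::readPNG(fc)
  expect_true(all(abs(const - 0.5) < 0.01))
})
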