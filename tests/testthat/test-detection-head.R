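# Multibox machinery: default-box accounting, IoU, matching, loss, and NMS,
# each checked against an exhaustive brute-force oracle.

test_that("reference SSD300 configuration yields 8732 default boxes", {
  db <- generate_default_boxes(head_config())
  sizes <- c(38, 19, 10, 5, 3, 1)
  anchors <- c(4, 6, 6, 6, 4, 4)
  expect_equal(db$per_layer_counts, as.integer(sizes^2 * anchors))
  expect_equal(nrow(db$boxes), sum(sizes^2 * anchors))  # 8732
  expect_equal(nrow(db$boxes), 8732L)
  expect_equal(db$per_layer_counts[1], 5776L)
  expect_true(all(db$corners >= 0 & db$corners <= 1))
  expect_error(head_config(source_sizes = integer()), "at least one")
})

test_that("IoU satisfies its defining identities", {
  a <- c(0, 0, 2, 2)
  expect_equal(as.numeric(box_iou(a, a)), 1)
  expect_equal(as.numeric(box_iou(a, c(3, 3, 4, 4))), 0)
  expect_equal(as.numeric(box_iou(a, c(1, 0, 3, 2))), 1 / 3)
  expect_equal(as.numeric(box_iou(a, c(1, 1, 1, 3))), 0)   # zero-area box
  set.seed(4)
  x <- random_corner_boxes(12); y <- random_corner_boxes(9)
  m <- box_iou(x, y)
  expect_equal(m, t(box_iou(y, x)))
  for (i in 1:12) for (j in 1:9)
    expect_equal(m[i, j], oracle_iou(x[i, ], y[j, ]))
})

test_that("anchor matching equals the exhaustive oracle on random instances", {
  db <- generate_default_boxes(head_config(source_sizes = c(3L, 1L),
                                           anchors_per_cell = c(4L, 4L)))
  expect_equal(match_anchors(NULL, integer(), db)$class,
               integer(nrow(db$boxes)))
  set.seed(31)
  for (i in 1:100) {
    G <- sample(1:3, 1)
    gt <- random_corner_boxes(G)
    labels <- sample(1:2, G, replace = TRUE)
    got <- match_anchors(gt, labels, db, threshold = 0.5)
    want <- oracle_match(gt, labels, db$corners, threshold = 0.5)
    expect_identical(got$class, want$class)
    expect_equal(got$box, want$box)
    expect_equal(got$iou, want$iou)
  }
  # every ground truth claims at least one anchor even under poor overlap
  gt <- matrix(c(0.01, 0.01, 0.02, 0.02), 1)
  got <- match_anchors(gt, 1L, db)
  expect_gte(sum(got$class == 1L), 1L)
})

test_that("offset coding round-trips boxes through encode/decode", {
  db <- generate_default_boxes(head_config(source_sizes = c(5L, 3L),
                                           anchors_per_cell = c(4L, 6L)))
  set.seed(12)
  gt <- random_corner_boxes(nrow(db$boxes))
  enc <- encode_boxes(gt, db)
  dec <- decode_boxes(enc, db)
  expect_equal(dec, gt, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("multibox loss matches a hand-computed toy instance", {
  # 4 anchors, 2 classes; anchor 1 matched to a ground truth, rest background
  db <- list(boxes = cbind(c(0.25, 0.75, 0.25, 0.75),
                           c(0.25, 0.25, 0.75, 0.75), 0.5, 0.5))
  db$corners <- affssd:::center_to_corner(db$boxes)
  match <- list(class = c(1L, 0L, 0L, 0L),
                box = rbind(c(0.05, 0.05, 0.55, 0.55), 0, 0, 0) * 1,
                iou = c(0.8, 0, 0, 0))
  scores <- rbind(c(0.2, 1.1), c(0.5, -0.3), c(2.0, 0.4), c(0.1, 0.0))
  offsets <- rbind(c(0.1, -0.2, 0.3, 2.0), 0, 0, 0)
  L <- multibox_loss(scores, offsets, match, db, neg_pos_ratio = 3)
  # by hand: softmax CE for anchor 1 toward class 2 (foreground 1),
  # all three negatives kept (ratio 3), CE toward background
  p <- exp(scores) / rowSums(exp(scores))
  lc <- -log(p[1, 2]) - log(p[2, 1]) - log(p[3, 1]) - log(p[4, 1])
  enc <- affssd:::encode_boxes(match$box, db)
  d <- offsets[1, ] - enc[1, ]
  ll <- sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  expect_equal(L$total, (lc + ll) / 1)
  expect_equal(L$n_matched, 1L)
  # perfect localisation has zero smooth-L1 term
  Lperf <- multibox_loss(scores, enc, match, db)
  expect_equal(Lperf$loc, 0)
  # no ground truth: loss defined as zero
  L0 <- multibox_loss(scores, offsets,
                      list(class = integer(4), box = matrix(0, 4, 4),
                           iou = numeric(4)), db)
  expect_equal(L0$total, 0)
  expect_equal(L0$dconf, matrix(0, 4, 2))
})

test_that("multibox loss gradients match finite differences", {
  db <- generate_default_boxes(head_config(source_sizes = 2L,
                                           anchors_per_cell = 4L))
  set.seed(77)
  gt <- matrix(c(0.1, 0.1, 0.6, 0.6), 1)
  match <- match_anchors(gt, 1L, db)
  M <- nrow(db$boxes)
  scores <- matrix(rnorm(M * 2), M)
  offsets <- matrix(rnorm(M * 4, sd = 0.3), M)
  L <- multibox_loss(scores, offsets, match, db)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(3, 2), c(8, 1))) {
    sp <- scores; sp[probe[1], probe[2]] <- sp[probe[1], probe[2]] + eps
    sm <- scores; sm[probe[1], probe[2]] <- sm[probe[1], probe[2]] - eps
    num <- (multibox_loss(sp, offsets, match, db)$total -
              multibox_loss(sm, offsets, match, db)$total) / (2 * eps)
    expect_equal(L$dconf[probe[1], probe[2]], num, tolerance = 1e-4)
  }
  pos <- which(match$class > 0)[1]
  op <- offsets; op[pos, 3] <- op[pos, 3] + eps
  om <- offsets; om[pos, 3] <- om[pos, 3] - eps
  num <- (multibox_loss(scores, op, match, db)$total -
            multibox_loss(scores, om, match, db)$total) / (2 * eps)
  expect_equal(L$dloc[pos, 3], num, tolerance = 1e-4)
})

test_that("greedy NMS equals the exhaustive oracle and is idempotent", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    boxes <- random_corner_boxes(n)
    scores <- runif(n)
    keep <- nms(boxes, scores, iou_thresh = 0.45)
    expect_identical(keep, oracle_nms(boxes, scores, 0.45))
    # suppressing the survivors again changes nothing
    keep2 <- nms(boxes[keep, , drop = FALSE], scores[keep], 0.45)
    expect_identical(keep2, seq_along(keep))
  }
})

test_that("decode_and_nms keeps the confident box and drops duplicates", {
  db <- generate_default_boxes(head_config(source_sizes = 2L,
                                           anchors_per_cell = 4L))
  M <- nrow(db$boxes)
  scores <- matrix(0, M, 2)
  scores[, 1] <- 4                      # background everywhere
  scores[3, ] <- c(0, 3)                # one confident detection
  offsets <- matrix(0, M, 4)
  d <- decode_and_nms(scores, offsets, db, conf_thresh = 0.3)
  expect_equal(nrow(d), 1L)
  expect_equal(d$class, 1L)
  expect_equal(as.numeric(d[1, c("xmin", "ymin", "xmax", "ymax")]),
               unname(pmin(pmax(db$corners[3, ], 0), 1)), tolerance = 1e-12)
  # two identical boxes with scores 0.9-ish / 0.8-ish: higher one kept
  scores[4, ] <- c(0, 2.5)
  offsets[4, ] <- encode_boxes(matrix(db$corners[3, ], 1,
                                      4)[rep(1, M), ], db)[4, ]
  d2 <- decode_and_nms(scores, offsets, db, conf_thresh = 0.3)
  same <- d2[d2$class == 1, ]
  expect_equal(nrow(same), 1L)
  expect_equal(same$score, max(same$score))
})
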