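# Independent brute-force oracles used to cross-check the vectorised
# implementations. These are deliberately naive (scalar loops, exhaustive
# enumeration) and share no code with the package internals they test.

# Per-element SimAM evaluation: for each channel of each image, loop over
# elements and evaluate the energy expression directly.
oracle_simam_weights <- function(x, lambda = 1e-4) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d4 <- dim(x)
  w <- array(NA_real_, d4)
  n <- d4[1] * d4[2]
  for (img in seq_len(d4[4])) {
    for (ch in seq_len(d4[3])) {
      v <- as.vector(x[, , ch, img])
      mu <- sum(v) / n
      sigma2 <- sum((v - mu)^2) / (n - 1)
      for (i in seq_len(d4[1])) for (j in seq_len(d4[2])) {
        t <- x[i, j, ch, img]
        einv <- (t - mu)^2 / (4 * (sigma2 + lambda)) + 0.5
        w[i, j, ch, img] <- 1 / (1 + exp(-einv))
      }
    }
  }
  if (length(d) == 3L) dim(w) <- d
  w
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  aa <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  ab <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (aa + ab - inter <= 0) return(0)
  inter / (aa + ab - inter)
}

# Exhaustive O(anchors x gts) matcher with the explicit tie rule
# (lowest index wins everywhere).
oracle_match <- function(gt_boxes, gt_labels, anchor_corners, threshold) {
  M <- nrow(anchor_corners)
  G <- NROW(gt_boxes)
  cls <- integer(M)
  box <- matrix(0, M, 4)
  best <- numeric(M)
  if (G == 0) return(list(class = cls, box = box, iou = best))
  iou <- matrix(0, M, G)
  for (m in seq_len(M)) for (g in seq_len(G))
    iou[m, g] <- oracle_iou(anchor_corners[m, ], gt_boxes[g, ])
  assigned <- integer(M)
  for (m in seq_len(M)) {
    g <- which(iou[m, ] == max(iou[m, ]))[1]
    best[m] <- iou[m, g]
    if (iou[m, g] >= threshold) assigned[m] <- g
  }
  for (g in seq_len(G)) {
    m <- which(iou[, g] == max(iou[, g]))[1]
    assigned[m] <- g
    best[m] <- iou[m, g]
  }
  take <- assigned > 0
  cls[take] <- gt_labels[assigned[take]]
  box[take, ] <- gt_boxes[assigned[take], , drop = FALSE]
  list(class = cls, box = box, iou = best)
}

# Exhaustive greedy NMS with the lowest-index tie rule.
oracle_nms <- function(boxes, scores, iou_thresh, top_k = Inf) {
  remaining <- seq_len(nrow(boxes))
  keep <- integer(0)
  while (length(remaining) && length(keep) < top_k) {
    sc <- scores[remaining]
    i <- remaining[which(sc == max(sc))[1]]
    keep <- c(keep, i)
    remaining <- setdiff(remaining, i)
    drop <- vapply(remaining, function(j)
      oracle_iou(boxes[i, ], boxes[j, ]) > iou_thresh, TRUE)
    remaining <- remaining[!drop]
  }
  keep
}

# Hand-enumerated AP: build the full precision/recall table and apply the
# protocol definition directly.
oracle_ap <- function(det, gt, iou_thresh = 0.5, protocol = "voc07") {
  # det: data.frame(image, score, xmin..ymax); gt: data.frame(image, xmin..ymax)
  det <- det[order(-det$score), , drop = FALSE]
  claimed <- rep(FALSE, nrow(gt))
  tp <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(gt$image == det$image[i] & !is.na(gt$image))
    bi <- 0; bj <- 0
    for (j in cand) {
      v <- oracle_iou(as.numeric(det[i, c("xmin", "ymin", "xmax", "ymax")]),
                      as.numeric(gt[j, c("xmin", "ymin", "xmax", "ymax")]))
      if (v > bi) { bi <- v; bj <- j }
    }
    if (bi >= iou_thresh && bj > 0 && !claimed[bj]) {
      claimed[bj] <- TRUE
      tp[i] <- 1
    }
  }
  rec <- cumsum(tp) / nrow(gt)
  prec <- cumsum(tp) / seq_along(tp)
  if (protocol != "voc07") stop("oracle_ap supports voc07 only")
  mean(vapply(seq(0, 1, 0.1), function(r) {
    p <- prec[rec >= r]
    if (length(p)) max(p) else 0
  }, 0))
}

# Layer-by-layer closed-form parameter count from a model description table.
oracle_param_count <- function(model) {
  d <- affssd::model_description(model)
  total <- 0
  shapes <- list()
  for (i in seq_len(nrow(d))) {
    shapes[[d$layer[i]]] <- c(d$out_h[i], d$out_w[i], d$out_c[i])
    if (d$op[i] == "conv") {
      cin <- shapes[[d$inputs[i]]][3]
      nd <- model$nodes[[d$layer[i]]]
      total <- total + nd$cfg$k^2 * cin * d$out_c[i] + d$out_c[i]
    } else if (d$op[i] == "bn") {
      total <- total + 2 * d$out_c[i]
    }
  }
  total
}

random_corner_boxes <- function(n, span = 1) {
  x1 <- runif(n, 0, 0.8 * span); y1 <- runif(n, 0, 0.8 * span)
  cbind(x1, y1, x1 + runif(n, 0.05, 0.2) * span,
        y1 + runif(n, 0.05, 0.2) * span)
}

tiny_manifest <- function(n_train = 6, n_test = 2, image_size = 96,
                          seed = 11) {
  td <- tempfile("voc")
  generate_dataset(td, n_train, n_test,
                   scene_spec(image_size = image_size), seed = seed)
}
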