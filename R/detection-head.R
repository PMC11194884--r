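# SSD multibox machinery: default (prior) boxes, IoU, anchor matching,
# multibox loss with hard-negative mining, offset coding, and greedy NMS.
# Boxes are corner-form (xmin, ymin, xmax, ymax), 0-based half-open, on the
# normalised [0, 1] scale unless stated otherwise. Priors are kept in
# centre-size form (cx, cy, w, h).

#' Detection-head configuration
#'
#' @param source_sizes Integer vector of feature-map sizes of the head's
#'   source layers (SSD300 reference: 38, 19, 10, 5, 3, 1).
#' @param anchors_per_cell Anchors per cell for each source layer (reference:
#'   4, 6, 6, 6, 4, 4; 4 means aspect ratios 1, 1', 2, 1/2 and 6 adds 3, 1/3).
#' @param s_min,s_max Scale schedule endpoints (fractions of the input size).
#' @param variances Offset-coding variances (cx, cy, w, h).
#' @param conf_thresh,nms_iou,top_k,neg_pos_ratio Post-processing and loss
#'   defaults.
#' @return A `head_config` list.
#' @export
head_config <- function(source_sizes = c(38L, 19L, 10L, 5L, 3L, 1L),
                        anchors_per_cell = c(4L, 6L, 6L, 6L, 4L, 4L),
                        s_min = 0.2, s_max = 0.9,
                        variances = c(0.1, 0.1, 0.2, 0.2),
                        conf_thresh = 0.01, nms_iou = 0.45, top_k = 200L,
                        neg_pos_ratio = 3) {
  if (length(source_sizes) < 1L)
    stop_config("head needs at least one source layer")
  if (length(anchors_per_cell) != length(source_sizes))
    stop_config("anchors_per_cell must match source_sizes")
  if (!all(anchors_per_cell %in% c(4L, 6L)))
    stop_config("anchors_per_cell entries must be 4 or 6")
  structure(list(source_sizes = as.integer(source_sizes),
                 anchors_per_cell = as.integer(anchors_per_cell),
                 s_min = s_min, s_max = s_max, variances = variances,
                 conf_thresh = conf_thresh, nms_iou = nms_iou,
                 top_k = as.integer(top_k), neg_pos_ratio = neg_pos_ratio),
            class = "head_config")
}

#' Generate the SSD default-box set
#'
#' Tiles anchor boxes of graded scales and aspect ratios over every source
#' feature map: layer k of m gets scale
#' `s_k = s_min + (s_max - s_min) (k - 1) / (m - 1)`. Anchor order per cell is
#' ratio 1, the intermediate scale `sqrt(s_k s_(k+1))`, then pairs
#' (`sqrt(ar)`, `1/sqrt(ar)`) for ar = 2 (and 3 for 6-anchor layers); cells
#' are visited column-major within each layer. The reference SSD300
#' configuration yields 8732 boxes.
#'
#' @param config A [head_config()].
#' @return List with `boxes` (M x 4 centre-size, unclipped), `corners`
#'   (M x 4 corner-form, clipped to \[0, 1\]), and `per_layer_counts`.
#' @export
generate_default_boxes <- function(config = head_config()) {
  m <- length(config$source_sizes)
  scales <- if (m == 1) config$s_min else
    config$s_min + (config$s_max - config$s_min) * (seq_len(m) - 1) / (m - 1)
  scales_next <- c(scales[-1], 1.0)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    fk <- config$source_sizes[k]
    s <- scales[k]
    sp <- sqrt(s * scales_next[k])
    wh <- rbind(c(s, s), c(sp, sp),
                c(s * sqrt(2), s / sqrt(2)), c(s / sqrt(2), s * sqrt(2)))
    if (config$anchors_per_cell[k] == 6L)
      wh <- rbind(wh, c(s * sqrt(3), s / sqrt(3)), c(s / sqrt(3), s * sqrt(3)))
    A <- nrow(wh)
    # cells column-major: column j (x), then row i (y), anchors fastest
    j <- rep(seq_len(fk) - 1L, each = fk * A)
    i <- rep(rep(seq_len(fk) - 1L, each = A), times = fk)
    a <- rep(seq_len(A), times = fk * fk)
    out[[k]] <- cbind(cx = (j + 0.5) / fk, cy = (i + 0.5) / fk,
                      w = wh[a, 1], h = wh[a, 2])
  }
  boxes <- do.call(rbind, out)
  corners <- center_to_corner(boxes)
  corners[corners < 0] <- 0
  corners[corners > 1] <- 1
  list(boxes = boxes, corners = corners,
       per_layer_counts = vapply(out, nrow, 0L), config = config)
}

center_to_corner <- function(b) {
  cbind(xmin = b[, 1] - b[, 3] / 2, ymin = b[, 2] - b[, 4] / 2,
        xmax = b[, 1] + b[, 3] / 2, ymax = b[, 2] + b[, 4] / 2)
}

corner_to_center <- function(b) {
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Intersection over union of corner-form boxes
#'
#' @param a,b Numeric matrices (N x 4 and M x 4) or length-4 vectors, corner
#'   form. Degenerate (zero-area) boxes have zero overlap with everything.
#' @return An N x M matrix of IoU values in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  area_a <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  area_b <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(area_a, area_b, `+`) - inter
  iou <- ifelse(un > 0, inter / un, 0)
  matrix(iou, nrow = nrow(a))
}

#' Match ground-truth boxes to default boxes
#'
#' Standard SSD bipartite-then-threshold matching: every ground truth is
#' force-assigned its best-IoU anchor (ties: lowest anchor index), and any
#' remaining anchor whose best IoU against some ground truth reaches the
#' threshold is assigned to that ground truth (ties: lowest ground-truth
#' index). All other anchors are background (class 0).
#'
#' @param gt_boxes G x 4 corner-form matrix (normalised), may have 0 rows.
#' @param gt_labels Integer vector of foreground class ids (>= 1).
#' @param defaults A default-box set from [generate_default_boxes()].
#' @param threshold IoU threshold (default 0.5).
#' @return List with `class` (length-M integer, 0 = background), `box`
#'   (M x 4 assigned ground-truth corners), `iou` (length-M max IoU).
#' @export
match_anchors <- function(gt_boxes, gt_labels, defaults, threshold = 0.5) {
  M <- nrow(defaults$corners)
  cls <- integer(M)
  box <- matrix(0, M, 4)
  best <- numeric(M)
  if (!is.null(gt_boxes) && NROW(gt_boxes) > 0) {
    if (is.null(dim(gt_boxes))) gt_boxes <- matrix(gt_boxes, nrow = 1)
    iou <- box_iou(defaults$corners, gt_boxes)        # M x G
    assigned_gt <- max.col(iou, ties.method = "first")
    best <- iou[cbind(seq_len(M), assigned_gt)]
    take <- best >= threshold
    # force the best anchor for every ground truth
    for (g in seq_len(ncol(iou))) {
      a <- which.max(iou[, g])                        # lowest index on ties
      assigned_gt[a] <- g
      best[a] <- iou[a, g]
      take[a] <- TRUE
    }
    cls[take] <- gt_labels[assigned_gt[take]]
    box[take, ] <- gt_boxes[assigned_gt[take], , drop = FALSE]
  }
  list(class = cls, box = box, iou = best)
}

#' Variance-scaled offset coding
#'
#' @param matched M x 4 corner-form ground-truth boxes (rows for background
#'   anchors are ignored).
#' @param defaults Default-box set.
#' @param variances Length-4 coding variances.
#' @return M x 4 matrix of regression targets.
#' @export
encode_boxes <- function(matched, defaults, variances = c(0.1, 0.1, 0.2, 0.2)) {
  g <- corner_to_center(matched)
  p <- defaults$boxes
  cbind((g[, 1] - p[, 1]) / (p[, 3] * variances[1]),
        (g[, 2] - p[, 2]) / (p[, 4] * variances[2]),
        log(pmax(g[, 3], 1e-8) / p[, 3]) / variances[3],
        log(pmax(g[, 4], 1e-8) / p[, 4]) / variances[4])
}

#' @rdname encode_boxes
#' @param offsets M x 4 predicted offsets.
#' @export
decode_boxes <- function(offsets, defaults, variances = c(0.1, 0.1, 0.2, 0.2)) {
  p <- defaults$boxes
  cx <- offsets[, 1] * variances[1] * p[, 3] + p[, 1]
  cy <- offsets[, 2] * variances[2] * p[, 4] + p[, 2]
  w <- p[, 3] * exp(offsets[, 3] * variances[3])
  h <- p[, 4] * exp(offsets[, 4] * variances[4])
  center_to_corner(cbind(cx, cy, w, h))
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Multibox loss with hard-negative mining
#'
#' Softmax cross-entropy classification plus smooth-L1 localisation over one
#' image's anchors: `(L_conf + L_loc) / N` with `N` the number of positive
#' (matched) anchors. Background anchors are subsampled to `neg_pos_ratio`
#' times the positives, keeping those with the largest classification loss
#' (ties: lowest anchor index). With no positives the loss is defined as 0.
#' Also returns the gradients w.r.t. the raw class scores and offsets, which
#' the training loop feeds back through the network.
#'
#' @param class_scores M x C matrix of raw (unnormalised) class scores;
#'   column 1 is background.
#' @param box_offsets M x 4 matrix of predicted offsets.
#' @param match A [match_anchors()] result.
#' @param defaults Default-box set (for target encoding).
#' @param neg_pos_ratio Negatives kept per positive (default 3).
#' @param variances Offset-coding variances.
#' @return List: `total`, `conf`, `loc`, `n_matched`, `dconf`, `dloc`.
#' @export
multibox_loss <- function(class_scores, box_offsets, match, defaults,
                          neg_pos_ratio = 3, variances = c(0.1, 0.1, 0.2, 0.2)) {
  M <- nrow(class_scores)
  if (M != length(match$class) || nrow(box_offsets) != M)
    stop_shape("multibox_loss: %d anchors in scores vs %d in match",
               M, length(match$class))
  C <- ncol(class_scores)
  pos <- which(match$class > 0L)
  npos <- length(pos)
  dconf <- matrix(0, M, C)
  dloc <- matrix(0, M, 4)
  if (npos == 0)
    return(list(total = 0, conf = 0, loc = 0, n_matched = 0L,
                dconf = dconf, dloc = dloc))
  p <- softmax_rows(class_scores)
  ce_bg <- -log(pmax(p[, 1], 1e-12))
  neg_cand <- setdiff(seq_len(M), pos)
  nneg <- min(length(neg_cand), ceiling(neg_pos_ratio * npos))
  neg <- neg_cand[order(-ce_bg[neg_cand])][seq_len(nneg)]
  target <- integer(M)                     # 0-based class column - 1
  target[pos] <- match$class[pos]
  sel <- c(pos, neg)
  l_conf <- sum(-log(pmax(p[cbind(sel, target[sel] + 1L)], 1e-12)))
  enc <- encode_boxes(match$box, defaults, variances)
  diff <- box_offsets[pos, , drop = FALSE] - enc[pos, , drop = FALSE]
  ad <- abs(diff)
  l_loc <- sum(ifelse(ad < 1, 0.5 * diff^2, ad - 0.5))
  # gradients
  onehot <- matrix(0, length(sel), C)
  onehot[cbind(seq_along(sel), target[sel] + 1L)] <- 1
  dconf[sel, ] <- (p[sel, , drop = FALSE] - onehot) / npos
  dloc[pos, ] <- ifelse(ad < 1, diff, sign(diff)) / npos
  list(total = (l_conf + l_loc) / npos, conf = l_conf / npos,
       loc = l_loc / npos, n_matched = npos, dconf = dconf, dloc = dloc)
}

#' Greedy non-maximum suppression
#'
#' @param boxes N x 4 corner-form matrix.
#' @param scores Length-N confidences.
#' @param iou_thresh Suppression threshold.
#' @param top_k Keep at most this many.
#' @return Integer indices of kept boxes, in descending score order (ties
#'   broken toward the lower index).
#' @export
nms <- function(boxes, scores, iou_thresh = 0.45, top_k = 200L) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord) && length(keep) < top_k) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord)) {
      iou <- as.vector(box_iou(boxes[i, , drop = FALSE],
                               boxes[ord, , drop = FALSE]))
      ord <- ord[iou <= iou_thresh]
    }
  }
  keep
}

#' Decode head outputs and apply per-class NMS
#'
#' @param class_scores M x C raw class scores for one image (column 1 =
#'   background).
#' @param box_offsets M x 4 predicted offsets.
#' @param defaults Default-box set.
#' @param conf_thresh Minimum class probability to consider.
#' @param nms_iou NMS suppression threshold.
#' @param top_k Maximum detections kept per class.
#' @param image_size If given, boxes are scaled to pixel coordinates.
#' @param variances Offset-coding variances.
#' @return Data frame of detections: `class`, `score`, `xmin`, `ymin`,
#'   `xmax`, `ymax`, sorted by descending score.
#' @export
decode_and_nms <- function(class_scores, box_offsets, defaults,
                           conf_thresh = 0.01, nms_iou = 0.45, top_k = 200L,
                           image_size = NULL,
                           variances = c(0.1, 0.1, 0.2, 0.2)) {
  p <- softmax_rows(class_scores)
  dec <- decode_boxes(box_offsets, defaults, variances)
  dec[dec < 0] <- 0
  dec[dec > 1] <- 1
  out <- list()
  for (cl in 2:ncol(p)) {
    sc <- p[, cl]
    idx <- which(sc >= conf_thresh)
    if (!length(idx)) next
    keep <- nms(dec[idx, , drop = FALSE], sc[idx], nms_iou, top_k)
    sel <- idx[keep]
    out[[length(out) + 1]] <- data.frame(
      class = cl - 1L, score = sc[sel],
      xmin = dec[sel, 1], ymin = dec[sel, 2],
      xmax = dec[sel, 3], ymax = dec[sel, 4])
  }
  if (!length(out))
    return(data.frame(class = integer(), score = numeric(), xmin = numeric(),
                      ymin = numeric(), xmax = numeric(), ymax = numeric()))
  d <- do.call(rbind, out)
  d <- d[order(-d$score), , drop = FALSE]
  rownames(d) <- NULL
  if (!is.null(image_size))
    d[, c("xmin", "ymin", "xmax", "ymax")] <-
      d[, c("xmin", "ymin", "xmax", "ymax")] * image_size
  d
}

#' Default-box configuration implied by a detector's head
#'
#' @param model An `affssd_model` built by [build_affssd()].
#' @param ... Overrides passed to [head_config()].
#' @return A [head_config()] matching the model's head sources.
#' @export
model_head_config <- function(model, ...) {
  if (is.null(model$meta$head)) stop_config("model has no detection head")
  sizes <- vapply(model$meta$head$source_shapes, `[`, 0L, 1)
  head_config(source_sizes = sizes,
              anchors_per_cell = model$meta$head$anchors, ...)
}
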