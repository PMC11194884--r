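# Pascal-VOC detection evaluation (per-class AP / mAP), training-curve
# logging, and feature-map visualisation.

#' Pascal-VOC average precision
#'
#' Ranks detections by descending confidence and greedily assigns each to the
#' highest-IoU unclaimed ground truth of the same class in the same image
#' (IoU >= `iou_thresh`); duplicates and unmatched detections are false
#' positives. Ground truths flagged `difficult` are excluded from the recall
#' denominator, and detections matching them count neither way. AP is either
#' the VOC2007 11-point interpolation or the continuous precision-envelope
#' area; mAP is the arithmetic mean over the ground-truth classes.
#'
#' @param detections Data frame with columns `image`, `class`, `score`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @param ground_truths Data frame with columns `image`, `class`, `xmin`,
#'   `ymin`, `xmax`, `ymax` and optionally `difficult` (0/1).
#' @param iou_thresh IoU threshold for a true positive (default 0.5).
#' @param protocol `"voc07"` (11-point) or `"continuous"`.
#' @return List with `per_class_ap`, `map`, and `protocol`.
#' @export
voc_average_precision <- function(detections, ground_truths,
                                  iou_thresh = 0.5,
                                  protocol = c("voc07", "continuous")) {
  protocol <- match.arg(protocol)
  classes <- sort(unique(ground_truths$class))
  unknown <- setdiff(unique(detections$class), classes)
  if (length(unknown))
    warning("detections contain class(es) with no ground truth: ",
            paste(unknown, collapse = ", "), " (counted as misses)")
  if (is.null(ground_truths$difficult)) ground_truths$difficult <- 0L
  aps <- vapply(classes, function(cl) {
    gt <- ground_truths[ground_truths$class == cl, , drop = FALSE]
    npos <- sum(gt$difficult == 0L)
    det <- detections[detections$class == cl, , drop = FALSE]
    if (nrow(det) == 0L) return(0)
    det <- det[order(-det$score), , drop = FALSE]
    claimed <- logical(nrow(gt))
    tp <- fp <- numeric(nrow(det))
    for (i in seq_len(nrow(det))) {
      g <- which(gt$image == det$image[i])
      if (length(g)) {
        iou <- as.vector(box_iou(
          as.matrix(det[i, c("xmin", "ymin", "xmax", "ymax")]),
          as.matrix(gt[g, c("xmin", "ymin", "xmax", "ymax")])))
        j <- which.max(iou)
        if (iou[j] >= iou_thresh) {
          gi <- g[j]
          if (gt$difficult[gi] == 1L) next         # ignored either way
          if (!claimed[gi]) { claimed[gi] <- TRUE; tp[i] <- 1 }
          else fp[i] <- 1
          next
        }
      }
      fp[i] <- 1
    }
    if (npos == 0L) return(0)
    rec <- cumsum(tp) / npos
    prec <- cumsum(tp) / pmax(cumsum(tp) + cumsum(fp), 1e-12)
    average_precision(rec, prec, protocol)
  }, 0)
  names(aps) <- as.character(classes)
  list(per_class_ap = aps,
       map = if (length(aps)) mean(aps) else 0,
       protocol = protocol)
}

average_precision <- function(recall, precision, protocol) {
  if (protocol == "voc07") {
    mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- precision[recall >= r]
      if (length(p)) max(p) else 0
    }, 0))
  } else {
    # precision envelope over recall, integrated (VOC2010+)
    mrec <- c(0, recall, 1)
    mpre <- c(0, precision, 0)
    for (i in rev(seq_len(length(mpre) - 1)))
      mpre[i] <- max(mpre[i], mpre[i + 1])
    idx <- which(mrec[-1] != mrec[-length(mrec)])
    sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
  }
}

#' Write (and round-trip) a training-curve log
#'
#' @param history Data frame with columns `iteration`, `loss`, and optionally
#'   `map`; iterations must be strictly increasing.
#' @param out_path CSV destination.
#' @return The path, invisibly.
#' @export
log_training_curves <- function(history, out_path) {
  if (is.null(history$map)) history$map <- rep(NA_real_, nrow(history))
  if (nrow(history) && any(diff(history$iteration) <= 0))
    stop_config("curve log iterations must be strictly increasing")
  write.csv(history[, c("iteration", "loss", "map")], out_path,
            row.names = FALSE)
  invisible(out_path)
}

#' @rdname log_training_curves
#' @param path CSV written by `log_training_curves`.
#' @export
read_training_curves <- function(path) {
  read.csv(path)
}

#' Render feature-map channels as a grayscale panel grid
#'
#' Each selected channel (or the channel-wise mean/max) is min-max normalised
#' to \[0, 1\] and written as one tile of a grayscale PNG grid. An all-constant
#' map renders as mid-gray.
#'
#' @param endpoint Feature map `(H, W, C)` (a batch dimension of 1 is
#'   accepted).
#' @param out_path PNG destination.
#' @param reduce `"none"` (one panel per channel), `"mean"`, or `"max"`.
#' @param max_channels Cap on the number of per-channel panels.
#' @return The path, invisibly.
#' @export
visualize_endpoint <- function(endpoint, out_path,
                               reduce = c("none", "mean", "max"),
                               max_channels = 16L) {
  reduce <- match.arg(reduce)
  d <- dim(endpoint)
  if (length(d) == 4L) {
    if (d[4] != 1L) stop_config("visualize one image at a time")
    dim(endpoint) <- d[1:3]
    d <- d[1:3]
  }
  panels <- if (reduce == "none") {
    lapply(seq_len(min(d[3], max_channels)), function(c) endpoint[, , c])
  } else {
    list(apply(endpoint, c(1, 2), if (reduce == "mean") mean else max))
  }
  norm <- lapply(panels, function(p) {
    rng <- range(p)
    if (diff(rng) < 1e-12) matrix(0.5, nrow(p), ncol(p))
    else (p - rng[1]) / diff(rng)
  })
  ncolp <- ceiling(sqrt(length(norm)))
  nrowp <- ceiling(length(norm) / ncolp)
  h <- d[1]; w <- d[2]
  canvas <- matrix(0, nrowp * h, ncolp * w)
  for (i in seq_along(norm)) {
    r <- (i - 1) %/% ncolp
    c <- (i - 1) %% ncolp
    canvas[r * h + seq_len(h), c * w + seq_len(w)] <- norm[[i]]
  }
  png::writePNG(canvas, out_path)
  invisible(out_path)
}
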