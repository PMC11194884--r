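# Seeded generator of endoscopy-like detection scenes: whitish, low-contrast
# elliptical "capsule" sheets on reddish multi-octave tissue texture, with
# Pascal-VOC directory layout and XML annotations. Internal box convention:
# 0-based half-open pixel intervals; the VOC XML boundary converts to 1-based
# closed intervals and back losslessly.

#' Scene specification for the synthetic capsule generator
#'
#' @param image_size Square image size in pixels.
#' @param n_targets Length-2 integer range (min, max) of capsules per scene.
#' @param intensity_offset Mean luminance lift of a capsule over the local
#'   background, on the \[0, 1\] scale.
#' @param eccentricity Range of the minor/major semi-axis ratio.
#' @param edge_softness Width of the soft ellipse edge as a fraction of the
#'   semi-minor axis.
#' @param base_color Background base RGB (reddish tissue).
#' @param noise_amplitude Amplitude of the 3-octave value noise texture.
#' @param occlusion_prob Probability that a capsule is partially crossed by a
#'   darker tissue band.
#' @param min_box_frac Minimum box area as a fraction of the image area.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 300L, n_targets = c(1L, 3L),
                       intensity_offset = 0.30, eccentricity = c(0.5, 0.9),
                       edge_softness = 0.25,
                       base_color = c(0.52, 0.24, 0.22),
                       noise_amplitude = 0.12, occlusion_prob = 0.15,
                       min_box_frac = 0.02) {
  if (length(n_targets) == 1L) n_targets <- rep(n_targets, 2L)
  stopifnot(image_size >= 32, n_targets[1] >= 0, n_targets[2] >= n_targets[1],
            intensity_offset > 0, min_box_frac > 0)
  structure(list(image_size = as.integer(image_size),
                 n_targets = as.integer(n_targets),
                 intensity_offset = intensity_offset,
                 eccentricity = eccentricity, edge_softness = edge_softness,
                 base_color = base_color, noise_amplitude = noise_amplitude,
                 occlusion_prob = occlusion_prob, min_box_frac = min_box_frac),
            class = "scene_spec")
}

# Multi-octave value noise in [-1, 1]-ish range, deterministic under the
# caller's RNG state.
value_noise <- function(size, octaves = 3L, base_grid = 6L) {
  acc <- matrix(0, size, size)
  amp <- 1
  grid <- base_grid
  for (o in seq_len(octaves)) {
    g <- matrix(runif((grid + 1)^2, -1, 1), grid + 1, grid + 1)
    acc <- acc + amp * resize_bilinear(array(g, c(grid + 1, grid + 1, 1)),
                                       size, size)[, , 1]
    amp <- amp / 2
    grid <- grid * 2
  }
  acc / (2 - 2^(1 - octaves))
}

#' Generate one synthetic capsule scene
#'
#' Renders a reddish tissue-textured background and `n_targets` whitish
#' soft-edged elliptical capsule regions. Deterministic for a fixed seed;
#' all boxes lie fully inside the image and cover at least `min_box_frac`
#' of its area.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @param n_targets Optional override of the per-scene target count.
#' @return List with `image` (`H x W x 3` array in \[0, 1\]) and `boxes`
#'   (data frame `xmin`, `ymin`, `xmax`, `ymax` in 0-based half-open pixel
#'   coordinates, plus `class`).
#' @export
generate_scene <- function(spec = scene_spec(), seed = 0L, n_targets = NULL) {
  with_seed(seed, {
    S <- spec$image_size
    if (is.null(n_targets))
      n_targets <- if (spec$n_targets[1] == spec$n_targets[2])
        spec$n_targets[1] else
        sample(spec$n_targets[1]:spec$n_targets[2], 1L)
    img <- array(0, c(S, S, 3))
    tex <- value_noise(S)
    shade <- value_noise(S, octaves = 2L, base_grid = 3L)
    for (c in 1:3)
      img[, , c] <- spec$base_color[c] + spec$noise_amplitude * tex +
        0.06 * shade * (c == 1)
    boxes <- NULL
    if (n_targets > 0) {
      placed <- matrix(numeric(0), 0, 4)
      xg <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # x varies by col
      yg <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # y varies by row
      for (t in seq_len(n_targets)) {
        ok <- FALSE
        for (try in 1:60) {
          a <- runif(1, 0.11, 0.22) * S
          ratio <- runif(1, spec$eccentricity[1], spec$eccentricity[2])
          b <- a * ratio
          if (runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
          if (4 * a * b < spec$min_box_frac * S^2) next
          cx <- runif(1, a + 2, S - a - 2)
          cy <- runif(1, b + 2, S - b - 2)
          cand <- c(cx - a, cy - b, cx + a, cy + b)
          if (nrow(placed) &&
              max(box_iou(matrix(cand, 1), placed)) > 0.25) next
          ok <- TRUE
          break
        }
        if (!ok)
          stop(sprintf("could not place target %d after 60 tries (seed %d)",
                       t, seed), call. = FALSE)
        placed <- rbind(placed, cand)
        rr <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2)
        alpha <- pmin(1, pmax(0, (1 - rr) / spec$edge_softness))
        cap_col <- c(0.93, 0.90, 0.86)
        lift <- spec$intensity_offset / 0.3    # calibrated so the configured
        strength <- pmin(1, alpha * lift)      # offset is met at default mix
        cap_tex <- 0.05 * value_noise(S, octaves = 2L, base_grid = 10L)
        if (runif(1) < spec$occlusion_prob) {
          # darker band crossing the capsule
          ang <- runif(1, 0, pi)
          dist <- (xg - cx) * cos(ang) + (yg - cy) * sin(ang)
          band <- exp(-(dist / (0.25 * b))^2) * 0.5
          strength <- strength * (1 - band)
        }
        for (c in 1:3)
          img[, , c] <- img[, , c] * (1 - strength) +
            (cap_col[c] + cap_tex) * strength
      }
      boxes <- data.frame(xmin = placed[, 1], ymin = placed[, 2],
                          xmax = placed[, 3], ymax = placed[, 4],
                          class = "capsule", stringsAsFactors = FALSE)
      # snap to integer pixel bounds, staying inside the image
      boxes$xmin <- pmax(floor(boxes$xmin), 0)
      boxes$ymin <- pmax(floor(boxes$ymin), 0)
      boxes$xmax <- pmin(ceiling(boxes$xmax), S)
      boxes$ymax <- pmin(ceiling(boxes$ymax), S)
    } else {
      boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                          xmax = numeric(0), ymax = numeric(0),
                          class = character(0), stringsAsFactors = FALSE)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, boxes = boxes)
  })
}

#' Write / read Pascal-VOC XML annotations
#'
#' Boxes are converted between the internal 0-based half-open convention and
#' the VOC 1-based closed-interval XML fields (`xmin_xml = xmin + 1`,
#' `xmax_xml = xmax`), a lossless round trip on integer bounds.
#'
#' @param path XML file path.
#' @param filename Image file name recorded in the annotation.
#' @param size Length-2 integer (width, height) or length-3 with depth.
#' @param boxes Data frame with `xmin`, `ymin`, `xmax`, `ymax`, `class` and
#'   optionally `difficult`.
#' @return `write_voc_annotation` returns the path invisibly;
#'   `read_voc_annotation` returns a list with `filename`, `size`, `boxes`.
#' @export
write_voc_annotation <- function(path, filename, size, boxes) {
  if (length(size) == 2L) size <- c(size, 3L)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "JPEGImages")
  xml2::xml_add_child(doc, "filename", filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(size[1]))
  xml2::xml_add_child(sz, "height", as.character(size[2]))
  xml2::xml_add_child(sz, "depth", as.character(size[3]))
  if (!is.null(boxes) && nrow(boxes)) {
    diff <- if (is.null(boxes$difficult)) rep(0L, nrow(boxes)) else boxes$difficult
    for (i in seq_len(nrow(boxes))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", as.character(boxes$class[i]))
      xml2::xml_add_child(ob, "difficult", as.character(diff[i]))
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(as.integer(boxes$xmin[i]) + 1L))
      xml2::xml_add_child(bb, "ymin", as.character(as.integer(boxes$ymin[i]) + 1L))
      xml2::xml_add_child(bb, "xmax", as.character(as.integer(boxes$xmax[i])))
      xml2::xml_add_child(bb, "ymax", as.character(as.integer(boxes$ymax[i])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_voc_annotation
#' @export
read_voc_annotation <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse VOC annotation '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  filename <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  sz <- xml2::xml_find_first(doc, "./size")
  size <- c(as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./width"))),
            as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./height"))))
  objs <- xml2::xml_find_all(doc, "./object")
  get_num <- function(ob, field) {
    nd <- xml2::xml_find_first(ob, paste0("./bndbox/", field))
    if (inherits(nd, "xml_missing"))
      stop("annotation '", path, "': object is missing bndbox/", field,
           call. = FALSE)
    v <- suppressWarnings(as.numeric(xml2::xml_text(nd)))
    if (is.na(v))
      stop("annotation '", path, "': non-numeric bndbox/", field,
           call. = FALSE)
    v
  }
  boxes <- if (length(objs)) {
    data.frame(
      xmin = vapply(objs, get_num, 0, "xmin") - 1,
      ymin = vapply(objs, get_num, 0, "ymin") - 1,
      xmax = vapply(objs, get_num, 0, "xmax"),
      ymax = vapply(objs, get_num, 0, "ymax"),
      class = vapply(objs, function(o)
        xml2::xml_text(xml2::xml_find_first(o, "./name")), ""),
      difficult = vapply(objs, function(o) {
        d <- xml2::xml_text(xml2::xml_find_first(o, "./difficult"))
        if (is.na(d)) 0L else as.integer(d)
      }, 0L),
      stringsAsFactors = FALSE)
  } else {
    data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
               ymax = numeric(0), class = character(0),
               difficult = integer(0), stringsAsFactors = FALSE)
  }
  list(filename = filename, size = size, boxes = boxes)
}

#' Generate a Pascal-VOC-layout synthetic dataset
#'
#' Writes `JPEGImages/` (lossless PNG image files), `Annotations/` (VOC XML)
#' and `ImageSets/Main/{train,test}.txt` under `out_dir`. Deterministic for a
#' fixed seed: per-image seeds are drawn once from the dataset seed, so
#' re-running reproduces byte-identical images and annotations. The default
#' split sizes are 478 training and 119 test scenes.
#'
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite`).
#' @param n_train,n_test Split sizes.
#' @param spec A [scene_spec()].
#' @param seed Dataset seed.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return A manifest list: `root`, `train`, `test` (image ids), `classes`,
#'   `image_size`.
#' @export
generate_dataset <- function(out_dir, n_train = 478L, n_test = 119L,
                             spec = scene_spec(), seed = 0L,
                             overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop_config("output directory '%s' is not empty (use overwrite = TRUE)",
                out_dir)
  for (d in c("JPEGImages", "Annotations", file.path("ImageSets", "Main")))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  img_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("scene_%05d", seq_len(n))
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seed = img_seeds[i])
    png::writePNG(sc$image, file.path(out_dir, "JPEGImages",
                                      paste0(ids[i], ".png")))
    write_voc_annotation(file.path(out_dir, "Annotations",
                                   paste0(ids[i], ".xml")),
                         paste0(ids[i], ".png"),
                         c(spec$image_size, spec$image_size),
                         sc$boxes)
  }
  train <- ids[seq_len(n_train)]
  test <- if (n_test > 0) ids[n_train + seq_len(n_test)] else character(0)
  writeLines(train, file.path(out_dir, "ImageSets", "Main", "train.txt"))
  writeLines(test, file.path(out_dir, "ImageSets", "Main", "test.txt"))
  dataset_manifest(out_dir)
}

#' Read a VOC-layout dataset manifest
#'
#' @param root Dataset root containing `JPEGImages`, `Annotations`,
#'   `ImageSets/Main`.
#' @return Manifest list: `root`, `train`, `test`, `classes`, `image_size`.
#' @export
dataset_manifest <- function(root) {
  rl <- function(f) {
    p <- file.path(root, "ImageSets", "Main", f)
    if (file.exists(p)) {
      x <- readLines(p)
      x[nzchar(x)]
    } else character(0)
  }
  train <- rl("train.txt")
  test <- rl("test.txt")
  if (length(intersect(train, test)))
    stop_config("train and test splits overlap")
  ids <- c(train, test)
  classes <- character(0)
  size <- NA_integer_
  if (length(ids)) {
    for (id in ids) {
      ann <- read_voc_annotation(file.path(root, "Annotations",
                                           paste0(id, ".xml")))
      classes <- union(classes, ann$boxes$class)
      if (is.na(size)) size <- ann$size[1]
    }
  }
  list(root = root, train = train, test = test,
       classes = sort(classes), image_size = size)
}

#' Load one dataset image and its boxes
#'
#' @param manifest A dataset manifest.
#' @param id Image id (file stem).
#' @return List with `image` (`H x W x 3`), `boxes` (pixel coordinates), and
#'   `size`.
#' @export
load_example <- function(manifest, id) {
  img <- png::readPNG(file.path(manifest$root, "JPEGImages",
                                paste0(id, ".png")))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  ann <- read_voc_annotation(file.path(manifest$root, "Annotations",
                                       paste0(id, ".xml")))
  list(image = img[, , 1:3, drop = FALSE], boxes = ann$boxes,
       size = ann$size)
}
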