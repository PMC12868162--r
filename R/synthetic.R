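# Seeded synthetic paddy-scene generator: dense overlapping elongated
# "plant" blobs over textured ground, with shadow polygons and specular
# specks emulating the clutter of UAV rice imagery, plus YOLO-format
# annotation output and feature-map fixtures for unit tests.

gsd_scales <- c(fine = 1.0, medium = 0.6, coarse = 0.35)

#' Synthetic scene configuration
#'
#' Describes one family of synthetic UAV-style paddy scenes. Plants are
#' rendered as rotated elongated ellipses with per-instance hue jitter;
#' clutter comprises dark shadow polygons, bright specular specks and pixel
#' noise. The `gsd_level` scales plant size to emulate the three capture
#' altitudes of UAV surveys (fine/medium/coarse ground-sample distance).
#'
#' @param image_size square image side in pixels.
#' @param n_plants number of plants (>= 0).
#' @param length_range,width_range plant major/minor axis diameter ranges in
#'   pixels (before GSD scaling).
#' @param overlap_target fraction in `[0, 1]`: probability that a plant is
#'   placed adjacent to an existing one, driving overlapping canopies.
#' @param n_shadows,n_specks clutter element counts.
#' @param noise_sd standard deviation of additive pixel noise (in `[0,1]`
#'   intensity units).
#' @param gsd_level `"fine"`, `"medium"` or `"coarse"`.
#' @param class_id class label written for every plant.
#' @param seed integer seed; scenes are pure functions of (config, seed).
#' @return object of class `ivy_scene_config`.
#' @export
scene_config <- function(image_size = 320L, n_plants = 25L,
                         length_range = c(20, 44), width_range = c(6, 11),
                         overlap_target = 0.3, n_shadows = 6L,
                         n_specks = 40L, noise_sd = 0.02,
                         gsd_level = c("fine", "medium", "coarse"),
                         class_id = 0L, seed = 0L) {
  gsd_level <- match.arg(gsd_level)
  stopifnot(n_plants >= 0, all(length_range > 0), all(width_range > 0),
            overlap_target >= 0, overlap_target <= 1,
            n_shadows >= 0, n_specks >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_plants = as.integer(n_plants),
                 length_range = length_range, width_range = width_range,
                 overlap_target = overlap_target,
                 n_shadows = as.integer(n_shadows),
                 n_specks = as.integer(n_specks),
                 noise_sd = noise_sd, gsd_level = gsd_level,
                 class_id = as.integer(class_id), seed = as.integer(seed)),
            class = "ivy_scene_config")
}

#' Generate one synthetic paddy scene
#'
#' Fully determined by `config` (including its seed): the same configuration
#' always yields byte-identical pixels and labels. Pixels are quantized to
#' 8-bit levels so that a written PNG reads back exactly.
#'
#' @param config an [scene_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `ivy_image_sample`: `pixels` (H x W x 3 array in
#'   `[0,1]`, 8-bit quantized), `boxes` (matrix `class, cx, cy, w, h`,
#'   normalized), `image_id`.
#' @export
generate_scene <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ivy_scene_config"))
  if (is.null(seed)) seed <- config$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- config$image_size
  sc <- gsd_scales[[config$gsd_level]]
  if (max(config$length_range) * sc >= n)
    stop("plant size exceeds the image")

  # textured ground: brown-green base + low-frequency illumination field
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  lf <- 0.05 * sin(2 * pi * ii / n * runif(1, 1, 3) + runif(1, 0, 2 * pi)) *
    cos(2 * pi * jj / n * runif(1, 1, 3) + runif(1, 0, 2 * pi))
  base <- c(0.32, 0.36, 0.22)
  px <- array(0, dim = c(n, n, 3))
  for (c in 1:3) px[, , c] <- base[c] + lf +
    matrix(rnorm(n * n, sd = 0.015), n, n)

  boxes <- matrix(numeric(0), 0, 5)
  centers <- matrix(numeric(0), 0, 2)
  if (config$n_plants > 0) for (p in seq_len(config$n_plants)) {
    a <- runif(1, config$length_range[1], config$length_range[2]) * sc / 2
    b <- runif(1, config$width_range[1], config$width_range[2]) * sc / 2
    phi <- runif(1, 0, pi)
    attach_prev <- nrow(centers) > 0 && runif(1) < config$overlap_target
    if (attach_prev) {
      anchor <- centers[sample.int(nrow(centers), 1L), ]
      ctr <- anchor + rnorm(2, sd = a)
      ctr <- clamp(ctr, 0.06 * n, 0.94 * n)
    } else {
      ctr <- runif(2, 0.06 * n, 0.94 * n)
    }
    xc <- ctr[1]; yc <- ctr[2]            # xc: column coord, yc: row coord
    centers <- rbind(centers, ctr)
    # rasterize the rotated ellipse over its bounding window
    ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
    ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
    j0 <- max(1, floor(xc - ex)); j1 <- min(n, ceiling(xc + ex))
    i0 <- max(1, floor(yc - ey)); i1 <- min(n, ceiling(yc + ey))
    jw <- j0:j1; iw <- i0:i1
    u <- outer(iw - yc, rep(1, length(jw)))      # row offsets
    v <- outer(rep(1, length(iw)), jw - xc)      # column offsets
    rot_u <- v * cos(phi) + u * sin(phi)          # along major axis
    rot_v <- -v * sin(phi) + u * cos(phi)
    inside <- (rot_u / a)^2 + (rot_v / b)^2 <= 1
    hue <- c(0.45, 0.55, 0.26) + rnorm(3, sd = 0.04)
    shade <- 1 - 0.25 * abs(rot_u / a)            # brighter near the center
    for (c in 1:3) {
      plane <- px[iw, jw, c]
      plane[inside] <- (hue[c] * shade)[inside]
      px[iw, jw, c] <- plane
    }
    boxes <- rbind(boxes, c(config$class_id,
                            xc / n, yc / n,
                            2 * ex / n, 2 * ey / n))
  }

  # shadow polygons (triangles): darken
  if (config$n_shadows > 0) for (s in seq_len(config$n_shadows)) {
    ctr <- runif(2, 0.1 * n, 0.9 * n)
    r <- runif(1, 0.03, 0.12) * n
    ang <- sort(runif(3, 0, 2 * pi))
    vx <- ctr[1] + r * cos(ang); vy <- ctr[2] + r * sin(ang)
    j0 <- max(1, floor(min(vx))); j1 <- min(n, ceiling(max(vx)))
    i0 <- max(1, floor(min(vy))); i1 <- min(n, ceiling(max(vy)))
    if (j1 <= j0 || i1 <= i0) next
    jw <- j0:j1; iw <- i0:i1
    pxg <- outer(rep(1, length(iw)), jw)
    pyg <- outer(iw, rep(1, length(jw)))
    inside <- point_in_tri(pxg, pyg, vx, vy)
    dark <- runif(1, 0.45, 0.7)
    for (c in 1:3) {
      plane <- px[iw, jw, c]
      plane[inside] <- plane[inside] * dark
      px[iw, jw, c] <- plane
    }
  }

  # specular specks: small bright reflections
  if (config$n_specks > 0) for (s in seq_len(config$n_specks)) {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    rad <- sample(0:1, 1L)
    iw <- max(1, i - rad):min(n, i + rad)
    jw <- max(1, j - rad):min(n, j + rad)
    px[iw, jw, ] <- pmin(1, px[iw, jw, , drop = FALSE] + runif(1, 0.3, 0.6))
  }

  if (config$noise_sd > 0)
    px <- px + array(rnorm(length(px), sd = config$noise_sd), dim(px))
  px <- clamp(px, 0, 1)
  px <- round(px * 255) / 255            # 8-bit quantization

  if (nrow(boxes) > 0) {
    # clip boxes to the unit square, preserving positive area
    x1 <- clamp(boxes[, 2] - boxes[, 4] / 2, 0, 1)
    x2 <- clamp(boxes[, 2] + boxes[, 4] / 2, 0, 1)
    y1 <- clamp(boxes[, 3] - boxes[, 5] / 2, 0, 1)
    y2 <- clamp(boxes[, 3] + boxes[, 5] / 2, 0, 1)
    boxes <- cbind(boxes[, 1], (x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
  }
  colnames(boxes) <- c("class", "cx", "cy", "w", "h")
  structure(list(pixels = px, boxes = boxes,
                 image_id = sprintf("scene_%d", seed)),
            class = "ivy_image_sample")
}

# barycentric point-in-triangle test over coordinate grids
point_in_tri <- function(pxg, pyg, vx, vy) {
  d <- (vy[2] - vy[3]) * (vx[1] - vx[3]) + (vx[3] - vx[2]) * (vy[1] - vy[3])
  l1 <- ((vy[2] - vy[3]) * (pxg - vx[3]) + (vx[3] - vx[2]) * (pyg - vy[3])) / d
  l2 <- ((vy[3] - vy[1]) * (pxg - vx[3]) + (vx[1] - vx[3]) * (pyg - vy[3])) / d
  l3 <- 1 - l1 - l2
  l1 >= 0 & l2 >= 0 & l3 >= 0
}

#' Write a synthetic dataset in YOLO layout
#'
#' Renders `n` scenes (scene `i` uses seed `config$seed + i - 1`) and writes
#' `images/*.png`, `labels/*.txt` (one `class cx cy w h` line per object,
#' 6-decimal fixed point) and a JSON manifest recording the configuration,
#' seeds and file list. Regenerating from the same configuration reproduces
#' identical files.
#'
#' @param n number of scenes.
#' @param config an [scene_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(n, config, out_dir) {
  stopifnot(n >= 0)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- vector("list", n)
  if (n > 0) for (i in seq_len(n)) {
    s <- generate_scene(config, seed = config$seed + i - 1L)
    id <- sprintf("img_%04d", i)
    img_path <- file.path(out_dir, "images", paste0(id, ".png"))
    lbl_path <- file.path(out_dir, "labels", paste0(id, ".txt"))
    png::writePNG(s$pixels, img_path)
    write_yolo_labels(s$boxes, lbl_path)
    entries[[i]] <- list(id = id, image = file.path("images",
                                                    paste0(id, ".png")),
                         label = file.path("labels", paste0(id, ".txt")),
                         seed = config$seed + i - 1L,
                         n_objects = nrow(s$boxes))
  }
  manifest <- list(n = n, config = unclass(config), samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read and write YOLO-format label files
#'
#' @param boxes matrix with columns `class, cx, cy, w, h` (normalized).
#' @param path label file path.
#' @return `read_yolo_labels` returns the boxes matrix (0 rows for an empty
#'   or missing file).
#' @export
write_yolo_labels <- function(boxes, path) {
  lines <- if (nrow(boxes) > 0)
    sprintf("%d %.6f %.6f %.6f %.6f", as.integer(boxes[, 1]),
            boxes[, 2], boxes[, 3], boxes[, 4], boxes[, 5])
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  out <- matrix(numeric(0), 0, 5,
                dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  if (!file.exists(path)) return(out)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(out)
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  if (ncol(m) != 5) stop("malformed YOLO label file: ", path)
  colnames(m) <- c("class", "cx", "cy", "w", "h")
  m
}

#' Load a YOLO-layout dataset directory
#'
#' @param dir directory containing `images/` and `labels/`.
#' @return list of `ivy_image_sample` objects.
#' @export
load_yolo_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no PNG images found under ", dir)
  lapply(imgs, function(f) {
    id <- tools::file_path_sans_ext(basename(f))
    px <- png::readPNG(f)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    lbl <- file.path(dir, "labels", paste0(id, ".txt"))
    structure(list(pixels = px[, , 1:3, drop = FALSE],
                   boxes = read_yolo_labels(lbl), image_id = id),
              class = "ivy_image_sample")
  })
}

#' Feature-map fixtures for unit testing
#'
#' Deterministic small tensors: `constant` (a single value everywhere),
#' `ramp` (`v(i,j,c) = 100 i + 10 j + c`, 0-based indices), `two_blobs`
#' (two overlapping Gaussian bumps living in distinct channel groups plus
#' uniform noise — the "adhesion" fixture) and `random` (seeded standard
#' normal).
#'
#' @param H,W,C dimensions.
#' @param pattern fixture family.
#' @param seed seed for the stochastic patterns.
#' @param value fill value for `constant`.
#' @return feature map array (H, W, C).
#' @export
make_feature_fixture <- function(H, W, C,
                                 pattern = c("constant", "ramp", "two_blobs",
                                             "random"),
                                 seed = 0L, value = 1) {
  pattern <- match.arg(pattern)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  switch(pattern,
         constant = array(value, c(H, W, C)),
         ramp = {
           out <- array(0, c(H, W, C))
           for (c in 0:(C - 1))
             out[, , c + 1] <- outer(0:(H - 1), 0:(W - 1),
                                     function(i, j) 100 * i + 10 * j + c)
           out
         },
         two_blobs = {
           out <- array(runif(H * W * C, 0, 0.05), c(H, W, C))
           g <- function(ci, cj, s)
             outer(seq_len(H), seq_len(W),
                   function(i, j) exp(-((i - ci)^2 + (j - cj)^2) / (2 * s^2)))
           g1 <- g(H / 3, W / 3, max(2, H / 6))
           g2 <- g(2 * H / 3, 2 * W / 3, max(2, H / 6))
           half <- max(1L, C %/% 2L)
           for (c in seq_len(half)) out[, , c] <- out[, , c] + g1
           for (c in (half + 1):C) if (half < C)
             out[, , c] <- out[, , c] + g2
           out
         },
         random = array(rnorm(H * W * C), c(H, W, C)))
}
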