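## Embedding rendered human layers into backgrounds anchored to bed regions,
## the dataset-style rotation augmentation, and bed-region sidecar I/O.
## Annotations are carried exactly through every transform.

#' Construct a background asset
#'
#' @param image h x w x 3 array in [0, 1].
#' @param bed_bbox `[x, y, w, h]` pixels; must lie inside the image.
#' @param id identifier string.
#' @return an object of class `background_asset`.
#' @export
background_asset <- function(image, bed_bbox, id = "bg") {
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L) stop("background image must be h x w x 3")
  bb <- as.numeric(bed_bbox)
  if (length(bb) != 4L || bb[3] <= 0 || bb[4] <= 0 ||
      bb[1] < 0 || bb[2] < 0 || bb[1] + bb[3] > d[2] || bb[2] + bb[4] > d[1]) {
    stop("bed_bbox must be a positive box inside the image bounds")
  }
  structure(list(image = image[, , 1:3, drop = FALSE], bed_bbox = bb, id = id),
            class = "background_asset")
}

# overlap of box a with box b as a fraction of a's area
overlap_fraction <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  (ix * iy) / (a[3] * a[4])
}

dilate_box <- function(b, frac) {
  c(b[1] - b[3] * frac / 2, b[2] - b[4] * frac / 2,
    b[3] * (1 + frac), b[4] * (1 + frac))
}

#' Composite a rendered layer into a background near its bed
#'
#' Chooses a uniform scale so the human's long axis is a (sampled) fraction
#' of the bed box's long axis, then samples a translation until the placed
#' human bounding box overlaps the dilated bed box by at least
#' `min_overlap` of its own area ("near or on the bed"). The layer is
#' alpha-composited over the background; keypoints and the bounding box are
#' mapped through the same similarity transform and clipped to the image
#' (keypoints leaving the frame get visibility 0).
#'
#' @param layer a `rendered_layer` with a non-empty bbox.
#' @param bg a `background_asset`.
#' @param scale_frac_range human long axis as a fraction of the bed long
#'   axis; a value is drawn uniformly from this range.
#' @param min_overlap minimum overlap fraction with the dilated bed box.
#' @param bed_dilate bed-box dilation fraction.
#' @param max_tries placement attempts before failing.
#' @param transform optional explicit `list(scale=, tx=, ty=)` bypassing the
#'   sampler (used for exactness tests and provenance replay).
#' @return an object of class `composite_image`: `image` (h x w x 3),
#'   `keypoints2d`, `bbox`, `provenance` (background id + transform).
#' @export
place_and_composite <- function(layer, bg, scale_frac_range = c(0.6, 0.95),
                                min_overlap = 0.3, bed_dilate = 0.2,
                                max_tries = 100L, transform = NULL) {
  if (is.null(layer$bbox)) stop("cannot place an empty (fully transparent) layer")
  d <- dim(bg$image)
  h <- d[1]; w <- d[2]
  lb <- layer$bbox
  bed <- dilate_box(bg$bed_bbox, bed_dilate)
  if (is.null(transform)) {
    found <- FALSE
    for (try in seq_len(max_tries)) {
      frac <- stats::runif(1, scale_frac_range[1], scale_frac_range[2])
      s <- frac * max(bg$bed_bbox[3], bg$bed_bbox[4]) / max(lb[3], lb[4])
      # place the scaled human-box centre uniformly inside the dilated bed box
      cxr <- stats::runif(1, bed[1], bed[1] + bed[3])
      cyr <- stats::runif(1, bed[2], bed[2] + bed[4])
      tx <- cxr - s * (lb[1] + lb[3] / 2)
      ty <- cyr - s * (lb[2] + lb[4] / 2)
      hb <- c(s * lb[1] + tx, s * lb[2] + ty, s * lb[3], s * lb[4])
      ok_overlap <- overlap_fraction(hb, bed) >= min_overlap
      on_canvas <- overlap_fraction(hb, c(0, 0, w, h)) >= 0.5
      if (ok_overlap && on_canvas) { found <- TRUE; break }
    }
    if (!found) {
      stop(sprintf(paste0(
        "no feasible placement after %d tries (bed box [%g, %g, %g, %g], ",
        "layer box [%g, %g, %g, %g], min_overlap %g)"),
        max_tries, bg$bed_bbox[1], bg$bed_bbox[2], bg$bed_bbox[3],
        bg$bed_bbox[4], lb[1], lb[2], lb[3], lb[4], min_overlap))
    }
  } else {
    s <- transform$scale; tx <- transform$tx; ty <- transform$ty
  }
  lh <- dim(layer$rgba)[1]; lw <- dim(layer$rgba)[2]
  img <- composite_layer_cpp(bg$image, layer$rgba, s, tx, ty, h, w, lh, lw)
  kp <- layer$keypoints2d
  kx <- s * kp[, 1] + tx
  ky <- s * kp[, 2] + ty
  kv <- kp[, 3]
  kv[kx < 0 | kx >= w | ky < 0 | ky >= h] <- 0L
  hb <- c(s * lb[1] + tx, s * lb[2] + ty, s * lb[3], s * lb[4])
  clipped <- clip_box(hb, w, h)
  structure(list(
    image = img,
    keypoints2d = cbind(x = kx, y = ky, v = kv),
    bbox = clipped,
    joints3d = layer$joints3d,
    provenance = list(background_id = bg$id,
                      transform = list(scale = s, tx = tx, ty = ty))),
    class = "composite_image")
}

clip_box <- function(b, w, h) {
  x0 <- max(0, b[1]); y0 <- max(0, b[2])
  x1 <- min(w, b[1] + b[3]); y1 <- min(h, b[2] + b[4])
  if (x1 <= x0 || y1 <= y0) return(NULL)
  c(x0, y0, x1 - x0, y1 - y0)
}

#' Rotation augmentation toward lying-down poses
#'
#' Draws an angle uniformly from the two-interval union 70-110 or -110 to
#' -70 degrees (equal mass per interval), rotates the image about its centre
#' onto an expanded canvas that contains every source pixel (exposed canvas
#' is black), and maps keypoints and boxes through the same transform. With
#' the default convention, a +90 degree rotation of a w x h image yields an
#' h x w image with pixel `(x, y)` mapped to `(h - 1 - y, x)`. The bounding
#' box is recomputed as the tight box of the rotated source-box corners, or
#' of the rotated labelled keypoints when `bbox_from = "keypoints"`.
#'
#' @param image h x w x ch array.
#' @param annotations list of records, each with `bbox` and optionally
#'   `keypoints2d` (n x 3).
#' @param intervals_deg 2 x 2 matrix of `[low, high]` rows.
#' @param angle_deg optional fixed angle (bypasses sampling).
#' @param bbox_from `"corners"` (default) or `"keypoints"`.
#' @return list with `image`, `annotations` (transformed), `angle_deg`.
#' @export
rotate_augment <- function(image, annotations = list(),
                           intervals_deg = rbind(c(70, 110), c(-110, -70)),
                           angle_deg = NULL, bbox_from = c("corners", "keypoints")) {
  bbox_from <- match.arg(bbox_from)
  if (is.null(angle_deg)) {
    iv <- intervals_deg[sample.int(nrow(intervals_deg), 1L), ]
    angle_deg <- stats::runif(1, iv[1], iv[2])
  }
  th <- angle_deg * pi / 180
  d <- dim(image)
  h <- d[1]; w <- d[2]; ch <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(image) <- c(h, w, 1L)
  wout <- as.integer(ceiling(w * abs(cos(th)) + h * abs(sin(th)) - 1e-9))
  hout <- as.integer(ceiling(w * abs(sin(th)) + h * abs(cos(th)) - 1e-9))
  out <- rotate_image_cpp(image, th, h, w, ch, hout, wout)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  ctro <- c((wout - 1) / 2, (hout - 1) / 2)
  rot_pts <- function(p) {
    # p: n x 2; pixel-coordinate rotation (x right, y down)
    dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
    cbind(cos(th) * dx - sin(th) * dy + ctro[1],
          sin(th) * dx + cos(th) * dy + ctro[2])
  }
  ann_out <- lapply(annotations, function(a) {
    if (!is.null(a$keypoints2d)) {
      kp <- rot_pts(a$keypoints2d[, 1:2, drop = FALSE])
      a$keypoints2d[, 1:2] <- kp
      v <- a$keypoints2d[, 3]
      off <- kp[, 1] < 0 | kp[, 1] >= wout | kp[, 2] < 0 | kp[, 2] >= hout
      a$keypoints2d[off, 3] <- 0L
    }
    if (!is.null(a$bbox)) {
      b <- a$bbox
      if (bbox_from == "keypoints" && !is.null(a$keypoints2d) &&
          any(a$keypoints2d[, 3] > 0)) {
        pts <- a$keypoints2d[a$keypoints2d[, 3] > 0, 1:2, drop = FALSE]
      } else {
        pts <- rot_pts(rbind(c(b[1], b[2]), c(b[1] + b[3], b[2]),
                             c(b[1], b[2] + b[4]), c(b[1] + b[3], b[2] + b[4])))
      }
      a$bbox <- c(min(pts[, 1]), min(pts[, 2]),
                  max(pts[, 1]) - min(pts[, 1]), max(pts[, 2]) - min(pts[, 2]))
    }
    a
  })
  list(image = out, annotations = ann_out, angle_deg = angle_deg)
}

#' Load a background image with its bed-region sidecar
#'
#' The sidecar is a small JSON file (same path with extension `.json`)
#' holding the image id and the bed bounding box; it substitutes for a bed
#' detector, keeping the pipeline download-free. A pluggable detector can be
#' passed to [run_generate()] instead.
#'
#' @param image_path path to a PNG background.
#' @param sidecar_path path to the JSON sidecar; defaults to
#'   `<image_path>.json`.
#' @return a `background_asset`.
#' @export
load_bed_sidecar <- function(image_path,
                             sidecar_path = paste0(image_path, ".json")) {
  if (!file.exists(image_path)) stop("background image not found: ", image_path)
  if (!file.exists(sidecar_path)) stop("bed sidecar not found: ", sidecar_path)
  img <- png::readPNG(image_path)
  meta <- jsonlite::fromJSON(sidecar_path)
  if (is.null(meta$bed_bbox)) stop("sidecar lacks a bed_bbox: ", sidecar_path)
  background_asset(img, as.numeric(meta$bed_bbox),
                   id = if (!is.null(meta$id)) meta$id else basename(image_path))
}

#' Save a background asset as PNG + sidecar
#' @param asset a `background_asset`.
#' @param image_path destination PNG path.
#' @return `image_path`, invisibly.
#' @export
save_bed_sidecar <- function(asset, image_path) {
  png::writePNG(asset$image, image_path)
  jsonlite::write_json(list(id = asset$id, bed_bbox = asset$bed_bbox),
                       paste0(image_path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}
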