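## Renderer-agnostic rendering interface with a built-in software rasterizer:
## pinhole projection, z-buffered flat Lambertian shading under the five
## directional lights, RGBA layers with transparent background, and exact
## ground-truth extraction (bbox, 17 keypoints with visibility, 3D joints).
##
## Image convention: origin top-left, x right, y down, 0-based pixels; pixel
## (c, r) covers [c, c+1) x [r, r+1) with its sample point at the centre.
## Bounding boxes are [x, y, w, h], half-open (COCO convention).

# world -> camera rotation (rows: right, down, forward) and position
camera_frame <- function(cam) {
  pos <- camera_position(cam)
  fwd <- cam$target - pos
  fwd <- fwd / sqrt(sum(fwd^2))
  up_w <- c(0, 0, 1)
  r <- c(fwd[2] * up_w[3] - fwd[3] * up_w[2],
         fwd[3] * up_w[1] - fwd[1] * up_w[3],
         fwd[1] * up_w[2] - fwd[2] * up_w[1])
  if (sqrt(sum(r^2)) < 1e-9) { # looking straight up/down
    up_w <- c(1, 0, 0)
    r <- c(fwd[2] * up_w[3] - fwd[3] * up_w[2],
           fwd[3] * up_w[1] - fwd[1] * up_w[3],
           fwd[1] * up_w[2] - fwd[2] * up_w[1])
  }
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * fwd[3] - r[3] * fwd[2], r[3] * fwd[1] - r[1] * fwd[3],
         r[1] * fwd[2] - r[2] * fwd[1]) # true up
  R <- rbind(r, -u, fwd) # x right, y down, z forward
  th <- cam$roll_deg * pi / 180
  roll <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  list(R = roll %*% R, pos = pos)
}

#' Project world points through a camera
#'
#' Applies the world-to-camera rigid transform (look-at the target, +z up,
#' then roll about the optical axis) followed by a pinhole projection with
#' the camera's focal length; the principal point is the image centre.
#'
#' @param points3d n x 3 matrix of world points.
#' @param cam a `camera_spec`.
#' @return n x 3 matrix with columns `x`, `y` (pixels) and `depth` (metres
#'   along the optical axis).
#' @export
project_points <- function(points3d, cam) {
  points3d <- matrix(as.numeric(points3d), ncol = 3)
  fr <- camera_frame(cam)
  pc <- sweep(points3d, 2, fr$pos, `-`) %*% t(fr$R)
  z <- pc[, 3]
  if (any(abs(z) < 1e-12 & abs(pc[, 1]) < 1e-12 & abs(pc[, 2]) < 1e-12)) {
    stop("point at the camera centre has no defined projection")
  }
  w <- cam$image_size[1]
  h <- cam$image_size[2]
  cbind(x = w / 2 + cam$focal_px * pc[, 1] / z,
        y = h / 2 + cam$focal_px * pc[, 2] / z,
        depth = z)
}

# flat Lambertian radiance per face: ambient + sum over lights of
# intensity * max(0, dot(normal, direction-to-light)); linear in the light
# intensities when ambient = 0
shade_faces <- function(vertices, faces, base_rgb, lights, ambient = 0) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(n^2))
  nl[nl < 1e-15] <- 1
  n <- n / nl
  rad <- rep(ambient, nrow(faces))
  for (l in lights) {
    to_light <- -l$direction # direction points toward the mesh
    # two-sided: winding should not darken a face lit from its front
    rad <- rad + l$intensity * abs(n %*% to_light)
  }
  radiance <- as.numeric(rad)
  list(rgb = base_rgb * pmin(1, radiance), radiance = radiance)
}

# per-face base colour (0-1 RGB rows) from part labels and an appearance
face_base_colors <- function(part_label, appearance, blanket_color = NULL) {
  n <- length(part_label)
  skin <- appearance$skin_rgb / 255
  col <- matrix(rep(skin, each = n), n, 3)
  if (isTRUE(appearance$clothed)) {
    cl <- part_label %in% clothing_parts()
    col[cl, ] <- matrix(rep(appearance$clothing_rgb / 255, each = sum(cl)),
                        sum(cl), 3)
  }
  if (isTRUE(appearance$hair)) {
    sc <- part_label == "head_scalp"
    col[sc, ] <- matrix(rep(appearance$hair_rgb / 255, each = sum(sc)),
                        sum(sc), 3)
  }
  if (isTRUE(appearance$eyewear)) {
    eb <- part_label == "head_eyeband"
    col[eb, ] <- matrix(rep(c(0.1, 0.1, 0.1), each = sum(eb)), sum(eb), 3)
  }
  if (!is.null(blanket_color)) {
    bl <- part_label == "blanket"
    col[bl, ] <- matrix(rep(blanket_color / 255, each = sum(bl)), sum(bl), 3)
  }
  col
}

#' Rasterize a scene configuration into an annotated RGBA layer
#'
#' Z-buffered triangle rasterisation with per-face flat Lambertian shading
#' summed over the scene's five directional lights (clamped to the display
#' range; pre-clamp radiance is linear in the intensities when `ambient = 0`).
#' The background stays fully transparent (alpha = 0 exactly where no
#' geometry projects). Ground truth is extracted exactly: the bounding box is
#' the tight box of opaque pixels, keypoint visibility is resolved against
#' the z-buffer (2 = visible, 1 = present but occluded by the body or
#' blanket, 0 = outside the image), and 3D joints are reported in the camera
#' frame. Deterministic for fixed inputs.
#'
#' @param config a `scene_config` (carries camera, lights, appearance).
#' @param mesh a `human_mesh`.
#' @param blanket optional blanket mesh from [generate_blanket()].
#' @param ambient ambient radiance term (default 0.15 for legible renders;
#'   set 0 for a strictly linear Lambertian sum).
#' @param vis_tol depth slack (metres) when testing keypoint occlusion;
#'   joints sit inside the body, roughly one limb radius below the surface.
#' @param tree the `kinematic_tree` the mesh joints belong to.
#' @return an object of class `rendered_layer`: `rgba` (h x w x 4 in [0,1],
#'   8-bit quantised), `keypoints2d` (17 x 3: x, y, visibility), `joints3d`
#'   (camera frame), `bbox` (`[x, y, w, h]` or NULL when empty), `zbuf`.
#' @export
rasterize <- function(config, mesh, blanket = NULL, ambient = 0.15,
                      vis_tol = 0.15, tree = kinematic_tree()) {
  validate_scene_config(config)
  cam <- config$camera
  w <- cam$image_size[1]
  h <- cam$image_size[2]
  if (w < 1L || h < 1L) stop("image must have positive size")
  verts <- mesh$vertices
  faces <- mesh$faces
  labels <- mesh$part_label
  if (!is.null(blanket)) {
    off <- nrow(verts)
    verts <- rbind(verts, blanket$vertices)
    faces <- rbind(faces, blanket$faces + off)
    labels <- c(labels, blanket$part_label)
  }
  base <- face_base_colors(labels, config$appearance,
                           blanket_color = if (!is.null(blanket)) blanket$color)
  sh <- shade_faces(verts, faces, base, config$lights, ambient = ambient)
  if (nrow(faces) > 0L) {
    pr <- project_points(verts, cam)
    fcol <- matrix(pmin(1, pmax(0, sh$rgb)), nrow(faces), 3)
    storage.mode(faces) <- "integer"
    ras <- raster_triangles_cpp(pr[, 1:2, drop = FALSE], pr[, 3], faces,
                                fcol, w, h)
    rgba <- round(ras$rgba * 255) / 255
    rgba[, , 4] <- ras$rgba[, , 4] # alpha stays exact 0/1
    zbuf <- ras$zbuf
  } else {
    rgba <- array(0, c(h, w, 4))
    zbuf <- matrix(Inf, h, w)
  }
  kin <- coco_keypoint_index(tree)
  jp <- project_points(mesh$joints3d, cam)
  kp <- jp[kin, , drop = FALSE]
  vis <- integer(length(kin))
  for (i in seq_along(kin)) {
    x <- kp[i, 1]; y <- kp[i, 2]; z <- kp[i, 3]
    if (z <= 0 || x < 0 || x >= w || y < 0 || y >= h) {
      vis[i] <- 0L
    } else {
      zb <- zbuf[floor(y) + 1L, floor(x) + 1L]
      vis[i] <- if (is.finite(zb) && zb < z - vis_tol) 1L else 2L
    }
  }
  fr <- camera_frame(cam)
  joints_cam <- sweep(mesh$joints3d, 2, fr$pos, `-`) %*% t(fr$R)
  structure(list(
    rgba = rgba,
    keypoints2d = cbind(x = kp[, 1], y = kp[, 2], v = vis),
    joints3d = joints_cam,
    bbox = bbox_from_alpha(rgba),
    zbuf = zbuf), class = "rendered_layer")
}

#' Tight bounding box of the opaque pixels of an RGBA raster
#'
#' Returns the COCO-style `[x, y, w, h]` (0-based, half-open) box of all
#' pixels with alpha > 0, or `NULL` when the raster is fully transparent.
#'
#' @param rgba h x w x 4 array.
#' @return numeric `[x, y, w, h]` or `NULL`.
#' @export
bbox_from_alpha <- function(rgba) {
  alpha <- rgba[, , 4]
  hit <- which(alpha > 0, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  rows <- range(hit[, 1]) # y
  cols <- range(hit[, 2]) # x
  c(cols[1] - 1, rows[1] - 1, cols[2] - cols[1] + 1, rows[2] - rows[1] + 1)
}

#' Write a rendered layer (or composite image) to PNG
#' @param image array: h x w x 4 (RGBA) or h x w x 3 (RGB), values in [0,1].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' The built-in rasterizer as a renderer backend
#'
#' Renderer backends consume a scene configuration plus meshes and return a
#' `rendered_layer`; any external engine can be slotted in by providing a
#' function with this signature. The built-in software rasterizer is the
#' reference implementation.
#'
#' @return a function `(config, mesh, blanket, ...) -> rendered_layer`.
#' @export
default_renderer <- function() rasterize
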