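## Per-scene sampling: appearance, blanket occlusion, camera, lights, and the
## generation plan that expands a scenario preset into renderable scenes.
## Sampling functions draw from R's global RNG; the plan builder seeds each
## draw through derive_seed() so plans are reproducible end to end.

# ---- config assets ---------------------------------------------------------

load_preset_config <- function(path = system.file("extdata", "presets.yaml",
                                                  package = "synthretarget")) {
  yaml::read_yaml(path)
}

#' Default RGB skin-tone palette
#' @return integer matrix, one 0-255 RGB triple per row.
#' @export
default_skin_palette <- function() {
  p <- load_preset_config()$skin_palette
  do.call(rbind, lapply(p, as.integer))
}

default_hair_palette <- function() {
  do.call(rbind, lapply(load_preset_config()$hair_palette, as.integer))
}

default_blanket_palette <- function() {
  do.call(rbind, lapply(load_preset_config()$blanket_palette, as.integer))
}

# ---- scenario presets ------------------------------------------------------

#' A named scenario preset (sampling-range bundle)
#'
#' Presets `"B"`, `"C"` and `"D"` ship with the package: B spans azimuths
#' -35 to 35 degrees about the bed's right side, C spans 15 to 35 degrees
#' about the bed's front, and D views the bed front dead on (degenerate
#' azimuth interval). All three share the vertical-angle range
#' `[-54, 18]` degrees, optical-axis roll `[-115, -30]` degrees and camera
#' distance `[0.3, 0.6]` scene units, and render each configuration four
#' times (2,700 configurations, 10,800 images).
#'
#' @param name `"B"`, `"C"`, `"D"`, or `"custom"` (then supply ranges via
#'   `...`).
#' @param ... overrides for any preset field (e.g. `n_configs`,
#'   `renders_per_config`, `azimuth_range_deg`).
#' @return an object of class `scenario_preset`.
#' @export
scenario_preset <- function(name = c("B", "C", "D", "custom"), ...) {
  name <- match.arg(name)
  cfg <- load_preset_config()
  base <- cfg$defaults
  if (name != "custom") base <- utils::modifyList(base, cfg$presets[[name]])
  base <- utils::modifyList(base, list(...))
  p <- structure(c(list(name = name), base), class = "scenario_preset")
  validate_preset(p)
  p
}

validate_preset <- function(p) {
  for (f in c("azimuth_range_deg", "elevation_range_deg", "roll_range_deg",
              "distance_range")) {
    iv <- p[[f]]
    if (is.null(iv) || length(iv) != 2L || iv[1] > iv[2]) {
      stop("preset interval ", f, " must be a valid [low, high] pair")
    }
  }
  if (is.null(p$azimuth_zero_reference) ||
      !p$azimuth_zero_reference %in% c("bed_right", "bed_front")) {
    stop("azimuth_zero_reference must be 'bed_right' or 'bed_front'")
  }
  if (p$renders_per_config < 1L) stop("renders_per_config must be >= 1")
  if (p$n_configs < 1L) stop("n_configs must be >= 1")
  invisible(p)
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf(
    "scenario_preset %s: azimuth [%g, %g] deg about %s, elevation [%g, %g], roll [%g, %g], distance [%g, %g] units; %d configs x %d renders\n",
    x$name, x$azimuth_range_deg[1], x$azimuth_range_deg[2],
    x$azimuth_zero_reference, x$elevation_range_deg[1], x$elevation_range_deg[2],
    x$roll_range_deg[1], x$roll_range_deg[2], x$distance_range[1],
    x$distance_range[2], x$n_configs, x$renders_per_config))
  invisible(x)
}

# ---- appearance ------------------------------------------------------------

#' Sample an appearance (skin tone, clothing, hair, eyewear)
#'
#' Skin colour is a uniform draw from the palette; clothing, hair and eyewear
#' are independent toggles with configurable probabilities. Clothing and hair
#' colours are drawn uniformly (clothing over the full RGB cube, hair from a
#' small palette).
#'
#' @param palette integer matrix of RGB rows (0-255); must be non-empty.
#' @param p_clothed,p_hair,p_eyewear toggle probabilities.
#' @return an object of class `appearance`.
#' @export
sample_appearance <- function(palette = default_skin_palette(),
                              p_clothed = 0.5, p_hair = 0.5, p_eyewear = 0.3) {
  palette <- as.matrix(palette)
  if (nrow(palette) < 1L) stop("palette must contain at least one colour")
  i <- if (nrow(palette) == 1L) 1L else sample.int(nrow(palette), 1L)
  hair_pal <- default_hair_palette()
  structure(list(
    skin_rgb = as.integer(palette[i, ]),
    clothed = stats::runif(1) < p_clothed,
    clothing_rgb = as.integer(floor(stats::runif(3, 0, 256))),
    hair = stats::runif(1) < p_hair,
    hair_rgb = as.integer(hair_pal[sample.int(nrow(hair_pal), 1L), ]),
    eyewear = stats::runif(1) < p_eyewear
  ), class = "appearance")
}

# ---- lights ----------------------------------------------------------------

light_directions <- function() {
  # unit propagation directions toward the mesh (bed front = -x side, bed
  # left = +y side, above = +z)
  list(front = c(1, 0, 0), back = c(-1, 0, 0), left = c(0, -1, 0),
       right = c(0, 1, 0), above = c(0, 0, -1))
}

#' Sample the five directional lights
#'
#' Five directional lights aimed at the mesh from the front, back, left,
#' right and above, each with intensity drawn i.i.d. uniformly from
#' `intensity_range`.
#'
#' @param intensity_range `[low, high]`, default `c(0.3, 3.0)`.
#' @return a list of 5 `light_spec` objects (direction_label, unit direction,
#'   intensity), in the canonical order front/back/left/right/above.
#' @export
sample_lights <- function(intensity_range = c(0.3, 3.0)) {
  if (length(intensity_range) != 2L || intensity_range[1] > intensity_range[2]) {
    stop("intensity_range must be a valid [low, high] pair")
  }
  dirs <- light_directions()
  ints <- stats::runif(5, intensity_range[1], intensity_range[2])
  out <- vector("list", 5)
  for (i in seq_along(dirs)) {
    out[[i]] <- structure(list(direction_label = names(dirs)[i],
                               direction = dirs[[i]], intensity = ints[i]),
                          class = "light_spec")
  }
  out
}

# ---- camera ----------------------------------------------------------------

azimuth_reference_vector <- function(ref) {
  switch(ref,
         bed_right = c(0, -1, 0), # the supine body's right side
         bed_front = c(-1, 0, 0), # the foot end of the bed
         stop("unknown azimuth reference: ", ref))
}

#' Construct a camera specification
#'
#' The camera sits on a sphere of radius `distance * unit_scale` metres about
#' the target, at the given azimuth (about +z, from the scenario's
#' zero-reference axis) and elevation (above the horizontal plane through the
#' target), looks at the target, and is then rolled about its optical axis.
#'
#' @param distance scene units (> 0).
#' @param azimuth_deg,elevation_deg,roll_deg angles in degrees.
#' @param target 3-vector the camera is aimed at (the mesh root).
#' @param image_size `c(width, height)` in pixels.
#' @param focal_px pinhole focal length in pixels.
#' @param unit_scale metres per scene unit.
#' @param zero_reference `"bed_right"` or `"bed_front"`.
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(distance, azimuth_deg, elevation_deg, roll_deg,
                        target = c(0, 0, 0), image_size = c(640L, 480L),
                        focal_px = 500, unit_scale = 5,
                        zero_reference = "bed_right") {
  if (distance <= 0) stop("camera distance must be positive")
  if (any(image_size < 1L)) stop("image_size must be positive")
  structure(list(distance = distance, azimuth_deg = azimuth_deg,
                 elevation_deg = elevation_deg, roll_deg = roll_deg,
                 target = as.numeric(target),
                 image_size = as.integer(image_size), focal_px = focal_px,
                 unit_scale = unit_scale, zero_reference = zero_reference),
            class = "camera_spec")
}

#' Sample a camera from a scenario preset
#'
#' Distance, azimuth, elevation and roll are drawn independently and
#' uniformly from the preset's intervals (a sample never falls outside its
#' interval; nothing is clipped post hoc).
#'
#' @param preset a `scenario_preset`.
#' @param target aim point, default the origin (mesh root).
#' @param image_size,focal_px image geometry.
#' @return a `camera_spec`.
#' @export
sample_camera <- function(preset, target = c(0, 0, 0),
                          image_size = c(640L, 480L), focal_px = NULL) {
  validate_preset(preset)
  # default focal scales with the frame so the body fills a similar fraction
  # of the image at any resolution (~40-90% of frame height over the
  # distance range)
  if (is.null(focal_px)) focal_px <- round(0.8 * image_size[1])
  runif1 <- function(iv) stats::runif(1, iv[1], iv[2])
  el <- runif1(preset$elevation_range_deg)
  if (isTRUE(preset$flip_elevation)) el <- -el
  camera_spec(distance = runif1(preset$distance_range),
              azimuth_deg = runif1(preset$azimuth_range_deg),
              elevation_deg = el,
              roll_deg = runif1(preset$roll_range_deg),
              target = target, image_size = image_size, focal_px = focal_px,
              unit_scale = preset$unit_scale,
              zero_reference = preset$azimuth_zero_reference)
}

# camera position in world coordinates
camera_position <- function(cam) {
  ref <- azimuth_reference_vector(cam$zero_reference)
  az <- cam$azimuth_deg * pi / 180
  el <- cam$elevation_deg * pi / 180
  # rotate the reference about +z by the azimuth
  h <- c(cos(az) * ref[1] - sin(az) * ref[2],
         sin(az) * ref[1] + cos(az) * ref[2], 0)
  d <- cam$distance * cam$unit_scale
  cam$target + d * (cos(el) * h + sin(el) * c(0, 0, 1))
}

# ---- blanket ---------------------------------------------------------------

#' Blanket-drape parameters
#'
#' @param coverage_fraction fraction of body length covered, in (0, 1].
#' @param anchor_fraction where the covered segment starts along the body
#'   (0 = foot end), in [0, 1].
#' @param offset metres the blanket floats above the body surface.
#' @param noise_amplitude i.i.d. Gaussian height noise, metres.
#' @param smoothing_iters rounds of Laplacian (umbrella) smoothing.
#' @param grid_resolution heightfield cells per metre.
#' @param margin lateral margin beyond the body footprint, metres.
#' @param color RGB 0-255 triple for rendering.
#' @return an object of class `blanket_params`.
#' @export
blanket_params <- function(coverage_fraction = 0.6, anchor_fraction = 0,
                           offset = 0.03, noise_amplitude = 0.008,
                           smoothing_iters = 2L, grid_resolution = 40,
                           margin = 0.06, color = c(200L, 215L, 235L)) {
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in (0, 1]")
  }
  if (offset < 0 || noise_amplitude < 0 || smoothing_iters < 0 ||
      grid_resolution <= 0) {
    stop("blanket parameters must be non-negative (grid_resolution positive)")
  }
  structure(list(coverage_fraction = coverage_fraction,
                 anchor_fraction = anchor_fraction, offset = offset,
                 noise_amplitude = noise_amplitude,
                 smoothing_iters = as.integer(smoothing_iters),
                 grid_resolution = grid_resolution, margin = margin,
                 color = as.integer(color)),
            class = "blanket_params")
}

# morphological dilation: max over the 3x3 cell neighbourhood ("tenting")
dilate_heightfield <- function(h) {
  nr <- nrow(h); nc <- ncol(h)
  out <- h
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(nr) + di
    rj <- seq_len(nc) + dj
    ok_i <- ri >= 1L & ri <= nr
    ok_j <- rj >= 1L & rj <= nc
    out[ok_i, ok_j] <- pmax(out[ok_i, ok_j, drop = FALSE],
                            h[ri[ok_i], rj[ok_j], drop = FALSE])
  }
  out
}

# one smoothing round: h <- h + (lambda/4) * sum_neighbours (h_j - h_i).
# The operator is I - (lambda/4) L with L the symmetric 4-neighbour graph
# Laplacian; for lambda <= 0.5 its spectrum lies in [0, 1], so the height
# variance never increases and the mean is preserved.
smooth_heightfield <- function(h, iters, lambda = 0.5) {
  if (iters < 1L) return(h)
  nr <- nrow(h); nc <- ncol(h)
  for (it in seq_len(iters)) {
    acc <- matrix(0, nr, nc)
    if (nr > 1L) {
      d <- h[-1, , drop = FALSE] - h[-nr, , drop = FALSE]
      acc[-nr, ] <- acc[-nr, ] + d
      acc[-1, ] <- acc[-1, ] - d
    }
    if (nc > 1L) {
      d <- h[, -1, drop = FALSE] - h[, -nc, drop = FALSE]
      acc[, -nc] <- acc[, -nc] + d
      acc[, -1] <- acc[, -1] - d
    }
    h <- h + (lambda / 4) * acc
  }
  h
}

#' Drape a blanket mesh over the body
#'
#' Adapts a planar grid to conform to part of the body surface: (1) a
#' rectangular grid is laid over the covered sub-region's footprint in the
#' bed plane; (2) each grid height is the maximum body-surface height under
#' that cell (cells with no body underneath fall to bed level), tented over a
#' one-cell neighbourhood so the cloth does not drop vertically at
#' silhouette edges, plus `offset`; (3) i.i.d. Gaussian noise is added; (4)
#' Laplacian smoothing is applied; the result is triangulated.
#'
#' @param mesh a `human_mesh` in world coordinates (supine along x).
#' @param params a `blanket_params`.
#' @return a list with `vertices`, `faces`, `part_label` (all "blanket"),
#'   `color`, and the `heightfield` used (for tests).
#' @export
generate_blanket <- function(mesh, params = blanket_params()) {
  v <- mesh$vertices
  if (is.null(v) || nrow(v) == 0L) {
    stop("blanket coverage region has no body underneath")
  }
  xr <- range(v[, 1]); yr <- range(v[, 2])
  bed_z <- min(v[, 3])
  L <- diff(xr)
  cov_len <- params$coverage_fraction * L
  x0 <- xr[1] + params$anchor_fraction * (L - cov_len)
  x1 <- x0 + cov_len
  y0 <- yr[1] - params$margin
  y1 <- yr[2] + params$margin
  nx <- max(2L, as.integer(ceiling((x1 - x0) * params$grid_resolution)) + 1L)
  ny <- max(2L, as.integer(ceiling((y1 - y0) * params$grid_resolution)) + 1L)
  gx <- seq(x0, x1, length.out = nx)
  gy <- seq(y0, y1, length.out = ny)
  # max body vertex height per cell (cell = nearest grid node)
  sel <- v[, 1] >= x0 & v[, 1] <= x1
  if (!any(sel)) stop("blanket coverage region has no body underneath")
  vi <- pmin(nx, pmax(1L, as.integer(round((v[sel, 1] - x0) / (x1 - x0) * (nx - 1L))) + 1L))
  vj <- pmin(ny, pmax(1L, as.integer(round((v[sel, 2] - y0) / (y1 - y0) * (ny - 1L))) + 1L))
  h <- matrix(bed_z, nx, ny)
  zs <- v[sel, 3]
  idx <- (vj - 1L) * nx + vi
  o <- order(idx, zs) # last per cell = max
  h[idx[o]] <- zs[o]
  h <- dilate_heightfield(h)
  h <- h + params$offset
  if (params$noise_amplitude > 0) {
    h <- h + matrix(stats::rnorm(nx * ny, 0, params$noise_amplitude), nx, ny)
  }
  h <- smooth_heightfield(h, params$smoothing_iters)
  verts <- cbind(rep(gx, times = ny), rep(gy, each = nx), as.numeric(h))
  faces <- matrix(0L, 0, 3)
  ia <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- ia(i, j); b <- ia(i + 1L, j); cc <- ia(i + 1L, j + 1L); d <- ia(i, j + 1L)
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  list(vertices = verts, faces = faces,
       part_label = rep("blanket", nrow(faces)),
       color = params$color, heightfield = h,
       grid_x = gx, grid_y = gy)
}

#' Sample blanket parameters for a scene
#'
#' Coverage fraction is drawn uniformly from `coverage_range` (default 0.3 to
#' 0.9 of body length), the anchor uniformly along the body, and the colour
#' from the blanket palette.
#'
#' @param coverage_range `[low, high]` coverage fractions.
#' @return a `blanket_params`.
#' @export
sample_blanket_params <- function(coverage_range = c(0.3, 0.9)) {
  pal <- default_blanket_palette()
  blanket_params(
    coverage_fraction = stats::runif(1, coverage_range[1], coverage_range[2]),
    anchor_fraction = stats::runif(1),
    color = pal[sample.int(nrow(pal), 1L), ])
}

# ---- scene configuration & generation plan ---------------------------------

#' Build a generation plan from a scenario preset
#'
#' Expands the preset into `n_configs * renders_per_config` scene
#' configurations. Each base configuration samples a fresh shape, pose,
#' appearance, blanket and camera; its renders re-sample only the lighting
#' and the background reference, so annotations can be reused across the
#' renders of one configuration. Every draw is seeded through
#' [derive_seed()], so identical seeds give identical plans.
#'
#' @param preset a `scenario_preset`.
#' @param seed integer master seed.
#' @param tree the `kinematic_tree` (defaults to the packaged tree).
#' @param image_size,focal_px image geometry for all scenes.
#' @param n_backgrounds size of the background bank referenced by the plan.
#' @param blanket_prob probability a scene gets a blanket.
#' @param pose_step random-walk step (radians) for the pose generator.
#' @return a list of `scene_config` objects of length
#'   `n_configs * renders_per_config`.
#' @export
build_generation_plan <- function(preset, seed = 1L, tree = kinematic_tree(),
                                  image_size = c(640L, 480L), focal_px = NULL,
                                  n_backgrounds = 20L, blanket_prob = 0.7,
                                  pose_step = 0.12) {
  validate_preset(preset)
  plan <- vector("list", preset$n_configs * preset$renders_per_config)
  k <- 0L
  for (i in seq_len(preset$n_configs)) {
    cfg_id <- sprintf("cfg%05d", i)
    base <- with_seed(derive_seed(seed, paste0("config:", i)), {
      shape <- sample_body_shape()
      pose <- sample_pose(tree, step_scale = pose_step, n_steps = 8L)
      appearance <- sample_appearance()
      blanket <- if (stats::runif(1) < blanket_prob) sample_blanket_params()
                 else NULL
      camera <- sample_camera(preset, image_size = image_size,
                              focal_px = focal_px)
      list(shape = shape, pose = pose, appearance = appearance,
           blanket = blanket, camera = camera)
    })
    for (r in seq_len(preset$renders_per_config)) {
      rd <- with_seed(derive_seed(seed, paste0("render:", i, ":", r)), {
        list(lights = sample_lights(preset$intensity_range),
             background_ref = sample.int(n_backgrounds, 1L))
      })
      k <- k + 1L
      plan[[k]] <- structure(
        c(base, list(config_id = cfg_id, render_index = r - 1L,
                     lights = rd$lights, background_ref = rd$background_ref,
                     preset_name = preset$name)),
        class = "scene_config")
    }
  }
  plan
}

validate_scene_config <- function(cfg) {
  if (length(cfg$lights) != 5L) stop("a scene must have exactly 5 lights")
  invisible(cfg)
}

#' Image-table view of a generation plan
#'
#' One row per planned image, with the config/render provenance needed for
#' leakage-guarded splitting before (or without) rasterisation.
#'
#' @param plan output of [build_generation_plan()].
#' @return data.frame with columns `id`, `config_id`, `render_index`.
#' @export
plan_image_table <- function(plan) {
  data.frame(
    id = seq_along(plan),
    config_id = vapply(plan, function(s) s$config_id, ""),
    render_index = vapply(plan, function(s) s$render_index, 0L),
    stringsAsFactors = FALSE)
}
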