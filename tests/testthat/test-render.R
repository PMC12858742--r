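tree <- kinematic_tree()

with_seed_appearance <- function() {
  set.seed(1)
  sample_appearance()
}

with_seed_local <- function(seed, expr) {
  old <- .Random.seed
  on.exit(.Random.seed <<- old)
  set.seed(seed)
  expr
}

mk_cam <- function(...) {
  camera_spec(distance = 0.4, azimuth_deg = 20, elevation_deg = -20,
              roll_deg = -60, image_size = c(160L, 120L), focal_px = 140, ...)
}

test_that("projection sends the target to the principal point", {
  cam <- mk_cam()
  p <- project_points(rbind(cam$target), cam)
  expect_equal(unname(p[1, 1:2]), c(80, 60), tolerance = 1e-9)
  expect_gt(p[1, 3], 0)
})

test_that("roll rotates image coordinates about the principal point", {
  cam0 <- camera_spec(0.4, 15, -10, 0, image_size = c(200L, 150L), focal_px = 180)
  cam90 <- camera_spec(0.4, 15, -10, 90, image_size = c(200L, 150L), focal_px = 180)
  set.seed(8)
  pts <- cbind(runif(20, -0.4, 0.4), runif(20, -0.4, 0.4), runif(20, -0.2, 0.2))
  p0 <- project_points(pts, cam0)
  p90 <- project_points(pts, cam90)
  pp <- c(100, 75)
  # rolling the camera by +90 rotates every projection by +90 (pixel
  # convention, y down) about the principal point
  d0 <- sweep(p0[, 1:2], 2, pp)
  expected <- cbind(-d0[, 2], d0[, 1])
  expect_lt(max(abs(sweep(p90[, 1:2], 2, pp) - expected)), 1e-6)
})

test_that("projection matches an independent homogeneous matrix chain", {
  set.seed(9)
  for (i in 1:5) {
    cam <- camera_spec(runif(1, 0.3, 0.6), runif(1, -180, 180),
                       runif(1, -54, 18), runif(1, -115, -30),
                       image_size = c(320L, 240L), focal_px = 250)
    pts <- cbind(runif(50, -1, 1), runif(50, -1, 1), runif(50, -1, 1))
    expect_lt(max(abs(project_points(pts, cam) - oracle_project(pts, cam))), 1e-9)
  }
})

test_that("rasterized triangle coverage equals the half-plane oracle", {
  # a front-parallel triangle placed directly in front of a roll-free camera
  cam <- camera_spec(0.4, 0, 0, 0, image_size = c(64L, 48L), focal_px = 60,
                     zero_reference = "bed_front", unit_scale = 5)
  fr <- synthretarget:::camera_frame(cam)
  # build world points that project to chosen pixel coords at depth 1
  to_world <- function(px, py, z) {
    pc <- c((px - 32) / 60 * z, (py - 24) / 60 * z, z)
    as.numeric(t(fr$R) %*% pc + fr$pos)
  }
  tri_px <- rbind(c(5.2, 4.1), c(49.7, 10.3), c(20.4, 44.6))
  verts <- t(vapply(seq_len(3), function(i) to_world(tri_px[i, 1], tri_px[i, 2], 1),
                    numeric(3)))
  pr <- project_points(verts, cam)
  expect_lt(max(abs(pr[, 1:2] - tri_px)), 1e-9)
  ras <- synthretarget:::raster_triangles_cpp(
    pr[, 1:2, drop = FALSE], pr[, 3], matrix(1:3, 1), matrix(1, 1, 3), 64L, 48L)
  covered <- ras$rgba[, , 4] > 0
  # oracle: pixel centres inside all three (inclusive) half-planes
  inside <- matrix(FALSE, 48, 64)
  sgn <- function(a, b, p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  orient <- sgn(tri_px[1, ], tri_px[2, ], tri_px[3, ])
  for (yy in 0:47) for (xx in 0:63) {
    p <- c(xx + 0.5, yy + 0.5)
    e <- c(sgn(tri_px[1, ], tri_px[2, ], p), sgn(tri_px[2, ], tri_px[3, ], p),
           sgn(tri_px[3, ], tri_px[1, ], p))
    inside[yy + 1, xx + 1] <- if (orient > 0) all(e >= 0) else all(e <= 0)
  }
  expect_identical(covered, inside)
})

test_that("empty scenes give fully transparent layers with empty bbox", {
  empty <- structure(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
                          joints3d = matrix(0.1, length(tree$joint_names), 3),
                          part_label = character(0)), class = "human_mesh")
  cfg <- structure(list(camera = mk_cam(),
                        lights = sample_lights(c(1, 1)),
                        appearance = with_seed_appearance(),
                        config_id = "t", render_index = 0L),
                   class = "scene_config")
  layer <- rasterize(cfg, empty, tree = tree)
  expect_true(all(layer$rgba[, , 4] == 0))
  expect_null(layer$bbox)
  expect_null(bbox_from_alpha(layer$rgba))
})

test_that("Lambertian radiance is linear in light intensities before clamping", {
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  mesh <- build_surface_mesh(j, NULL, tree)
  l1 <- sample_lights(c(1, 1))
  l2 <- lapply(l1, function(l) { l$intensity <- 2 * l$intensity; l })
  base <- matrix(0.5, nrow(mesh$faces), 3)
  s1 <- synthretarget:::shade_faces(mesh$vertices, mesh$faces, base, l1, ambient = 0)
  s2 <- synthretarget:::shade_faces(mesh$vertices, mesh$faces, base, l2, ambient = 0)
  expect_equal(s2$radiance, 2 * s1$radiance, tolerance = 1e-12)
})

test_that("bbox_from_alpha matches its definition and a pixel-scan oracle", {
  a <- array(0, c(12, 16, 4))
  a[5, 4, 4] <- 1   # pixel (x=3, y=4)
  a[10, 11, 4] <- 1 # pixel (x=10, y=9)
  expect_equal(bbox_from_alpha(a), c(3, 4, 8, 6))
  expect_null(bbox_from_alpha(array(0, c(5, 5, 4))))
  set.seed(10)
  for (i in 1:20) {
    a <- array(0, c(20, 30, 4))
    n <- sample(0:15, 1)
    if (n > 0) a[cbind(sample(20, n, TRUE), sample(30, n, TRUE), 4)] <- 1
    b <- bbox_from_alpha(a)
    # exhaustive scan oracle
    xs <- ys <- integer(0)
    for (yy in 1:20) for (xx in 1:30) if (a[yy, xx, 4] > 0) {
      xs <- c(xs, xx - 1); ys <- c(ys, yy - 1)
    }
    if (length(xs) == 0) expect_null(b)
    else expect_equal(b, c(min(xs), min(ys), diff(range(xs)) + 1,
                           diff(range(ys)) + 1))
  }
})

test_that("rendered layers are deterministic with consistent annotations", {
  preset <- scenario_preset("B", n_configs = 1L, renders_per_config = 1L)
  plan <- build_generation_plan(preset, seed = 21L, tree = tree,
                                image_size = c(160L, 120L))
  sc <- plan[[1]]
  j <- forward_kinematics(sc$pose, sc$shape, tree)
  mesh <- build_surface_mesh(j, sc$shape, tree)
  bl <- if (!is.null(sc$blanket)) {
    with_seed_local(1, generate_blanket(mesh, sc$blanket))
  }
  l1 <- rasterize(sc, mesh, bl, tree = tree)
  l2 <- rasterize(sc, mesh, bl, tree = tree)
  expect_identical(serialize(l1, NULL), serialize(l2, NULL)) # bit-identical
  # alpha = 0 exactly where no geometry projects; bbox tight over alpha > 0
  expect_equal(l1$bbox, bbox_from_alpha(l1$rgba))
  # visible keypoints lie inside the bbox grown by 1 px and match projection
  pr <- project_points(mesh$joints3d, sc$camera)[coco_keypoint_index(tree), ]
  vis <- l1$keypoints2d[, 3] == 2
  expect_lt(max(abs(l1$keypoints2d[vis, 1:2] - pr[vis, 1:2])), 0.5)
  if (any(vis)) {
    b <- l1$bbox
    expect_true(all(l1$keypoints2d[vis, 1] >= b[1] - 1 &
                      l1$keypoints2d[vis, 1] <= b[1] + b[3] + 1 &
                      l1$keypoints2d[vis, 2] >= b[2] - 1 &
                      l1$keypoints2d[vis, 2] <= b[2] + b[4] + 1))
  }
})

test_that("blanket occlusion downgrades covered keypoints to visibility 1", {
  # top-down view: the blanket shell lies between the camera and the body
  cam <- camera_spec(0.45, 0, 70, 0, image_size = c(160L, 120L),
                     focal_px = 128, zero_reference = "bed_front")
  sc <- structure(list(camera = cam, lights = sample_lights(c(1, 1)),
                       appearance = with_seed_appearance(),
                       config_id = "occ", render_index = 0L),
                  class = "scene_config")
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  mesh <- build_surface_mesh(j, NULL, tree)
  full <- blanket_params(coverage_fraction = 1, anchor_fraction = 0,
                         offset = 0.25, noise_amplitude = 0, smoothing_iters = 0L)
  bl <- generate_blanket(mesh, full)
  bare <- rasterize(sc, mesh, NULL, tree = tree)
  cov <- rasterize(sc, mesh, bl, tree = tree)
  in_frame_bare <- bare$keypoints2d[, 3] > 0
  in_frame_cov <- cov$keypoints2d[, 3] > 0
  expect_identical(in_frame_bare, in_frame_cov) # frame geometry unchanged
  # a quarter-metre shell over the whole body must occlude every in-frame
  # joint that the bare render saw as visible
  was_vis <- bare$keypoints2d[, 3] == 2
  expect_true(all(cov$keypoints2d[was_vis, 3] == 1))
})

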