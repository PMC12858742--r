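tree <- kinematic_tree()

test_that("appearance sampling stays on the palette with uniform frequencies", {
  expect_error(sample_appearance(matrix(numeric(0), 0, 3)), "palette")
  one <- matrix(c(10L, 20L, 30L), 1)
  set.seed(1)
  for (i in 1:5) expect_equal(sample_appearance(one)$skin_rgb, c(10L, 20L, 30L))
  pal <- default_skin_palette()
  set.seed(2)
  draws <- replicate(10000, sample_appearance(pal)$skin_rgb)
  keys <- apply(draws, 2, paste, collapse = ",")
  pal_keys <- apply(pal, 1, paste, collapse = ",")
  expect_true(all(keys %in% pal_keys))
  # multinomial: each entry within 3 sigma of uniform
  n <- 10000; p <- 1 / nrow(pal)
  tol <- 3 * sqrt(n * p * (1 - p))
  counts <- table(factor(keys, levels = pal_keys))
  expect_true(all(abs(counts - n * p) <= tol))
})

test_that("the five lights carry canonical labels and uniform intensities", {
  set.seed(3)
  ls <- sample_lights()
  expect_length(ls, 5)
  expect_setequal(vapply(ls, `[[`, "", "direction_label"),
                  c("front", "back", "left", "right", "above"))
  for (l in ls) {
    expect_equal(sqrt(sum(l$direction^2)), 1, tolerance = 1e-12)
    expect_true(l$intensity >= 0.3 && l$intensity <= 3.0)
  }
  # collapsed interval
  ls1 <- sample_lights(c(1, 1))
  expect_true(all(vapply(ls1, `[[`, 1, "intensity") == 1))
  # mean of U(0.3, 3) is 1.65
  set.seed(4)
  ints <- replicate(2000, vapply(sample_lights(), `[[`, 1, "intensity"))
  expect_lt(abs(mean(ints) - 1.65), 0.02)
})

test_that("camera samples stay inside the preset intervals and look uniform", {
  B <- scenario_preset("B")
  set.seed(5)
  n <- 10000
  draws <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    cm <- sample_camera(B)
    draws[i, ] <- c(cm$azimuth_deg, cm$elevation_deg, cm$roll_deg, cm$distance)
  }
  expect_true(all(draws[, 1] >= -35 & draws[, 1] <= 35))
  expect_true(all(draws[, 2] >= -54 & draws[, 2] <= 18))
  expect_true(all(draws[, 3] >= -115 & draws[, 3] <= -30))
  expect_true(all(draws[, 4] >= 0.3 & draws[, 4] <= 0.6))
  # KS uniformity at the 1% level (critical value 1.63 / sqrt(n))
  lo <- c(-35, -54, -115, 0.3); hi <- c(35, 18, -30, 0.6)
  for (k in 1:4) {
    stat <- unname(stats::ks.test(draws[, k], "punif", lo[k], hi[k])$statistic)
    expect_lt(stat, 1.63 / sqrt(n))
  }
  # collapsed preset: identical camera every draw
  P0 <- scenario_preset("custom", azimuth_range_deg = c(10, 10),
                        elevation_range_deg = c(-5, -5),
                        roll_range_deg = c(-40, -40),
                        distance_range = c(0.5, 0.5),
                        azimuth_zero_reference = "bed_front")
  c1 <- sample_camera(P0); c2 <- sample_camera(P0)
  expect_equal(c1[c("distance", "azimuth_deg", "elevation_deg", "roll_deg")],
               c2[c("distance", "azimuth_deg", "elevation_deg", "roll_deg")])
  # empty interval rejected
  expect_error(scenario_preset("custom", azimuth_range_deg = c(10, -10)),
               "interval")
})

test_that("preset D is the degenerate front view", {
  D <- scenario_preset("D")
  expect_equal(D$azimuth_range_deg, c(0, 0))
  expect_equal(D$azimuth_zero_reference, "bed_front")
  set.seed(1)
  expect_equal(sample_camera(D)$azimuth_deg, 0)
})

test_that("blanket drape conforms to the body with controlled noise", {
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  mesh <- build_surface_mesh(j, NULL, tree)
  # degenerate parameters: vertices exactly offset above the draped surface
  p0 <- blanket_params(coverage_fraction = 0.5, anchor_fraction = 0.5,
                       offset = 0.04, noise_amplitude = 0, smoothing_iters = 0L)
  b0 <- generate_blanket(mesh, p0)
  expect_lt(max(abs(b0$vertices[, 3] - as.numeric(b0$heightfield))), 1e-9)
  # the heightfield is the (tented) cell-max body height + offset
  under <- mesh$vertices[, 1] >= min(b0$grid_x) &
           mesh$vertices[, 1] <= max(b0$grid_x)
  expect_gte(min(b0$heightfield), min(mesh$vertices[, 3]) + 0.04 - 1e-9)
  # default parameters: no vertex penetrates the body surface beyond
  # noise + offset slack
  set.seed(6)
  pd <- blanket_params(coverage_fraction = 0.7, anchor_fraction = 0.3)
  bd <- generate_blanket(mesh, pd)
  vb <- mesh$vertices[under, , drop = FALSE]
  # body-surface height under each blanket vertex: max body vertex within
  # half a cell (point-to-surface check)
  cell <- 1 / pd$grid_resolution
  worst <- 0
  for (i in seq_len(nrow(bd$vertices))) {
    vx <- bd$vertices[i, 1]; vy <- bd$vertices[i, 2]
    nb <- abs(vb[, 1] - vx) <= cell / 2 & abs(vb[, 2] - vy) <= cell / 2
    if (!any(nb)) next
    worst <- max(worst, max(vb[nb, 3]) - bd$vertices[i, 3])
  }
  expect_lt(worst, pd$noise_amplitude + pd$offset)
  # empty coverage region errors
  away <- mesh
  expect_error(generate_blanket(
    structure(list(vertices = mesh$vertices[mesh$vertices[, 1] > 10, , drop = FALSE],
                   faces = matrix(0L, 0, 3), part_label = character(0)),
              class = "human_mesh"),
    p0))
})

test_that("blanket smoothing never increases height variance", {
  set.seed(7)
  for (i in 1:20) {
    h <- matrix(rnorm(30 * 12), 30, 12)
    v0 <- stats::var(as.numeric(h))
    h1 <- synthretarget:::smooth_heightfield(h, 1L)
    expect_lte(stats::var(as.numeric(h1)), v0 + 1e-12)
    expect_equal(mean(h1), mean(h), tolerance = 1e-12)
  }
})

test_that("generation plans have exact counts, traceability and determinism", {
  p <- scenario_preset("B", n_configs = 6L, renders_per_config = 4L)
  plan <- build_generation_plan(p, seed = 11L, tree = tree)
  expect_length(plan, 24)
  tab <- plan_image_table(plan)
  expect_identical(length(unique(tab$config_id)), 6L)
  expect_true(all(table(tab$config_id) == 4))
  # one config holds pose/shape/camera fixed across renders, varies lights
  s1 <- plan[[1]]; s2 <- plan[[2]]
  expect_identical(s1$config_id, s2$config_id)
  expect_identical(s1$shape$betas, s2$shape$betas)
  expect_identical(s1$camera$azimuth_deg, s2$camera$azimuth_deg)
  expect_false(identical(vapply(s1$lights, `[[`, 1, "intensity"),
                         vapply(s2$lights, `[[`, 1, "intensity")))
  # trivial plan
  p1 <- scenario_preset("B", n_configs = 1L, renders_per_config = 1L)
  expect_length(build_generation_plan(p1, seed = 1L, tree = tree), 1)
  # determinism: identical seeds give identical plans
  plan2 <- build_generation_plan(p, seed = 11L, tree = tree)
  expect_identical(serialize(plan, NULL), serialize(plan2, NULL))
  plan3 <- build_generation_plan(p, seed = 12L, tree = tree)
  expect_false(identical(serialize(plan, NULL), serialize(plan3, NULL)))
})

test_that("every plan draw lies inside its preset interval", {
  p <- scenario_preset("C", n_configs = 40L, renders_per_config = 2L)
  plan <- build_generation_plan(p, seed = 3L, tree = tree)
  for (sc in plan) {
    expect_true(sc$camera$azimuth_deg >= 15 && sc$camera$azimuth_deg <= 35)
    expect_true(sc$camera$elevation_deg >= -54 && sc$camera$elevation_deg <= 18)
    expect_true(sc$camera$roll_deg >= -115 && sc$camera$roll_deg <= -30)
    expect_true(sc$camera$distance >= 0.3 && sc$camera$distance <= 0.6)
    for (l in sc$lights) {
      expect_true(l$intensity >= 0.3 && l$intensity <= 3.0)
    }
    if (!is.null(sc$blanket)) {
      expect_true(sc$blanket$coverage_fraction >= 0.3 &&
                    sc$blanket$coverage_fraction <= 0.9)
    }
  }
})
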