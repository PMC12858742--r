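tree <- kinematic_tree()

test_that("tree asset satisfies its structural invariants", {
  expect_s3_class(tree, "kinematic_tree")
  expect_identical(sum(tree$parent_index == 0L), 1L)
  expect_true(all(tree$parent_index < seq_along(tree$joint_names)))
  expect_length(setdiff(coco_keypoint_names(), tree$joint_names), 0)
  # left/right rest offsets mirror about the sagittal plane
  expect_silent(validate_tree(tree))
})

test_that("body shape sampling respects bounds and the stated distribution", {
  expect_error(sample_body_shape(sigma = 0), "positive")
  expect_error(sample_body_shape(sigma = -1), "positive")
  set.seed(1)
  b <- sample_body_shape(sigma = 0.5)
  expect_length(b$betas, 10)
  expect_true(all(abs(b$betas) <= 1))
  # degenerate spread: all betas collapse to ~0
  set.seed(99)
  b0 <- sample_body_shape(sigma = 1e-8)
  expect_true(all(abs(b0$betas) < 1e-6))
  # Monte-Carlo mean check against the stated zero mean (oracle = averaging)
  set.seed(1)
  draws <- t(replicate(10000, sample_body_shape(0.5)$betas))
  expect_true(all(abs(colMeans(draws)) < 0.02))
  expect_true(all(abs(draws) <= 1))
})

test_that("forward kinematics matches cumulative offsets and a matrix oracle", {
  # zero rotations, zero betas: joints are cumulative rest offsets
  j <- forward_kinematics(rest_pose(tree), body_shape(rep(0, 10)), tree)
  expected <- matrix(0, nrow(j), 3)
  for (k in seq_along(tree$joint_names)) {
    p <- tree$parent_index[k]
    expected[k, ] <- if (p == 0L) c(0, 0, 0) else expected[p, ] + tree$rest_offset[k, ]
  }
  expect_equal(unname(j), expected, tolerance = 1e-12)

  # 3-joint chain against an independent rotation-matrix product
  rot <- matrix(0, length(tree$joint_names), 3)
  aa1 <- c(0.3, -0.2, 0.5); aa2 <- c(-0.1, 0.4, 0.2)
  i_sp1 <- match("spine1", tree$joint_names)
  i_sp2 <- match("spine2", tree$joint_names)
  i_sp3 <- match("spine3", tree$joint_names)
  rot[i_sp1, ] <- aa1
  rot[i_sp2, ] <- aa2
  j2 <- forward_kinematics(pose_aa(c(0, 0, 0), rot, tree), NULL, tree)
  rodrigues <- function(aa) {
    th <- sqrt(sum(aa^2)); k <- aa / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  R1 <- rodrigues(aa1)
  p_sp1 <- tree$rest_offset[i_sp1, ]
  p_sp2 <- p_sp1 + as.numeric(R1 %*% tree$rest_offset[i_sp2, ])
  p_sp3 <- p_sp2 + as.numeric(R1 %*% rodrigues(aa2) %*% tree$rest_offset[i_sp3, ])
  expect_lt(max(abs(j2[i_sp3, ] - p_sp3)), 1e-9)
  expect_lt(max(abs(j2[i_sp2, ] - p_sp2)), 1e-9)
})

test_that("forward kinematics is equivariant under rigid root motion", {
  set.seed(4)
  pose <- generate_pose_sequence(pose_sequence_spec(2, 0.15, seed = 11), tree)[[2]]
  j <- forward_kinematics(pose, NULL, tree)
  # rotate only the root by 90 degrees about z
  rot <- pose$joint_rotation
  root <- which(tree$parent_index == 0L)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Rroot <- synthretarget:::aa_to_rotmat(rot[root, ])
  rot[root, ] <- synthretarget:::rotmat_to_aa(Rz %*% Rroot)
  t_new <- c(0.7, -0.4, 0.2)
  j_moved <- forward_kinematics(pose_aa(t_new, rot, tree), NULL, tree)
  expected <- sweep(sweep(j, 2, j[root, ]) %*% t(Rz), 2, t_new, `+`)
  expect_lt(max(abs(j_moved - expected)), 1e-9)
})

test_that("pose conversion round-trips joint positions and drops translation", {
  # rest positions give a zero-norm pose
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  p <- pose_from_joint_positions(j, tree)
  expect_lt(max(abs(p$joint_rotation)), 1e-9)
  # translation invariance of the rotational part
  p_shift <- pose_from_joint_positions(sweep(j, 2, c(5, 5, 5), `+`), tree)
  expect_equal(p_shift$joint_rotation, p$joint_rotation, tolerance = 1e-12)
  expect_equal(p_shift$root_translation, c(5, 5, 5))
  # position-level identity over random joint-limited poses
  for (s in 1:10) {
    pose <- generate_pose_sequence(pose_sequence_spec(3, 0.18, seed = s), tree)[[3]]
    jj <- forward_kinematics(pose, NULL, tree)
    rec <- pose_from_joint_positions(jj, tree)
    j2 <- forward_kinematics(rec, NULL, tree)
    expect_lt(max(abs(jj - j2)), 1e-6)
    expect_true(all(sqrt(rowSums(rec$joint_rotation^2)) <= pi + 1e-9))
  }
})

test_that("pose conversion reports degenerate zero-length bones by name", {
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  j[match("spine2", tree$joint_names), ] <- j[match("spine1", tree$joint_names), ]
  expect_error(pose_from_joint_positions(j, tree), "spine2")
})

test_that("surface mesh is sagittally symmetric, contains joints, grows with betas", {
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  mesh <- build_surface_mesh(j, body_shape(rep(0, 10)), tree)
  # mirror-symmetry: reflected vertex multiset equals the original
  refl <- mesh$vertices %*% diag(c(1, -1, 1))
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_identical(key(refl), key(mesh$vertices))
  # every joint inside the mesh bounding box, for random poses too
  for (s in 1:3) {
    pose <- generate_pose_sequence(pose_sequence_spec(2, 0.15, seed = s), tree)[[2]]
    jj <- forward_kinematics(pose, NULL, tree)
    expect_silent(validate_mesh(build_surface_mesh(jj, NULL, tree)))
  }
  # volume strictly increases from betas -1 to +1
  mk <- function(s) {
    sh <- body_shape(rep(s, 10))
    mesh_volume(build_surface_mesh(forward_kinematics(rest_pose(tree), sh, tree),
                                   sh, tree))
  }
  expect_gt(mk(1), mk(-1))
  expect_gt(mk(1), 0)
})

test_that("mesh size is a pure function of tessellation settings", {
  j <- forward_kinematics(rest_pose(tree), NULL, tree)
  m1 <- build_surface_mesh(j, NULL, tree)
  m2 <- build_surface_mesh(j, NULL, tree)
  expect_identical(dim(m1$vertices), dim(m2$vertices))
  expect_identical(m1$faces, m2$faces)
  m3 <- build_surface_mesh(j, NULL, tree, n_theta = 10L, n_len = 4L)
  expect_gt(nrow(m3$faces), nrow(m1$faces))
})
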