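## Procedural surface mesh: a union of capsule segments per bone plus a head
## ellipsoid, standing in for a statistical body model behind the same
## interface (an adapter accepting externally produced meshes can replace it).

# deterministic orthonormal frame (v, w) perpendicular to unit axis u, chosen
# so that mirroring about the sagittal plane maps frames onto each other
# (v -> -Mv, w -> Mw); this keeps left/right capsules exactly mirror-images.
axis_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(ref[2] * u[3] - ref[3] * u[2],
         ref[3] * u[1] - ref[1] * u[3],
         ref[1] * u[2] - ref[2] * u[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

# capped cylinder ("capsule") from p0 to p1 with radius r; n_theta must be
# even so the ring point set is symmetric under reflection.
make_capsule <- function(p0, p1, r, n_theta = 8L, n_len = 4L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("capsule with zero-length axis")
  u <- axis / len
  fr <- axis_frame(u)
  phi <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  circ <- outer(cos(phi), fr$v) + outer(sin(phi), fr$w) # n_theta x 3
  ts <- seq(0, 1, length.out = n_len + 1L)
  verts <- do.call(rbind, lapply(ts, function(t) {
    ctr <- p0 + t * axis
    sweep(circ * r, 2, ctr, `+`)
  }))
  poles <- rbind(p0 - r * u, p1 + r * u)
  verts <- rbind(verts, poles)
  i0 <- nrow(verts) - 1L # pole at p0 end
  i1 <- nrow(verts)      # pole at p1 end
  faces <- list()
  ring <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
  for (i in seq_len(n_len)) {
    a <- ring(i); b <- ring(i + 1L)
    nxt <- c(seq_len(n_theta)[-1L], 1L)
    # outward winding (verified by positive enclosed volume)
    faces[[length(faces) + 1L]] <- cbind(a, b[nxt], b)
    faces[[length(faces) + 1L]] <- cbind(a, a[nxt], b[nxt])
  }
  a <- ring(1L); b <- ring(n_len + 1L)
  nxt <- c(seq_len(n_theta)[-1L], 1L)
  faces[[length(faces) + 1L]] <- cbind(a[nxt], a, i0)
  faces[[length(faces) + 1L]] <- cbind(b, b[nxt], i1)
  list(vertices = verts, faces = do.call(rbind, faces))
}

# lat-long tessellated ellipsoid; axes is a 3x3 rotation (columns = local
# x, y, z directions in world coordinates), radii a 3-vector.
make_ellipsoid <- function(center, radii, axes = diag(3),
                           n_theta = 10L, n_phi = 8L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_phi + 1L)[-c(1L, n_phi + 1L)]
  phi <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  verts <- matrix(0, 0, 3)
  for (la in lat) {
    local <- cbind(radii[1] * cos(la) * cos(phi),
                   radii[2] * cos(la) * sin(phi),
                   radii[3] * sin(la))
    verts <- rbind(verts, local)
  }
  verts <- rbind(verts, c(0, 0, -radii[3]), c(0, 0, radii[3]))
  verts <- sweep(verts %*% t(axes), 2, center, `+`)
  nb <- length(lat)
  ibot <- nb * n_theta + 1L
  itop <- nb * n_theta + 2L
  faces <- list()
  ring <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
  nxt <- c(seq_len(n_theta)[-1L], 1L)
  for (i in seq_len(nb - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    faces[[length(faces) + 1L]] <- cbind(a, b[nxt], b)
    faces[[length(faces) + 1L]] <- cbind(a, a[nxt], b[nxt])
  }
  a <- ring(1L); b <- ring(nb)
  faces[[length(faces) + 1L]] <- cbind(a[nxt], a, ibot)
  faces[[length(faces) + 1L]] <- cbind(b, b[nxt], itop)
  list(vertices = verts, faces = do.call(rbind, faces))
}

# append part (vertices/faces + one label recycled over faces) to a mesh
# accumulator
mesh_append <- function(acc, part, label) {
  off <- nrow(acc$vertices)
  acc$vertices <- rbind(acc$vertices, part$vertices)
  acc$faces <- rbind(acc$faces, part$faces + off)
  acc$part_label <- c(acc$part_label, rep(label, nrow(part$faces)))
  acc
}

# per-bone capsule radii (metres, neutral shape), keyed by child joint name
bone_radii <- c(
  left_hip = 0.075, right_hip = 0.075, spine1 = 0.105, spine2 = 0.115,
  spine3 = 0.115, neck = 0.05, head = 0.05,
  left_collar = 0.045, right_collar = 0.045,
  left_knee = 0.07, right_knee = 0.07, left_ankle = 0.055, right_ankle = 0.055,
  left_foot = 0.04, right_foot = 0.04,
  left_shoulder = 0.05, right_shoulder = 0.05,
  left_elbow = 0.045, right_elbow = 0.045,
  left_wrist = 0.04, right_wrist = 0.04)

# body-part label per bone (child joint name -> part used for texturing and
# blanket-region selection)
bone_part <- c(
  left_hip = "pelvis", right_hip = "pelvis", spine1 = "torso",
  spine2 = "torso", spine3 = "torso", neck = "neck", head = "neck",
  left_collar = "torso", right_collar = "torso",
  left_knee = "left_thigh", right_knee = "right_thigh",
  left_ankle = "left_calf", right_ankle = "right_calf",
  left_foot = "left_foot", right_foot = "right_foot",
  left_shoulder = "torso", right_shoulder = "torso",
  left_elbow = "left_upper_arm", right_elbow = "right_upper_arm",
  left_wrist = "left_forearm", right_wrist = "right_forearm")

# parts covered by clothing when the appearance has a clothing overlay
clothing_parts <- function() {
  c("pelvis", "torso", "left_thigh", "right_thigh",
    "left_upper_arm", "right_upper_arm")
}

#' Build the humanoid surface mesh
#'
#' Constructs a watertight-per-segment triangle mesh from posed joint
#' positions: one capsule per bone, a head ellipsoid (split into face, scalp
#' and eye-band parts for appearance control). Segment radii are modulated by
#' the shape coefficients (girth grows monotonically with the mean beta).
#' Vertex and face counts are pure functions of the tessellation settings.
#'
#' @param joints3d n x 3 matrix of joint positions from [forward_kinematics()].
#' @param shape optional `body_shape` modulating girth.
#' @param tree the `kinematic_tree` the joints belong to.
#' @param n_theta,n_len capsule tessellation (n_theta must be even).
#' @return an object of class `human_mesh`: `vertices` (V x 3), `faces`
#'   (F x 3 vertex indices), `joints3d`, `part_label` (length F).
#' @export
build_surface_mesh <- function(joints3d, shape = NULL, tree,
                               n_theta = 8L, n_len = 3L) {
  stopifnot(n_theta %% 2L == 0L)
  joints3d <- as.matrix(joints3d)
  if (nrow(joints3d) != n_joints(tree)) stop("joints do not match tree")
  g <- shape_girth_scale(shape)
  acc <- list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
              part_label = character(0))
  jn <- tree$joint_names
  for (child in names(bone_radii)) {
    j <- match(child, jn)
    p <- tree$parent_index[j]
    cap <- make_capsule(joints3d[p, ], joints3d[j, ], g * bone_radii[[child]],
                        n_theta = n_theta, n_len = n_len)
    acc <- mesh_append(acc, cap, bone_part[[child]])
  }
  # head ellipsoid, oriented by the head's local frame recovered from the
  # face-joint layout (superior = +x local, anterior = +z local in rest pose)
  hj <- match("head", jn)
  nj <- match("nose", jn)
  lj <- match("left_ear", jn)
  rj <- match("right_ear", jn)
  ant <- joints3d[nj, ] - joints3d[hj, ]
  lr <- joints3d[lj, ] - joints3d[rj, ] # +left
  sup <- c(lr[2] * ant[3] - lr[3] * ant[2], lr[3] * ant[1] - lr[1] * ant[3],
           lr[1] * ant[2] - lr[2] * ant[1]) # left x anterior = superior
  nrm <- function(v) v / sqrt(sum(v^2))
  ex <- nrm(sup)
  ez0 <- nrm(ant)
  ey <- nrm(c(ez0[2] * ex[3] - ez0[3] * ex[2], ez0[3] * ex[1] - ez0[1] * ex[3],
              ez0[1] * ex[2] - ez0[2] * ex[1])) # z cross x = y (left)
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  axes <- cbind(ex, ey, ez)
  center <- joints3d[hj, ] + as.numeric(axes %*% c(0.03, 0, 0.02))
  radii <- g * c(0.115, 0.085, 0.105)
  ell <- make_ellipsoid(center, radii, axes, n_theta = 10L, n_phi = 8L)
  # split head faces into scalp / face / eye-band by local coordinates
  local <- sweep(ell$vertices, 2, as.numeric(center), `-`) %*% axes
  fc <- (local[ell$faces[, 1], ] + local[ell$faces[, 2], ] +
           local[ell$faces[, 3], ]) / 3
  lab <- rep("head_face", nrow(ell$faces))
  lab[fc[, 1] > 0.04 | fc[, 3] < -0.02] <- "head_scalp"
  lab[abs(fc[, 1] - 0.02) < 0.025 & fc[, 3] > 0.055] <- "head_eyeband"
  acc$vertices <- rbind(acc$vertices, ell$vertices)
  acc$faces <- rbind(acc$faces, ell$faces + (nrow(acc$vertices) - nrow(ell$vertices)))
  acc$part_label <- c(acc$part_label, lab)
  mesh <- structure(
    list(vertices = acc$vertices, faces = acc$faces,
         joints3d = joints3d, part_label = acc$part_label),
    class = "human_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate a triangle mesh's invariants
#'
#' All face indices must reference existing vertices, part labels must cover
#' all faces, and the axis-aligned bounding box of the vertices must contain
#' every joint.
#'
#' @param mesh a `human_mesh`.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  V <- nrow(mesh$vertices)
  if (any(mesh$faces < 1L) || any(mesh$faces > V)) stop("face index out of range")
  if (length(mesh$part_label) != nrow(mesh$faces)) {
    stop("part_label must have one entry per face")
  }
  if (!is.null(mesh$joints3d)) {
    lo <- apply(mesh$vertices, 2, min)
    hi <- apply(mesh$vertices, 2, max)
    inside <- sweep(mesh$joints3d, 2, lo, `>=`) & sweep(mesh$joints3d, 2, hi, `<=`)
    if (!all(inside)) stop("mesh bounding box does not contain every joint")
  }
  invisible(mesh)
}

#' Enclosed volume of a triangle mesh (divergence theorem)
#'
#' Sum of signed tetrahedron volumes; positive for consistently outward-wound
#' closed surfaces. For a union of overlapping closed segments this counts
#' overlap regions multiple times, which is still a monotone proxy for girth.
#'
#' @param mesh a mesh with `vertices` and `faces`.
#' @return volume in cubic metres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}
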