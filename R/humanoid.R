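## Parametric articulated humanoid: shape sampling, axis-angle poses,
## forward kinematics, and conversion from Cartesian joint positions.

# ---- rotation utilities ----------------------------------------------------

skew3 <- function(k) {
  matrix(c(0, k[3], -k[2],
           -k[3], 0, k[1],
           k[2], -k[1], 0), 3, 3)
}

# Rodrigues: axis-angle 3-vector -> 3x3 rotation matrix
aa_to_rotmat <- function(aa) {
  th <- sqrt(sum(aa^2))
  if (th < 1e-12) return(diag(3))
  k <- aa / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# 3x3 rotation matrix -> axis-angle 3-vector with norm in [0, pi]
rotmat_to_aa <- function(R) {
  tr <- sum(diag(R))
  c_th <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(c_th)
  if (th < 1e-12) return(c(0, 0, 0))
  if (th < pi - 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
    return(ax * th)
  }
  # near pi: extract axis from the symmetric part, robustly
  B <- (R + diag(3)) / 2
  i <- which.max(diag(B))
  ax <- B[, i] / sqrt(max(B[i, i], 1e-18))
  ax <- ax / sqrt(sum(ax^2))
  # fix sign convention (irrelevant at exactly pi, but keep deterministic)
  s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sum(ax * s) < 0) ax <- -ax
  ax * th
}

# minimal rotation mapping unit vector a onto unit vector b (zero twist)
minimal_rotation <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # anti-parallel: rotate by pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    ax <- c(a[2] * ref[3] - a[3] * ref[2], a[3] * ref[1] - a[1] * ref[3],
            a[1] * ref[2] - a[2] * ref[1])
    ax <- ax / sqrt(sum(ax^2))
    return(aa_to_rotmat(ax * pi))
  }
  V <- skew3(v)
  diag(3) + V + V %*% V * ((1 - cth) / s^2)
}

# best-fit rotation mapping columns of A (3 x k rest directions) onto columns
# of B (observed directions): Kabsch via SVD
kabsch_rotation <- function(A, B) {
  H <- B %*% t(A)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# ---- body shape ------------------------------------------------------------

#' Construct a body-shape descriptor
#'
#' Ten dimensionless shape coefficients (betas), each constrained to
#' `[-1, 1]`. The first coefficient scales stature (bone lengths); the mean of
#' all ten modulates segment girth in [build_surface_mesh()].
#'
#' @param betas numeric vector of exactly 10 values in `[-1, 1]`.
#' @return an object of class `body_shape`.
#' @export
body_shape <- function(betas) {
  betas <- as.numeric(betas)
  if (length(betas) != 10L) stop("betas must have length 10")
  if (any(!is.finite(betas)) || any(abs(betas) > 1)) {
    stop("every beta must lie in [-1, 1]")
  }
  structure(list(betas = betas), class = "body_shape")
}

#' Sample a body shape
#'
#' Draws the 10 shape coefficients from Normal(0, sigma), re-sampling any draw
#' that falls outside `[-1, 1]` (rejection rather than clipping, so no
#' probability mass accumulates at the boundary).
#'
#' @param sigma positive standard deviation; default 0.5.
#' @return a `body_shape`.
#' @export
sample_body_shape <- function(sigma = 0.5) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  betas <- numeric(10)
  for (i in 1:10) {
    repeat {
      v <- stats::rnorm(1, 0, sigma)
      if (abs(v) <= 1) break
    }
    betas[i] <- v
  }
  body_shape(betas)
}

# bone-length scale factor implied by a shape (identity for NULL shape)
shape_length_scale <- function(shape) {
  if (is.null(shape)) 1 else 1 + 0.1 * shape$betas[1]
}

# girth scale factor for surface segment radii
shape_girth_scale <- function(shape) {
  if (is.null(shape)) 1 else 1 + 0.15 * mean(shape$betas)
}

# ---- poses -----------------------------------------------------------------

#' Construct an axis-angle pose
#'
#' @param root_translation 3-vector, metres.
#' @param joint_rotation n x 3 matrix of per-joint axis-angle rotations
#'   (direction = axis, norm = angle in radians), rows in tree order.
#' @param tree the associated `kinematic_tree` (used for validation).
#' @return an object of class `pose_aa`.
#' @export
pose_aa <- function(root_translation, joint_rotation, tree) {
  root_translation <- as.numeric(root_translation)
  stopifnot(length(root_translation) == 3L)
  joint_rotation <- as.matrix(joint_rotation)
  if (nrow(joint_rotation) != n_joints(tree) || ncol(joint_rotation) != 3L) {
    stop("joint_rotation must be an n_joints x 3 matrix matching the tree")
  }
  nrm <- sqrt(rowSums(joint_rotation^2))
  if (any(nrm > pi + 1e-9)) stop("axis-angle rotation norm exceeds pi")
  structure(list(root_translation = root_translation,
                 joint_rotation = joint_rotation),
            class = "pose_aa")
}

#' The rest (supine) pose: zero rotations, zero translation
#' @param tree a `kinematic_tree`.
#' @return a `pose_aa`.
#' @export
rest_pose <- function(tree) {
  pose_aa(c(0, 0, 0), matrix(0, n_joints(tree), 3), tree)
}

#' Forward kinematics
#'
#' Composes per-joint rotations down the tree: each joint's position is its
#' parent's position plus the parent's accumulated rotation applied to the
#' (shape-scaled) rest offset. The root's rotation orients the whole body;
#' `root_translation` shifts it rigidly.
#'
#' @param pose a `pose_aa` matching `tree`.
#' @param shape optional `body_shape` (scales bone lengths); `NULL` = neutral.
#' @param tree a `kinematic_tree`.
#' @return n x 3 matrix of joint positions, metres, rows in tree order.
#' @export
forward_kinematics <- function(pose, shape = NULL, tree) {
  n <- n_joints(tree)
  if (nrow(pose$joint_rotation) != n) stop("pose does not match tree")
  sc <- shape_length_scale(shape)
  pos <- matrix(0, n, 3, dimnames = list(tree$joint_names, c("x", "y", "z")))
  racc <- vector("list", n)
  for (j in seq_len(n)) {
    Rj <- aa_to_rotmat(pose$joint_rotation[j, ])
    p <- tree$parent_index[j]
    if (p == 0L) {
      pos[j, ] <- pose$root_translation
      racc[[j]] <- Rj
    } else {
      pos[j, ] <- pos[p, ] + as.numeric(racc[[p]] %*% (sc * tree$rest_offset[j, ]))
      racc[[j]] <- racc[[p]] %*% Rj
    }
  }
  pos
}

#' Convert Cartesian joint positions to an axis-angle pose
#'
#' Walks the tree from the root, recovering at each joint the rotation that
#' maps rest-pose bone directions onto the observed directions expressed in
#' the parent's accumulated frame. Joints with a single child get the minimal
#' (zero-twist) rotation; joints with several children get the best-fit
#' rotation over all child directions (Kabsch). Twist about a single-child
#' bone axis is unobservable from positions and is set to zero. The root
#' translation is carried separately, so the rotational part of the pose is
#' invariant under translation of the input.
#'
#' @param joints n x 3 matrix of joint positions matching `tree`.
#' @param tree a `kinematic_tree`.
#' @return a `pose_aa`.
#' @export
pose_from_joint_positions <- function(joints, tree) {
  n <- n_joints(tree)
  joints <- as.matrix(joints)
  if (nrow(joints) != n || ncol(joints) != 3L) {
    stop("joints must be an n_joints x 3 matrix matching the tree")
  }
  children <- split(seq_len(n), factor(tree$parent_index, levels = 0:n))
  rot <- matrix(0, n, 3)
  racc <- vector("list", n)
  root <- which(tree$parent_index == 0L)
  for (j in seq_len(n)) {
    kids <- children[[as.character(j)]]
    p <- tree$parent_index[j]
    Rparent <- if (p == 0L) diag(3) else racc[[p]]
    if (length(kids) == 0L) {
      racc[[j]] <- Rparent
      next
    }
    rest_d <- obs_d <- matrix(0, 3, 0)
    for (k in kids) {
      r <- tree$rest_offset[k, ]
      rl <- sqrt(sum(r^2))
      d <- joints[k, ] - joints[j, ]
      dl <- sqrt(sum(d^2))
      if (rl < 1e-9) next # zero rest offset carries no direction
      if (dl < 1e-9) {
        stop("degenerate geometry: zero-length bone at joint ",
             tree$joint_names[k])
      }
      rest_d <- cbind(rest_d, r / rl)
      obs_d <- cbind(obs_d, as.numeric(t(Rparent) %*% d) / dl)
    }
    Rj <- if (ncol(rest_d) == 0L) diag(3)
          else if (ncol(rest_d) == 1L) minimal_rotation(rest_d[, 1], obs_d[, 1])
          else kabsch_rotation(rest_d, obs_d)
    rot[j, ] <- rotmat_to_aa(Rj)
    racc[[j]] <- Rparent %*% Rj
  }
  pose_aa(joints[root, ], rot, tree)
}
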