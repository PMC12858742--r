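#' Load the articulated kinematic tree
#'
#' The tree is shipped as a versioned plain-text asset (one joint per line:
#' name, parent, rest offset in metres, per-axis pose limit in radians). It is
#' an SMPL-compatible 22-body-joint subset extended with five face joints so
#' that all 17 COCO person keypoints are tree joints. The rest pose is supine:
#' head toward +x, anatomical left toward +y, +z up, pelvis at the origin.
#'
#' @param path path to the tree asset; defaults to the packaged tree.
#' @return an object of class `kinematic_tree` with elements `joint_names`,
#'   `parent_index` (0 for the root), `rest_offset` (n x 3 matrix, metres) and
#'   `joint_limit` (radians, per-axis bound used by the pose generator).
#' @export
kinematic_tree <- function(path = system.file("extdata", "kinematic_tree.txt",
                                              package = "synthretarget")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(parts) != 6L
  if (any(bad)) stop("malformed kinematic tree line: ", lines[which(bad)[1]])
  nm <- vapply(parts, `[`, "", 1L)
  parent_nm <- vapply(parts, `[`, "", 2L)
  off <- t(vapply(parts, function(p) as.numeric(p[3:5]), numeric(3)))
  lim <- vapply(parts, function(p) as.numeric(p[6]), numeric(1))
  if (anyDuplicated(nm)) stop("duplicate joint name in kinematic tree")
  parent_index <- ifelse(parent_nm == "-", 0L, match(parent_nm, nm))
  if (anyNA(parent_index)) {
    stop("unknown parent joint: ", parent_nm[which(is.na(parent_index))[1]])
  }
  tree <- structure(
    list(joint_names = nm, parent_index = as.integer(parent_index),
         rest_offset = `dimnames<-`(off, list(nm, c("x", "y", "z"))),
         joint_limit = stats::setNames(lim, nm)),
    class = "kinematic_tree")
  validate_tree(tree)
  tree
}

#' @export
print.kinematic_tree <- function(x, ...) {
  cat("kinematic_tree:", length(x$joint_names), "joints, root =",
      x$joint_names[x$parent_index == 0L], "\n")
  invisible(x)
}

n_joints <- function(tree) length(tree$joint_names)

#' Validate kinematic-tree invariants
#'
#' Checks: exactly one root; topological order (parent index < child index);
#' mirror symmetry of left/right joint pairs about the sagittal plane (y = 0);
#' presence of all 17 COCO keypoint joints.
#'
#' @param tree a `kinematic_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  n <- n_joints(tree)
  if (sum(tree$parent_index == 0L) != 1L) stop("tree must have exactly one root")
  if (any(tree$parent_index >= seq_len(n))) {
    stop("tree is not in topological order (parent index must precede child)")
  }
  lefts <- grep("^left_", tree$joint_names, value = TRUE)
  for (l in lefts) {
    r <- sub("^left_", "right_", l)
    if (!r %in% tree$joint_names) stop("unpaired left joint: ", l)
    ol <- tree$rest_offset[l, ]
    or <- tree$rest_offset[r, ]
    if (max(abs(ol - or * c(1, -1, 1))) > 1e-9) {
      stop("rest offsets of ", l, "/", r, " are not mirror-symmetric")
    }
  }
  miss <- setdiff(coco_keypoint_names(), tree$joint_names)
  if (length(miss)) stop("tree lacks COCO keypoint joints: ",
                         paste(miss, collapse = ", "))
  invisible(tree)
}

#' Names of the 17 COCO person keypoints, in standard order
#' @return character vector of length 17.
#' @export
coco_keypoint_names <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

# Indices of the COCO keypoints within the tree's joint list.
coco_keypoint_index <- function(tree) {
  match(coco_keypoint_names(), tree$joint_names)
}

# Standard COCO person skeleton (1-based keypoint index pairs).
coco_skeleton <- function() {
  matrix(c(16, 14, 14, 12, 17, 15, 15, 13, 12, 13, 6, 12, 7, 13, 6, 7,
           6, 8, 7, 9, 8, 10, 9, 11, 2, 3, 1, 2, 1, 3, 2, 4, 3, 5, 4, 6, 5, 7),
         ncol = 2, byrow = TRUE)
}
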