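## Synthetic stand-ins for every external asset: procedural ward backgrounds
## with exact bed boxes, joint-limited pose sequences (a motion-capture
## stand-in), and controlled-error detection simulators for exercising the
## evaluation and statistics modules end to end without any downloads.

#' Generate a procedural ward-like background with an exact bed box
#'
#' A flat-shaded indoor scene: a wall band, a floor band, a bed rectangle
#' with a darker frame and a pillow at the head end, plus optional distractor
#' rectangles. The bed bounding box is recorded exactly. Deterministic for a
#' fixed seed.
#'
#' @param seed integer seed.
#' @param size `c(width, height)` pixels.
#' @param n_distractors number of distractor rectangles.
#' @param min_bed_frac minimum bed area as a fraction of the image.
#' @return a `background_asset`.
#' @export
generate_background <- function(seed = 1L, size = c(640L, 480L),
                                n_distractors = 3L, min_bed_frac = 0.12) {
  w <- as.integer(size[1]); h <- as.integer(size[2])
  if (w < 16L || h < 16L) stop("background size must be at least 16 x 16")
  with_seed(seed, {
    img <- array(0, c(h, w, 3))
    wall <- stats::runif(3, 0.55, 0.85)
    floor_c <- stats::runif(3, 0.35, 0.6)
    split_y <- as.integer(round(h * stats::runif(1, 0.3, 0.45)))
    for (ch in 1:3) {
      img[seq_len(split_y), , ch] <- wall[ch]
      img[seq.int(split_y + 1L, h), , ch] <- floor_c[ch]
    }
    # bed rectangle on the floor, landscape orientation
    bw <- as.integer(round(w * stats::runif(1, 0.45, 0.7)))
    bh <- as.integer(round(h * stats::runif(1, 0.3, 0.45)))
    if (bw * bh < min_bed_frac * w * h) {
      bw <- as.integer(ceiling(min_bed_frac * w * h / bh))
    }
    bw <- min(bw, w - 2L)
    bx <- as.integer(floor(stats::runif(1, 0, w - bw)))
    by <- as.integer(floor(stats::runif(1, split_y * 0.8, h - bh)))
    by <- max(1L, min(by, h - bh))
    bed_c <- stats::runif(3, 0.8, 0.95)
    frame_c <- bed_c * 0.5
    rows <- seq.int(by + 1L, by + bh)
    cols <- seq.int(bx + 1L, bx + bw)
    for (ch in 1:3) img[rows, cols, ch] <- frame_c[ch]
    inset <- max(2L, as.integer(round(min(bw, bh) * 0.06)))
    ri <- seq.int(by + 1L + inset, by + bh - inset)
    ci <- seq.int(bx + 1L + inset, bx + bw - inset)
    for (ch in 1:3) img[ri, ci, ch] <- bed_c[ch]
    # pillow block at the head end (+x end of the bed)
    pw <- as.integer(round(bw * 0.18)); ph <- as.integer(round(bh * 0.5))
    pr <- seq.int(by + 1L + as.integer((bh - ph) / 2), length.out = ph)
    pc <- seq.int(bx + bw - inset - pw, length.out = pw)
    pc <- pc[pc >= 1L & pc <= w]
    for (ch in 1:3) img[pr, pc, ch] <- min(1, bed_c[ch] * 1.05)
    # distractors (cabinets, drip stands) outside the bed where possible
    if (n_distractors > 0L) for (k in seq_len(n_distractors)) {
      dw <- as.integer(round(w * stats::runif(1, 0.03, 0.1)))
      dh <- as.integer(round(h * stats::runif(1, 0.08, 0.25)))
      dx <- as.integer(floor(stats::runif(1, 0, w - dw)))
      dy <- as.integer(floor(stats::runif(1, 0, h - dh)))
      dc <- stats::runif(3, 0.1, 0.9)
      for (ch in 1:3) {
        img[seq.int(dy + 1L, dy + dh), seq.int(dx + 1L, dx + dw), ch] <- dc[ch]
      }
    }
    background_asset(img, c(bx, by, bw, bh),
                     id = sprintf("synthbg%06d", seed))
  })
}

#' Specification for a joint-limited synthetic pose sequence
#'
#' @param n_frames number of frames.
#' @param step_scale per-frame random-walk step, radians.
#' @param seed integer seed.
#' @return an object of class `pose_sequence_spec`.
#' @export
pose_sequence_spec <- function(n_frames = 10L, step_scale = 0.08, seed = 1L) {
  if (step_scale < 0) stop("step_scale must be non-negative")
  structure(list(n_frames = as.integer(n_frames), step_scale = step_scale,
                 seed = as.integer(seed)), class = "pose_sequence_spec")
}

# reflect value into [-lim, lim]
reflect_into <- function(x, lim) {
  if (lim <= 0) return(0 * x)
  period <- 4 * lim
  y <- (x + lim) %% period
  y <- ifelse(y < 0, y + period, y)
  ifelse(y <= 2 * lim, y - lim, 3 * lim - y)
}

#' Generate a joint-limited pose sequence
#'
#' A reflected random walk per joint and axis-angle component, starting from
#' the supine rest pose and confined to the per-joint limits shipped with
#' the kinematic tree. Every frame satisfies the limits; a fixed seed gives
#' a reproducible sequence. This emulates sampling plausible poses from a
#' motion-capture archive without requiring one.
#'
#' @param spec a `pose_sequence_spec`.
#' @param tree a `kinematic_tree`.
#' @return list of `pose_aa`, length `n_frames`.
#' @export
generate_pose_sequence <- function(spec, tree = kinematic_tree()) {
  n <- n_joints(tree)
  lim <- tree$joint_limit
  with_seed(spec$seed, {
    state <- matrix(0, n, 3)
    out <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      step <- matrix(stats::rnorm(n * 3, 0, spec$step_scale), n, 3)
      state <- state + step
      for (j in seq_len(n)) state[j, ] <- reflect_into(state[j, ], lim[j])
      out[[f]] <- pose_aa(c(0, 0, 0), state, tree)
    }
    out
  })
}

# one plausible pose drawn with the current RNG (used by the plan builder):
# a short random walk whose endpoint is taken as the pose
sample_pose <- function(tree, step_scale = 0.12, n_steps = 8L) {
  n <- n_joints(tree)
  lim <- tree$joint_limit
  state <- matrix(0, n, 3)
  for (f in seq_len(n_steps)) {
    state <- state + matrix(stats::rnorm(n * 3, 0, step_scale), n, 3)
    for (j in seq_len(n)) state[j, ] <- reflect_into(state[j, ], lim[j])
  }
  pose_aa(c(0, 0, 0), state, tree)
}

#' Perturb a ground-truth box to a target IoU
#'
#' Produces a detection whose box has IoU within 0.01 of the requested
#' target, by shifting the box along a random axis/sign with the shift
#' magnitude solved by bisection. Useful for probing the 0.75 scoring
#' boundary with constructed detections.
#'
#' @param gt_bbox `[x, y, w, h]` ground-truth box.
#' @param target_iou target in (0, 1].
#' @param image_id id for the returned detection.
#' @param confidence_range confidence is drawn uniformly from this range.
#' @return a `detection`.
#' @export
perturb_to_target_iou <- function(gt_bbox, target_iou, image_id = 1L,
                                  confidence_range = c(0.5, 1.0)) {
  if (target_iou <= 0 || target_iou > 1) stop("target_iou must lie in (0, 1]")
  conf <- stats::runif(1, confidence_range[1], confidence_range[2])
  if (target_iou == 1) {
    return(detection(image_id, gt_bbox, conf))
  }
  axis <- sample(c(1L, 2L), 1L)
  sgn <- sample(c(-1, 1), 1L)
  extent <- gt_bbox[2L + axis]
  shift_box <- function(s) {
    b <- gt_bbox
    b[axis] <- b[axis] + sgn * s
    b
  }
  lo <- 0; hi <- extent # IoU(extent) = 0 < target; IoU(0) = 1 > target
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (iou(gt_bbox, shift_box(mid)) > target_iou) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  got <- iou(gt_bbox, shift_box(s))
  if (abs(got - target_iou) > 0.01) {
    stop(sprintf("could not reach target IoU %.3f (achieved %.3f)",
                 target_iou, got))
  }
  detection(image_id, shift_box(s), conf)
}
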