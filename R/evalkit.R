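## Detection and pose evaluation: IoU, confidence filtering, greedy NMS, the
## COCO AP/AR sweep over IoU thresholds 0.50-0.95, OKS, the per-person
## IoU-threshold scoring system, and the ln(width/height) diagnostic.

#' Evaluation configuration
#'
#' Default thresholds: detections are de-noised at confidence 0.001 (0.2 for
#' the pose pipeline), overlapping boxes suppressed at NMS IoU 0.65, the
#' per-person score counts a match only at IoU >= 0.75, and AP/AR average
#' over IoU thresholds 0.50 to 0.95 in steps of 0.05.
#'
#' @param conf_threshold_detect,conf_threshold_pose,nms_iou,score_iou_threshold
#'   thresholds in [0, 1].
#' @param ap_iou_grid strictly increasing IoU thresholds for AP/AR.
#' @param score_mode `"iou"` (score = matched IoU when above threshold) or
#'   `"binary"` (1/0 at the threshold).
#' @param max_detections per-image cap for AP/AR (COCO convention).
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(conf_threshold_detect = 0.001, conf_threshold_pose = 0.2,
                        nms_iou = 0.65, score_iou_threshold = 0.75,
                        ap_iou_grid = seq(0.5, 0.95, by = 0.05),
                        score_mode = c("iou", "binary"), max_detections = 100L) {
  score_mode <- match.arg(score_mode)
  thr <- c(conf_threshold_detect, conf_threshold_pose, nms_iou,
           score_iou_threshold)
  if (any(thr < 0 | thr > 1)) stop("all thresholds must lie in [0, 1]")
  if (any(diff(ap_iou_grid) <= 0)) stop("ap_iou_grid must be strictly increasing")
  structure(list(conf_threshold_detect = conf_threshold_detect,
                 conf_threshold_pose = conf_threshold_pose, nms_iou = nms_iou,
                 score_iou_threshold = score_iou_threshold,
                 ap_iou_grid = ap_iou_grid, score_mode = score_mode,
                 max_detections = as.integer(max_detections)),
            class = "eval_config")
}

#' Intersection over union of two boxes
#'
#' Standard axis-aligned IoU on continuous `[x, y, w, h]` boxes (no pixel
#' discretisation); 0 for disjoint boxes and, by convention, for two empty
#' boxes.
#'
#' @param a,b boxes `[x, y, w, h]` with non-negative sizes.
#' @return a value in [0, 1].
#' @export
iou <- function(a, b) {
  if (a[3] < 0 || a[4] < 0 || b[3] < 0 || b[4] < 0) {
    stop("box widths/heights must be non-negative")
  }
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between rows of two n x 4 box matrices
iou_matrix <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  M <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) M[i, j] <- iou(A[i, ], B[j, ])
  M
}

#' Filter detections by confidence
#'
#' Keeps detections with confidence greater than or equal to the threshold,
#' preserving order.
#'
#' @param detections list of `detection` records.
#' @param threshold value in [0, 1].
#' @return filtered list.
#' @export
filter_confidence <- function(detections, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  Filter(function(d) d$confidence >= threshold, detections)
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence remaining detection and discards
#' all others whose IoU with it exceeds the threshold. Ties in confidence are
#' broken deterministically by input position (earlier wins). Detections from
#' different images never suppress each other.
#'
#' @param detections list of `detection` records.
#' @param iou_threshold suppression threshold, default 0.65.
#' @return the surviving detections, ordered by decreasing confidence
#'   (position-stable within ties).
#' @export
nms <- function(detections, iou_threshold = 0.65) {
  if (iou_threshold < 0 || iou_threshold > 1) stop("iou_threshold must lie in [0, 1]")
  if (length(detections) <= 1L) return(detections)
  conf <- vapply(detections, function(d) d$confidence, 1)
  imgs <- vapply(detections, function(d) as.character(d$image_id), "")
  ord <- order(-conf, seq_along(detections))
  alive <- rep(TRUE, length(detections))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) {
      if (!alive[j] || j == i || imgs[j] != imgs[i]) next
      if (iou(detections[[i]]$bbox, detections[[j]]$bbox) > iou_threshold) {
        alive[j] <- FALSE
      }
    }
  }
  detections[keep]
}

#' Per-person IoU-threshold scores
#'
#' For each ground-truth person, the matched detection's IoU counts as the
#' score only when it reaches the threshold (default 0.75); unmatched or
#' poorly-localised ground truths score 0. Matching is one-to-one and
#' globally greedy: the highest-IoU (ground truth, detection) pair among
#' unmatched items is taken repeatedly, with ties broken by higher detection
#' confidence then lower ground-truth id. This captures detection
#' sensitivity (was the person found) and localisation accuracy (how
#' precisely) in one number per person. Detections are expected to be
#' confidence-filtered and NMS-processed already.
#'
#' @param ground_truths list of `coco_annotation` records.
#' @param detections list of `detection` records.
#' @param config an `eval_config`.
#' @return data.frame with one row per ground truth: `image_id`, `gt_id`,
#'   `matched_iou`, `score`.
#' @export
score_persons <- function(ground_truths, detections, config = eval_config()) {
  gt_img <- vapply(ground_truths, function(g) as.character(g$image_id), "")
  out <- data.frame(
    image_id = gt_img,
    gt_id = vapply(ground_truths, function(g) as.numeric(g$id), 1),
    matched_iou = 0, score = 0, stringsAsFactors = FALSE)
  if (length(ground_truths) == 0L) return(out)
  det_img <- vapply(detections, function(d) as.character(d$image_id), "")
  for (img in unique(gt_img)) {
    gi <- which(gt_img == img)
    di <- which(det_img == img)
    if (length(di) == 0L) next
    M <- iou_matrix(do.call(rbind, lapply(ground_truths[gi], `[[`, "bbox")),
                    do.call(rbind, lapply(detections[di], `[[`, "bbox")))
    conf <- vapply(detections[di], function(d) d$confidence, 1)
    gids <- out$gt_id[gi]
    repeat {
      if (all(M < 0) || max(M) <= 0) break
      best <- max(M)
      cand <- which(M == best, arr.ind = TRUE)
      if (nrow(cand) > 1L) {
        o <- order(-conf[cand[, 2]], gids[cand[, 1]])
        cand <- cand[o[1], , drop = FALSE]
      }
      g <- cand[1, 1]; d <- cand[1, 2]
      out$matched_iou[gi[g]] <- best
      M[g, ] <- -1
      M[, d] <- -1
    }
  }
  thr <- config$score_iou_threshold
  hit <- out$matched_iou >= thr
  out$score <- if (config$score_mode == "binary") as.numeric(hit)
               else ifelse(hit, out$matched_iou, 0)
  out
}

# COCO-style matching at one IoU threshold: detections in decreasing
# confidence, each matched to the highest-IoU unmatched gt above threshold.
# Returns logical TP flags aligned with the (sorted) detections.
match_at_threshold <- function(gt_boxes_by_img, det_tab, thr) {
  tp <- logical(nrow(det_tab))
  used <- lapply(gt_boxes_by_img, function(g) rep(FALSE, nrow(g)))
  for (k in seq_len(nrow(det_tab))) {
    img <- det_tab$image_id[k]
    G <- gt_boxes_by_img[[img]]
    if (is.null(G) || nrow(G) == 0L) next
    ious <- vapply(seq_len(nrow(G)), function(i)
      iou(G[i, ], c(det_tab$x[k], det_tab$y[k], det_tab$w[k], det_tab$h[k])), 1)
    ious[used[[img]]] <- -1
    best <- which.max(ious)
    if (ious[best] >= thr) {
      tp[k] <- TRUE
      used[[img]][best] <- TRUE
    }
  }
  tp
}

#' COCO AP/AR over the IoU threshold sweep
#'
#' For each IoU threshold in the grid, detections are ranked by confidence
#' (capped at `max_detections` per image), matched greedily to ground truths,
#' and the precision-recall curve is summarised by the 101-point interpolated
#' average precision and the maximum recall. The summary is the mean over the
#' grid, reported in percent (single category, all areas).
#'
#' @param ground_truths list of `coco_annotation` records.
#' @param detections list of `detection` records.
#' @param config an `eval_config`.
#' @return an object of class `eval_summary`: `AP`, `AR` (percent), and a
#'   `per_threshold` data.frame. With no ground truths, `AP`/`AR` are `NA`
#'   (undefined), not 0.
#' @export
ap_ar <- function(ground_truths, detections, config = eval_config()) {
  n_gt <- length(ground_truths)
  grid <- config$ap_iou_grid
  if (n_gt == 0L) {
    return(structure(list(AP = NA_real_, AR = NA_real_,
                          per_threshold = data.frame(iou = grid, ap = NA_real_,
                                                     ar = NA_real_)),
                     class = "eval_summary"))
  }
  gt_img <- vapply(ground_truths, function(g) as.character(g$image_id), "")
  gt_boxes_by_img <- lapply(split(ground_truths, gt_img), function(gs)
    do.call(rbind, lapply(gs, `[[`, "bbox")))
  if (length(detections)) {
    det_tab <- data.frame(
      image_id = vapply(detections, function(d) as.character(d$image_id), ""),
      x = vapply(detections, function(d) d$bbox[1], 1),
      y = vapply(detections, function(d) d$bbox[2], 1),
      w = vapply(detections, function(d) d$bbox[3], 1),
      h = vapply(detections, function(d) d$bbox[4], 1),
      conf = vapply(detections, function(d) d$confidence, 1),
      stringsAsFactors = FALSE)
    # cap detections per image by confidence
    det_tab <- do.call(rbind, lapply(split(det_tab, det_tab$image_id), function(t) {
      t[order(-t$conf)[seq_len(min(nrow(t), config$max_detections))], , drop = FALSE]
    }))
    det_tab <- det_tab[order(-det_tab$conf), , drop = FALSE]
  } else {
    det_tab <- data.frame(image_id = character(), x = numeric(), y = numeric(),
                          w = numeric(), h = numeric(), conf = numeric())
  }
  rec_grid <- seq(0, 1, by = 0.01)
  aps <- ars <- numeric(length(grid))
  for (t in seq_along(grid)) {
    if (nrow(det_tab) == 0L) { aps[t] <- 0; ars[t] <- 0; next }
    tp <- match_at_threshold(gt_boxes_by_img, det_tab, grid[t])
    ctp <- cumsum(tp)
    recall <- ctp / n_gt
    precision <- ctp / seq_along(ctp)
    # precision envelope (monotone non-increasing from the right)
    penv <- rev(cummax(rev(precision)))
    aps[t] <- mean(vapply(rec_grid, function(r) {
      i <- which(recall >= r)
      if (length(i)) penv[i[1]] else 0
    }, 1))
    ars[t] <- max(recall)
  }
  structure(list(AP = 100 * mean(aps), AR = 100 * mean(ars),
                 per_threshold = data.frame(iou = grid, ap = 100 * aps,
                                            ar = 100 * ars)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("AP = %.1f%% | AR = %.1f%% (IoU %.2f-%.2f)\n", x$AP, x$AR,
              min(x$per_threshold$iou), max(x$per_threshold$iou)))
  invisible(x)
}

#' Standard per-keypoint OKS constants (k = 2 * sigma)
#' @return named numeric vector of length 17.
#' @export
oks_constants <- function() {
  sigmas <- c(0.026, 0.025, 0.025, 0.035, 0.035, 0.079, 0.079, 0.072, 0.072,
              0.062, 0.062, 0.107, 0.107, 0.087, 0.087, 0.089, 0.089)
  stats::setNames(2 * sigmas, coco_keypoint_names())
}

#' Object keypoint similarity
#'
#' `OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]`
#' with `d_i` the Euclidean pixel distance between predicted and labelled
#' keypoint i, `s^2` the ground-truth area, and `k_i` the standard
#' per-keypoint constants.
#'
#' @param gt a `coco_annotation` with keypoints and positive area.
#' @param pred_keypoints 17 x 2 (or 17 x 3) matrix of predicted positions.
#' @param constants per-keypoint constants, default [oks_constants()].
#' @return OKS in [0, 1]; `NA` when the ground truth has no labelled
#'   keypoints.
#' @export
oks <- function(gt, pred_keypoints, constants = oks_constants()) {
  if (is.null(gt$keypoints)) return(NA_real_)
  if (gt$area <= 0) stop("ground truth must have positive area")
  kp <- matrix(gt$keypoints, ncol = 3, byrow = TRUE)
  lab <- kp[, 3] > 0
  if (!any(lab)) return(NA_real_)
  pred_keypoints <- as.matrix(pred_keypoints)
  d2 <- (pred_keypoints[lab, 1] - kp[lab, 1])^2 +
        (pred_keypoints[lab, 2] - kp[lab, 2])^2
  mean(exp(-d2 / (2 * gt$area * constants[lab]^2)))
}

#' Bounding-box aspect diagnostic: ln(width/height)
#'
#' Lower values indicate a more upright pose, higher values a more
#' lying-down pose; 0 is a square box. The density is a normalised histogram
#' (integrates to 1).
#'
#' @param bboxes n x 4 matrix of `[x, y, w, h]` boxes, or a `coco_dataset`.
#' @param bins number of histogram bins.
#' @return list with `values` (per-box ln(w/h)) and `density` (data.frame
#'   `mid`, `density`, `width`).
#' @export
aspect_log_ratio <- function(bboxes, bins = 50L) {
  if (inherits(bboxes, "coco_dataset")) {
    bboxes <- do.call(rbind, lapply(bboxes$annotations, `[[`, "bbox"))
  }
  bboxes <- matrix(as.numeric(bboxes), ncol = 4)
  if (nrow(bboxes) == 0L) stop("dataset contains no boxes")
  if (any(bboxes[, 3] <= 0 | bboxes[, 4] <= 0)) {
    stop("all boxes must have positive width and height")
  }
  v <- log(bboxes[, 3] / bboxes[, 4])
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  hh <- graphics::hist(v, breaks = brk, plot = FALSE)
  list(values = v,
       density = data.frame(mid = hh$mids, density = hh$density,
                            width = diff(brk)))
}
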