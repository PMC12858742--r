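## COCO-style annotation and detection-result files: construction, canonical
## serialisation, reading with validation, and leakage-guarded splitting.
## 3D joints are stored under a namespaced extension key ("x_joints3d") so
## files remain valid standard COCO.

#' Construct a COCO annotation record
#'
#' @param id annotation id.
#' @param image_id id of the image the annotation belongs to.
#' @param bbox `[x, y, w, h]` pixels.
#' @param keypoints numeric vector of length 51 (17 x (x, y, v)) or a 17 x 3
#'   matrix; may be NULL.
#' @param joints3d optional per-joint 3D positions (matrix), stored under the
#'   `x_joints3d` extension key.
#' @return a list with class `coco_annotation`.
#' @export
coco_annotation <- function(id, image_id, bbox, keypoints = NULL,
                            joints3d = NULL) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || bbox[3] < 0 || bbox[4] < 0) {
    stop("bbox must be [x, y, w, h] with non-negative size (annotation ", id, ")")
  }
  if (!is.null(keypoints)) {
    if (is.matrix(keypoints)) keypoints <- as.numeric(t(keypoints))
    if (length(keypoints) != 51L) {
      stop("keypoints must be 17 x (x, y, v) (annotation ", id, ")")
    }
  }
  nk <- if (is.null(keypoints)) 0L else sum(keypoints[seq(3, 51, 3)] > 0)
  structure(list(
    id = id, image_id = image_id, category_id = 1L, bbox = bbox,
    area = bbox[3] * bbox[4], iscrowd = 0L,
    keypoints = keypoints, num_keypoints = as.integer(nk),
    joints3d = joints3d), class = "coco_annotation")
}

#' Construct a COCO-style dataset
#'
#' @param images data.frame with columns `id`, `width`, `height`,
#'   `file_name`, and optionally `config_id`, `render_index`.
#' @param annotations list of `coco_annotation` records.
#' @return an object of class `coco_dataset`.
#' @export
coco_dataset <- function(images = data.frame(id = integer(), width = integer(),
                                             height = integer(),
                                             file_name = character()),
                         annotations = list()) {
  need <- c("id", "width", "height", "file_name")
  miss <- setdiff(need, names(images))
  if (length(miss)) stop("images table lacks columns: ", paste(miss, collapse = ", "))
  img_ids <- images$id
  for (a in annotations) {
    if (!a$image_id %in% img_ids) {
      stop("annotation ", a$id, " references unknown image ", a$image_id)
    }
  }
  structure(list(images = images, annotations = annotations),
            class = "coco_dataset")
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat("coco_dataset:", nrow(x$images), "images,", length(x$annotations),
      "annotations\n")
  invisible(x)
}

person_category <- function() {
  list(id = 1L, name = "person", supercategory = "person",
       keypoints = coco_keypoint_names(),
       skeleton = lapply(seq_len(nrow(coco_skeleton())),
                         function(i) as.integer(coco_skeleton()[i, ])))
}

annotation_to_list <- function(a) {
  out <- list(id = a$id, image_id = a$image_id, category_id = a$category_id,
              bbox = round(a$bbox, 6), area = round(a$area, 6),
              iscrowd = a$iscrowd)
  if (!is.null(a$keypoints)) {
    out$keypoints <- round(a$keypoints, 6)
    out$num_keypoints <- a$num_keypoints
  }
  if (!is.null(a$joints3d)) {
    out$x_joints3d <- round(as.numeric(t(a$joints3d)), 6)
  }
  if (!is.null(a$score)) out$score <- a$score
  out
}

#' Write a dataset as standard COCO JSON
#'
#' The serialisation is canonical (fixed key order, coordinates rounded to
#' 1e-6 px), so a fixed dataset always produces byte-identical files.
#'
#' @param ds a `coco_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(ds, path) {
  imgs <- lapply(seq_len(nrow(ds$images)), function(i) {
    r <- as.list(ds$images[i, , drop = FALSE])
    out <- list(id = r$id[[1]], width = r$width[[1]], height = r$height[[1]],
                file_name = r$file_name[[1]])
    if (!is.null(r$config_id)) out$x_config_id <- r$config_id[[1]]
    if (!is.null(r$render_index)) out$x_render_index <- r$render_index[[1]]
    out
  })
  obj <- list(images = imgs,
              annotations = lapply(ds$annotations, annotation_to_list),
              categories = list(person_category()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

req_field <- function(rec, field, what, i) {
  if (is.null(rec[[field]])) {
    stop("COCO ", what, " record ", i, " lacks required key '", field, "'")
  }
  rec[[field]]
}

#' Read a COCO JSON annotation file
#'
#' Validates the layout (required keys, image references) and reports the
#' offending record on failure. `write_coco()` then `read_coco()` is the
#' identity on the data model.
#'
#' @param path path to a COCO JSON file.
#' @return a `coco_dataset`.
#' @export
read_coco <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$images) || is.null(obj$annotations)) {
    stop("COCO file lacks images/annotations lists: ", path)
  }
  imgs <- obj$images
  images <- data.frame(
    id = vapply(seq_along(imgs), function(i) as.integer(req_field(imgs[[i]], "id", "image", i)), 1L),
    width = vapply(seq_along(imgs), function(i) as.integer(req_field(imgs[[i]], "width", "image", i)), 1L),
    height = vapply(seq_along(imgs), function(i) as.integer(req_field(imgs[[i]], "height", "image", i)), 1L),
    file_name = vapply(seq_along(imgs), function(i) as.character(req_field(imgs[[i]], "file_name", "image", i)), ""),
    stringsAsFactors = FALSE)
  if (any(vapply(imgs, function(r) !is.null(r$x_config_id), TRUE))) {
    images$config_id <- vapply(imgs, function(r)
      if (is.null(r$x_config_id)) NA_character_ else as.character(r$x_config_id), "")
    images$render_index <- vapply(imgs, function(r)
      if (is.null(r$x_render_index)) NA_integer_ else as.integer(r$x_render_index), 1L)
  }
  anns <- lapply(seq_along(obj$annotations), function(i) {
    r <- obj$annotations[[i]]
    kp <- if (!is.null(r$keypoints)) as.numeric(unlist(r$keypoints))
    j3 <- if (!is.null(r$x_joints3d)) {
      v <- as.numeric(unlist(r$x_joints3d))
      matrix(v, ncol = 3, byrow = TRUE)
    }
    coco_annotation(id = req_field(r, "id", "annotation", i),
                    image_id = req_field(r, "image_id", "annotation", i),
                    bbox = as.numeric(unlist(req_field(r, "bbox", "annotation", i))),
                    keypoints = kp, joints3d = j3)
  })
  coco_dataset(images, anns)
}

#' Construct a detection record
#'
#' @param image_id image the detection belongs to.
#' @param bbox `[x, y, w, h]`.
#' @param confidence score in [0, 1].
#' @param keypoints optional keypoints with per-point scores.
#' @return a list with class `detection`.
#' @export
detection <- function(image_id, bbox, confidence, keypoints = NULL) {
  if (!is.finite(confidence) || confidence < 0 || confidence > 1) {
    stop("confidence must lie in [0, 1]")
  }
  structure(list(image_id = image_id, bbox = as.numeric(bbox),
                 confidence = confidence, keypoints = keypoints),
            class = "detection")
}

#' Write detections in the COCO results dialect (bare list with scores)
#' @param detections list of `detection` records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(detections, path) {
  obj <- lapply(detections, function(d) {
    out <- list(image_id = d$image_id, category_id = 1L,
                bbox = round(d$bbox, 6), score = d$confidence)
    if (!is.null(d$keypoints)) out$keypoints <- round(as.numeric(d$keypoints), 6)
    out
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO results file into a list of detections
#' @param path path to a results JSON (bare annotation list with scores).
#' @return list of `detection` records.
#' @export
read_coco_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(obj), function(i) {
    r <- obj[[i]]
    detection(image_id = req_field(r, "image_id", "result", i),
              bbox = as.numeric(unlist(req_field(r, "bbox", "result", i))),
              confidence = req_field(r, "score", "result", i),
              keypoints = if (!is.null(r$keypoints)) as.numeric(unlist(r$keypoints)))
  })
}

#' Split a dataset into train and validation without configuration leakage
#'
#' Uniform random partition without replacement, seeded-deterministic, with
#' the guard that all renders of one configuration (same `config_id`) land on
#' the same side, so near-duplicate renders can never span the split.
#'
#' @param ds a `coco_dataset`, or a data.frame with `id` and optionally
#'   `config_id` columns (e.g. [plan_image_table()]).
#' @param train_n,val_n target sizes; defaults 10,000 and 800.
#' @param seed integer seed.
#' @return list with `train` and `validation`, each the same type as `ds`.
#' @export
split_dataset <- function(ds, train_n = 10000L, val_n = 800L, seed = 1L) {
  images <- if (inherits(ds, "coco_dataset")) ds$images else ds
  n <- nrow(images)
  if (train_n + val_n > n) {
    stop("requested split (", train_n, " + ", val_n,
         ") exceeds dataset size (", n, ")")
  }
  grp <- if (!is.null(images$config_id)) images$config_id else as.character(images$id)
  groups <- split(seq_len(n), grp)
  ord <- with_seed(seed, sample(length(groups)))
  train_idx <- integer(0)
  val_idx <- integer(0)
  for (g in ord) {
    idx <- groups[[g]]
    if (length(train_idx) + length(idx) <= train_n) {
      train_idx <- c(train_idx, idx)
    } else if (length(val_idx) + length(idx) <= val_n) {
      val_idx <- c(val_idx, idx)
    }
  }
  if (length(train_idx) != train_n || length(val_idx) != val_n) {
    stop("cannot reach the requested split sizes with whole configurations; ",
         "achieved ", length(train_idx), " train / ", length(val_idx),
         " validation")
  }
  take <- function(idx) {
    if (!inherits(ds, "coco_dataset")) return(ds[sort(idx), , drop = FALSE])
    imgs <- images[sort(idx), , drop = FALSE]
    keep <- imgs$id
    coco_dataset(imgs, Filter(function(a) a$image_id %in% keep, ds$annotations))
  }
  list(train = take(train_idx), validation = take(val_idx))
}
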