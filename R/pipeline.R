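## Orchestration: seeded end-to-end runs wiring configuration to modules,
## with provenance manifests. Every run is reproducible from its manifest
## (config digest + seed); identical seeds give byte-identical outputs.

pkg_version <- function() {
  as.character(utils::packageVersion("synthretarget"))
}

config_digest <- function(cfg) {
  fnv1a_hex(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10))
}

#' Generate a scenario dataset end to end
#'
#' Expands the scenario preset into a generation plan, renders each scene
#' with the built-in rasterizer, drapes blankets where planned, composites
#' each render onto a procedurally generated ward background near its bed,
#' writes COCO annotation files for a leakage-guarded train/validation
#' split, and returns a run manifest with full provenance.
#'
#' @param preset a `scenario_preset` (or preset name).
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; all randomness derives from it.
#' @param train_n,val_n split sizes (defaults 10,000 / 800 scale with the
#'   plan when it is smaller; see Details).
#' @param image_size rendered image size `c(width, height)`.
#' @param n_backgrounds size of the procedural background bank.
#' @param write_images write composite PNGs (annotations are always written).
#' @param renderer a renderer backend, default the built-in rasterizer.
#' @param backgrounds optional list of `background_asset` to use instead of
#'   the procedural bank (e.g. loaded via [load_bed_sidecar()]).
#'
#' @details When `train_n`/`val_n` are left `NULL` they default to the
#' canonical 10,000/800 proportions, rounded to whole configurations (the
#' full-size 2,700 x 4 plan splits exactly 10,000 / 800).
#'
#' @return the run manifest (list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_generate <- function(preset = scenario_preset("B"), out_dir, seed = 1L,
                         train_n = NULL, val_n = NULL,
                         image_size = c(640L, 480L), n_backgrounds = 20L,
                         write_images = TRUE, renderer = default_renderer(),
                         backgrounds = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  validate_preset(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images) {
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  }
  tree <- kinematic_tree()
  if (is.null(backgrounds)) {
    backgrounds <- lapply(seq_len(n_backgrounds), function(i)
      generate_background(seed = derive_seed(seed, paste0("background:", i)),
                          size = image_size))
  }
  plan <- build_generation_plan(preset, seed = seed, tree = tree,
                                image_size = image_size,
                                n_backgrounds = length(backgrounds))
  n_total <- length(plan)
  if (is.null(val_n)) {
    # canonical 10,000 / 800 proportions, rounded to whole configurations
    val_configs <- max(1L, as.integer(round(preset$n_configs * 800 / 10800)))
    val_n <- min(val_configs * preset$renders_per_config, n_total)
  }
  if (is.null(train_n)) train_n <- n_total - val_n
  images <- data.frame(id = integer(n_total), width = integer(n_total),
                       height = integer(n_total),
                       file_name = character(n_total),
                       config_id = character(n_total),
                       render_index = integer(n_total),
                       stringsAsFactors = FALSE)
  annotations <- vector("list", n_total)
  last_cfg <- NULL
  mesh <- NULL
  blanket <- NULL
  for (k in seq_len(n_total)) {
    sc <- plan[[k]]
    if (!identical(sc$config_id, last_cfg)) {
      joints <- forward_kinematics(sc$pose, sc$shape, tree)
      mesh <- build_surface_mesh(joints, sc$shape, tree)
      blanket <- if (!is.null(sc$blanket)) {
        with_seed(derive_seed(seed, paste0("blanket:", sc$config_id)),
                  generate_blanket(mesh, sc$blanket))
      }
      last_cfg <- sc$config_id
    }
    layer <- renderer(sc, mesh, blanket, tree = tree)
    if (is.null(layer$bbox)) {
      stop("rendered layer is empty for ", sc$config_id,
           " render ", sc$render_index,
           " (camera outside the scene?)")
    }
    bg <- backgrounds[[sc$background_ref]]
    comp <- with_seed(
      derive_seed(seed, paste0("place:", sc$config_id, ":", sc$render_index)),
      place_and_composite(layer, bg))
    fname <- sprintf("%s_r%d.png", sc$config_id, sc$render_index)
    if (write_images) {
      write_image_png(comp$image, file.path(out_dir, "images", fname))
    }
    images$id[k] <- k
    images$width[k] <- dim(comp$image)[2]
    images$height[k] <- dim(comp$image)[1]
    images$file_name[k] <- fname
    images$config_id[k] <- sc$config_id
    images$render_index[k] <- sc$render_index
    annotations[[k]] <- coco_annotation(
      id = k, image_id = k, bbox = comp$bbox,
      keypoints = cbind(comp$keypoints2d[, 1:2], comp$keypoints2d[, 3]),
      joints3d = comp$joints3d)
  }
  ds <- coco_dataset(images, annotations)
  sp <- split_dataset(ds, train_n = train_n, val_n = val_n,
                      seed = derive_seed(seed, "split"))
  write_coco(ds, file.path(out_dir, "annotations_all.json"))
  write_coco(sp$train, file.path(out_dir, "annotations_train.json"))
  write_coco(sp$validation, file.path(out_dir, "annotations_val.json"))
  manifest <- list(
    command = "generate",
    package_version = pkg_version(),
    seed = seed,
    config_digest = config_digest(list(
      preset = unclass(preset), image_size = image_size,
      n_backgrounds = length(backgrounds), train_n = train_n, val_n = val_n)),
    preset = preset$name,
    counts = list(total = n_total, train = nrow(sp$train$images),
                  validation = nrow(sp$validation$images)),
    outputs = list(annotations_all = "annotations_all.json",
                   annotations_train = "annotations_train.json",
                   annotations_val = "annotations_val.json",
                   images = if (write_images) "images/" else NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Evaluate detection results against ground truth
#'
#' Applies the standard chain — confidence filtering, NMS, the AP/AR sweep
#' and per-person scoring — with the canonical thresholds, and writes a
#' summary JSON plus a per-person scores CSV.
#'
#' @param gt COCO annotation file path or `coco_dataset`.
#' @param results COCO results file path or list of `detection` records.
#' @param config an `eval_config`.
#' @param out_dir optional output directory for `eval_summary.json` and
#'   `person_scores.csv`.
#' @return list with `summary` (`eval_summary`), `scores` (data.frame) and
#'   `mean_score`.
#' @export
run_evaluate <- function(gt, results, config = eval_config(), out_dir = NULL) {
  ds <- if (is.character(gt)) read_coco(gt) else gt
  dets <- if (is.character(results)) read_coco_results(results) else results
  gt_imgs <- unique(as.character(ds$images$id))
  det_imgs <- unique(vapply(dets, function(d) as.character(d$image_id), ""))
  unknown <- setdiff(det_imgs, gt_imgs)
  if (length(unknown)) {
    stop("detection image ids not present in ground truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  dets <- filter_confidence(dets, config$conf_threshold_detect)
  dets <- nms(dets, config$nms_iou)
  summary <- ap_ar(ds$annotations, dets, config)
  scores <- score_persons(ds$annotations, dets, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(AP = summary$AP, AR = summary$AR,
           mean_person_score = mean(scores$score),
           config = unclass(config)),
      file.path(out_dir, "eval_summary.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(scores, file.path(out_dir, "person_scores.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, scores = scores, mean_score = mean(scores$score))
}

#' Run the full statistical comparison grid
#'
#' One improvement report per (architecture, dataset contrast) cell, with
#' Bonferroni control over the whole grid; emits a table mirroring the
#' improvement/CI/p-value layout used for reporting.
#'
#' @param scores long data.frame with columns `architecture`, `dataset`,
#'   `image_id`, `gt_id`, `score` covering every dataset named in the grid.
#' @param grid a `comparison_grid`.
#' @param familywise familywise error rate, default 0.05.
#' @param n_boot bootstrap replicates per cell.
#' @param seed integer seed.
#' @param out_dir optional directory for `stat_reports.json` / `.csv`.
#' @return data.frame with one row per grid cell: architecture, scenario,
#'   contrast, improvement, CI, p-values, significance at the corrected
#'   alpha.
#' @export
run_stats <- function(scores, grid = comparison_grid(), familywise = 0.05,
                      n_boot = 2000L, seed = 1L, out_dir = NULL) {
  need <- c("architecture", "dataset", "image_id", "gt_id", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores table lacks columns: ",
                         paste(miss, collapse = ", "))
  alpha <- bonferroni_alpha(familywise, grid)
  cells <- grid$contrasts
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    a <- scores[scores$architecture == cell$architecture &
                  scores$dataset == cell$dataset_a, ]
    b <- scores[scores$architecture == cell$architecture &
                  scores$dataset == cell$dataset_b, ]
    key_a <- paste(a$image_id, a$gt_id)
    key_b <- paste(b$image_id, b$gt_id)
    if (nrow(a) != nrow(b) || !all(sort(key_a) == sort(key_b))) {
      stop("misaligned score rows for ", cell$architecture, " ",
           cell$dataset_a, " vs ", cell$dataset_b)
    }
    a <- a[order(key_a), ]
    b <- b[order(key_b), ]
    rep <- improvement_report(a$score, b$score, alpha = alpha$rounded,
                              n_boot = n_boot,
                              seed = derive_seed(seed, paste0("cell:", i)))
    out[[i]] <- data.frame(
      architecture = cell$architecture, scenario = cell$scenario,
      dataset_a = cell$dataset_a, dataset_b = cell$dataset_b,
      improvement_pp = rep$mean_improvement,
      ci_low = rep$ci95[1], ci_high = rep$ci95[2],
      p_t = rep$p_t, p_w = rep$p_w,
      significant = rep$significant, zero_flag = rep$zero_flag,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  attr(tab, "alpha") <- alpha
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(alpha = alpha, reports = tab),
                         file.path(out_dir, "stat_reports.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(tab, file.path(out_dir, "stat_reports.csv"),
                     row.names = FALSE)
  }
  tab
}

#' Aspect-distribution diagnostic over two COCO files
#'
#' @param dataset_a,dataset_b COCO annotation paths or `coco_dataset`s.
#' @param out_dir optional directory for `aspect_comparison.json` and a
#'   density plot PNG.
#' @param bins shared histogram bins.
#' @return a `density_comparison`.
#' @export
run_diagnose <- function(dataset_a, dataset_b, out_dir = NULL, bins = 50L) {
  cmp <- compare_aspect_distributions(dataset_a, dataset_b, bins = bins)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(divergence_nats = cmp$divergence,
           mean_a = mean(cmp$values_a), mean_b = mean(cmp$values_b),
           n_a = length(cmp$values_a), n_b = length(cmp$values_b)),
      file.path(out_dir, "aspect_comparison.json"), auto_unbox = TRUE,
      digits = NA)
    plot_aspect_comparison(cmp, file.path(out_dir, "aspect_density.png"))
  }
  cmp
}
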