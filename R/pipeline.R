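#' Read an RGB image from PNG
#'
#' @param path PNG file path.
#' @return H x W x 3 array in `[0, 1]` (gray PNGs are replicated to 3
#'   channels; any alpha channel is dropped).
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image or binary mask to PNG
#'
#' @param x Numeric array in `[0, 1]` or logical mask (written as 0/255).
#' @param path Destination path.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- x * 1
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

.known_config_keys <- list(
  global = c("seed", "log_level", "out_dir"),
  preprocess = c("denoise", "n_partitions"),
  segment = c("combine", "se", "n_bins"),
  features = c("glcm_levels", "mode"),
  select = c("enabled", "iterations", "population", "hidden", "k"),
  elm = c("hidden", "as_value", "bs_bounds", "iterations", "population"),
  evaluate = c("repeats", "train_frac"),
  synth = c("n", "image_size", "noise_sigma", "hair_count")
)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with per-stage blocks
#' (`global`, `preprocess`, `segment`, `features`, `select`, `elm`,
#' `evaluate`, `synth`); unknown blocks or keys are rejected.
#'
#' @param path File path, or `NULL` for an all-defaults configuration.
#' @return Named list of stage blocks.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (block in names(cfg)) {
    if (!block %in% names(.known_config_keys))
      stop("unknown config block: ", block, call. = FALSE)
    bad <- setdiff(names(cfg[[block]]), .known_config_keys[[block]])
    if (length(bad))
      stop("unknown key(s) in block '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

.cfg_get <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

#' Run the full detection pipeline on an image directory
#'
#' Chains preprocessing (median denoise + contrast stretch), lesion
#' segmentation, feature extraction, and - when a `labels.csv` file is
#' present - the repeated split / feature selection / optimized-ELM
#' evaluation protocol. Intermediate artifacts (masks, the feature table, a
#' manifest with the package version and a hash of the resolved
#' configuration) are written to `out_dir`.
#'
#' @param image_dir Directory containing `img_*.png` and optionally
#'   `labels.csv` (columns `image`, `label`).
#' @param out_dir Output directory (created if missing).
#' @param config A configuration list from [load_run_config()].
#' @param seed Overrides `config$global$seed`.
#' @return Invisibly, a list with `features` (data frame) and, when labels
#'   were available, `report` (an `"experiment_report"`).
#' @export
run_pipeline <- function(image_dir, out_dir = file.path(image_dir, "out"),
                         config = list(), seed = NULL) {
  paths <- sort(list.files(image_dir, pattern = "^img_.*\\.png$",
                           full.names = TRUE))
  if (!length(paths)) stop("no img_*.png files in ", image_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- .cfg_get(config, "global", "seed", 1L)
  set.seed(seed)

  feats <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- read_image(paths[i])
    pre <- preprocess_image(img)
    seg <- segment_lesion(pre,
                          combine = .cfg_get(config, "segment", "combine", "and"),
                          se = .cfg_get(config, "segment", "se", "identity5"),
                          n_bins = .cfg_get(config, "segment", "n_bins", 256L))
    write_image(seg$mask, file.path(out_dir, sub("^img_", "mask_",
                                                 basename(paths[i]))))
    feats[[i]] <- extract_features(
      pre, seg, glcm_levels = .cfg_get(config, "features", "glcm_levels", 32L),
      mode = .cfg_get(config, "features", "mode", "standard"))
  }
  ft <- as.data.frame(do.call(rbind, feats))
  ft <- cbind(image = basename(paths), ft)
  utils::write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE)

  report <- NULL
  labels_path <- file.path(image_dir, "labels.csv")
  if (file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    lab <- lab[match(basename(paths), lab$image), ]
    report <- run_experiment(
      as.matrix(ft[, -1]), lab$label,
      repeats = .cfg_get(config, "evaluate", "repeats", 15L),
      train_frac = .cfg_get(config, "evaluate", "train_frac", 0.8),
      select = .cfg_get(config, "select", "enabled", TRUE),
      select_iterations = .cfg_get(config, "select", "iterations", 50L),
      select_population = .cfg_get(config, "select", "population", 20L),
      hidden = .cfg_get(config, "elm", "hidden", 30L),
      slope_iterations = .cfg_get(config, "elm", "iterations", 100L),
      slope_population = .cfg_get(config, "elm", "population", 20L),
      seed = seed)
    jsonlite::write_json(
      list(metrics = report$metrics, counts = report$counts,
           per_repeat = report$per_repeat),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  } else {
    warning("no labels.csv: evaluation skipped; masks and features written",
            call. = FALSE)
  }

  manifest <- list(
    tool = "thermoderm",
    version = as.character(utils::packageVersion("thermoderm")),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    n_images = length(paths),
    evaluated = !is.null(report))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(features = ft, report = report))
}

#' Write a synthetic dataset to disk
#'
#' Materializes [generate_dataset()] output as `img_NNNN.png`,
#' `mask_NNNN.png`, `labels.csv` and `features.csv` in a directory, the
#' on-disk layout the pipeline consumes.
#'
#' @param n Number of images.
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param ... Passed to [generate_dataset()].
#' @return Invisibly, the dataset list.
#' @export
write_synthetic_dataset <- function(n, dir, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- generate_dataset(n, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- sprintf("img_%04d.png", seq_along(ds$images))
  for (i in seq_along(ds$images)) {
    write_image(ds$images[[i]], file.path(dir, names[i]))
    write_image(ds$masks[[i]], file.path(dir, sprintf("mask_%04d.png", i)))
  }
  utils::write.csv(data.frame(image = names, label = as.character(ds$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(ds$features))
    utils::write.csv(cbind(image = names, ds$features),
                     file.path(dir, "features.csv"), row.names = FALSE)
  invisible(ds)
}
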