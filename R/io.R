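# Dataset and result IO: PNG/TIFF image reading, manifest CSVs linking
# images to per-class mask files, result CSV/JSON export.

read_image_file <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (expected PNG or TIFF): %s",
          ext, path))
  if (length(dim(px)) == 3L) px <- px[, , 1]  # first channel of gray-as-RGB
  px <- as.matrix(px)
  if (max(px) > 1) px <- px / max(px)  # integer-coded images -> [0, 1]
  px
}

mask_channel_from_file <- function(path, channel_name) {
  px <- read_image_file(path)
  b <- round(px)
  if (any(abs(px - b) > 1e-6)) {
    stopf("mask channel '%s' is not binary: %s", channel_name, path)
  }
  b
}

manifest_columns <- c("id", "image_path", "mask_bg_path", "mask_femur_path",
                      "mask_acetabulum_path", "split")

#' Write a phantom corpus to disk
#'
#' Writes one grayscale PNG per sample plus three per-class binary mask PNGs
#' and a manifest CSV (columns `id`, `image_path`, `mask_bg_path`,
#' `mask_femur_path`, `mask_acetabulum_path`, `split`). Paths in the
#' manifest are relative to its directory.
#'
#' @param samples list of [image_sample] objects with masks.
#' @param dir output directory (created if missing).
#' @param split optional named character vector id -> split label.
#' @return the manifest path, invisibly.
#' @export
write_phantom_dataset <- function(samples, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    img_rel <- file.path("images", paste0(s$id, ".png"))
    png::writePNG(s$pixels, file.path(dir, img_rel))
    mask_rel <- vapply(1:3, function(c) {
      rel <- file.path("masks", sprintf("%s_%s.png", s$id,
                                        s$mask$class_names[c]))
      png::writePNG(s$mask$channels[, , c], file.path(dir, rel))
      rel
    }, character(1))
    data.frame(id = s$id, image_path = img_rel, mask_bg_path = mask_rel[1],
               mask_femur_path = mask_rel[2],
               mask_acetabulum_path = mask_rel[3],
               split = if (is.null(split)) "" else unname(split[s$id]))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a corpus from a manifest CSV
#'
#' Reads the manifest written by [write_phantom_dataset] (or an equivalent
#' hand-built one pointing at PNG/TIFF files). Images are rescaled to
#' `[0, 1]`; mask channels are validated strictly binary; ids must be
#' unique.
#'
#' @param path manifest CSV path.
#' @return list of [image_sample] objects; the `split` column, if non-empty,
#'   is attached as the `"split"` attribute (named by id).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_columns, names(man))
  if (length(missing_cols) > 0) {
    stopf("manifest lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(man$id[duplicated(man$id)])
  if (length(dup) > 0) {
    stopf("duplicate id(s) in manifest: %s", paste(dup, collapse = ", "))
  }
  base <- dirname(path)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    px <- tryCatch(read_image_file(resolve(row$image_path)),
                   error = function(e) {
                     stopf("manifest row %d (id '%s'): %s", i, row$id,
                           conditionMessage(e))
                   })
    fem <- mask_channel_from_file(resolve(row$mask_femur_path), "femur")
    ace <- mask_channel_from_file(resolve(row$mask_acetabulum_path),
                                  "acetabulum")
    image_sample(row$id, px, mask_stack(fem, ace))
  })
  if (any(nzchar(man$split))) {
    attr(samples, "split") <- stats::setNames(man$split, man$id)
  }
  samples
}

#' Write experiment results
#'
#' Writes `results.csv` with the deterministic per-iteration metrics
#' (columns `query`, `repeat`, `iteration`, `n_labeled`, `dice_test_macro`,
#' `dice_joint`, `dice_femur`, `dice_acetabulum`), `timings.csv` with the
#' measured per-iteration query wall times, and `run_manifest.json` echoing
#' the configuration, master seed and package version. Keeping wall times in
#' their own file makes `results.csv` byte-reproducible under a fixed master
#' seed.
#'
#' @param records an `al_run_record` data.frame or row-bound collection of
#'   them (e.g. `run_experiment(...)$records`).
#' @param dir output directory.
#' @param config optional [al_config] echoed into the run manifest.
#' @return the directory, invisibly.
#' @export
write_results <- function(records, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metric_cols <- c("query", "repeat", "iteration", "n_labeled",
                   "dice_test_macro", "dice_joint", "dice_femur",
                   "dice_acetabulum")
  utils::write.csv(as.data.frame(records)[metric_cols],
                   file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(records)[c("query", "repeat", "iteration",
                                            "query_seconds")],
                   file.path(dir, "timings.csv"), row.names = FALSE)
  manifest <- list(
    package = "alseg",
    version = as.character(utils::packageVersion("alseg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = if (is.null(config)) NULL else unclass_config(config))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$train <- unclass(out$train)
  out$fractions <- as.list(out$fractions)
  out
}

#' Read a results CSV written by [write_results]
#' @param path path to `results.csv`.
#' @return data.frame with the metric columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a run configuration from YAML or JSON
#'
#' Key-value file mirroring the [al_config] and [phantom_params] fields;
#' command-line flags override file values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    cfg <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare "n" key as boolean false; restore the batch-size key
    names(cfg)[names(cfg) == "FALSE"] <- "n"
    cfg
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("unsupported config format '%s' (expected YAML or JSON)", ext)
  }
}
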