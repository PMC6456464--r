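# End-to-end orchestration: train the three models from a corpus manifest,
# fuse scores, pick the sensitivity-targeted threshold, and filter an
# unlabeled file set. Files are scored in chunks read from disk so no full
# resolution tensor set is ever held in memory.

#' Pipeline run configuration
#'
#' @param manifest corpus manifest data frame or path to a manifest CSV
#'   (columns `image_id`, `file_path`, `view_class` or `binary_label`,
#'   `split`).
#' @param seed_header,seed_general,seed_wire per-stage RNG seeds.
#' @param width_multiplier image model filter scale.
#' @param epochs_general,epochs_wire training epochs per image model.
#' @param gbm_grid header model hyperparameter grid.
#' @param tta_general,tta_wire TTA combination rules (`"mean"` / `"max"`).
#' @param image_source which image score feeds the image+header mean
#'   (`"general"` or `"combined"`).
#' @param target_sensitivity sensitivity target for threshold selection;
#'   mutually exclusive with `fixed_threshold`.
#' @param fixed_threshold use this operating threshold instead of selecting
#'   one.
#' @param threshold_split split on which the threshold is selected
#'   (`"validation"` default, or `"holdout"`).
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, seed_header = 0L, seed_general = 0L,
                       seed_wire = 0L, width_multiplier = 0.25,
                       epochs_general = 10L, epochs_wire = 10L,
                       gbm_grid = default_gbm_grid(),
                       tta_general = "mean", tta_wire = "max",
                       image_source = "general",
                       target_sensitivity = 0.99, fixed_threshold = NULL,
                       threshold_split = "validation") {
  if (!is.null(fixed_threshold) && !is.null(target_sensitivity)) {
    stop("fixed_threshold and target_sensitivity are mutually exclusive; ",
         "set one of them to NULL")
  }
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("image_id", "file_path", "split") %in% names(manifest)))
  if (is.null(manifest$binary_label) && !is.null(manifest$view_class)) {
    manifest$binary_label <- as.integer(manifest$view_class != "full_field")
  }
  structure(list(
    manifest = manifest, seed_header = seed_header,
    seed_general = seed_general, seed_wire = seed_wire,
    width_multiplier = width_multiplier, epochs_general = epochs_general,
    epochs_wire = epochs_wire, gbm_grid = gbm_grid,
    tta_general = tta_general, tta_wire = tta_wire,
    image_source = image_source,
    target_sensitivity = target_sensitivity,
    fixed_threshold = fixed_threshold, threshold_split = threshold_split
  ), class = "run_config")
}

# read one DICOM into a record + preprocessed tensors; NULL on failure
.read_for_scoring <- function(path, image_id, sizes = c(99L, 299L)) {
  d <- tryCatch(dicom_read(path, read_pixels = TRUE), error = function(e) e)
  if (inherits(d, "error")) {
    return(list(error = conditionMessage(d)))
  }
  if (is.null(d$pixels)) return(list(error = "no pixel data"))
  tags <- .flatten_code_sequences(d$tags)
  tags$PixelData <- NULL
  out <- list(record = header_record(image_id, tags, path))
  for (s in sizes) {
    out[[paste0("px", s)]] <- preprocess(d$pixels, s, source_id = image_id)
  }
  out
}

# wire-localization TTA-max scores from a list of 299x299 tensors
.wire_tta_scores <- function(wire_model, imgs299) {
  f_id <- gap_features(wire_model, imgs299)
  f_fl <- gap_features(wire_model, lapply(imgs299, .hflip))
  pmax(.score_dense_features(wire_model, f_id),
       .score_dense_features(wire_model, f_fl))
}

#' Score files through all three models
#'
#' Reads each DICOM once, preprocesses to both model input sizes, and
#' computes the general-image TTA score, the wire-localization TTA score
#' and the header-model score. Unreadable files are quarantined, not fatal.
#'
#' @param bundle a `model_bundle` from [run_train()].
#' @param paths DICOM file paths.
#' @param ids image identifiers (default: file names).
#' @param chunk_size files read and scored per chunk.
#' @return list with `scores` (data frame `image_id`, `s_img`, `s_wire`,
#'   `s_hdr` plus fused columns) and `errors` (data frame `image_id`,
#'   `path`, `message`).
#' @export
score_files <- function(bundle, paths, ids = NULL, chunk_size = 64L) {
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  scores <- NULL
  errors <- data.frame(image_id = character(), path = character(),
                       message = character())
  for (start in seq(1L, length(paths), by = chunk_size)) {
    idx <- start:min(length(paths), start + chunk_size - 1L)
    loaded <- lapply(idx, function(i) .read_for_scoring(paths[i], ids[i]))
    failed <- vapply(loaded, function(x) !is.null(x$error), TRUE)
    for (w in which(failed)) {
      errors <- rbind(errors, data.frame(
        image_id = ids[idx[w]], path = paths[idx[w]],
        message = loaded[[w]]$error
      ))
    }
    loaded <- loaded[!failed]
    if (length(loaded) == 0L) next
    recs <- lapply(loaded, `[[`, "record")
    imgs99 <- lapply(loaded, `[[`, "px99")
    imgs299 <- lapply(loaded, `[[`, "px299")
    s_img <- score_images(bundle$general_model, imgs99,
                          tta = bundle$config$tta_general)$score_combined
    s_wire <- .wire_tta_scores(bundle$wire_model, imgs299)
    Xh <- transform_headers(recs, bundle$schema)
    s_hdr <- predict_header(bundle$header_model, Xh)
    scores <- rbind(scores, data.frame(
      image_id = vapply(recs, `[[`, "", "image_id"),
      s_img = s_img, s_wire = s_wire, s_hdr = s_hdr
    ))
  }
  if (is.null(scores)) stop("no files could be scored")
  list(scores = fuse_scores(scores, bundle$config$image_source),
       errors = errors)
}

.load_tensor_stack <- function(paths, size) {
  n <- length(paths)
  X <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    d <- dicom_read(paths[i], read_pixels = TRUE)
    X[, , i] <- preprocess(d$pixels, size)
  }
  X
}

#' Train the full view-triage model bundle
#'
#' Trains, on the manifest's train split: the gradient-boosting header
#' model (with cross-validated grid search), the abridged general image
#' model (all layers), and the wire-localization detector (dense head on
#' the frozen full-depth trunk, wire-vs-rest labels). Scores the
#' validation and holdout splits, fuses, selects the operating threshold on
#' the configured split, and reports per-model and ensemble metrics.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return a `model_bundle`: schema, the three models, fusion/threshold
#'   configuration, per-split score tables, metrics, and provenance.
#' @export
run_train <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  mf <- config$manifest
  for (s in c("train", "validation")) {
    if (!any(mf$split == s)) stop("manifest has no rows in split: ", s)
  }
  say <- function(...) if (verbose) message(...)
  tr <- mf[mf$split == "train", ]
  va <- mf[mf$split == "validation", ]

  say("extracting headers (", nrow(tr), " training files)")
  rec_tr <- read_headers(tr$file_path)
  schema <- fit_schema(rec_tr)
  X_tr <- transform_headers(rec_tr, schema)

  say("training header model")
  header_model <- train_header_model(X_tr, tr$binary_label, kind = "gbm",
                                     grid = config$gbm_grid,
                                     seed = config$seed_header)

  say("training general image model")
  imgs_tr <- .load_tensor_stack(tr$file_path, 99L)
  imgs_va <- .load_tensor_stack(va$file_path, 99L)
  general <- build_model("general", width_multiplier = config$width_multiplier,
                         seed = config$seed_general)
  general <- train_image_model(
    general, imgs_tr, tr$binary_label, epochs = config$epochs_general,
    seed = config$seed_general,
    validation = list(images = imgs_va, y = va$binary_label)
  )
  rm(imgs_tr, imgs_va)

  say("training wire-localization detector")
  wire <- build_model("wire", width_multiplier = config$width_multiplier,
                      seed = config$seed_wire)
  y_wire <- as.integer(tr$view_class == "wire_localization")
  if (sum(y_wire) == 0L) {
    stop("no wire_localization cases in the train split")
  }
  feats <- .streamed_wire_features(wire, tr$file_path)
  old_seed <- .save_rng()
  set.seed(config$seed_wire)
  wire <- .fit_dense_on_features(wire, feats, y_wire,
                                 epochs = config$epochs_wire)
  .restore_rng(old_seed)

  bundle <- structure(list(
    schema = schema, header_model = header_model,
    general_model = general, wire_model = wire,
    config = config[c("tta_general", "tta_wire", "image_source")],
    created = as.character(Sys.time()), package_version = "0.1.0"
  ), class = "model_bundle")

  say("scoring validation/holdout splits")
  split_scores <- list()
  for (s in intersect(c("validation", "holdout"), unique(mf$split))) {
    rows <- mf[mf$split == s, ]
    sc <- score_files(bundle, rows$file_path, rows$image_id)$scores
    sc$binary_label <- rows$binary_label[match(sc$image_id, rows$image_id)]
    sc$view_class <- rows$view_class[match(sc$image_id, rows$image_id)]
    split_scores[[s]] <- sc
  }

  thr_scores <- split_scores[[config$threshold_split]]
  if (is.null(thr_scores)) {
    stop("threshold split not present in manifest: ", config$threshold_split)
  }
  threshold <- if (!is.null(config$fixed_threshold)) {
    structure(list(threshold = config$fixed_threshold,
                   target_sensitivity = NA_real_,
                   achieved_sensitivity = mean(
                     thr_scores$s_final[thr_scores$binary_label == 1L] >=
                       config$fixed_threshold),
                   n_removed = sum(thr_scores$s_final >= config$fixed_threshold),
                   n_kept = sum(thr_scores$s_final < config$fixed_threshold)),
              class = "threshold_decision")
  } else {
    select_threshold(thr_scores$s_final, thr_scores$binary_label,
                     config$target_sensitivity)
  }
  bundle$threshold <- threshold
  bundle$split_scores <- split_scores
  bundle$metrics <- lapply(split_scores, function(sc) {
    list(
      header = evaluate_scores(sc$s_hdr, sc$binary_label),
      image = evaluate_scores(sc$s_img, sc$binary_label),
      image_combined = evaluate_scores(sc$s_img_combined, sc$binary_label),
      ensemble = evaluate_scores(sc$s_final, sc$binary_label)
    )
  })
  bundle$provenance_hash <- .bundle_hash(config)
  bundle
}

.streamed_wire_features <- function(wire_model, paths, chunk_size = 64L) {
  out <- NULL
  for (start in seq(1L, length(paths), by = chunk_size)) {
    idx <- start:min(length(paths), start + chunk_size - 1L)
    imgs <- lapply(paths[idx], function(p) {
      preprocess(dicom_read(p, read_pixels = TRUE)$pixels, 299L)
    })
    out <- rbind(out, gap_features(wire_model, imgs))
  }
  out
}

.bundle_hash <- function(config) {
  cfg <- config[setdiff(names(config), "manifest")]
  cfg$manifest_ids <- config$manifest$image_id
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(cfg, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>\n  schema:", length(x$schema), "fields\n")
  cat("  threshold:", signif(x$threshold$threshold, 4), "\n")
  for (s in names(x$metrics)) {
    cat(sprintf("  %s ensemble auROC: %.4f\n", s, x$metrics[[s]]$ensemble$auroc))
  }
  invisible(x)
}

#' Save / load a model bundle
#'
#' @param bundle a `model_bundle`.
#' @param path file path.
#' @return `path` (save) or the bundle (load).
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)

#' Apply a trained bundle to an unlabeled corpus
#'
#' Scores every file through the three models, fuses, applies the bundle's
#' operating threshold, and writes `keep.txt`, `remove.txt`, `scores.csv`
#' and (if any file failed) `errors.txt` to `out_dir`. Per-file failures
#' are quarantined without aborting the run.
#'
#' @param bundle a `model_bundle` with a threshold decision.
#' @param paths unlabeled DICOM file paths.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param ids image identifiers (default: file names).
#' @return list with `kept`, `removed` (image id vectors), `scores`
#'   (data frame) and `errors` (data frame).
#' @export
run_filter <- function(bundle, paths, out_dir = NULL, ids = NULL) {
  stopifnot(inherits(bundle, "model_bundle"), !is.null(bundle$threshold))
  res <- score_files(bundle, paths, ids)
  parts <- filter_corpus(res$scores, bundle$threshold$threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(parts$kept, file.path(out_dir, "keep.txt"))
    writeLines(parts$removed, file.path(out_dir, "remove.txt"))
    utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    if (nrow(res$errors) > 0) {
      utils::write.csv(res$errors, file.path(out_dir, "errors.txt"),
                       row.names = FALSE)
    }
  }
  list(kept = parts$kept, removed = parts$removed,
       scores = res$scores, errors = res$errors)
}
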