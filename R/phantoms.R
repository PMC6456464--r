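# Synthetic mammography phantom generator: schematic pixel phantoms with
# class-discriminating artifacts (collimation circle, guide wire, fiducial
# grid, specimen container) plus class-correlated DICOM headers with
# configurable missingness. Phantoms are schematic stand-ins, not
# anatomically realistic renders: their job is to carry a reliable visual
# and metadata signal for pipeline testing.

#' Supported phantom view classes
#'
#' Full-field plus the four special diagnostic view classes.
#' @export
VIEW_CLASSES <- c("full_field", "spot_mag", "stereotactic", "specimen",
                  "wire_localization")

#' Phantom rendering specification
#'
#' @param view_class one of `"full_field"`, `"spot_mag"`, `"stereotactic"`,
#'   `"specimen"`, `"wire_localization"`.
#' @param image_size side of the square phantom in pixels (pre-downscale).
#' @param seed integer; identical spec + seed renders byte-identical pixels.
#' @param noise_sd per-pixel Gaussian intensity noise, on the \[0,1\] scale.
#' @param artifacts if `FALSE`, the class-specific artifact is suppressed and
#'   every class renders as a plain full-field breast — the dial that makes
#'   classes visually indistinguishable for negative-control experiments.
#' @param wire_brightness,wire_width,wire_length wire-localization artifact
#'   parameters (intensity on \[0,1\], width in px, length as a fraction of
#'   the image side).
#' @param collimation_radius spot/magnification collimation circle radius as
#'   a fraction of the image side.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(view_class, image_size = 128L, seed = 0L,
                         noise_sd = 0.02, artifacts = TRUE,
                         wire_brightness = 0.98, wire_width = 1.6,
                         wire_length = 0.5, collimation_radius = 0.34) {
  view_class <- match.arg(view_class, VIEW_CLASSES)
  stopifnot(image_size >= 32L, noise_sd >= 0)
  structure(list(
    view_class = view_class, image_size = as.integer(image_size),
    seed = as.integer(seed), noise_sd = noise_sd, artifacts = artifacts,
    wire_brightness = wire_brightness, wire_width = wire_width,
    wire_length = wire_length, collimation_radius = collimation_radius
  ), class = "phantom_spec")
}

# smooth texture field in [0,1]: low-resolution noise upsampled bilinearly
.texture_field <- function(S, cells = 9L) {
  low <- matrix(stats::runif(cells * cells), cells, cells)
  m <- EBImage::resize(EBImage::Image(low), w = S, h = S, filter = "bilinear")
  EBImage::imageData(m)
}

.breast_mask <- function(S, a, b, cy) {
  x <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  y <- matrix(rep(seq_len(S), times = S), S, S)  # row index
  (x / a)^2 + ((y - cy) / b)^2 <= 1
}

.tissue <- function(S, mask, noise_sd, base = 0.45, amp = 0.16) {
  tex <- .texture_field(S)
  img <- matrix(0.01, S, S)
  img[mask] <- base + amp * (tex[mask] - 0.5) * 2
  img <- img + matrix(stats::rnorm(S * S, sd = noise_sd), S, S)
  img
}

.draw_segment <- function(img, x0, y0, x1, y1, half_width, value) {
  S <- nrow(img)
  x <- matrix(rep(seq_len(S), each = S), S, S)
  y <- matrix(rep(seq_len(S), times = S), S, S)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((x - x0) * dx + (y - y0) * dy) / len2))
  d2 <- (x - x0 - t * dx)^2 + (y - y0 - t * dy)^2
  img[d2 <= half_width^2] <- value
  img
}

#' Render a phantom pixel array
#'
#' Produces a 16-bit grayscale image (values in \[0, 4095\]): dark
#' background, a bright half-elliptical "breast" with smooth texture noise,
#' plus the class-specific artifact — full collimation circle for
#' spot/magnification views, a bright straight guide wire for
#' wire-localization views, paired narrow-field panels with a fiducial dot
#' grid for stereotactic views, and a small tissue blob inside a rectangular
#' container frame for specimen radiographs. Deterministic per spec + seed.
#'
#' @param spec a [phantom_spec()].
#' @return integer matrix `image_size` x `image_size`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(spec$seed)
  cls <- if (spec$artifacts) spec$view_class else "full_field"
  img <- switch(cls,
    full_field = .render_full_field(S, spec),
    spot_mag = .render_spot_mag(S, spec),
    stereotactic = .render_stereotactic(S, spec),
    specimen = .render_specimen(S, spec),
    wire_localization = .render_wire(S, spec)
  )
  img <- pmin(pmax(img, 0), 1)
  matrix(as.integer(round(img * 4095)), S, S)
}

.render_full_field <- function(S, spec) {
  a <- stats::runif(1, 1.5, 1.7) * S
  b <- stats::runif(1, 0.85, 0.95) * S
  cy <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  mask <- .breast_mask(S, a, b, cy)
  .tissue(S, mask, spec$noise_sd)
}

.render_spot_mag <- function(S, spec) {
  r <- spec$collimation_radius * S * stats::runif(1, 0.9, 1.1)
  cx <- S / 2 + stats::runif(1, -0.04, 0.04) * S
  cy <- S / 2 + stats::runif(1, -0.04, 0.04) * S
  x <- matrix(rep(seq_len(S), each = S), S, S)
  y <- matrix(rep(seq_len(S), times = S), S, S)
  circle <- (x - cx)^2 + (y - cy)^2 <= r^2
  img <- .tissue(S, circle, spec$noise_sd, base = 0.52, amp = 0.18)
  # small dense focus, the reason the spot view was taken
  fx <- cx + stats::runif(1, -0.3, 0.3) * r
  fy <- cy + stats::runif(1, -0.3, 0.3) * r
  focus <- (x - fx)^2 + (y - fy)^2 <= (0.12 * r)^2
  img[focus & circle] <- img[focus & circle] + 0.2
  img
}

.render_stereotactic <- function(S, spec) {
  img <- matrix(0.01, S, S) + matrix(stats::rnorm(S * S, sd = spec$noise_sd), S, S)
  offset <- round(stats::runif(1, 0.04, 0.10) * S) # paired-crop vertical offset
  band <- round(0.30 * S)
  tex <- .texture_field(S)
  mid <- round(S / 2)
  for (panel in 1:2) {
    cols <- if (panel == 1) seq_len(mid - 2) else (mid + 2):S
    r0 <- round(S / 2 - band / 2) + (panel - 1) * offset
    rows <- max(1, r0):min(S, r0 + band)
    img[rows, cols] <- 0.45 + 0.25 * (tex[rows, cols] - 0.5) * 2
    # fiducial dot grid
    dr <- rows[seq(3, length(rows) - 2, by = max(4, round(S / 16)))]
    dc <- cols[seq(3, length(cols) - 2, by = max(4, round(S / 16)))]
    img[dr, dc] <- 0.95
  }
  img
}

.render_specimen <- function(S, spec) {
  img <- matrix(0.01, S, S) + matrix(stats::rnorm(S * S, sd = spec$noise_sd), S, S)
  m <- round(0.18 * S) # container frame margin
  fr <- m:(S - m)
  img[c(fr[1:2], fr[(length(fr) - 1):length(fr)]), fr] <- 0.85
  img[fr, c(fr[1:2], fr[(length(fr) - 1):length(fr)])] <- 0.85
  x <- matrix(rep(seq_len(S), each = S), S, S)
  y <- matrix(rep(seq_len(S), times = S), S, S)
  cx <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  cy <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  blob <- ((x - cx) / (0.16 * S))^2 + ((y - cy) / (0.13 * S))^2 <= 1
  tex <- .texture_field(S)
  img[blob] <- 0.5 + 0.2 * (tex[blob] - 0.5) * 2
  img
}

.render_wire <- function(S, spec) {
  img <- .render_full_field(S, spec)
  theta <- stats::runif(1, 0, pi)
  cx <- stats::runif(1, 0.3, 0.6) * S
  cy <- stats::runif(1, 0.3, 0.7) * S
  half_len <- spec$wire_length * S / 2
  x0 <- cx - cos(theta) * half_len; y0 <- cy - sin(theta) * half_len
  x1 <- cx + cos(theta) * half_len; y1 <- cy + sin(theta) * half_len
  .draw_segment(img, x0, y0, x1, y1, spec$wire_width / 2, spec$wire_brightness)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default header-synthesis profile
#'
#' Per-class tag value distributions and per-tag missingness probabilities.
#' `ViewModifierCode` carries a spot/magnification code for 90% of spot_mag
#' views with a 5% leakage rate onto full-field views, making the header
#' model good but imperfect. Wire-localization views never carry a modifier
#' code: technically they are full-field acquisitions, which is exactly why
#' a dedicated image detector is needed. Decoy date/device/demographic tags
#' are always emitted so schema fitting has something to exclude.
#'
#' @param confound_manufacturer if `TRUE`, special views are
#'   disproportionately assigned outside-institution manufacturers,
#'   emulating referral bias.
#' @return a nested list consumed by [synthesize_headers()].
#' @export
default_header_profile <- function(confound_manufacturer = FALSE) {
  list(
    p_modifier = c(full_field = 0.05, spot_mag = 0.90, stereotactic = 0.10,
                   specimen = 0.10, wire_localization = 0.00),
    spot_codes = c("R-102D6", "R-102D7"), # spot compression / magnification
    p_ermf_present = c(full_field = 0.97, spot_mag = 0.97, stereotactic = 0.97,
                       specimen = 0.95, wire_localization = 0.97),
    ermf_range = list(default = c(0.98, 1.08), spot_compression = c(1.0, 1.15),
                      magnification = c(1.3, 1.8)),
    kvp = list(full_field = c(28, 2), spot_mag = c(26, 2),
               stereotactic = c(30, 2), specimen = c(24, 2),
               wire_localization = c(28, 2)),
    thickness = list(full_field = c(55, 10), spot_mag = c(35, 8),
                     stereotactic = c(45, 8), specimen = c(18, 4),
                     wire_localization = c(55, 10)),
    exposure_time = list(full_field = c(600, 150), spot_mag = c(900, 200),
                         stereotactic = c(400, 100), specimen = c(300, 80),
                         wire_localization = c(650, 150)),
    p_grid_in = c(full_field = 0.95, spot_mag = 0.30, stereotactic = 0.90,
                  specimen = 0.05, wire_localization = 0.95),
    manufacturers = c(HOLOGIC = 0.5, GE = 0.3, SIEMENS = 0.2),
    outside_manufacturers = c(`OUTSIDE-A` = 0.5, `OUTSIDE-B` = 0.5),
    p_outside_if_special = if (confound_manufacturer) 0.4 else 0,
    detector_dims = list(HOLOGIC = c(239, 287), GE = c(230, 286),
                         SIEMENS = c(240, 300), `OUTSIDE-A` = c(250, 300),
                         `OUTSIDE-B` = c(225, 280)),
    missing = c(KVP = 0.02, BodyPartThickness = 0.08, Grid = 0.05,
                ExposureTime = 0.06, DetectorActiveDimensions = 0.04,
                PatientOrientation = 0.05, CompressionForce = 0.25,
                RelativeXRayExposure = 0.02)
  )
}

.maybe_missing <- function(profile, tag) {
  p <- profile$missing[[tag]]
  !is.null(p) && stats::runif(1) < p
}

#' Synthesize class-correlated DICOM header tags
#'
#' Draws one header tag set for a phantom of the given view class. Returns a
#' named list suitable for [dicom_write()]: informative physics fields (KVP,
#' BodyPartThickness, Grid, ExposureTime, magnification factor, detector
#' dimensions), the view code sequences, manufacturer, plus decoy
#' date/time, device-identifier and demographic fields that downstream
#' schema fitting must exclude. Per-tag missingness follows the profile.
#'
#' @param view_class phantom view class.
#' @param profile see [default_header_profile()].
#' @param seed integer RNG seed.
#' @return named list of tags (sequences as item lists).
#' @export
synthesize_headers <- function(view_class, profile = default_header_profile(),
                               seed = 0L) {
  view_class <- match.arg(view_class, VIEW_CLASSES)
  stopifnot(all(unlist(profile[c("p_modifier", "p_ermf_present", "p_grid_in")]) >= 0),
            all(unlist(profile[c("p_modifier", "p_ermf_present", "p_grid_in")]) <= 1))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  special <- view_class != "full_field"
  tags <- list()

  tags$ViewModifierCodeSequence <- if (stats::runif(1) < profile$p_modifier[[view_class]]) {
    code <- sample(profile$spot_codes, 1)
    list(list(
      CodeValue = code, CodingSchemeDesignator = "SRT",
      CodeMeaning = if (code == "R-102D6") "Spot compression" else "Magnification"
    ))
  } else {
    list() # present but empty, as written for unmodified views
  }
  tags$ViewCodeSequence <- list(list(
    CodeValue = sample(c("R-10242", "R-10226"), 1), # CC / MLO
    CodingSchemeDesignator = "SRT"
  ))

  if (stats::runif(1) < profile$p_ermf_present[[view_class]]) {
    # geometric magnification factor: ~1 for contact views and plain spot
    # compression, raised only for true magnification acquisitions
    rng <- if (view_class == "spot_mag") {
      if (stats::runif(1) < 0.5) profile$ermf_range$magnification else
        profile$ermf_range$spot_compression
    } else {
      profile$ermf_range$default
    }
    tags$EstimatedRadiographicMagnificationFactor <-
      round(stats::runif(1, rng[1], rng[2]), 3)
  }
  if (!.maybe_missing(profile, "KVP")) {
    p <- profile$kvp[[view_class]]
    tags$KVP <- round(max(20, stats::rnorm(1, p[1], p[2])), 1)
  }
  if (!.maybe_missing(profile, "BodyPartThickness")) {
    p <- profile$thickness[[view_class]]
    tags$BodyPartThickness <- round(max(5, stats::rnorm(1, p[1], p[2])), 1)
  }
  if (!.maybe_missing(profile, "Grid")) {
    tags$Grid <- if (stats::runif(1) < profile$p_grid_in[[view_class]])
      "IN" else "NONE"
  }
  if (!.maybe_missing(profile, "ExposureTime")) {
    p <- profile$exposure_time[[view_class]]
    tags$ExposureTime <- as.integer(max(50, round(stats::rnorm(1, p[1], p[2]))))
  }
  if (!.maybe_missing(profile, "CompressionForce")) {
    tags$CompressionForce <- round(max(20, stats::rnorm(1, 120, 30)), 1)
  }
  if (!.maybe_missing(profile, "RelativeXRayExposure")) {
    # weakly class-dependent: informative but subordinate to the view
    # modifier code, as in the source system
    tags$RelativeXRayExposure <- as.integer(max(
      10, round(stats::rnorm(1, if (special) 330 else 300, 80))))
  }

  mfr_pool <- if (special && stats::runif(1) < profile$p_outside_if_special) {
    profile$outside_manufacturers
  } else {
    profile$manufacturers
  }
  mfr <- sample(names(mfr_pool), 1, prob = mfr_pool)
  tags$Manufacturer <- mfr
  if (!.maybe_missing(profile, "DetectorActiveDimensions")) {
    tags$DetectorActiveDimensions <- profile$detector_dims[[mfr]]
  }
  if (!.maybe_missing(profile, "PatientOrientation")) {
    tags$PatientOrientation <- if (stats::runif(1) < 0.5) c("A", "FR") else c("P", "FL")
  }

  # decoy fields: must be rejected by schema fitting
  tags$Modality <- "MG"
  tags$StudyDate <- format(as.Date("2000-01-01") + sample.int(6000, 1), "%Y%m%d")
  tags$StudyTime <- sprintf("%02d%02d%02d", sample.int(24, 1) - 1,
                            sample.int(60, 1) - 1, sample.int(60, 1) - 1)
  tags$SOPClassUID <- "1.2.840.10008.5.1.4.1.1.1.2"
  tags$SOPInstanceUID <- paste0("1.2.826.0.1.3680043.9999.2.", seed + 1)
  tags$DeviceSerialNumber <- sprintf("%s-%05d", substr(mfr, 1, 2), sample.int(99999, 1))
  tags$StationName <- sprintf("MAMMO%02d", sample.int(8, 1))
  tags$InstitutionAddress <- "550 Example St"
  tags$PatientID <- sprintf("P%06d", sample.int(999999, 1))
  tags$PatientAge <- sprintf("%03dY", sample(35:85, 1))
  tags
}

#' Default labeled-corpus composition
#'
#' 4000 images: 3406 full-field and 594 special views (555 spot or
#' magnification, 24 stereotactic, 6 wire localization, 9 specimen).
#'
#' @return named integer vector over view classes.
#' @export
default_composition <- function() {
  c(full_field = 3406L, spot_mag = 555L, stereotactic = 24L,
    wire_localization = 6L, specimen = 9L)
}

#' Desk-scale benchmark composition
#'
#' A 1200-image corpus with the same class proportions as the default
#' labeled corpus (14.8% special views), sized so the full pipeline trains
#' in minutes on one CPU.
#'
#' @return named integer vector over view classes.
#' @export
benchmark_composition <- function() {
  c(full_field = 1022L, spot_mag = 166L, stereotactic = 7L,
    wire_localization = 2L, specimen = 3L)
}

# largest-remainder allocation of n into parts proportional to ratio
.allocate <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# per-class split counts that are simultaneously stratified (largest
# remainder within each class) and exact on the global split totals: each
# class's remainder units go to the split with the largest fractional part
# among splits with remaining global capacity
.stratified_split_counts <- function(class_counts, ratio) {
  targets <- .allocate(sum(class_counts), ratio)
  q <- outer(class_counts, ratio / sum(ratio))
  base <- floor(q)
  cap <- targets - colSums(base)
  counts <- base
  for (ci in seq_along(class_counts)) {
    rem <- class_counts[ci] - sum(base[ci, ])
    frac <- q[ci, ] - base[ci, ]
    while (rem > 0) {
      elig <- which(cap > 0)
      s <- elig[which.max(frac[elig])]
      counts[ci, s] <- counts[ci, s] + 1
      cap[s] <- cap[s] - 1
      frac[s] <- frac[s] - 1
      rem <- rem - 1
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a labeled synthetic DICOM corpus
#'
#' Renders one phantom per manifest row, synthesizes its class-correlated
#' header, writes a DICOM Part 10 file, and assigns train/validation/holdout
#' splits stratified by view class with largest-remainder rounding. The
#' split RNG and the per-image content seeds are derived from `seed` via
#' fixed offsets, so regenerating pixels never perturbs split assignment.
#'
#' @param out_dir directory for the DICOM files (created if needed).
#' @param composition named integer vector of per-class counts.
#' @param ratio train/validation/holdout ratio (default `c(4, 1, 1)`).
#' @param seed corpus seed.
#' @param image_size phantom side in pixels.
#' @param n_unlabeled additional rows written with `split = "unlabeled"`,
#'   classes drawn from the composition proportions.
#' @param profile header profile, see [default_header_profile()].
#' @param phantom_args extra arguments passed to [phantom_spec()]
#'   (e.g. `artifacts = FALSE`).
#' @return the manifest `data.frame` (`image_id`, `file_path`, `view_class`,
#'   `binary_label`, `split`), invisibly written to
#'   `file.path(out_dir, "manifest.csv")` as well.
#' @export
generate_corpus <- function(out_dir, composition = default_composition(),
                            ratio = c(4, 1, 1), seed = 0L, image_size = 128L,
                            n_unlabeled = 0L,
                            profile = default_header_profile(),
                            phantom_args = list()) {
  stopifnot(all(composition >= 0), all(ratio > 0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  classes <- rep(names(composition), times = composition)
  n_lab <- length(classes)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed + 101L) # split RNG
  split_names <- c("train", "validation", "holdout")
  split <- character(n_lab)
  counts <- .stratified_split_counts(composition, ratio)
  for (ci in seq_along(composition)) {
    idx <- which(classes == names(composition)[ci])
    split[sample(idx)] <- rep(split_names, times = counts[ci, ])
  }
  if (n_unlabeled > 0) {
    extra <- sample(names(composition), n_unlabeled, replace = TRUE,
                    prob = composition / sum(composition))
    classes <- c(classes, extra)
    split <- c(split, rep("unlabeled", n_unlabeled))
  }

  n <- length(classes)
  image_id <- sprintf("img%05d", seq_len(n))
  file_path <- file.path(out_dir, paste0(image_id, ".dcm"))
  manifest <- data.frame(
    image_id = image_id, file_path = file_path, view_class = classes,
    binary_label = as.integer(classes != "full_field"), split = split,
    stringsAsFactors = FALSE
  )
  .write_corpus_files(manifest, seed, image_size, profile, phantom_args)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

.write_corpus_files <- function(manifest, seed, image_size, profile,
                                phantom_args = list(), seed_offset = 1000L) {
  for (i in seq_len(nrow(manifest))) {
    content_seed <- seed + seed_offset + i
    spec <- do.call(phantom_spec, c(list(
      view_class = manifest$view_class[i], image_size = image_size,
      seed = content_seed
    ), phantom_args))
    px <- render_phantom(spec)
    tags <- synthesize_headers(manifest$view_class[i], profile,
                               seed = content_seed + 1L)
    dicom_write(manifest$file_path[i], tags, px,
                sop_instance_uid = tags$SOPInstanceUID)
  }
  invisible(manifest)
}

#' Augment a corpus with additional wire-localization cases
#'
#' Emulates report-keyword mining of extra wire-localization images: adds
#' synthetic WL cases until the corpus contains `total` of them, splitting
#' the additions so the WL total is distributed proportionally across
#' train/validation/holdout.
#'
#' @param manifest corpus manifest from [generate_corpus()].
#' @param out_dir directory for the new DICOM files.
#' @param total target total number of wire-localization rows (default 57).
#' @param ratio split ratio for the WL total.
#' @param seed RNG seed for the new cases.
#' @param image_size phantom side in pixels.
#' @param profile header profile.
#' @return the augmented manifest.
#' @export
augment_wire_cases <- function(manifest, out_dir, total = 57L,
                               ratio = c(4, 1, 1), seed = 0L,
                               image_size = 128L,
                               profile = default_header_profile()) {
  existing <- manifest[manifest$view_class == "wire_localization" &
                         manifest$split != "unlabeled", ]
  n_add <- total - nrow(existing)
  if (n_add <= 0) return(manifest)
  split_names <- c("train", "validation", "holdout")
  target <- .allocate(total, ratio)
  have <- vapply(split_names, function(s) sum(existing$split == s), 0L)
  add_per_split <- pmax(0L, target - have)
  # rounding slack: trim or pad on the train split
  delta <- n_add - sum(add_per_split)
  add_per_split[1] <- add_per_split[1] + delta
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  image_id <- sprintf("wlaug%04d", seq_len(n_add))
  addition <- data.frame(
    image_id = image_id,
    file_path = file.path(out_dir, paste0(image_id, ".dcm")),
    view_class = "wire_localization", binary_label = 1L,
    split = rep(split_names, times = add_per_split),
    stringsAsFactors = FALSE
  )
  .write_corpus_files(addition, seed, image_size, profile,
                      seed_offset = 700000L)
  rbind(manifest, addition)
}
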