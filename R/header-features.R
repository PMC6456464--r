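# DICOM header feature engineering: tag extraction, field filtering
# (missingness + keyword classes), median imputation with missing flags,
# and one-hot encoding into a dense numeric feature matrix.

#' Extract header records from DICOM files
#'
#' Reads the header of each file (pixel data is never decoded), flattening
#' the view code sequences to scalar fields: the `CodeValue` of the first
#' item of `ViewModifierCodeSequence` becomes `ViewModifierCode`, and of
#' `ViewCodeSequence` becomes `ViewCodeValue`. A present-but-empty sequence
#' yields an observed empty-string value (as written for unmodified views);
#' only an absent sequence yields an absent scalar.
#'
#' Unreadable files do not abort the run: their errors are collected in the
#' `"errors"` attribute of the result (a data frame with `path` and
#' `message`) and reported as a warning.
#'
#' @param paths character vector of DICOM file paths.
#' @param tag_allowlist optional character vector of DICOM keywords to keep;
#'   `NULL` keeps every header tag.
#' @return list of `header_record` objects (fields `image_id`, `tags`,
#'   `source_path`), one per readable file, in input order.
#' @export
read_headers <- function(paths, tag_allowlist = NULL) {
  records <- list()
  errors <- list()
  for (p in paths) {
    d <- tryCatch(dicom_read(p, read_pixels = FALSE), error = function(e) e)
    if (inherits(d, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        path = p, message = conditionMessage(d), stringsAsFactors = FALSE
      )
      next
    }
    tags <- .flatten_code_sequences(d$tags)
    tags$PixelData <- NULL
    if (!is.null(tag_allowlist)) tags <- tags[names(tags) %in% tag_allowlist]
    records[[length(records) + 1L]] <- header_record(
      image_id = sub("\\.[^.]*$", "", basename(p)),
      tags = tags, source_path = p
    )
  }
  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(path = character(), message = character())
  if (nrow(err_df) > 0) {
    warning(nrow(err_df), " file(s) could not be read as DICOM")
  }
  structure(records, errors = err_df)
}

#' Construct a header record
#'
#' @param image_id unique identifier within a manifest.
#' @param tags named list of raw tag values; absent tags are simply not
#'   present in the list (distinct from empty strings).
#' @param source_path originating file path.
#' @return a `header_record` object.
#' @export
header_record <- function(image_id, tags, source_path = NA_character_) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  structure(
    list(image_id = image_id, tags = as.list(tags), source_path = source_path),
    class = "header_record"
  )
}

.flatten_code_sequences <- function(tags) {
  seq_map <- c(
    ViewModifierCodeSequence = "ViewModifierCode",
    ViewCodeSequence = "ViewCodeValue"
  )
  for (seq_name in names(seq_map)) {
    if (seq_name %in% names(tags)) {
      items <- tags[[seq_name]]
      # an empty-but-present sequence is an observed empty value, not a
      # missing one: standard views carry the sequence with no items, and
      # treating that as missing would knock the field out on missingness
      tags[[seq_map[[seq_name]]]] <-
        if (length(items) >= 1L && !is.null(items[[1L]]$CodeValue)) {
          items[[1L]]$CodeValue[1L]
        } else ""
      tags[[seq_name]] <- NULL
    }
  }
  tags
}

#' Default field-exclusion rules
#'
#' Keyword classes omitted from modeling regardless of missingness:
#' date/time stamps, device identifiers, and demographic fields. Each rule
#' is a regular expression plus an optional exemption pattern:
#' `PatientOrientation` is a geometric, not demographic, field and
#' `ExposureTime` is an exposure physics parameter, not a timestamp, so both
#' are retained.
#'
#' @return a list of rules, each with `reason`, `pattern`, `exempt`.
#' @export
default_exclusion_rules <- function() {
  list(
    list(reason = "datetime", pattern = "Date|Time", exempt = "Exposure"),
    list(reason = "device_id",
         pattern = "UID|SerialNumber|StationName|DeviceID|InstitutionAddress",
         exempt = NA_character_),
    list(reason = "demographic", pattern = "Patient",
         exempt = "PatientOrientation")
  )
}

.match_exclusion <- function(name, rules) {
  for (r in rules) {
    if (grepl(r$pattern, name) &&
        (is.na(r$exempt) || !grepl(r$exempt, name))) {
      return(r$reason)
    }
  }
  "none"
}

.field_values <- function(records, name) {
  lapply(records, function(rec) rec$tags[[name]])
}

.is_numeric_field <- function(values) {
  obs <- values[!vapply(values, is.null, TRUE)]
  length(obs) > 0L && all(vapply(obs, is.numeric, TRUE))
}

#' Fit a header field schema on training records
#'
#' Determines, for every tag keyword observed in `records`, whether the
#' field is retained for modeling and how it is encoded. A field is excluded
#' when its missing fraction exceeds `max_missing` or its keyword matches an
#' exclusion rule (rule classes take precedence over the missingness reason).
#' Retained numeric fields store per-position medians of observed values
#' (multi-valued tags such as `DetectorActiveDimensions` get one position
#' per value); retained categorical fields store the sorted set of observed
#' values. Fit on the training split only, then frozen.
#'
#' @param records list of `header_record` (training split).
#' @param max_missing maximum tolerated missing fraction (default 0.10;
#'   fields strictly above it are dropped).
#' @param exclusion_rules see [default_exclusion_rules()].
#' @return a `header_schema` object: list of per-field schemas with
#'   `name`, `kind`, `missing_fraction`, `excluded`, `exclusion_reason`,
#'   `median` (numeric fields), `categories` (categorical fields),
#'   `n_values`.
#' @export
fit_schema <- function(records, max_missing = 0.10,
                       exclusion_rules = default_exclusion_rules()) {
  stopifnot(length(records) > 0L)
  fields <- unique(unlist(lapply(records, function(r) names(r$tags))))
  fields <- sort(fields)
  n <- length(records)
  schema <- lapply(fields, function(name) {
    values <- .field_values(records, name)
    observed <- values[!vapply(values, is.null, TRUE)]
    missing_fraction <- 1 - length(observed) / n
    reason <- .match_exclusion(name, exclusion_rules)
    if (reason == "none" && missing_fraction > max_missing) {
      reason <- "high_missing"
    }
    excluded <- reason != "none"
    numeric_kind <- .is_numeric_field(values)
    fs <- list(
      name = name,
      kind = if (numeric_kind) "numeric" else "categorical",
      missing_fraction = missing_fraction,
      excluded = excluded,
      exclusion_reason = reason,
      median = NULL, categories = NULL, n_values = 1L
    )
    if (!excluded) {
      if (numeric_kind) {
        k <- max(vapply(observed, length, 0L))
        fs$n_values <- k
        fs$median <- vapply(seq_len(k), function(j) {
          vals <- vapply(observed, function(v) {
            if (length(v) >= j) as.numeric(v[j]) else NA_real_
          }, 0)
          stats::median(vals, na.rm = TRUE)
        }, 0)
      } else {
        vals <- unlist(lapply(observed, function(v) {
          paste(as.character(v), collapse = "\\")
        }))
        fs$categories <- sort(unique(vals))
      }
    }
    fs
  })
  names(schema) <- fields
  if (all(vapply(schema, `[[`, TRUE, "excluded"))) {
    stop("no usable features: every header field was excluded")
  }
  structure(schema, class = "header_schema", n_records = n)
}

#' @export
print.header_schema <- function(x, ...) {
  kept <- sum(!vapply(x, `[[`, TRUE, "excluded"))
  cat("<header_schema> ", length(x), " fields (", kept, " retained)\n", sep = "")
  for (fs in x) {
    cat(sprintf(
      "  %-45s %-11s miss=%.2f %s\n", fs$name, fs$kind, fs$missing_fraction,
      if (fs$excluded) paste0("excluded(", fs$exclusion_reason, ")") else "retained"
    ))
  }
  invisible(x)
}

# column names a schema generates, in schema (alphabetical field) order
.schema_columns <- function(schema) {
  cols <- character(0)
  for (fs in schema) {
    if (fs$excluded) next
    if (fs$kind == "numeric") {
      base <- if (fs$n_values > 1L) {
        paste0(fs$name, "_", seq_len(fs$n_values))
      } else fs$name
      cols <- c(cols, base, paste0(fs$name, "_missing"))
    } else {
      cols <- c(cols, paste0(fs$name, "=", fs$categories),
                paste0(fs$name, "_missing"))
    }
  }
  cols
}

#' Transform header records into a numeric feature matrix
#'
#' Applies a fitted schema: numeric fields carry their raw values with
#' absences imputed by the schema median; every retained field contributes a
#' 0/1 missing-flag column; categorical fields become one indicator column
#' per schema category, with values unseen at fit time mapping to all zeros.
#' Column set and order depend only on the schema. The output contains no
#' absent values.
#'
#' @param records list of `header_record` (any split).
#' @param schema a fitted `header_schema`.
#' @return a `feature_matrix`: numeric matrix with `image_id` rownames and
#'   schema-derived column names.
#' @export
transform_headers <- function(records, schema) {
  stopifnot(inherits(schema, "header_schema"))
  cols <- .schema_columns(schema)
  n <- length(records)
  X <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  for (fs in schema) {
    if (fs$excluded) next
    if (fs$kind == "numeric") {
      base <- if (fs$n_values > 1L) {
        paste0(fs$name, "_", seq_len(fs$n_values))
      } else fs$name
      flag <- paste0(fs$name, "_missing")
      for (i in seq_len(n)) {
        v <- records[[i]]$tags[[fs$name]]
        v <- if (is.null(v)) rep(NA_real_, fs$n_values) else
          suppressWarnings(as.numeric(v))
        v <- c(v, rep(NA_real_, max(0L, fs$n_values - length(v))))[seq_len(fs$n_values)]
        imputed <- is.na(v)
        v[imputed] <- fs$median[imputed]
        X[i, base] <- v
        X[i, flag] <- as.numeric(any(imputed))
      }
    } else {
      flag <- paste0(fs$name, "_missing")
      for (i in seq_len(n)) {
        v <- records[[i]]$tags[[fs$name]]
        if (is.null(v)) {
          X[i, flag] <- 1
        } else {
          key <- paste(as.character(v), collapse = "\\")
          if (key %in% fs$categories) {
            X[i, paste0(fs$name, "=", key)] <- 1
          } # unseen category: all indicators stay 0, flag stays 0
        }
      }
    }
  }
  rownames(X) <- vapply(records, `[[`, "", "image_id")
  structure(X, class = c("feature_matrix", class(X)))
}

#' Write a feature matrix as CSV
#'
#' @param X a `feature_matrix`.
#' @param path output CSV path; `image_id` is the first column.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- data.frame(image_id = rownames(X), unclass(X),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a header schema to JSON
#'
#' @param schema a `header_schema`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(
    list(n_records = attr(schema, "n_records"), fields = unclass(schema)),
    path, auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Read a header schema from JSON
#'
#' @param path JSON file written by [write_schema()].
#' @return a `header_schema`.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fields <- lapply(obj$fields, function(fs) {
    fs$median <- if (is.null(fs$median)) NULL else as.numeric(fs$median)
    fs$categories <- if (is.null(fs$categories)) NULL else as.character(fs$categories)
    fs$n_values <- as.integer(fs$n_values)
    fs
  })
  structure(fields, class = "header_schema", n_records = obj$n_records)
}
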