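# Schema fitting (missingness + keyword exclusion) and the
# impute/flag/one-hot transform.

test_that("fields above the missingness cutoff are excluded, at the boundary kept", {
  # field 'a' observed in 89/100 records (11% missing) -> excluded;
  # field 'b' observed in 90/100 (exactly 10%) -> retained
  tag_sets <- lapply(1:100, function(i) {
    tags <- list(KVP = 28)
    if (i <= 89) tags$a <- i
    if (i <= 90) tags$b <- i
    tags
  })
  schema <- fit_schema(make_records(tag_sets))
  expect_true(schema$a$excluded)
  expect_identical(schema$a$exclusion_reason, "high_missing")
  expect_false(schema$b$excluded)
  expect_equal(schema$a$missing_fraction, 0.11)
})

test_that("datetime, device and demographic keywords are excluded with their reasons", {
  tag_sets <- lapply(1:20, function(i) list(
    KVP = 28, StudyDate = "20200101", StudyTime = "1200",
    SOPInstanceUID = "1.2", DeviceSerialNumber = "X1", StationName = "M1",
    InstitutionAddress = "A", PatientID = "P", PatientAge = "050Y",
    PatientOrientation = "A\\FR", ExposureTime = 500L
  ))
  schema <- fit_schema(make_records(tag_sets))
  for (f in c("StudyDate", "StudyTime")) {
    expect_identical(schema[[f]]$exclusion_reason, "datetime")
  }
  for (f in c("SOPInstanceUID", "DeviceSerialNumber", "StationName",
              "InstitutionAddress")) {
    expect_identical(schema[[f]]$exclusion_reason, "device_id")
  }
  for (f in c("PatientID", "PatientAge")) {
    expect_identical(schema[[f]]$exclusion_reason, "demographic")
  }
  # exemptions: geometric orientation and exposure physics are retained
  expect_false(schema$PatientOrientation$excluded)
  expect_false(schema$ExposureTime$excluded)
})

test_that("median imputation and flag columns follow the schema", {
  tag_sets <- list(list(x = 1), list(), list(x = 3), list(x = 2))
  schema <- fit_schema(make_records(tag_sets), max_missing = 0.5)
  expect_equal(schema$x$median, 2) # median of {1, 3, 2}
  X <- transform_headers(make_records(list(list(x = 1), list(), list(x = 3))),
                         schema)
  expect_equal(unname(X[, "x"]), c(1, 2, 3))
  expect_equal(unname(X[, "x_missing"]), c(0, 1, 0))
  expect_no_na(X)
})

test_that("even-count medians average the central values", {
  tag_sets <- list(list(x = 1), list(x = 2), list(x = 3), list(x = 10))
  schema <- fit_schema(make_records(tag_sets))
  expect_equal(schema$x$median, 2.5)
})

test_that("one-hot encoding maps seen categories to a single indicator and unseen to zeros", {
  tag_sets <- list(list(g = "A"), list(g = "B"), list(g = "A"))
  schema <- fit_schema(make_records(tag_sets))
  expect_identical(schema$g$categories, c("A", "B"))
  new <- make_records(list(list(g = "A"), list(g = "C"), list(), list(g = "B")))
  X <- transform_headers(new, schema)
  expect_equal(unname(X[, "g=A"]), c(1, 0, 0, 0))
  expect_equal(unname(X[, "g=B"]), c(0, 0, 0, 1))
  # row sums over the field's indicators: 1 seen, 0 unseen/absent
  sums <- X[, "g=A"] + X[, "g=B"]
  expect_equal(unname(sums), c(1, 0, 0, 1))
  # flag marks absence, not unseen values
  expect_equal(unname(X[, "g_missing"]), c(0, 0, 1, 0))
})

test_that("multi-valued numeric tags expand to one column per position", {
  tag_sets <- list(list(d = c(239, 287)), list(d = c(230, 286)), list())
  schema <- fit_schema(make_records(tag_sets), max_missing = 0.5)
  expect_identical(schema$d$n_values, 2L)
  X <- transform_headers(make_records(tag_sets), schema)
  expect_equal(unname(X[, "d_1"]), c(239, 230, 234.5))
  expect_equal(unname(X[, "d_2"]), c(287, 286, 286.5))
  expect_equal(unname(X[, "d_missing"]), c(0, 0, 1))
})

test_that("transform is schema-determined and idempotent", {
  mf <- small_corpus()
  recs <- read_headers(mf$file_path[mf$split == "train"])
  schema <- fit_schema(recs)
  X1 <- transform_headers(recs, schema)
  X2 <- transform_headers(recs, schema)
  expect_identical(X1, X2)
  # column set/order depends only on the schema, not the transformed rows
  Xsub <- transform_headers(rev(recs)[1:5], schema)
  expect_identical(colnames(Xsub), colnames(X1))
  expect_no_na(X1)
  # round trip: a record with no absences and all-seen values is unchanged
  full_idx <- which(X1[, grepl("_missing$", colnames(X1))] |> apply(1, sum) == 0)
  if (length(full_idx) > 0) {
    i <- full_idx[1]
    num_cols <- colnames(X1)[!grepl("_missing$|=", colnames(X1))]
    for (cn in num_cols) {
      fs_name <- sub("_[0-9]+$", "", cn)
      raw <- recs[[i]]$tags[[fs_name]]
      if (!is.null(raw) && length(raw) == 1L) {
        expect_equal(unname(X1[i, cn]), as.numeric(raw))
      }
    }
  }
})

test_that("an all-excluded field set is rejected", {
  tag_sets <- lapply(1:10, function(i) list(StudyDate = "20200101"))
  expect_error(fit_schema(make_records(tag_sets)), "no usable features")
})

test_that("schema JSON round-trips and drives an identical transform", {
  mf <- small_corpus()
  recs <- read_headers(mf$file_path[1:20])
  schema <- fit_schema(recs)
  f <- tempfile(fileext = ".json")
  write_schema(schema, f)
  schema2 <- read_schema(f)
  expect_identical(transform_headers(recs, schema2),
                   transform_headers(recs, schema))
  unlink(f)
})

test_that("feature matrix CSV has image_id first and all columns", {
  mf <- small_corpus()
  recs <- read_headers(mf$file_path[1:10])
  schema <- fit_schema(recs)
  X <- transform_headers(recs, schema)
  f <- tempfile(fileext = ".csv")
  write_features(X, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_identical(names(df)[1], "image_id")
  expect_identical(names(df)[-1], colnames(X))
  expect_equal(nrow(df), nrow(X))
  unlink(f)
})
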