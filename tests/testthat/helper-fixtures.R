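# Shared fixtures. Heavy artifacts (the seeded benchmark corpus and its
# trained bundle) are built once per session and memoised, so the
# end-to-end assertions across files share a single training run.

.fixture_env <- new.env(parent = emptyenv())

# seeded desk-scale benchmark: 1200-image corpus + proportional (17-case)
# wire augmentation, all models trained at width 0.25 for 10 epochs
benchmark_fixture <- function() {
  if (is.null(.fixture_env$bundle)) {
    dir <- file.path(tempdir(), "mt-benchmark-corpus")
    unlink(dir, recursive = TRUE)
    mf <- generate_corpus(dir, benchmark_composition(), seed = 0)
    mf <- augment_wire_cases(mf, dir, total = 17L, seed = 0)
    cfg <- run_config(mf, target_sensitivity = 0.99)
    .fixture_env$manifest <- mf
    .fixture_env$bundle <- run_train(cfg)
  }
  list(bundle = .fixture_env$bundle, manifest = .fixture_env$manifest)
}

# small corpus for unit tests: ~60 files at 64 px
small_corpus <- function() {
  if (is.null(.fixture_env$small_manifest)) {
    dir <- file.path(tempdir(), "mt-small-corpus")
    unlink(dir, recursive = TRUE)
    .fixture_env$small_manifest <- generate_corpus(
      dir,
      composition = c(full_field = 36L, spot_mag = 12L, stereotactic = 3L,
                      wire_localization = 6L, specimen = 3L),
      seed = 11, image_size = 64L, n_unlabeled = 6L
    )
  }
  .fixture_env$small_manifest
}

# hand-built header records with controlled missingness
make_records <- function(tag_sets) {
  lapply(seq_along(tag_sets), function(i) {
    header_record(sprintf("rec%03d", i), tag_sets[[i]])
  })
}

expect_no_na <- function(x) expect_false(anyNA(unclass(x)))

# independent Mann-Whitney auROC oracle: explicit pair counting
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# independent DeLong oracle: explicit per-case structural components and
# the covariance algebra written out longhand
delong_oracle <- function(sa, sb, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  psi <- function(p, q) if (p > q) 1 else if (p == q) 0.5 else 0
  comp <- function(s) {
    v10 <- vapply(pos, function(i) mean(vapply(neg, function(j) psi(s[i], s[j]), 0)), 0)
    v01 <- vapply(neg, function(j) mean(vapply(pos, function(i) psi(s[i], s[j]), 0)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- comp(sa); b <- comp(sb)
  cov_ <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  var_diff <- (cov_(a$v10, a$v10) + cov_(b$v10, b$v10) - 2 * cov_(a$v10, b$v10)) / m +
    (cov_(a$v01, a$v01) + cov_(b$v01, b$v01) - 2 * cov_(a$v01, b$v01)) / n
  z <- (a$auc - b$auc) / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), auc_a = a$auc, auc_b = b$auc,
       var_diff = var_diff)
}

# exhaustive threshold-selection oracle over all candidate cutoffs
select_threshold_bruteforce <- function(scores, labels, target) {
  cands <- sort(unique(c(scores, 0)), decreasing = TRUE)
  pos <- scores[labels == 1]
  for (t in cands) {
    if (mean(pos >= t) >= target) return(t)
  }
  stop("unreachable")
}
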