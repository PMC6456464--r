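# Evaluation statistics against independent oracles: brute-force pair
# counting, longhand DeLong structural components, closed-form binomial
# tails, and pROC / binom.test as external cross-checks.

test_that("auroc matches brute-force pair counting on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(10:100, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE)) # both classes guaranteed
    scores <- if (rep %% 3 == 0) {
      sample(seq(0, 1, 0.1), n, TRUE) # heavy ties
    } else {
      runif(n)
    }
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("auroc handles the canonical examples", {
  expect_equal(auroc(c(0.1, 0.9), c(0, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(0.2, 0.6, 0.5, 0.4), c(0, 1, 0, 1)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auroc is invariant under monotone transforms and complements to 1", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 40
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- runif(n)
    a <- auroc(scores, labels)
    expect_equal(auroc(exp(3 * scores) + 2, labels), a)
    expect_equal(auroc(qlogis(scores / 1.001 + 1e-4), labels), a)
    expect_equal(auroc(scores, 1 - labels), 1 - a)
  }
})

test_that("auroc equals the trapezoidal area under the empirical ROC curve", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.05), n, TRUE)
    rc <- roc_points(scores, labels)
    trap <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
    expect_equal(auroc(scores, labels), trap)
  }
})

test_that("delong_test agrees with the longhand structural-components oracle", {
  set.seed(1)
  for (rep in 1:10) {
    n <- 40
    labels <- c(rep(1, 15), rep(0, 25))
    truth <- labels + rnorm(n, sd = 1.2)
    sa <- plogis(truth + rnorm(n, sd = 0.8))
    sb <- plogis(truth + rnorm(n, sd = 1.5))
    got <- delong_test(sa, sb, labels)
    want <- delong_oracle(sa, sb, labels)
    expect_equal(got$statistic, want$z, tolerance = 1e-6)
    expect_equal(got$p_value, want$p, tolerance = 1e-6)
    expect_equal(got$auc_a, want$auc_a, tolerance = 1e-12)
  }
})

test_that("delong_test matches pROC on auROC CIs and the paired test", {
  set.seed(2)
  labels <- c(rep(1, 20), rep(0, 30))
  truth <- labels + rnorm(50, sd = 1)
  sa <- plogis(truth + rnorm(50, sd = 0.7))
  sb <- plogis(truth + rnorm(50, sd = 1.3))
  got <- delong_test(sa, sb, labels)
  ra <- pROC::roc(labels, sa, direction = "<", levels = c(0, 1), quiet = TRUE)
  rb <- pROC::roc(labels, sb, direction = "<", levels = c(0, 1), quiet = TRUE)
  ci_a <- as.numeric(pROC::ci.auc(ra, method = "delong"))
  expect_equal(got$ci_a[1], ci_a[1], tolerance = 1e-8)
  expect_equal(got$ci_a[2], ci_a[3], tolerance = 1e-8)
  rt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p_value, rt$p.value, tolerance = 1e-8)
})

test_that("delong_test is antisymmetric in its arguments and detects a better scorer", {
  set.seed(3)
  labels <- c(rep(1, 50), rep(0, 70))
  truth <- labels + rnorm(120, sd = 0.8)
  sa <- plogis(2 * truth)                         # strong scorer
  sb <- plogis(0.3 * truth + rnorm(120, sd = 2))  # near-noise scorer
  ab <- delong_test(sa, sb, labels)
  ba <- delong_test(sb, sa, labels)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_lt(ab$p_value, 0.05)
  expect_gt(ab$auc_a, ab$auc_b)
})

test_that("delong_test raises a degenerate-variance error without discordance", {
  labels <- c(1, 1, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.1)
  expect_error(delong_test(s, s, labels), "degenerate variance")
  # both models separate perfectly: auROC 1.0, variance zero
  expect_error(delong_test(c(0.9, 0.8, 0.2, 0.1), c(0.7, 0.9, 0.3, 0.2),
                           labels), "degenerate variance")
})

test_that("mcnemar_exact equals the closed-form binomial tail", {
  r <- mcnemar_exact(1, 5)
  expect_equal(r$p_value, 2 * (1 + 6) / 64) # 0.21875
  expect_equal(mcnemar_exact(0, 0)$p_value, 1)
  expect_equal(mcnemar_exact(4, 4)$p_value, 1)
  expect_error(mcnemar_exact(-1, 2), "non-negative")
  # symmetry, and agreement with binom.test across a grid
  for (b in 0:6) for (cc in 0:6) {
    pa <- mcnemar_exact(b, cc)$p_value
    expect_equal(pa, mcnemar_exact(cc, b)$p_value)
    if (b + cc > 0) {
      expect_equal(pa, stats::binom.test(min(b, cc), b + cc, 0.5)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("bonferroni adjustment multiplies and caps at one", {
  r <- bonferroni_adjust(mcnemar_exact(1, 5), m = 3)
  expect_equal(r$adjusted_p, min(1, 3 * 0.21875))
  r2 <- bonferroni_adjust(mcnemar_exact(3, 4), m = 10)
  expect_equal(r2$adjusted_p, 1)
})

test_that("average precision matches its defining examples and the prevalence null", {
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), c(1, 1, 1, 0, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  set.seed(5)
  n <- 2000; prev <- 0.3
  labels <- rbinom(n, 1, prev)
  labels[1:2] <- c(0, 1)
  ap <- auprc(runif(n), labels)
  expect_gt(ap, mean(labels) - 0.05)
  expect_lt(ap, mean(labels) + 0.05)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("thresholded metrics reproduce confusion-count arithmetic", {
  # counts TP=3 FP=1 FN=1 TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- thresholded_metrics(scores, labels, 0.5)
  expect_equal(m[c("tp", "fp", "fn", "tn")], list(tp = 3L, fp = 1L, fn = 1L, tn = 5L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.75 / 1.5)
  # no predicted positives: precision absent, recall zero
  m0 <- thresholded_metrics(c(0.1, 0.2, 0.3), c(0, 1, 1), 0.5)
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)
  # perfect scores
  mp <- thresholded_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(unlist(mp[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
})

test_that("evaluate_scores assembles a coherent report", {
  set.seed(9)
  labels <- c(rep(1, 30), rep(0, 70))
  scores <- plogis(labels + rnorm(100))
  r <- evaluate_scores(scores, labels)
  expect_equal(r$auroc, auroc_bruteforce(scores, labels))
  expect_lte(r$auroc_ci[1], r$auroc)
  expect_gte(r$auroc_ci[2], r$auroc)
  expect_equal(r$n_pos, 30L)
  if (!is.na(r$f1)) {
    expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
  }
})
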