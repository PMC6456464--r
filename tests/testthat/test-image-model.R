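# Image pipeline: preprocessing contracts, architecture invariants,
# gradient correctness, training sanity, and TTA algebra.

test_that("preprocess resizes without preserving aspect and min-max normalizes", {
  const <- matrix(1000L, 500, 400)
  t1 <- preprocess(const, 99L)
  expect_identical(dim(t1), c(99L, 99L))
  expect_true(all(t1 == 0)) # constant image maps to zeros
  ramp <- matrix(rep(0:98, each = 99), 99, 99)
  t2 <- preprocess(ramp, 99L)
  expect_equal(max(t2), 1)
  expect_equal(min(t2), 0)
  expect_equal(unclass(t2), unclass(ramp) / max(ramp), ignore_attr = TRUE)
  # 2:1 aspect input still becomes square
  t3 <- preprocess(matrix(runif(200 * 100), 200, 100), 99L)
  expect_identical(dim(t3), c(99L, 99L))
  expect_true(all(t3 >= 0 & t3 <= 1))
  expect_error(preprocess(1:10, 99L), "2-D")
})

test_that("architecture invariants hold for both modes", {
  g <- build_model("general", width_multiplier = 0.25)
  expect_identical(g$arch$n_blocks, 4L)
  expect_identical(g$trainable_scope, "all_layers")
  expect_identical(utils::tail(g$arch$layers, 3),
                   c("global_average_pool", "dropout", "dense(1)"))
  expect_identical(sum(g$arch$layers == "inception"), 4L)
  w <- build_model("wire", width_multiplier = 0.25)
  expect_identical(w$arch$input_size, 299L)
  expect_identical(w$trainable_scope, "last_dense_only")
  expect_gt(w$arch$n_blocks, g$arch$n_blocks) # full-depth topology
  expect_error(build_model("general", init = "pretrained"), "pretrained")
})

test_that("width multiplier scales every filter count by its ceiling", {
  full <- build_model("general", width_multiplier = 1)
  quarter <- build_model("general", width_multiplier = 0.25)
  expect_identical(quarter$arch$stem_filters,
                   as.integer(ceiling(0.25 * full$arch$stem_filters)))
  expect_identical(quarter$arch$block_filters,
                   vapply(full$arch$block_filters,
                          function(f) as.integer(ceiling(0.25 * f)), 0L))
})

test_that("convolution gradients match finite differences", {
  set.seed(4)
  X <- array(rnorm(9 * 9 * 2 * 3), c(9, 9, 2, 3))
  W <- array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 0), c(1, 1), c(2, 1))) {
    stride <- cfg[1]; pad <- cfg[2]
    fwd <- mammotriage:::.conv_fwd(X, W, b, stride, pad)
    loss <- function(Xv, Wv) sum(mammotriage:::.conv_fwd(Xv, Wv, b, stride, pad)$Y^2) / 2
    bwd <- mammotriage:::.conv_bwd(fwd$Y, W, fwd$cache)
    eps <- 1e-6
    for (trial in 1:3) {
      i <- sample(length(W), 1)
      W2 <- W; W2[i] <- W2[i] + eps
      expect_equal(bwd$dW[i], (loss(X, W2) - loss(X, W)) / eps, tolerance = 1e-3)
      j <- sample(length(X), 1)
      X2 <- X; X2[j] <- X2[j] + eps
      expect_equal(bwd$dX[j], (loss(X2, W) - loss(X, W)) / eps, tolerance = 1e-3)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(21)
  n <- 40
  classes <- rep(c("full_field", "spot_mag"), n / 2)
  imgs <- array(0, c(99, 99, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- preprocess(
      render_phantom(phantom_spec(classes[i], 64L, seed = 300 + i)), 99L)
  }
  y <- as.integer(classes == "spot_mag")
  m0 <- build_model("general", width_multiplier = 0.1, seed = 0)
  m1 <- train_image_model(m0, imgs, y, epochs = 3, seed = 0)
  expect_lt(utils::tail(m1$training_log$train_loss, 1),
            m1$training_log$train_loss[1])
  m2 <- train_image_model(m0, imgs, y, epochs = 3, seed = 0)
  expect_identical(m1$params, m2$params)
  expect_error(train_image_model(m0, imgs, rep(1L, n), epochs = 1), "both classes")
  expect_error(train_image_model(m0, array(0, c(50, 50, 4)), c(0, 1, 0, 1)),
               "input size")
})

test_that("TTA combines identity and mirror scores by mean or max", {
  m <- build_model("general", width_multiplier = 0.1, seed = 2)
  img <- preprocess(render_phantom(phantom_spec("spot_mag", 64L, seed = 8)), 99L)
  s <- score_images(m, list(img), tta = "none")
  s_fl <- score_images(m, list(mammotriage:::.hflip(img)), tta = "none")
  expect_equal(score_tta(m, img, tta_policy("mean")), mean(c(s, s_fl)))
  expect_equal(score_tta(m, img, tta_policy("max")), max(s, s_fl))
  # max-combined >= mean-combined for every image
  set.seed(3)
  for (rep in 1:5) {
    im <- preprocess(matrix(runif(80 * 70), 80, 70), 99L)
    expect_gte(score_tta(m, im, tta_policy("max")),
               score_tta(m, im, tta_policy("mean")))
  }
  # flip equivariance: mirrored input gives the same combined score
  im <- preprocess(matrix(runif(99 * 99), 99, 99), 99L)
  for (comb in c("mean", "max")) {
    expect_equal(score_tta(m, im, tta_policy(comb)),
                 score_tta(m, mammotriage:::.hflip(im), tta_policy(comb)))
  }
  # left-right symmetric image: both combines agree
  sym <- im + mammotriage:::.hflip(im)
  sym <- sym / max(sym)
  expect_equal(score_tta(m, sym, tta_policy("mean")),
               score_tta(m, sym, tta_policy("max")))
  # mode-specific defaults
  expect_identical(default_tta("general")$combine, "mean")
  expect_identical(default_tta("wire")$combine, "max")
})

test_that("score tables carry identity, flipped and combined columns", {
  m <- build_model("general", width_multiplier = 0.1, seed = 2)
  imgs <- array(runif(99 * 99 * 3), c(99, 99, 3))
  df <- score_images(m, imgs, tta = "mean")
  expect_identical(names(df), c("score_identity", "score_flipped", "score_combined"))
  expect_equal(df$score_combined, (df$score_identity + df$score_flipped) / 2)
  dfm <- score_images(m, imgs, tta = "max")
  expect_equal(dfm$score_combined, pmax(dfm$score_identity, dfm$score_flipped))
  expect_true(all(df >= 0 & df <= 1))
})

test_that("the wire head trains only the dense layer on frozen trunk features", {
  set.seed(6)
  n <- 30
  classes <- c(rep("wire_localization", 6), rep("full_field", n - 6))
  imgs <- lapply(seq_len(n), function(i) {
    preprocess(render_phantom(phantom_spec(classes[i], 64L, seed = 400 + i)), 299L)
  })
  y <- as.integer(classes == "wire_localization")
  m0 <- build_model("wire", width_multiplier = 0.1, seed = 0)
  expect_message(
    m1 <- train_image_model(m0, imgs, y, epochs = 5, seed = 0),
    "frozen trunk"
  )
  # trunk untouched, head moved
  expect_identical(m1$params$stem1, m0$params$stem1)
  expect_identical(m1$params$blocks, m0$params$blocks)
  expect_false(identical(m1$params$dense, m0$params$dense))
  expect_false(is.null(m1$feature_stats))
})
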