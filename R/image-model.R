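# Image classifiers: preprocessing, the abridged Inception-style general
# view model (99x99 input, all layers trained) and the full-depth
# wire-localization detector (299x299 input, only the dense head trained on
# features of a frozen trunk), each scored with horizontal-flip test-time
# augmentation.

#' Preprocess a raw pixel array for an image model
#'
#' Bilinearly rescales to `target_size` x `target_size` without preserving
#' aspect ratio, then min-max normalizes intensities to \[0, 1\]; a constant
#' image maps to all zeros.
#'
#' @param pixel_array 2-D numeric matrix of raw intensities.
#' @param target_size 99 (general model) or 299 (wire-localization model).
#' @param source_id optional image identifier carried on the result.
#' @return an `image_tensor`: normalized `target_size` x `target_size`
#'   matrix with attributes `source_id` and `laterality_flipped`.
#' @export
preprocess <- function(pixel_array, target_size = 99L, source_id = NA_character_) {
  if (is.null(dim(pixel_array)) || length(dim(pixel_array)) != 2L ||
      any(dim(pixel_array) == 0L)) {
    stop("pixel_array must be a non-empty 2-D matrix")
  }
  m <- pixel_array
  storage.mode(m) <- "double"
  if (!all(dim(m) == target_size)) {
    m <- EBImage::imageData(EBImage::resize(
      EBImage::Image(m), w = target_size, h = target_size, filter = "bilinear"
    ))
  }
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, target_size, target_size)
  structure(m, source_id = source_id, laterality_flipped = FALSE,
            class = c("image_tensor", class(m)))
}

#' Build an image model
#'
#' The general mode is the abridged topology: Inception-style stem followed
#' by the first four inception blocks, global average pooling, dropout and
#' one densely connected sigmoid unit, with every layer trainable. The wire
#' mode is the full-depth topology (eight blocks, 299x299 input) with only
#' the last dense layer trainable. `width_multiplier` scales all filter
#' counts (ceiling) so desk-scale training runs in minutes.
#'
#' @param mode `"general"` or `"wire"`.
#' @param init `"random"` (default) or `"pretrained"`; no pretrained weight
#'   source ships with the package, so `"pretrained"` errors unless
#'   `pretrained_weights` supplies a compatible parameter list.
#' @param width_multiplier filter-count scale in (0, 1\].
#' @param dropout dropout rate applied to the pooled features in training.
#' @param seed RNG seed for weight initialization.
#' @param pretrained_weights optional parameter list used when
#'   `init = "pretrained"`.
#' @return an `image_model`.
#' @export
build_model <- function(mode = c("general", "wire"), init = c("random", "pretrained"),
                        width_multiplier = 1.0, dropout = 0.5, seed = 0L,
                        pretrained_weights = NULL) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  stopifnot(width_multiplier > 0, width_multiplier <= 1)
  if (init == "pretrained" && is.null(pretrained_weights)) {
    stop("no pretrained weight source available; use init = \"random\" ",
         "or supply pretrained_weights")
  }
  sf <- .scaled_filters(width_multiplier)
  arch <- list(
    mode = mode,
    input_size = if (mode == "general") 99L else 299L,
    n_blocks = if (mode == "general") 4L else 8L,
    pool_after = if (mode == "general") 2L else c(2L, 4L, 6L),
    stem2_stride = if (mode == "general") 1L else 2L,
    stem_filters = sf$stem, block_filters = sf$block,
    width_multiplier = width_multiplier, dropout = dropout
  )
  c_out <- .block_out_channels(sf$block)
  arch$layers <- c(
    "conv3x3/2", "conv3x3", "maxpool2",
    rep("inception", arch$n_blocks),
    "global_average_pool", "dropout", "dense(1)"
  )
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  params <- list(
    stem1 = list(W = .he_init(c(3, 3, 3, sf$stem), 27), b = numeric(sf$stem)),
    stem2 = list(W = .he_init(c(3, 3, sf$stem, sf$stem), 9 * sf$stem),
                 b = numeric(sf$stem)),
    blocks = local({
      c_in <- sf$stem
      lapply(seq_len(arch$n_blocks), function(i) {
        p <- .init_block_params(c_in, sf$block)
        c_in <<- c_out
        p
      })
    }),
    dense = list(W = matrix(stats::rnorm(c_out, sd = sqrt(1 / c_out)), c_out, 1),
                 b = 0)
  )
  if (init == "pretrained") params <- pretrained_weights
  structure(list(
    mode = mode, arch = arch, params = params,
    trainable_scope = if (mode == "general") "all_layers" else "last_dense_only",
    feature_stats = NULL, training_log = NULL, init = init, seed = seed
  ), class = "image_model")
}

#' @export
print.image_model <- function(x, ...) {
  cat(sprintf(
    "<image_model> mode=%s input=%dx%d blocks=%d width=%.2f scope=%s%s\n",
    x$mode, x$arch$input_size, x$arch$input_size, x$arch$n_blocks,
    x$arch$width_multiplier, x$trainable_scope,
    if (is.null(x$training_log)) " (untrained)" else ""
  ))
  invisible(x)
}

# stack images (list of image_tensor or (H,W,N) array) into (H,W,N,3);
# the single gray channel is replicated to three channels
.stack_images <- function(images, input_size) {
  if (is.list(images)) {
    n <- length(images)
    X <- array(0, c(input_size, input_size, n, 3L))
    for (i in seq_len(n)) {
      m <- images[[i]]
      if (!all(dim(m)[1:2] == input_size)) {
        stop("image ", i, " does not match model input size ", input_size)
      }
      X[, , i, 1L] <- m; X[, , i, 2L] <- m; X[, , i, 3L] <- m
    }
    X
  } else {
    d <- dim(images)
    if (length(d) == 2L) d <- c(d, 1L)
    if (!all(d[1:2] == input_size)) {
      stop("images do not match model input size ", input_size)
    }
    X <- array(0, c(d[1], d[2], d[3], 3L))
    for (ch in 1:3) X[, , , ch] <- images
    X
  }
}

.forward_proba <- function(net, X, drop_mask = NULL) {
  tf <- .trunk_fwd(net, X, keep_cache = FALSE)
  feats <- .gap_fwd(tf$Y) # (N, C)
  if (!is.null(net$feature_stats)) {
    feats <- sweep(sweep(feats, 2, net$feature_stats$mean), 2,
                   net$feature_stats$sd, "/")
  }
  if (!is.null(drop_mask)) feats <- sweep(feats, 2, drop_mask, "*")
  z <- feats %*% net$params$dense$W + net$params$dense$b
  as.numeric(.sigmoid(z))
}

# GAP features for a stacked batch, standardized if stats are present
.model_features <- function(net, X) {
  feats <- .gap_fwd(.trunk_fwd(net, X, keep_cache = FALSE)$Y)
  if (!is.null(net$feature_stats)) {
    feats <- sweep(sweep(feats, 2, net$feature_stats$mean), 2,
                   net$feature_stats$sd, "/")
  }
  feats
}

#' Compute pooled trunk features for a set of images
#'
#' Runs the (possibly frozen) convolutional trunk and global average
#' pooling batch-wise, returning one feature row per image. Used to train
#' and apply the wire-localization dense head without holding all full
#' resolution tensors in memory.
#'
#' @param model an `image_model`.
#' @param images list of `image_tensor` or an (H, W, N) array.
#' @param batch_size images per forward batch.
#' @return numeric matrix (n images x channels), unstandardized.
#' @export
gap_features <- function(model, images, batch_size = 16L) {
  n <- if (is.list(images)) length(images) else dim(images)[3]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    sub <- if (is.list(images)) images[idx] else
      images[, , idx, drop = FALSE]
    X <- .stack_images(sub, model$arch$input_size)
    f <- .gap_fwd(.trunk_fwd(model, X, keep_cache = FALSE)$Y)
    out <- rbind(out, f)
  }
  out
}

#' Train an image model
#'
#' Minimizes binary cross-entropy with Adam. For the general model every
#' layer is trained by backpropagation; for the wire model the frozen trunk
#' is applied once to extract pooled features, which are standardized using
#' training statistics, and only the dense sigmoid head is trained. A wire
#' model with random initialization therefore trains its head on features
#' of a randomly initialized frozen trunk; this is logged. Deterministic
#' given the seed.
#'
#' @param model an `image_model` from [build_model()].
#' @param images training images: list of `image_tensor` or (H, W, N) array.
#' @param y binary labels (1 = positive class).
#' @param epochs training epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @param batch_size minibatch size.
#' @param lr learning rate; default 1e-3 for all-layer training, 1e-2 for
#'   dense-head-only training.
#' @param validation optional list with `images` and `y` for per-epoch
#'   validation loss.
#' @param train_all_layers override to train all layers of a wire model.
#' @param verbose print per-epoch losses.
#' @return the trained `image_model` with a `training_log` data frame.
#' @export
train_image_model <- function(model, images, y, epochs = 10L, seed = 0L,
                              batch_size = 32L, lr = NULL, validation = NULL,
                              train_all_layers = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "image_model"))
  y <- .check_binary(y)
  n <- if (is.list(images)) length(images) else dim(images)[3]
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  scope <- if (train_all_layers) "all_layers" else model$trainable_scope
  if (is.null(lr)) lr <- if (scope == "last_dense_only") 1e-2 else 1e-3
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  if (scope == "last_dense_only") {
    if (model$init == "random") {
      message("wire head is being trained on features of a randomly ",
              "initialized frozen trunk")
    }
    model <- .train_dense_head(model, images, y, epochs, batch_size, lr,
                               validation, verbose)
  } else {
    model <- .train_all_layers(model, images, y, epochs, batch_size, lr,
                               validation, verbose)
  }
  model
}

.train_all_layers <- function(model, images, y, epochs, batch_size, lr,
                              validation, verbose) {
  X_all <- .stack_images(images, model$arch$input_size)
  n <- dim(X_all)[3]
  drop_rate <- model$arch$dropout
  adam <- .adam_new()
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  val_X <- if (!is.null(validation)) {
    .stack_images(validation$images, model$arch$input_size)
  }
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(n, start + batch_size - 1L)]
      X <- X_all[, , idx, , drop = FALSE]
      yb <- y[idx]
      tf <- .trunk_fwd(model, X, keep_cache = TRUE)
      feats <- .gap_fwd(tf$Y) # (nb, C)
      mask <- (stats::runif(ncol(feats)) >= drop_rate) / (1 - drop_rate)
      fd <- sweep(feats, 2, mask, "*")
      z <- fd %*% model$params$dense$W + model$params$dense$b
      p <- as.numeric(.sigmoid(z))
      losses <- c(losses, .bce_loss(p, yb))
      nb <- length(yb)
      dz <- matrix((p - yb) / nb, nb, 1)
      dW_dense <- crossprod(fd, dz)
      db_dense <- sum(dz)
      dfeats <- sweep(dz %*% t(model$params$dense$W), 2, mask, "*")
      dY <- .gap_bwd(dfeats, dim(tf$Y))
      grads <- .trunk_bwd(model, dY, tf$caches)
      model$params$dense$W <- .adam_step(adam, "dense.W", model$params$dense$W,
                                         dW_dense, lr)
      model$params$dense$b <- .adam_step(adam, "dense.b", model$params$dense$b,
                                         db_dense, lr)
      for (nm in c("stem1", "stem2")) {
        model$params[[nm]]$W <- .adam_step(adam, paste0(nm, ".W"),
                                           model$params[[nm]]$W,
                                           grads[[nm]]$W, lr)
        model$params[[nm]]$b <- .adam_step(adam, paste0(nm, ".b"),
                                           model$params[[nm]]$b,
                                           grads[[nm]]$b, lr)
      }
      for (i in seq_len(model$arch$n_blocks)) {
        for (br in names(model$params$blocks[[i]])) {
          key <- paste0("b", i, ".", br)
          model$params$blocks[[i]][[br]]$W <-
            .adam_step(adam, paste0(key, ".W"),
                       model$params$blocks[[i]][[br]]$W,
                       grads$blocks[[i]][[br]]$W, lr)
          model$params$blocks[[i]][[br]]$b <-
            .adam_step(adam, paste0(key, ".b"),
                       model$params$blocks[[i]][[br]]$b,
                       grads$blocks[[i]][[br]]$b, lr)
        }
      }
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      pv <- .forward_proba(model, val_X)
      val_loss <- .bce_loss(pv, validation$y)
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_loss = val_loss))
    if (verbose) {
      cat(sprintf("epoch %d  train %.4f  val %s\n", epoch, mean(losses),
                  ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
  }
  model$training_log <- log
  model
}

.train_dense_head <- function(model, images, y, epochs, batch_size, lr,
                              validation, verbose) {
  feats_raw <- gap_features(model, images)
  val <- if (!is.null(validation)) {
    list(features = gap_features(model, validation$images), y = validation$y)
  }
  .fit_dense_on_features(model, feats_raw, y, epochs, batch_size, lr, val,
                         verbose)
}

# fit the dense sigmoid head on precomputed (unstandardized) trunk features;
# standardization statistics are estimated on the training rows and stored.
# The loss weights positives by the inverse class ratio: wire prevalence is
# around a percent, and an unweighted head barely leaves its prior.
.fit_dense_on_features <- function(model, feats_raw, y, epochs = 10L,
                                   batch_size = 32L, lr = 1e-2,
                                   validation = NULL, verbose = FALSE,
                                   pos_weight = NULL) {
  if (is.null(pos_weight)) pos_weight <- sum(y == 0L) / max(1L, sum(y == 1L))
  mu <- colMeans(feats_raw)
  sd_ <- apply(feats_raw, 2, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  model$feature_stats <- list(mean = mu, sd = sd_)
  feats <- sweep(sweep(feats_raw, 2, mu), 2, sd_, "/")
  val_feats <- NULL
  if (!is.null(validation)) {
    val_feats <- sweep(sweep(validation$features, 2, mu), 2, sd_, "/")
  }
  n <- nrow(feats)
  drop_rate <- model$arch$dropout
  adam <- .adam_new()
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(n, start + batch_size - 1L)]
      f <- feats[idx, , drop = FALSE]
      yb <- y[idx]
      mask <- (stats::runif(ncol(f)) >= drop_rate) / (1 - drop_rate)
      fd <- sweep(f, 2, mask, "*")
      z <- fd %*% model$params$dense$W + model$params$dense$b
      p <- as.numeric(.sigmoid(z))
      w <- ifelse(yb == 1L, pos_weight, 1)
      w <- w / sum(w)
      losses <- c(losses, -sum(w * (yb * log(pmax(p, 1e-7)) +
                                      (1 - yb) * log(pmax(1 - p, 1e-7)))))
      dz <- matrix(w * (p - yb), length(yb), 1)
      model$params$dense$W <- .adam_step(adam, "dense.W", model$params$dense$W,
                                         crossprod(fd, dz), lr)
      model$params$dense$b <- .adam_step(adam, "dense.b", model$params$dense$b,
                                         sum(dz), lr)
    }
    val_loss <- NA_real_
    if (!is.null(val_feats)) {
      zv <- val_feats %*% model$params$dense$W + model$params$dense$b
      val_loss <- .bce_loss(as.numeric(.sigmoid(zv)), validation$y)
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_loss = val_loss))
    if (verbose) {
      cat(sprintf("epoch %d  train %.4f  val %s\n", epoch, mean(losses),
                  ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
  }
  model$training_log <- log
  model
}

# score precomputed (unstandardized) trunk features through the dense head
.score_dense_features <- function(model, feats_raw) {
  f <- sweep(sweep(feats_raw, 2, model$feature_stats$mean), 2,
             model$feature_stats$sd, "/")
  as.numeric(.sigmoid(f %*% model$params$dense$W + model$params$dense$b))
}

#' Test-time augmentation policy
#'
#' @param combine `"mean"` or `"max"`. The general model defaults to mean
#'   combination, the wire-localization model to max.
#' @return a `tta_policy`.
#' @export
tta_policy <- function(combine = c("mean", "max")) {
  combine <- match.arg(combine)
  structure(list(augmentations = c("identity", "horizontal_flip"),
                 combine = combine), class = "tta_policy")
}

#' Default TTA policy for a model mode
#'
#' @param mode `"general"` (mean combination) or `"wire"` (max).
#' @return a `tta_policy`.
#' @export
default_tta <- function(mode = c("general", "wire")) {
  mode <- match.arg(mode)
  tta_policy(if (mode == "general") "mean" else "max")
}

.hflip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Score one image with test-time augmentation
#'
#' Scores the image and its horizontal mirror and combines the two
#' probabilities by the policy's mean or max.
#'
#' @param model a trained `image_model`.
#' @param image an `image_tensor` matching the model input size.
#' @param policy a [tta_policy()]; defaults to the model mode's convention.
#' @return combined score in \[0, 1\].
#' @export
score_tta <- function(model, image, policy = default_tta(model$mode)) {
  s <- score_images(model, list(image, .hflip(image)), tta = "none")
  if (policy$combine == "mean") mean(s) else max(s)
}

#' Score a set of images
#'
#' @param model a trained `image_model`.
#' @param images list of `image_tensor` or (H, W, N) array, already
#'   preprocessed to the model input size.
#' @param tta `"mean"`, `"max"`, or `"none"` (identity scores only).
#' @param batch_size images per forward batch.
#' @return for `tta = "none"` a numeric score vector; otherwise a data
#'   frame with `score_identity`, `score_flipped`, `score_combined`.
#' @export
score_images <- function(model, images, tta = c("mean", "max", "none"),
                         batch_size = 32L) {
  tta <- match.arg(tta)
  n <- if (is.list(images)) length(images) else dim(images)[3]
  score_batch <- function(flip) {
    out <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(n, start + batch_size - 1L)
      sub <- if (is.list(images)) images[idx] else images[, , idx, drop = FALSE]
      if (flip) {
        sub <- if (is.list(sub)) lapply(sub, .hflip) else
          sub[, rev(seq_len(dim(sub)[2])), , drop = FALSE]
      }
      X <- .stack_images(sub, model$arch$input_size)
      out <- c(out, .forward_proba(model, X))
    }
    out
  }
  s_id <- score_batch(FALSE)
  if (tta == "none") return(s_id)
  s_fl <- score_batch(TRUE)
  combined <- if (tta == "mean") (s_id + s_fl) / 2 else pmax(s_id, s_fl)
  data.frame(score_identity = s_id, score_flipped = s_fl,
             score_combined = combined)
}
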