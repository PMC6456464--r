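# Score-fusion algebra and sensitivity-targeted threshold selection.
# The fusion rules are fixed, not learned: the combined image score is
# max(general image, wire), the image+header score is their mean, and the
# final ensemble is max(wire, mean(image, header)).

.check_score <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be within [0, 1]")
  }
  x
}

#' Combined image score: max of general-image and wire scores
#'
#' @param s_img general image model score(s), TTA-mean.
#' @param s_wire wire-localization model score(s), TTA-max.
#' @return element-wise maximum.
#' @export
fuse_image <- function(s_img, s_wire) {
  .check_score(s_img, "s_img"); .check_score(s_wire, "s_wire")
  pmax(s_img, s_wire)
}

#' Final ensemble score: max(wire, mean(image, header))
#'
#' The general image and header model probabilities are averaged, then the
#' wire-localization score overrides by maximum so that a confident wire
#' detection alone flags an image.
#'
#' @param s_img general image model score(s).
#' @param s_hdr header model score(s).
#' @param s_wire wire-localization model score(s).
#' @return fused score(s) in \[0, 1\].
#' @export
fuse_final <- function(s_img, s_hdr, s_wire) {
  .check_score(s_img, "s_img"); .check_score(s_hdr, "s_hdr")
  .check_score(s_wire, "s_wire")
  pmax(s_wire, (s_img + s_hdr) / 2)
}

#' Fuse a score table
#'
#' Adds the derived columns `s_img_combined = max(s_img, s_wire)`,
#' `s_img_hdr = mean(s_img, s_hdr)` and the final ensemble `s_final` to a
#' data frame of per-image model scores.
#'
#' @param scores data frame with columns `image_id`, `s_img`, `s_wire`,
#'   `s_hdr`.
#' @param image_source which image score feeds the image+header mean:
#'   `"general"` (the general model score, default) or `"combined"` (the
#'   wire-fused image score).
#' @return the input with `s_img_combined`, `s_img_hdr`, `s_final` added.
#' @export
fuse_scores <- function(scores, image_source = c("general", "combined")) {
  image_source <- match.arg(image_source)
  stopifnot(all(c("image_id", "s_img", "s_wire", "s_hdr") %in% names(scores)))
  scores$s_img_combined <- fuse_image(scores$s_img, scores$s_wire)
  img <- if (image_source == "general") scores$s_img else scores$s_img_combined
  scores$s_img_hdr <- (img + scores$s_hdr) / 2
  scores$s_final <- pmax(scores$s_wire, scores$s_img_hdr)
  scores
}

#' Sensitivity-targeted threshold selection
#'
#' Finds the largest threshold (among the observed scores and 0) whose
#' sensitivity — the fraction of positives with `score >= threshold` —
#' meets the target. Because sensitivity is a step function of the
#' threshold with jumps only at observed scores, this finite search is
#' exact.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = special view); at least one positive.
#' @param target_sensitivity required sensitivity in \[0, 1\].
#' @return a `threshold_decision` list: `threshold`, `target_sensitivity`,
#'   `achieved_sensitivity`, `n_removed`, `n_kept`.
#' @export
select_threshold <- function(scores, labels, target_sensitivity) {
  labels <- .check_binary(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1L) == 0L) stop("at least one positive label required")
  if (target_sensitivity > 1 || target_sensitivity < 0) {
    stop("target_sensitivity must be in [0, 1]")
  }
  pos <- scores[labels == 1L]
  candidates <- sort(unique(c(scores, 0)), decreasing = TRUE)
  for (t in candidates) {
    sens <- mean(pos >= t)
    if (sens >= target_sensitivity) {
      return(structure(list(
        threshold = t, target_sensitivity = target_sensitivity,
        achieved_sensitivity = sens,
        n_removed = sum(scores >= t), n_kept = sum(scores < t)
      ), class = "threshold_decision"))
    }
  }
  stop("unreachable: threshold 0 always reaches sensitivity 1")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf(
    "<threshold_decision> threshold %.4f (target sens %.3f, achieved %.3f); %d removed / %d kept\n",
    x$threshold, x$target_sensitivity, x$achieved_sensitivity,
    x$n_removed, x$n_kept
  ))
  invisible(x)
}

#' Partition a scored corpus at a threshold
#'
#' Images with `s_final >= threshold` are removed (classified as special
#' views); the rest are kept. Order is preserved within each part.
#'
#' @param scoresets data frame with columns `image_id` and `s_final`.
#' @param threshold decision threshold.
#' @return list with character vectors `kept` and `removed` of image ids.
#' @export
filter_corpus <- function(scoresets, threshold) {
  stopifnot(all(c("image_id", "s_final") %in% names(scoresets)))
  missing <- is.na(scoresets$s_final)
  if (any(missing)) {
    stop("s_final absent for: ",
         paste(scoresets$image_id[missing], collapse = ", "))
  }
  removed <- scoresets$s_final >= threshold
  list(kept = scoresets$image_id[!removed],
       removed = scoresets$image_id[removed])
}
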