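#' Loss configuration for multi-scale deep supervision
#'
#' @param smooth Positive stabiliser added to numerator and denominator of
#'   the soft dice score. The default of 1 keeps the loss finite and defined
#'   on empty masks; taking `smooth` toward 0 recovers `1 - DSC` on binary
#'   inputs.
#' @param scale_weights Optional nonnegative per-scale weights, finest scale
#'   first. `NULL` (default) weights all scales uniformly.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(smooth = 1, scale_weights = NULL) {
  stopifnot(is.numeric(smooth), length(smooth) == 1L, smooth > 0)
  if (!is.null(scale_weights)) {
    stopifnot(is.numeric(scale_weights), all(scale_weights >= 0),
              any(scale_weights > 0))
  }
  structure(list(smooth = smooth, scale_weights = scale_weights),
            class = "loss_config")
}

#' Foreground-preserving label pyramid
#'
#' Downsamples a binary label image to `levels` scales by repeated 2x2
#' foreground-preserving (max) pooling: a coarse pixel is foreground iff any
#' pixel of its 2x2 fine-scale block is foreground. This keeps thin, small
#' structures such as perivascular spaces represented at every supervision
#' depth, where plain average pooling would wash them out. An average-pool
#' alternative producing soft labels in `[0, 1]` is available via `policy`.
#'
#' @param label 2D binary matrix (values 0/1) with both sides divisible by
#'   `2^(levels - 1)`.
#' @param levels Number of pyramid levels, finest (original) scale included.
#' @param policy `"max"` (foreground-preserving, default) or `"mean"`
#'   (average-pool soft labels).
#' @return A list of `levels` matrices, element `s` of dimension
#'   `dim(label) / 2^(s-1)`; element 1 is `label` itself.
#' @export
hf_downsample <- function(label, levels, policy = c("max", "mean")) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(label), levels >= 1)
  f <- 2L^(levels - 1L)
  if (nrow(label) %% f != 0L || ncol(label) %% f != 0L) {
    stop("label sides (", nrow(label), "x", ncol(label),
         ") must be divisible by 2^(levels-1) = ", f,
         "; pad the input first")
  }
  pyr <- vector("list", levels)
  pyr[[1L]] <- label
  cur <- label
  if (levels > 1L) {
    for (s in 2L:levels) {
      cur <- pool2(cur, if (policy == "max") max else mean)
      pyr[[s]] <- cur
    }
  }
  pyr
}

# 2x2 block pooling of a matrix with an arbitrary reducer.
pool2 <- function(m, fun) {
  h <- nrow(m) %/% 2L
  w <- ncol(m) %/% 2L
  a <- m[seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE]
  b <- m[seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE]
  cc <- m[seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE]
  d <- m[seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE]
  if (identical(fun, max)) {
    pmax(a, b, cc, d)
  } else {
    (a + b + cc + d) / 4
  }
}

#' Soft dice loss
#'
#' Differentiable relaxation of `1 - DSC` comparing a probability map
#' against a binary label:
#' `loss = 1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)`.
#' A perfect binary prediction gives exactly 0 (the stabiliser cancels), and
#' an all-zero prediction of an empty label also gives 0 (agreement on
#' absence).
#'
#' @param prob Numeric array of probabilities in `[0, 1]`.
#' @param label Binary array of the same dimensions.
#' @param smooth Positive stabiliser (see [loss_config()]).
#' @return Scalar loss in `[0, 1)`.
#' @export
soft_dice_loss <- function(prob, label, smooth = 1) {
  if (!identical(dim(prob), dim(label)) &&
      !(is.null(dim(prob)) && is.null(dim(label)) &&
        length(prob) == length(label))) {
    stop("prob and label must have identical shape")
  }
  stopifnot(smooth > 0)
  inter <- sum(prob * label)
  denom <- sum(prob) + sum(label) + smooth
  1 - (2 * inter + smooth) / denom
}

#' Multi-scale deep-supervision loss
#'
#' Weighted mean of per-scale soft dice losses over a probability pyramid
#' (network heads, finest first) and the matching label pyramid from
#' [hf_downsample()].
#'
#' @param pyr_p List of probability maps, finest scale first.
#' @param pyr_y List of label masks with matching shapes.
#' @param cfg A [loss_config()].
#' @return Scalar loss with attribute `per_scale` giving the unweighted
#'   per-scale losses for logging.
#' @export
multiscale_loss <- function(pyr_p, pyr_y, cfg = loss_config()) {
  L <- length(pyr_p)
  if (length(pyr_y) != L) stop("pyramids have different level counts")
  w <- cfg$scale_weights
  if (is.null(w)) w <- rep(1, L)
  if (length(w) != L) stop("scale_weights length must equal level count")
  per <- numeric(L)
  for (s in seq_len(L)) {
    if (!identical(dim(pyr_p[[s]]), dim(pyr_y[[s]]))) {
      stop("shape mismatch at scale ", s)
    }
    per[s] <- soft_dice_loss(pyr_p[[s]], pyr_y[[s]], smooth = cfg$smooth)
  }
  structure(sum(w * per) / sum(w), per_scale = per)
}

# Gradient of soft_dice_loss with respect to prob; used by the trainer.
soft_dice_grad <- function(prob, label, smooth = 1) {
  inter <- sum(prob * label)
  denom <- sum(prob) + sum(label) + smooth
  (2 * inter + smooth) / denom^2 - 2 * label / denom
}
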