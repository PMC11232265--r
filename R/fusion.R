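# Parameter-free spatial-mean-attention fusion layer. The per-pixel weight
# of each source is its channel-mean activation normalized across sources,
# so positions where one modality's features respond more strongly draw
# the fused features toward that modality. The layer has no parameters and
# is absent during training; it is inserted only at inference.

#' Per-pixel fusion weight maps from channel-mean attention
#'
#' For each source feature map, computes the mean over channels at every
#' pixel and normalizes across sources:
#' `w_i(x, y) = Q_i(x, y) / (sum_j Q_j(x, y) + epsilon)`. Pixels where all
#' sources respond zero get uniform weights `1/s`. Features are expected
#' non-negative (post-ReLU); negative values trigger a warning and are
#' clamped at zero before the means are taken.
#'
#' @param features List of `s >= 2` feature arrays of identical dim
#'   (H, W, C).
#' @param epsilon Denominator guard (default `1e-8`).
#' @param weight_mode `"l1"` (default): linear normalization of the means;
#'   `"softmax"`: softmax of the means across sources.
#' @param local_window `NULL` (default) or an odd integer k: additionally
#'   box-filter each channel-mean map with a k x k window before
#'   normalizing, so weights respond to the local (windowed) mean.
#' @return An (H, W, s) array of class `weight_map`; entries in \[0, 1\]
#'   and summing to 1 across sources at every pixel.
#' @export
compute_weight_maps <- function(features, epsilon = 1e-8,
                                weight_mode = c("l1", "softmax"),
                                local_window = NULL) {
  weight_mode <- match.arg(weight_mode)
  s <- length(features)
  if (s < 2) stop("need at least two sources")
  d <- dim(features[[1]])
  for (f in features) {
    if (!identical(dim(f), d))
      stop("shape error: feature maps must share dimensions")
  }
  if (any(vapply(features, function(f) min(f) < 0, logical(1)))) {
    warning("negative feature values violate the post-ReLU contract; ",
            "clamping at zero")
    features <- lapply(features, function(f) pmax(f, 0))
  }
  q <- lapply(features, function(f) rowMeans(f, dims = 2L))
  if (!is.null(local_window)) {
    k <- as.integer(local_window)
    stopifnot(k >= 1, k %% 2 == 1)
    box <- rep(1 / k, k)
    q <- lapply(q, function(m) cpp_sepfilter2(m, box, "same_reflect"))
  }
  if (weight_mode == "softmax") q <- lapply(q, exp)
  denom <- Reduce(`+`, q)
  zero <- denom == 0
  w <- array(0, c(d[1], d[2], s))
  for (i in seq_len(s)) {
    wi <- q[[i]] / (denom + epsilon)
    wi[zero] <- 1 / s
    w[, , i] <- wi
  }
  # renormalize away the epsilon perturbation so weights sum to 1 exactly
  tot <- apply(w, c(1, 2), sum)
  for (i in seq_len(s)) w[, , i] <- w[, , i] / tot
  structure(w, class = c("weight_map", "array"))
}

#' Weighted fusion of source feature maps
#'
#' Computes the convex per-pixel combination
#' `f(c, x, y) = sum_i w_i(x, y) * phi_i(c, x, y)`: one weight per source
#' and pixel, broadcast over all channels.
#'
#' @param features List of (H, W, C) feature arrays.
#' @param w Weight array (H, W, s) from [compute_weight_maps()].
#' @return The fused (H, W, C) feature array.
#' @export
fuse_features <- function(features, w) {
  s <- length(features)
  d <- dim(features[[1]])
  if (!identical(dim(w)[1:2], d[1:2]) || dim(w)[3] != s)
    stop("shape error: weight map inconsistent with features")
  for (f in features) {
    if (!identical(dim(f), d))
      stop("shape error: feature maps must share dimensions")
  }
  out <- array(0, d)
  for (i in seq_len(s)) {
    wi <- as.vector(w[, , i])      # recycled across channels (column-major)
    out <- out + features[[i]] * wi
  }
  out
}

#' Available fusion strategies
#'
#' `mean_attention` is the spatial-mean-attention rule; `addition` and
#' `average` are the classical parameter-free baselines it is compared
#' against.
#'
#' @return Character vector of strategy names.
#' @export
fusion_strategies <- function() c("mean_attention", "addition", "average")

#' Apply a named fusion strategy to source feature maps
#'
#' @param features List of (H, W, C) feature arrays.
#' @param strategy One of [fusion_strategies()].
#' @param ... Passed to [compute_weight_maps()] for `mean_attention`.
#' @return The fused (H, W, C) feature array.
#' @export
apply_fusion_strategy <- function(features, strategy = "mean_attention", ...) {
  strategy <- match.arg(strategy, fusion_strategies())
  switch(strategy,
         mean_attention = fuse_features(features,
                                        compute_weight_maps(features, ...)),
         addition = Reduce(`+`, features),
         average = Reduce(`+`, features) / length(features))
}
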