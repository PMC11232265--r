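# Core network: feature extractor (two 3x3 convs + a scale-4 Res2Net block)
# and feature reconstructor (four 3x3 convs). All convolutions are stride 1
# and size-preserving (zero padding (k-1)/2), so the fusion layer can act
# per pixel and the reconstructor returns an image of the input size.

#' Layer inventory of the fusion network
#'
#' Returns the fixed layer table of the network: the extractor's two 3x3
#' convolutions, the five (or eight, when each Res2Net group stacks two
#' convolutions) convolutions of the Res2Net block, and the reconstructor's
#' four 3x3 convolutions. The final reconstructor layer is linear; every
#' other layer is followed by ReLU.
#'
#' @param group_conv_depth 1 (default) or 2: number of stacked 3x3
#'   convolutions per Res2Net group transform.
#' @return A data frame with columns `name`, `kernel`, `in_channels`,
#'   `out_channels`, `activation`, `stage`.
#' @export
network_inventory <- function(group_conv_depth = 1L) {
  stopifnot(group_conv_depth %in% c(1L, 2L))
  row <- function(name, k, cin, cout, act, stage)
    data.frame(name = name, kernel = k, in_channels = cin,
               out_channels = cout, activation = act, stage = stage,
               stringsAsFactors = FALSE)
  inv <- rbind(
    row("enc_conv1", 3L, 1L, 32L, "relu", "extractor"),
    row("enc_conv2", 3L, 32L, 64L, "relu", "extractor"),
    row("block_in", 1L, 64L, 64L, "relu", "res2net"))
  for (g in 2:4) {
    if (group_conv_depth == 1L) {
      inv <- rbind(inv, row(sprintf("block_g%d", g), 3L, 16L, 16L,
                            "relu", "res2net"))
    } else {
      inv <- rbind(inv,
                   row(sprintf("block_g%d_1", g), 3L, 16L, 16L, "relu", "res2net"),
                   row(sprintf("block_g%d_2", g), 3L, 16L, 16L, "relu", "res2net"))
    }
  }
  rbind(inv,
        row("block_out", 1L, 64L, 64L, "relu", "res2net"),
        row("dec_conv1", 3L, 64L, 64L, "relu", "reconstructor"),
        row("dec_conv2", 3L, 64L, 32L, "relu", "reconstructor"),
        row("dec_conv3", 3L, 32L, 16L, "relu", "reconstructor"),
        row("dec_conv4", 3L, 16L, 1L, "none", "reconstructor"))
}

#' Initialize network parameters
#'
#' Builds every kernel and bias of the layer inventory. Kernels are drawn
#' from a fan-in-scaled uniform distribution (He-style limit
#' `sqrt(6 / (k * k * in_channels))`, appropriate for ReLU layers); biases
#' start at zero. Fully deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param group_conv_depth Passed to [network_inventory()].
#' @return An object of class `network_params`: a named list of layers
#'   (each with kernel array `w` of dim `(k, k, in, out)`, bias `b`,
#'   padding and activation), plus the seed and the inventory.
#' @export
init_params <- function(seed = 0L, group_conv_depth = 1L) {
  inv <- network_inventory(group_conv_depth)
  layers <- with_seed(seed, {
    out <- list()
    for (r in seq_len(nrow(inv))) {
      k <- inv$kernel[r]; cin <- inv$in_channels[r]; cout <- inv$out_channels[r]
      limit <- sqrt(6 / (k * k * cin))
      out[[inv$name[r]]] <- list(
        w = array(runif(k * k * cin * cout, -limit, limit), c(k, k, cin, cout)),
        b = numeric(cout),
        pad = (k - 1L) %/% 2L,
        act = inv$activation[r])
    }
    out
  })
  structure(list(layers = layers, seed = as.integer(seed),
                 group_conv_depth = as.integer(group_conv_depth),
                 inventory = inv),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  n <- sum(vapply(x$layers, function(l) length(l$w) + length(l$b), 0))
  cat(sprintf("<network_params: %d layers, %d parameters, seed %d>\n",
              length(x$layers), n, x$seed))
  invisible(x)
}

# One conv layer forward; x is an (H, W, C) or batched (H, W, C, B) array.
# With keep = TRUE (training), also returns the im2col patch matrix as an
# external pointer so the backward pass reuses it.
conv_fwd <- function(x, layer, keep = FALSE) {
  cpp_conv2d(x, layer$w, layer$b, layer$pad, identical(layer$act, "relu"),
             keep)
}

# Backward through one conv layer. `out` is the stored forward output,
# used in C++ to mask the ReLU derivative before the linear-conv adjoint.
conv_bwd <- function(layer, x_in, out, g_out, patches = NULL,
                     need_gx = TRUE) {
  cpp_conv2d_bwd(x_in, layer$w, g_out, out, layer$pad,
                 identical(layer$act, "relu"), patches, need_gx)
}

# Channel concatenation of (H, W, C_i[, B]) arrays along dim 3.
cat_channels <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[3], 0)
  if (length(d) == 3)
    return(array(unlist(arrs, use.names = FALSE), c(d[1], d[2], sum(cs))))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (a in arrs) {
    out[, , (at + 1L):(at + dim(a)[3]), ] <- a
    at <- at + dim(a)[3]
  }
  out
}

# Channel slice that works for 3-d and batched 4-d activations.
chan_slice <- function(x, idx) {
  if (length(dim(x)) == 3) x[, , idx, drop = FALSE]
  else x[, , idx, , drop = FALSE]
}

# Wrap a (possibly patch-keeping) layer forward into a uniform record.
layer_fwd <- function(x, p, name, keep) {
  r <- conv_fwd(x, p$layers[[name]], keep)
  if (keep) list(x = x, o = r$out, k = r$patches)
  else list(x = x, o = r, k = NULL)
}

layer_bwd <- function(p, name, rec, g_out, need_gx = TRUE) {
  conv_bwd(p$layers[[name]], rec$x, rec$o, g_out, rec$k, need_gx)
}

# Res2Net group transform H_i: one conv, or two stacked when depth 2.
group_fwd <- function(x, p, g, keep = FALSE) {
  if (p$group_conv_depth == 1L) {
    r <- layer_fwd(x, p, sprintf("block_g%d", g), keep)
    list(out = r$o, mids = list(r1 = r))
  } else {
    r1 <- layer_fwd(x, p, sprintf("block_g%d_1", g), keep)
    r2 <- layer_fwd(r1$o, p, sprintf("block_g%d_2", g), keep)
    list(out = r2$o, mids = list(r1 = r1, r2 = r2))
  }
}

group_bwd <- function(p, g, mids, g_out, grads) {
  if (p$group_conv_depth == 1L) {
    nm <- sprintf("block_g%d", g)
    bw <- layer_bwd(p, nm, mids$r1, g_out)
    grads[[nm]] <- list(w = bw$gw, b = bw$gb)
    list(gx = bw$gx, grads = grads)
  } else {
    nm2 <- sprintf("block_g%d_2", g); nm1 <- sprintf("block_g%d_1", g)
    bw2 <- layer_bwd(p, nm2, mids$r2, g_out)
    grads[[nm2]] <- list(w = bw2$gw, b = bw2$gb)
    bw1 <- layer_bwd(p, nm1, mids$r1, bw2$gx)
    grads[[nm1]] <- list(w = bw1$gw, b = bw1$gb)
    list(gx = bw1$gx, grads = grads)
  }
}

res2net_forward <- function(x, p, keep = FALSE) {
  rin <- layer_fwd(x, p, "block_in", keep)
  u <- rin$o
  C <- dim(u)[3]
  gw <- C %/% 4L
  idx <- function(g) ((g - 1L) * gw + 1L):(g * gw)
  xs <- lapply(1:4, function(g) chan_slice(u, idx(g)))
  y1 <- xs[[1]]
  f2 <- group_fwd(xs[[2]], p, 2L, keep)
  z3 <- xs[[3]] + f2$out
  f3 <- group_fwd(z3, p, 3L, keep)
  z4 <- xs[[4]] + f3$out
  f4 <- group_fwd(z4, p, 4L, keep)
  cc <- cat_channels(y1, f2$out, f3$out, f4$out)
  rout <- layer_fwd(cc, p, "block_out", keep)
  list(out = rout$o,
       cache = list(rin = rin, gw = gw, f2 = f2$mids, f3 = f3$mids,
                    f4 = f4$mids, rout = rout))
}

res2net_backward <- function(p, cache, g_out, grads) {
  bw <- layer_bwd(p, "block_out", cache$rout, g_out)
  grads$block_out <- list(w = bw$gw, b = bw$gb)
  gw <- cache$gw
  idx <- function(g) ((g - 1L) * gw + 1L):(g * gw)
  gcc <- bw$gx
  gy <- lapply(1:4, function(g) chan_slice(gcc, idx(g)))
  gu <- array(0, dim(cache$rin$o))
  b4 <- length(dim(gu)) == 4
  assign_chan <- function(arr, idx, val) {
    if (b4) arr[, , idx, ] <- val else arr[, , idx] <- val
    arr
  }
  # group 4: input was x4 + y3
  r4 <- group_bwd(p, 4L, cache$f4, gy[[4]], grads); grads <- r4$grads
  gu <- assign_chan(gu, idx(4), r4$gx)
  g_y3 <- gy[[3]] + r4$gx
  r3 <- group_bwd(p, 3L, cache$f3, g_y3, grads); grads <- r3$grads
  gu <- assign_chan(gu, idx(3), r3$gx)
  g_y2 <- gy[[2]] + r3$gx
  r2 <- group_bwd(p, 2L, cache$f2, g_y2, grads); grads <- r2$grads
  gu <- assign_chan(gu, idx(2), r2$gx)
  gu <- assign_chan(gu, idx(1), gy[[1]])
  bwi <- layer_bwd(p, "block_in", cache$rin, gu)
  grads$block_in <- list(w = bwi$gw, b = bwi$gb)
  list(gx = bwi$gx, grads = grads)
}

#' Res2Net block
#'
#' The hierarchical-residual multiscale block: a 1x1 conv (ReLU) whose
#' output is split channel-wise into four ordered groups; the first group
#' passes through unchanged, each later group is transformed by a 3x3 conv
#' (ReLU) after adding the previous group's output
#' (`y1 = x1`, `y2 = H2(x2)`, `y_i = H_i(x_i + y_{i-1})`); the groups are
#' re-concatenated and passed through a closing 1x1 conv (ReLU). Later
#' groups therefore see progressively larger receptive fields, which is
#' what makes the features multiscale.
#'
#' @param f An (H, W, C) feature array; C must match the block's 1x1 input
#'   width (64 in the standard inventory) and be divisible by 4.
#' @param p `network_params` (or any parameter list with the block layers).
#' @return An (H, W, C) feature array of the same spatial size.
#' @export
res2net_block <- function(f, p) {
  stopifnot(is.array(f), length(dim(f)) == 3)
  cin <- dim(p$layers$block_in$w)[3]
  if (dim(f)[3] != cin)
    stop(sprintf("shape error: block expects %d channels, got %d",
                 cin, dim(f)[3]))
  if (dim(f)[1] < 3 || dim(f)[2] < 3)
    stop("input too small: Res2Net block needs at least 3 x 3")
  res2net_forward(f, p)$out
}

#' Extract multiscale features from an image
#'
#' Applies the feature extractor: Conv3x3 (1 to 32, ReLU), Conv3x3
#' (32 to 64, ReLU), then the Res2Net block. Spatial size is preserved.
#'
#' @param img A `fusion_image` or numeric matrix with values in \[0, 1\].
#' @param p `network_params`.
#' @return An (H, W, 64) non-negative feature array.
#' @export
extract_features <- function(img, p) {
  x <- as_pixel_matrix(img)
  if (!all(is.finite(x))) stop("image contains non-finite pixels")
  if (min(x) < 0 || max(x) > 1) stop("image intensities must lie in [0, 1]")
  if (nrow(x) < 8 || ncol(x) < 8) stop("image must be at least 8 x 8")
  x <- array(x, c(nrow(x), ncol(x), 1L))
  e1 <- conv_fwd(x, p$layers$enc_conv1)
  e2 <- conv_fwd(e1, p$layers$enc_conv2)
  out <- res2net_forward(e2, p)$out
  attr(out, "stage") <- "extractor"
  out
}

#' Reconstruct an image from fused (or raw) features
#'
#' Applies the reconstructor: Conv3x3 64-64, 64-32, 32-16 (ReLU) and a
#' final linear Conv3x3 16-1. The output is clamped to \[0, 1\] and
#' returned as a `fusion_image` tagged `FUSED`.
#'
#' @param f An (H, W, 64) feature array.
#' @param p `network_params`.
#' @return A `fusion_image` of the same spatial size.
#' @export
reconstruct <- function(f, p) {
  cin <- dim(p$layers$dec_conv1$w)[3]
  if (!is.array(f) || length(dim(f)) != 3 || dim(f)[3] != cin)
    stop(sprintf("shape error: reconstructor expects %d channels", cin))
  raw <- reconstruct_raw(f, p)
  fusion_image(pmin(pmax(raw[, , 1], 0), 1), source_tag = "FUSED")
}

# Unclamped reconstructor output; the training loss is computed on this
# (the clamp has zero gradient in saturated regions).
reconstruct_raw <- function(f, p) {
  d1 <- conv_fwd(f, p$layers$dec_conv1)
  d2 <- conv_fwd(d1, p$layers$dec_conv2)
  d3 <- conv_fwd(d2, p$layers$dec_conv3)
  conv_fwd(d3, p$layers$dec_conv4)
}

# Full autoencoder forward with cached intermediates (training path).
# `x` may be a matrix, an (H, W, 1) array, or a batched (H, W, 1, B) array.
net_forward <- function(x, p, keep = TRUE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) == 3 && dim(x)[3] != 1)
    stop("autoencoder input must be single-channel")
  e1 <- layer_fwd(x, p, "enc_conv1", keep)
  e2 <- layer_fwd(e1$o, p, "enc_conv2", keep)
  blk <- res2net_forward(e2$o, p, keep)
  d1 <- layer_fwd(blk$out, p, "dec_conv1", keep)
  d2 <- layer_fwd(d1$o, p, "dec_conv2", keep)
  d3 <- layer_fwd(d2$o, p, "dec_conv3", keep)
  d4 <- layer_fwd(d3$o, p, "dec_conv4", keep)
  list(out = d4$o,
       cache = list(e1 = e1, e2 = e2, blk = blk$cache,
                    d1 = d1, d2 = d2, d3 = d3, d4 = d4))
}

# Backward pass: gradient of a scalar loss wrt every kernel and bias.
net_backward <- function(p, cache, g_out) {
  grads <- list()
  bw4 <- layer_bwd(p, "dec_conv4", cache$d4, g_out)
  grads$dec_conv4 <- list(w = bw4$gw, b = bw4$gb)
  bw3 <- layer_bwd(p, "dec_conv3", cache$d3, bw4$gx)
  grads$dec_conv3 <- list(w = bw3$gw, b = bw3$gb)
  bw2 <- layer_bwd(p, "dec_conv2", cache$d2, bw3$gx)
  grads$dec_conv2 <- list(w = bw2$gw, b = bw2$gb)
  bw1 <- layer_bwd(p, "dec_conv1", cache$d1, bw2$gx)
  grads$dec_conv1 <- list(w = bw1$gw, b = bw1$gb)
  rb <- res2net_backward(p, cache$blk, bw1$gx, grads)
  grads <- rb$grads
  bwe2 <- layer_bwd(p, "enc_conv2", cache$e2, rb$gx)
  grads$enc_conv2 <- list(w = bwe2$gw, b = bwe2$gb)
  bwe1 <- layer_bwd(p, "enc_conv1", cache$e1, bwe2$gx, need_gx = FALSE)
  grads$enc_conv1 <- list(w = bwe1$gw, b = bwe1$gb)
  grads
}
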