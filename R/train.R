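# Two-phase protocol: (1) train extractor + reconstructor as a plain
# reconstruction autoencoder on single images -- the fusion layer does not
# exist in the training graph; (2) freeze the weights and insert the
# parameter-free fusion layer between extractor and reconstructor at
# inference. Optimizer is Adam at the reference learning rate 1e-4.

#' Training configuration
#'
#' @param learning_rate Adam step size (default `1e-4`).
#' @param batch_size Images per gradient step (default 4).
#' @param crop_size Side length of the random square crops (default 256;
#'   must be even and `>= 32`).
#' @param epochs Number of passes over the dataset (default 30, the
#'   desk-scale setting).
#' @param seed Seed controlling initialization, shuffling and crops.
#' @param optimizer_name Only `"adam"` is available.
#' @param device Informational hint (`"cpu"`).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         crop_size = 256L, epochs = 30L, seed = 0L,
                         optimizer_name = "adam", device = "cpu") {
  stopifnot(learning_rate >= 0, batch_size >= 1,
            crop_size >= 32, crop_size %% 2 == 0, epochs >= 1)
  optimizer_name <- match.arg(optimizer_name, "adam")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer_name = optimizer_name, device = device),
            class = "train_config")
}

#' Random square crops from a set of images
#'
#' Takes one `crop_size` x `crop_size` crop at a random offset from each
#' image; images smaller than the crop in either dimension are skipped
#' with a warning. Deterministic for a fixed seed.
#'
#' @param images List of `fusion_image`s or matrices.
#' @param crop_size Side length.
#' @param seed RNG seed.
#' @return List of cropped matrices.
#' @export
make_crops <- function(images, crop_size, seed = 0L) {
  with_seed(seed, {
    out <- list()
    for (img in images) {
      x <- as_pixel_matrix_or_array(img)
      if (nrow(x) < crop_size || ncol(x) < crop_size) {
        warning(sprintf("skipping %dx%d image smaller than crop size %d",
                        nrow(x), ncol(x), crop_size))
        next
      }
      i0 <- sample.int(nrow(x) - crop_size + 1L, 1L)
      j0 <- sample.int(ncol(x) - crop_size + 1L, 1L)
      out[[length(out) + 1]] <-
        x[i0:(i0 + crop_size - 1L), j0:(j0 + crop_size - 1L), drop = FALSE]
    }
    out
  })
}

# Topology order of the single-conv-per-group network, as consumed by the
# C++ whole-network training path.
fast_layer_order <- function() {
  c("enc_conv1", "enc_conv2", "block_in", "block_g2", "block_g3",
    "block_g4", "block_out", "dec_conv1", "dec_conv2", "dec_conv3",
    "dec_conv4")
}

fast_layer_list <- function(params) {
  lapply(fast_layer_order(), function(nm) {
    l <- params$layers[[nm]]
    list(w = l$w, b = l$b, pad = l$pad, relu = identical(l$act, "relu"))
  })
}

adam_init <- function(params) {
  lapply(params$layers, function(l)
    list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (nm in names(params$layers)) {
    g <- grads[[nm]]; st <- state[[nm]]
    st$mw <- beta1 * st$mw + (1 - beta1) * g$w
    st$vw <- beta2 * st$vw + (1 - beta2) * g$w^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params$layers[[nm]]$w <- params$layers[[nm]]$w -
      lr * (st$mw / b1t) / (sqrt(st$vw / b2t) + eps)
    params$layers[[nm]]$b <- params$layers[[nm]]$b -
      lr * (st$mb / b1t) / (sqrt(st$vb / b2t) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the reconstruction autoencoder
#'
#' Phase one of the protocol: every image (CT and MR alike, shuffled
#' jointly) is pushed through extractor and reconstructor and the network
#' is trained to reproduce it under the hybrid SSIM + pixel loss. The
#' fusion layer is never instantiated here. When images are larger than
#' `cfg$crop_size`, one fresh random crop per image is drawn each epoch.
#'
#' @param dataset Nonempty list of `fusion_image`s or matrices (mix the
#'   modalities; both are reconstruction targets).
#' @param cfg A [train_config()].
#' @param params Optional warm-start `network_params` (default: fresh
#'   initialization from `cfg$seed`).
#' @param verbose Print per-epoch losses.
#' @return List with `params` (trained `network_params`) and `history`
#'   (class `train_history`: per-epoch mean total/ssim/pixel loss and
#'   wall-clock seconds, plus the operation names of the training graph).
#' @export
train_autoencoder <- function(dataset, cfg = train_config(), params = NULL,
                              verbose = FALSE) {
  if (length(dataset) == 0) stop("usage error: empty dataset")
  mats <- lapply(dataset, as_pixel_matrix_or_array)
  if (is.null(params)) params <- init_params(cfg$seed, 1L)
  fast <- params$group_conv_depth == 1L
  net_state <- NULL
  state <- adam_init(params)
  step <- 0L
  hist <- data.frame(epoch = integer(), total = numeric(), ssim = numeric(),
                     pixel = numeric(), seconds = numeric())
  sub_seeds <- derive_seeds(cfg$seed + 1L, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- Sys.time()
    epoch_imgs <- mats
    needs_crop <- any(vapply(mats, function(m)
      nrow(m) > cfg$crop_size || ncol(m) > cfg$crop_size, logical(1)))
    if (needs_crop)
      epoch_imgs <- make_crops(mats, cfg$crop_size, seed = sub_seeds[ep])
    ord <- with_seed(sub_seeds[ep] + 1L, sample(length(epoch_imgs)))
    epoch_imgs <- epoch_imgs[ord]
    ep_tot <- ep_ssim <- ep_pix <- 0; n_batches <- 0L
    dims <- unique(lapply(epoch_imgs, dim))
    if (length(dims) > 1)
      stop("training images must share a size (set crop_size to the ",
           "smallest image side)")
    for (b0 in seq(1, length(epoch_imgs), by = cfg$batch_size)) {
      batch <- epoch_imgs[b0:min(b0 + cfg$batch_size - 1L, length(epoch_imgs))]
      xarr <- array(unlist(batch, use.names = FALSE),
                    c(dims[[1]][1], dims[[1]][2], 1L, length(batch)))
      if (fast) {
        fl <- fast_layer_list(params)
        fwd <- cpp_net_forward_fast(fl, xarr, net_state)
        net_state <- fwd$state
        out <- fwd$out
      } else {
        fwd <- net_forward(xarr, params)
        out <- fwd$out
      }
      loss <- hybrid_loss(out, xarr)
      if (!is.finite(loss$total))
        stop(sprintf("non-finite loss at epoch %d (total=%g); aborting",
                     ep, loss$total))
      garr <- array(unlist(hybrid_loss_grad(out, xarr),
                           use.names = FALSE), dim(xarr))
      grads <- if (fast)
        stats::setNames(cpp_net_backward_fast(fl, net_state, garr),
                        fast_layer_order())
      else net_backward(params, fwd$cache, garr)
      step <- step + 1L
      upd <- adam_step(params, grads, state, cfg$learning_rate, step)
      params <- upd$params; state <- upd$state
      ep_tot <- ep_tot + loss$total; ep_ssim <- ep_ssim + loss$ssim_term
      ep_pix <- ep_pix + loss$pixel_term; n_batches <- n_batches + 1L
    }
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    hist <- rbind(hist, data.frame(epoch = ep, total = ep_tot / n_batches,
                                   ssim = ep_ssim / n_batches,
                                   pixel = ep_pix / n_batches,
                                   seconds = secs))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f (ssim %.5f pixel %.5f) %.1fs",
                      ep, ep_tot / n_batches, ep_ssim / n_batches,
                      ep_pix / n_batches, secs))
  }
  history <- structure(list(epochs = hist,
                            graph_ops = c("extract_features", "reconstruct",
                                          "hybrid_loss"),
                            config = cfg),
                       class = "train_history")
  list(params = params, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  n <- nrow(x$epochs)
  cat(sprintf("<train_history: %d epochs, loss %.5f -> %.5f>\n",
              n, x$epochs$total[1], x$epochs$total[n]))
  invisible(x)
}

#' Fuse a registered CT/MR pair
#'
#' Phase two of the protocol: both images pass through the (frozen)
#' feature extractor, the feature maps are combined by the chosen fusion
#' strategy, and the reconstructor decodes the fused features into the
#' fused image.
#'
#' @param ct,mr Registered same-size images.
#' @param p Trained `network_params`.
#' @param strategy One of [fusion_strategies()].
#' @param ... Passed to [compute_weight_maps()] for `mean_attention`.
#' @return A `fusion_image` tagged `FUSED`, same size as the inputs.
#' @export
fuse_pair <- function(ct, mr, p, strategy = "mean_attention", ...) {
  xct <- as_pixel_matrix_or_array(ct)
  xmr <- as_pixel_matrix_or_array(mr)
  if (!identical(dim(xct), dim(xmr)))
    stop("registration error: CT and MR sizes differ; inputs must be ",
         "pre-registered and equal-sized")
  f_ct <- extract_features(xct, p)
  f_mr <- extract_features(xmr, p)
  fused <- apply_fusion_strategy(list(f_ct, f_mr), strategy, ...)
  reconstruct(fused, p)
}

#' Save network parameters to a checkpoint file
#'
#' One archive holding every layer tensor keyed by the inventory names,
#' the initialization seed and a configuration hash.
#'
#' @param params `network_params`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  payload <- list(layers = params$layers, seed = params$seed,
                  group_conv_depth = params$group_conv_depth,
                  inventory = params$inventory,
                  config_hash = config_hash(params),
                  package_version = as.character(utils::packageVersion("res2fuse")))
  saveRDS(payload, path)
  invisible(path)
}

config_hash <- function(params) {
  key <- paste(names(params$layers),
               vapply(params$layers, function(l) paste(dim(l$w), collapse = "x"), ""),
               collapse = ";")
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 1000000L
}

#' Load network parameters from a checkpoint file
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return `network_params`.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  structure(list(layers = payload$layers, seed = payload$seed,
                 group_conv_depth = payload$group_conv_depth,
                 inventory = payload$inventory),
            class = "network_params")
}
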