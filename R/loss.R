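# Hybrid training loss: L = L_ssim + L_pixel with unit weights.
# L_ssim = 1 - SSIM(fused, input) keeps structure and texture;
# L_pixel = mean squared element-wise difference keeps pixel fidelity.
# SSIM uses the de-facto standard 11x11 Gaussian window (sigma 1.5),
# c1 = (0.01 L)^2, c2 = (0.03 L)^2 with L = 1 on normalized intensities,
# averaged over valid windows.

ssim_c1 <- 0.01^2
ssim_c2 <- 0.03^2
ssim_window <- function() gaussian_kernel(11L, 1.5)

# Coerce a batch (matrix, (H,W,C) or (H,W,C,B) array, list of either,
# fusion_image) to a list of (H, W, C) arrays.
as_image_batch <- function(x) {
  one <- function(a) {
    a <- as_pixel_matrix_or_array(a)
    if (is.matrix(a)) array(a, c(nrow(a), ncol(a), 1L)) else a
  }
  if (is.list(x)) return(lapply(x, one))
  if (is.array(x) && length(dim(x)) == 4)
    return(lapply(seq_len(dim(x)[4]), function(b) x[, , , b, drop = TRUE] |>
                    array(dim(x)[1:3])))
  list(one(x))
}

as_pixel_matrix_or_array <- function(a) {
  if (inherits(a, "fusion_image")) as_pixel_matrix(a) else a
}

check_same_batch <- function(f, x) {
  if (length(f) != length(x)) stop("shape error: batch sizes differ")
  for (b in seq_along(f))
    if (!identical(dim(f[[b]]), dim(x[[b]])))
      stop("shape error: fused and input shapes differ")
}

# Windowed SSIM index of two matrices (mean over valid windows).
ssim_index <- function(x, y, window = ssim_window()) {
  st <- ssim_stats(x, y, window)
  mean(st$s)
}

ssim_stats <- function(x, y, window) {
  G <- function(m) cpp_sepfilter2(m, window, "valid")
  mu_x <- G(x); mu_y <- G(y)
  ex2 <- G(x * x); ey2 <- G(y * y); exy <- G(x * y)
  sx2 <- ex2 - mu_x^2; sy2 <- ey2 - mu_y^2; sxy <- exy - mu_x * mu_y
  a1 <- 2 * mu_x * mu_y + ssim_c1
  a2 <- 2 * sxy + ssim_c2
  b1 <- mu_x^2 + mu_y^2 + ssim_c1
  b2 <- sx2 + sy2 + ssim_c2
  list(mu_x = mu_x, mu_y = mu_y, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       s = (a1 * a2) / (b1 * b2))
}

# Analytic gradient of mean-window SSIM(x, y) with respect to x.
# The three filtered statistics that depend on x (mu_x, E[x^2], E[xy])
# are backpropagated through the valid-mode Gaussian correlation; its
# adjoint is full-mode correlation with the same (symmetric) kernel.
ssim_grad_x <- function(x, y, window = ssim_window()) {
  st <- ssim_stats(x, y, window)
  d <- st$b1 * st$b2
  dS_da1 <- st$a2 / d
  dS_da2 <- st$a1 / d
  dS_db1 <- -st$s / st$b1
  dS_db2 <- -st$s / st$b2
  dS_dmux <- dS_da1 * 2 * st$mu_y + dS_da2 * (-2 * st$mu_y) +
    dS_db1 * 2 * st$mu_x + dS_db2 * (-2 * st$mu_x)
  dS_dex2 <- dS_db2
  dS_dexy <- 2 * dS_da2
  Gt <- function(m) cpp_sepfilter2(m, window, "full")
  g <- Gt(dS_dmux) + 2 * x * Gt(dS_dex2) + y * Gt(dS_dexy)
  g / length(st$s)
}

#' Structural-similarity loss
#'
#' `1 - SSIM(fused, input)`, averaged over batch elements and channels.
#' Values lie in \[0, 2\] (SSIM is bounded by \[-1, 1\]); 0 iff the images
#' are structurally identical.
#'
#' @param fused,input Image batches: a matrix, `fusion_image`, an
#'   (H, W, C) or (H, W, C, B) array, or a list of these.
#' @return A scalar loss.
#' @export
ssim_loss <- function(fused, input) {
  f <- as_image_batch(fused); x <- as_image_batch(input)
  check_same_batch(f, x)
  vals <- unlist(lapply(seq_along(f), function(b) {
    vapply(seq_len(dim(f[[b]])[3]), function(ch)
      ssim_index(f[[b]][, , ch], x[[b]][, , ch]), 0)
  }))
  1 - mean(vals)
}

#' Pixel (mean-squared-error) loss
#'
#' `(1 / (B * C * H * W)) * || fused - input ||_2^2`: the mean squared
#' element-wise difference over the whole batch.
#'
#' @inheritParams ssim_loss
#' @return A scalar loss, `>= 0`.
#' @export
pixel_loss <- function(fused, input) {
  f <- as_image_batch(fused); x <- as_image_batch(input)
  check_same_batch(f, x)
  num <- sum(vapply(seq_along(f),
                    function(b) sum((f[[b]] - x[[b]])^2), 0))
  den <- sum(vapply(f, length, 0))
  num / den
}

#' Hybrid reconstruction loss
#'
#' `L = L_ssim + L_pixel` with unit weights; the loss the autoencoder is
#' trained with.
#'
#' @inheritParams ssim_loss
#' @return An object of class `loss_value`: list with `total`,
#'   `ssim_term`, `pixel_term`.
#' @export
hybrid_loss <- function(fused, input) {
  s <- ssim_loss(fused, input)
  p <- pixel_loss(fused, input)
  structure(list(total = s + p, ssim_term = s, pixel_term = p),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("hybrid loss %.6f (ssim %.6f + pixel %.6f)\n",
              x$total, x$ssim_term, x$pixel_term))
  invisible(x)
}

# Gradient of the hybrid loss wrt the fused batch: list of (H, W, C)
# arrays matching the batch layout.
hybrid_loss_grad <- function(fused, input) {
  f <- as_image_batch(fused); x <- as_image_batch(input)
  check_same_batch(f, x)
  n_total <- sum(vapply(f, length, 0))
  n_maps <- sum(vapply(f, function(a) dim(a)[3], 0L))
  lapply(seq_along(f), function(b) {
    g <- array(0, dim(f[[b]]))
    for (ch in seq_len(dim(f[[b]])[3])) {
      g[, , ch] <- 2 * (f[[b]][, , ch] - x[[b]][, , ch]) / n_total -
        ssim_grad_x(f[[b]][, , ch], x[[b]][, , ch]) / n_maps
    }
    g
  })
}
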