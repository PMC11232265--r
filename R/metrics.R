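# Fusion-quality metrics. Conventions (recorded per report):
#  - AG and SF are computed on the [0, 1] intensity scale;
#  - EN and MI quantize to `levels` equal-width bins (default 256);
#  - PSNR's peak defaults to the fused image's own maximum (`fused_max`),
#    with the conventional full-scale peak available;
#  - SSIM uses the 11x11 Gaussian window (sigma 1.5) two-term closed form;
#  - Qabf uses the Xydeas-Petrovic sigmoid constants;
#  - VIFF is the 4-scale pixel-domain visual-information-fidelity ratio,
#    averaged over the two sources.

#' Average gradient (AG)
#'
#' Mean local gradient magnitude,
#' `AG = mean over (M-1)(N-1) pixels of sqrt((dx^2 + dy^2) / 2)`,
#' with forward differences along rows and columns. A sharpness proxy:
#' larger is sharper.
#'
#' @param f A `fusion_image` or numeric matrix (at least 2 x 2).
#' @return A scalar.
#' @export
average_gradient <- function(f) {
  x <- as_pixel_matrix_or_array(f)
  m <- nrow(x); n <- ncol(x)
  if (m < 2 || n < 2) stop("size error: AG needs at least a 2 x 2 image")
  dr <- x[2:m, 1:(n - 1), drop = FALSE] - x[1:(m - 1), 1:(n - 1), drop = FALSE]
  dc <- x[1:(m - 1), 2:n, drop = FALSE] - x[1:(m - 1), 1:(n - 1), drop = FALSE]
  mean(sqrt((dr^2 + dc^2) / 2))
}

#' Spatial frequency (SF)
#'
#' Root-mean-square of first differences along rows (RF) and columns (CF),
#' `SF = sqrt(RF^2 + CF^2)`, a texture-richness proxy. Differences run
#' over valid index pairs; the normalization is `1/(MN)`.
#'
#' @inheritParams average_gradient
#' @param components If `TRUE`, return `c(rf, cf, sf)`.
#' @return A scalar (or named vector when `components`).
#' @export
spatial_frequency <- function(f, components = FALSE) {
  x <- as_pixel_matrix_or_array(f)
  m <- nrow(x); n <- ncol(x)
  if (m < 2 || n < 2) stop("size error: SF needs at least a 2 x 2 image")
  rf <- sqrt(sum((x[, 2:n, drop = FALSE] - x[, 1:(n - 1), drop = FALSE])^2) / (m * n))
  cf <- sqrt(sum((x[2:m, , drop = FALSE] - x[1:(m - 1), , drop = FALSE])^2) / (m * n))
  sf <- sqrt(rf^2 + cf^2)
  if (components) c(rf = rf, cf = cf, sf = sf) else sf
}

# Quantize [0, 1] intensities to integer levels 0 .. levels-1
# (equal-width bins).
quantize_levels <- function(x, levels = 256L) {
  pmin(floor(x * levels), levels - 1L)
}

#' Shannon entropy of the intensity histogram (EN)
#'
#' `EN = -sum p_n log2 p_n` over the normalized histogram of the image
#' quantized to `levels` gray levels, in bits; `0 * log 0 = 0`.
#'
#' @inheritParams average_gradient
#' @param levels Gray-level count (default taken from the image, else 256).
#' @return Entropy in bits, in `[0, log2(levels)]`.
#' @export
image_entropy <- function(f, levels = NULL) {
  levels <- as.integer(levels %||% image_levels(f))
  q <- quantize_levels(as_pixel_matrix_or_array(f), levels)
  p <- tabulate(q + 1L, nbins = levels) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Joint entropy of two images from the 2-d co-occurrence histogram.
joint_entropy <- function(a, b, levels = 256L) {
  qa <- quantize_levels(as_pixel_matrix_or_array(a), levels)
  qb <- quantize_levels(as_pixel_matrix_or_array(b), levels)
  if (!identical(dim(qa), dim(qb))) stop("shape error: sizes differ")
  idx <- as.vector(qa) * levels + as.vector(qb) + 1
  p <- tabulate(idx, nbins = levels^2) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a fused image with its sources (MI)
#'
#' In `fusion_standard` mode (default), the sum of the two pairwise mutual
#' informations between the fused image and each source:
#' `MI = I(a; f) + I(b; f)` with `I(x; y) = EN(x) + EN(y) - EN(x, y)`
#' from joint histograms. `pair_literal` mode evaluates the single pair
#' term `EN(a) + EN(b) - EN(a, b)` between the two sources only.
#'
#' @param f,a,b Fused image and the two sources, same size.
#' @param mode `"fusion_standard"` or `"pair_literal"`.
#' @param levels Shared gray-level count (default 256).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(f, a, b, mode = c("fusion_standard", "pair_literal"),
                               levels = 256L) {
  mode <- match.arg(mode)
  mi <- function(x, y)
    image_entropy(x, levels) + image_entropy(y, levels) -
      joint_entropy(x, y, levels)
  if (mode == "pair_literal") return(mi(a, b))
  mi(a, f) + mi(b, f)
}

#' Peak signal-to-noise ratio of a fused image (PSNR)
#'
#' `MSE` is the mean of the two source-vs-fused mean squared errors;
#' `PSNR = 10 log10(r^2 / MSE)` in dB. The peak `r` defaults to the fused
#' image's own maximum (`fused_max`); `full_scale` uses `r = 1`.
#' Returns `Inf` when `MSE = 0`.
#'
#' @inheritParams mutual_information
#' @param peak `"fused_max"` or `"full_scale"`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(f, a, b, peak = c("fused_max", "full_scale")) {
  peak <- match.arg(peak)
  xf <- as_pixel_matrix_or_array(f)
  xa <- as_pixel_matrix_or_array(a)
  xb <- as_pixel_matrix_or_array(b)
  if (!identical(dim(xf), dim(xa)) || !identical(dim(xf), dim(xb)))
    stop("shape error: sizes differ")
  mse <- (mean((xa - xf)^2) + mean((xb - xf)^2)) / 2
  r <- if (peak == "fused_max") max(xf) else 1
  if (mse == 0) return(Inf)
  10 * log10(r^2 / mse)
}

#' Structural similarity of a fused image with its sources (SSIM)
#'
#' The mean of the windowed SSIM indices between the fused image and each
#' source: `(SSIM(a, f) + SSIM(b, f)) / 2`, with an 11x11 Gaussian window
#' (sigma 1.5) and the standard two-term closed form
#' (`c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, `c3 = c2 / 2` collapsed).
#'
#' @inheritParams mutual_information
#' @return SSIM in \[-1, 1\].
#' @export
ssim_fusion <- function(f, a, b) {
  xf <- as_pixel_matrix_or_array(f)
  xa <- as_pixel_matrix_or_array(a)
  xb <- as_pixel_matrix_or_array(b)
  if (!identical(dim(xf), dim(xa)) || !identical(dim(xf), dim(xb)))
    stop("shape error: sizes differ")
  (ssim_index(xa, xf) + ssim_index(xb, xf)) / 2
}

# Sobel gradients with edge-replicated padding, so constant images have
# zero edge strength everywhere and image borders do not register as
# spurious edges.
sobel_edges <- function(x) {
  H <- nrow(x); W <- ncol(x)
  xp <- x[c(1, 1:H, H), c(1, 1:W, W)]
  n <- function(u, v) xp[(u + 2):(H + u + 1), (v + 2):(W + v + 1)]
  gx <- (n(-1, 1) + 2 * n(0, 1) + n(1, 1)) -
    (n(-1, -1) + 2 * n(0, -1) + n(1, -1))
  gy <- (n(1, -1) + 2 * n(1, 0) + n(1, 1)) -
    (n(-1, -1) + 2 * n(-1, 0) + n(-1, 1))
  g <- sqrt(gx^2 + gy^2)
  alpha <- ifelse(gx == 0, pi / 2, atan(gy / gx))
  list(g = g, alpha = alpha)
}

# Per-pixel edge-preservation factor between a source and the fused image.
qabf_preservation <- function(src, fus) {
  Tg <- 0.9994; kg <- -15; Dg <- 0.5
  Ta <- 0.9879; ka <- -22; Da <- 0.8
  G <- ifelse(src$g > fus$g, fus$g / src$g,
              ifelse(src$g == fus$g, as.numeric(src$g != 0),
                     src$g / fus$g))
  G[!is.finite(G)] <- 0
  A <- 1 - abs(src$alpha - fus$alpha) / (pi / 2)
  Qg <- Tg / (1 + exp(kg * (G - Dg)))
  Qa <- Ta / (1 + exp(ka * (A - Da)))
  Qg * Qa
}

#' Edge-preservation fusion quality (Qabf)
#'
#' The Xydeas-Petrovic index: Sobel edge strength and orientation are
#' computed per image; per-pixel preservation factors from relative
#' strength and orientation agreement (sigmoid constants Tg = 0.9994,
#' kg = -15, Dg = 0.5; Ta = 0.9879, ka = -22, Da = 0.8) are combined,
#' weighted by the source edge strengths. Values lie in \[0, 1\].
#'
#' @inheritParams mutual_information
#' @return Qabf in \[0, 1\].
#' @export
qabf <- function(f, a, b) {
  xf <- as_pixel_matrix_or_array(f)
  xa <- as_pixel_matrix_or_array(a)
  xb <- as_pixel_matrix_or_array(b)
  if (!identical(dim(xf), dim(xa)) || !identical(dim(xf), dim(xb)))
    stop("shape error: sizes differ")
  ef <- sobel_edges(xf); ea <- sobel_edges(xa); eb <- sobel_edges(xb)
  qaf <- qabf_preservation(ea, ef)
  qbf <- qabf_preservation(eb, ef)
  wa <- ea$g; wb <- eb$g
  den <- sum(wa + wb)
  if (den == 0) return(0)
  sum(qaf * wa + qbf * wb) / den
}

# Multi-scale pixel-domain VIF information ratio between a reference and
# a distorted image (GSM model, 4 scales). Intensities on the 0..255
# scale; visual-noise variance sigma_nsq = 2 as is conventional.
vif_ratio <- function(ref, dist, sigma_nsq = 2) {
  ref <- ref * 255; dist <- dist * 255
  num <- 0; den <- 0
  pyr <- gaussian_kernel(5L, 1)
  for (scale in 1:4) {
    if (scale > 1) {
      ref <- cpp_sepfilter2(ref, pyr, "same_reflect")
      dist <- cpp_sepfilter2(dist, pyr, "same_reflect")
      keep_r <- seq(1, nrow(ref), by = 2); keep_c <- seq(1, ncol(ref), by = 2)
      ref <- ref[keep_r, keep_c, drop = FALSE]
      dist <- dist[keep_r, keep_c, drop = FALSE]
    }
    n <- 2^(4 - scale + 1) + 1
    if (nrow(ref) < n || ncol(ref) < n)
      stop("size error: image too small for the VIF pyramid")
    win <- gaussian_kernel(as.integer(n), n / 5)
    Gf <- function(m) cpp_sepfilter2(m, win, "valid")
    mu1 <- Gf(ref); mu2 <- Gf(dist)
    s1 <- pmax(Gf(ref * ref) - mu1^2, 0)
    s2 <- pmax(Gf(dist * dist) - mu2^2, 0)
    s12 <- Gf(ref * dist) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    g[s1 < 1e-10] <- 0; sv[s1 < 1e-10] <- s2[s1 < 1e-10]; s1[s1 < 1e-10] <- 0
    g[s2 < 1e-10] <- 0; sv[s2 < 1e-10] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(1)
  num / den
}

#' Visual information fidelity for fusion (VIFF)
#'
#' Multi-scale visual-information-fidelity measure of how much source
#' information survives in the fused image: the GSM-model information
#' ratio is computed over a 4-scale Gaussian pyramid between each source
#' and the fused image and averaged over the two sources (symmetric in
#' the sources; equal to 1 when the fused image reproduces both).
#'
#' @inheritParams mutual_information
#' @return VIFF (around \[0, 1\]; 1 means full fidelity).
#' @export
viff <- function(f, a, b) {
  xf <- as_pixel_matrix_or_array(f)
  xa <- as_pixel_matrix_or_array(a)
  xb <- as_pixel_matrix_or_array(b)
  if (!identical(dim(xf), dim(xa)) || !identical(dim(xf), dim(xb)))
    stop("shape error: sizes differ")
  if (nrow(xf) < 32 || ncol(xf) < 32)
    stop("size error: VIFF needs at least a 32 x 32 image")
  (vif_ratio(xa, xf) + vif_ratio(xb, xf)) / 2
}

#' All eight metrics for one fused image
#'
#' @inheritParams mutual_information
#' @param psnr_peak,mi_mode Conventions passed to [psnr()] and
#'   [mutual_information()].
#' @return A one-row data frame with columns `ag`, `sf`, `en`, `mi`,
#'   `psnr`, `ssim`, `qabf`, `viff`.
#' @export
evaluate_pair <- function(f, a, b, psnr_peak = "fused_max",
                          mi_mode = "fusion_standard") {
  data.frame(ag = average_gradient(f),
             sf = spatial_frequency(f),
             en = image_entropy(f),
             mi = mutual_information(f, a, b, mode = mi_mode),
             psnr = psnr(f, a, b, peak = psnr_peak),
             ssim = ssim_fusion(f, a, b),
             qabf = qabf(f, a, b),
             viff = viff(f, a, b))
}

#' Metric table over a batch of fusion triples
#'
#' @param triples List of `list(f = , a = , b = )` triples (fused image
#'   plus its two sources).
#' @param ... Passed to [evaluate_pair()].
#' @return A data frame with one row per triple plus a final `mean` row.
#' @export
evaluate_batch <- function(triples, ...) {
  if (length(triples) == 0) stop("usage error: empty batch")
  rows <- do.call(rbind, lapply(triples, function(tr)
    evaluate_pair(tr$f, tr$a, tr$b, ...)))
  out <- rbind(rows, colMeans(rows))
  rownames(out) <- c(sprintf("pair_%d", seq_along(triples)), "mean")
  out
}

#' Two-sided paired t-test on per-image metric columns
#'
#' Wraps [stats::t.test()] with `paired = TRUE`. When the paired
#' differences have zero variance (where the t statistic is undefined),
#' returns `p = 0` if the mean difference is nonzero and `p = 1` if it is
#' zero, with a warning.
#'
#' @param col_x,col_y Numeric vectors of equal length `>= 2`.
#' @return List with elements `t` and `p`.
#' @export
paired_t_test <- function(col_x, col_y) {
  if (length(col_x) != length(col_y) || length(col_x) < 2)
    stop("usage error: columns must have equal length >= 2")
  d <- col_x - col_y
  if (sd(d) == 0) {
    warning("zero-variance paired differences; degenerate t-test")
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(col_x, col_y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
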