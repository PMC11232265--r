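# Synthetic registered CT/MR head-phantom pairs. The generator emulates
# the modality contrast the fusion method exploits: CT shows a bright
# high-density skull ring with low soft-tissue/lesion contrast; MR shows
# a dark skull, bright lesions and textured soft tissue. Both renders of
# a pair derive from one label map, so they are registered by construction.

PH_BACKGROUND <- 0L
PH_SKULL <- 1L
PH_SOFT <- 2L
PH_VENTRICLE <- 3L
PH_TUMOR <- 4L

#' Generate a random head-phantom label map
#'
#' Builds an elliptical head with a closed skull ring (thickness 2-6 px),
#' soft tissue inside, a small central ventricle and 0-2 circular tumors
#' (radius 5-15 % of the image size) placed strictly inside the soft
#' tissue. Deterministic for a fixed seed.
#'
#' @param size Image side length in pixels (`>= 64`).
#' @param seed Integer RNG seed.
#' @return An object of class `anatomy_phantom`: list with the integer
#'   `label_map` (0 background, 1 skull, 2 soft tissue, 3 ventricle,
#'   4 tumor), the sampled `geometry`, `size` and `seed`.
#' @export
generate_anatomy <- function(size = 128L, seed = 0L) {
  size <- as.integer(size)
  if (size < 64) stop("usage error: phantom size must be at least 64")
  geom <- with_seed(seed, {
    cx <- size / 2 + runif(1, -0.02, 0.02) * size
    cy <- size / 2 + runif(1, -0.02, 0.02) * size
    ax <- runif(1, 0.32, 0.42) * size
    ay <- runif(1, 0.32, 0.42) * size
    thick <- runif(1, 2, 6)
    vent_ax <- runif(1, 0.05, 0.08) * size
    vent_ay <- runif(1, 0.08, 0.12) * size
    n_tumor <- sample(0:2, 1)
    tumors <- list()
    for (t in seq_len(n_tumor)) {
      r <- runif(1, 0.05, 0.15) * size
      for (try in 1:100) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, 0.75)
        tx <- cx + rad * (ax - thick) * cos(ang)
        ty <- cy + rad * (ay - thick) * sin(ang)
        # fits strictly inside the inner (soft-tissue) ellipse?
        margin <- sqrt(((tx - cx) / (ax - thick - r - 1))^2 +
                         ((ty - cy) / (ay - thick - r - 1))^2)
        # stays clear of the ventricle?
        vent_d <- sqrt(((tx - cx) / (vent_ax + r))^2 +
                         ((ty - cy) / (vent_ay + r))^2)
        if (is.finite(margin) && margin < 1 && vent_d > 1.1) {
          tumors[[length(tumors) + 1]] <- list(x = tx, y = ty, r = r)
          break
        }
      }
    }
    list(cx = cx, cy = cy, ax = ax, ay = ay, thick = thick,
         vent_ax = vent_ax, vent_ay = vent_ay, tumors = tumors)
  })
  ii <- matrix(rep(seq_len(size), size), size, size)        # row coord
  jj <- t(ii)                                               # column coord
  lab <- matrix(PH_BACKGROUND, size, size)
  inside <- function(ax, ay) ((ii - geom$cx) / ax)^2 + ((jj - geom$cy) / ay)^2 <= 1
  head_mask <- inside(geom$ax, geom$ay)
  inner_mask <- inside(geom$ax - geom$thick, geom$ay - geom$thick)
  lab[head_mask] <- PH_SKULL
  lab[inner_mask] <- PH_SOFT
  lab[inside(geom$vent_ax, geom$vent_ay) & inner_mask] <- PH_VENTRICLE
  for (tm in geom$tumors) {
    tmask <- (ii - tm$x)^2 + (jj - tm$y)^2 <= tm$r^2
    lab[tmask & inner_mask] <- PH_TUMOR
  }
  structure(list(label_map = lab, geometry = geom, size = size,
                 seed = as.integer(seed)),
            class = "anatomy_phantom")
}

#' @export
print.anatomy_phantom <- function(x, ...) {
  cat(sprintf("<anatomy_phantom %dx%d, %d tumor(s), seed %d>\n",
              x$size, x$size, length(x$geometry$tumors), x$seed))
  invisible(x)
}

phantom_render <- function(ph, intensities, smooth_sigma, noise_sd, seed,
                           texture_amp = 0, texture_sigma = 3, tag = "OTHER") {
  lab <- ph$label_map
  img <- matrix(intensities[lab + 1L], nrow(lab), ncol(lab))
  img <- with_seed(seed, {
    if (texture_amp > 0) {
      tex <- gaussian_smooth(matrix(rnorm(length(lab)), nrow(lab)), texture_sigma)
      tex <- tex / max(sd(tex), 1e-12) * texture_amp
      img[lab == PH_SOFT] <- img[lab == PH_SOFT] + tex[lab == PH_SOFT]
    }
    img <- gaussian_smooth(img, smooth_sigma)
    if (noise_sd > 0)
      img <- img + matrix(rnorm(length(img), sd = noise_sd), nrow(img))
    img
  })
  fusion_image(pmin(pmax(img, 0), 1), source_tag = tag)
}

#' Render the CT view of a phantom
#'
#' High-density bone is bright (skull about 0.95) while soft tissue
#' (0.35), tumor (0.38) and ventricle (0.25) are dark with low lesion
#' contrast, mirroring the electron-density contrast of CT. Gaussian
#' smoothing plus seeded additive Gaussian noise, clipped to \[0, 1\].
#'
#' @param ph An `anatomy_phantom`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise (defaults to the phantom's seed).
#' @return A `fusion_image` tagged `CT`.
#' @export
render_ct <- function(ph, noise_sd = 0.01, seed = ph$seed + 1L) {
  stopifnot(inherits(ph, "anatomy_phantom"))
  phantom_render(ph,
                 intensities = c(0, 0.95, 0.35, 0.25, 0.38),
                 smooth_sigma = 0.4, noise_sd = noise_sd, seed = seed,
                 tag = "CT")
}

#' Render the MR view of a phantom
#'
#' Bone is dark (skull about 0.05); soft tissue (0.55) carries a smooth
#' random texture field of amplitude `texture_amp`; the tumor is bright
#' (0.85) with a sharp boundary (light smoothing); ventricle 0.2. Noise
#' and clipping as in [render_ct()].
#'
#' @inheritParams render_ct
#' @param texture_amp Amplitude (standard deviation) of the soft-tissue
#'   texture field.
#' @param texture_sigma Correlation length of the texture field in
#'   pixels; the default 1.2 px gives the fine-grained parenchymal
#'   texture that distinguishes MR from the smooth CT soft tissue.
#' @return A `fusion_image` tagged `MR`.
#' @export
render_mr <- function(ph, noise_sd = 0.01, texture_amp = 0.15,
                      texture_sigma = 1.2, seed = ph$seed + 2L) {
  stopifnot(inherits(ph, "anatomy_phantom"))
  phantom_render(ph,
                 intensities = c(0, 0.05, 0.55, 0.2, 0.85),
                 smooth_sigma = 0.5, noise_sd = noise_sd, seed = seed,
                 texture_amp = texture_amp, texture_sigma = texture_sigma,
                 tag = "MR")
}

#' Generate a dataset of registered CT/MR phantom pairs
#'
#' Draws `n_pairs` distinct phantoms (sub-seeds derived deterministically
#' from the master seed) and renders both modalities of each.
#'
#' @param n_pairs Number of pairs (`>= 1`).
#' @param size Image side length.
#' @param seed Master seed.
#' @param noise_sd,texture_amp Render settings.
#' @return A list of `list(ct = , mr = , ph = )` entries.
#' @export
generate_dataset <- function(n_pairs, size = 128L, seed = 0L,
                             noise_sd = 0.01, texture_amp = 0.15) {
  if (n_pairs < 1) stop("usage error: n_pairs must be >= 1")
  seeds <- derive_seeds(seed, n_pairs)
  lapply(seq_len(n_pairs), function(i) {
    ph <- generate_anatomy(size, seeds[i])
    list(ct = render_ct(ph, noise_sd = noise_sd),
         mr = render_mr(ph, noise_sd = noise_sd, texture_amp = texture_amp),
         ph = ph)
  })
}
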