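# Independent brute-force oracles, written directly from the definitions
# with plain nested loops and base R only. They share no code with the
# package implementation.

# Direct stride-1 zero-padded 2-d convolution (correlation) of an
# (H, W, Cin) array with a (kh, kw, Cin, Cout) kernel stack.
oracle_conv2d <- function(x, w, b, pad, relu = TRUE) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  out <- array(0, c(H, W, cout))
  for (oc in seq_len(cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- b[oc]
      for (c in seq_len(cin)) for (a in seq_len(kh)) for (d in seq_len(kw)) {
        ii <- i + a - 1 - pad; jj <- j + d - 1 - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          acc <- acc + x[ii, jj, c] * w[a, d, c, oc]
      }
      out[i, j, oc] <- acc
    }
  }
  if (relu) out[out < 0] <- 0
  out
}

# Hierarchical-residual block evaluated exactly as written:
# y1 = x1, y2 = H2(x2), y_i = H_i(x_i + y_{i-1}); groups are equal
# channel splits of the opening 1x1 conv's ReLU output.
oracle_res2net <- function(x, p) {
  u <- oracle_conv2d(x, p$layers$block_in$w, p$layers$block_in$b, 0)
  C <- dim(u)[3]; gw <- C / 4
  grp <- function(g) u[, , ((g - 1) * gw + 1):(g * gw), drop = FALSE]
  hconv <- function(z, g) {
    l <- p$layers[[sprintf("block_g%d", g)]]
    oracle_conv2d(z, l$w, l$b, 1)
  }
  y1 <- grp(1)
  y2 <- hconv(grp(2), 2)
  y3 <- hconv(grp(3) + y2, 3)
  y4 <- hconv(grp(4) + y3, 4)
  cc <- array(c(y1, y2, y3, y4), c(dim(u)[1], dim(u)[2], C))
  oracle_conv2d(cc, p$layers$block_out$w, p$layers$block_out$b, 0)
}

oracle_weight_maps <- function(features, epsilon = 0) {
  d <- dim(features[[1]]); s <- length(features)
  w <- array(0, c(d[1], d[2], s))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    q <- vapply(features, function(f) mean(f[i, j, ]), 0)
    if (sum(q) == 0) w[i, j, ] <- 1 / s
    else w[i, j, ] <- q / (sum(q) + epsilon)
  }
  w
}

oracle_fuse <- function(features, w) {
  d <- dim(features[[1]])
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3]))
    out[i, j, c] <- sum(vapply(seq_along(features), function(s)
      w[i, j, s] * features[[s]][i, j, c], 0))
  out
}

oracle_ag <- function(x) {
  M <- nrow(x); N <- ncol(x); acc <- 0
  for (i in 1:(M - 1)) for (j in 1:(N - 1))
    acc <- acc + sqrt(((x[i + 1, j] - x[i, j])^2 +
                         (x[i, j + 1] - x[i, j])^2) / 2)
  acc / ((M - 1) * (N - 1))
}

oracle_sf <- function(x) {
  M <- nrow(x); N <- ncol(x); rf <- 0; cf <- 0
  for (i in 1:M) for (j in 2:N) rf <- rf + (x[i, j] - x[i, j - 1])^2
  for (i in 2:M) for (j in 1:N) cf <- cf + (x[i, j] - x[i - 1, j])^2
  sqrt(rf / (M * N) + cf / (M * N))
}

oracle_quant <- function(x, levels) pmin(floor(x * levels), levels - 1)

oracle_en <- function(x, levels = 256) {
  q <- oracle_quant(x, levels)
  p <- as.vector(table(factor(q, levels = 0:(levels - 1)))) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_joint_en <- function(a, b, levels = 256) {
  qa <- oracle_quant(a, levels); qb <- oracle_quant(b, levels)
  key <- paste(qa, qb)
  p <- as.vector(table(key)) / length(key)
  -sum(p * log2(p))
}

oracle_mi_pair <- function(a, b, levels = 256) {
  oracle_en(a, levels) + oracle_en(b, levels) - oracle_joint_en(a, b, levels)
}

oracle_psnr <- function(f, a, b, r) {
  mse <- (mean((a - f)^2) + mean((b - f)^2)) / 2
  if (mse == 0) return(Inf)
  10 * log10(r^2 / mse)
}

oracle_gauss_kernel <- function(size, sigma) {
  t <- seq_len(size) - (size + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Windowed SSIM: direct per-window weighted statistics over every valid
# 11x11 (or given) window position.
oracle_ssim <- function(x, y, win = 11, sigma = 1.5, L = 1) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  k <- oracle_gauss_kernel(win, sigma)
  w2 <- outer(k, k)
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    px <- x[i:(i + win - 1), j:(j + win - 1)]
    py <- y[i:(i + win - 1), j:(j + win - 1)]
    mx <- sum(w2 * px); my <- sum(w2 * py)
    vx <- sum(w2 * px^2) - mx^2; vy <- sum(w2 * py^2) - my^2
    vxy <- sum(w2 * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# Xydeas-Petrovic edge-preservation index via explicit per-pixel loops.
oracle_qabf <- function(f, a, b) {
  sob <- function(x) {
    H <- nrow(x); W <- ncol(x)
    g <- matrix(0, H, W); al <- matrix(0, H, W)
    sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    sy <- t(sx)
    at <- function(i, j) x[min(max(i, 1), H), min(max(j, 1), W)]
    for (i in 1:H) for (j in 1:W) {
      gx <- 0; gy <- 0
      for (u in -1:1) for (v in -1:1) {
        gx <- gx + sx[u + 2, v + 2] * at(i + u, j + v)
        gy <- gy + sy[u + 2, v + 2] * at(i + u, j + v)
      }
      g[i, j] <- sqrt(gx^2 + gy^2)
      al[i, j] <- if (gx == 0) pi / 2 else atan(gy / gx)
    }
    list(g = g, a = al)
  }
  pres <- function(s, fe) {
    Tg <- 0.9994; kg <- -15; Dg <- 0.5
    Ta <- 0.9879; ka <- -22; Da <- 0.8
    H <- nrow(s$g); W <- ncol(s$g)
    q <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      gs <- s$g[i, j]; gf <- fe$g[i, j]
      G <- if (gs > gf) gf / gs else if (gf > gs) gs / gf
        else if (gs != 0) 1 else 0
      A <- 1 - abs(s$a[i, j] - fe$a[i, j]) / (pi / 2)
      q[i, j] <- (Tg / (1 + exp(kg * (G - Dg)))) *
        (Ta / (1 + exp(ka * (A - Da))))
    }
    q
  }
  ea <- sob(a); eb <- sob(b); ef <- sob(f)
  qa <- pres(ea, ef); qb <- pres(eb, ef)
  den <- sum(ea$g + eb$g)
  if (den == 0) return(0)
  sum(qa * ea$g + qb * eb$g) / den
}

# Multi-scale GSM/VIF information ratio via direct 2-d loop filters.
oracle_vif_ratio <- function(ref, dist, sigma_nsq = 2) {
  ref <- ref * 255; dist <- dist * 255
  corr_valid <- function(x, k1) {
    m <- length(k1); k2 <- outer(k1, k1)
    H <- nrow(x); W <- ncol(x)
    out <- matrix(0, H - m + 1, W - m + 1)
    for (i in seq_len(H - m + 1)) for (j in seq_len(W - m + 1))
      out[i, j] <- sum(k2 * x[i:(i + m - 1), j:(j + m - 1)])
    out
  }
  refl <- function(i, n) { while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i + 0; if (i > n) i <- 2 * n - i + 1 }; i }
  corr_reflect <- function(x, k1) {
    m <- length(k1); off <- (m - 1) / 2
    H <- nrow(x); W <- ncol(x)
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      acc <- 0
      for (u in 1:m) for (v in 1:m) {
        ii <- refl(i + u - 1 - off, H); jj <- refl(j + v - 1 - off, W)
        acc <- acc + k1[u] * k1[v] * x[ii, jj]
      }
      out[i, j] <- acc
    }
    out
  }
  pyr <- oracle_gauss_kernel(5, 1)
  num <- 0; den <- 0
  for (scale in 1:4) {
    if (scale > 1) {
      ref <- corr_reflect(ref, pyr)[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2)]
      dist <- corr_reflect(dist, pyr)[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2)]
    }
    n <- 2^(4 - scale + 1) + 1
    win <- oracle_gauss_kernel(n, n / 5)
    mu1 <- corr_valid(ref, win); mu2 <- corr_valid(dist, win)
    s1 <- pmax(corr_valid(ref * ref, win) - mu1^2, 0)
    s2 <- pmax(corr_valid(dist * dist, win) - mu2^2, 0)
    s12 <- corr_valid(ref * dist, win) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    g[s1 < 1e-10] <- 0; sv[s1 < 1e-10] <- s2[s1 < 1e-10]; s1[s1 < 1e-10] <- 0
    g[s2 < 1e-10] <- 0; sv[s2 < 1e-10] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

oracle_viff <- function(f, a, b) {
  (oracle_vif_ratio(a, f) + oracle_vif_ratio(b, f)) / 2
}

oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}

# Small deterministic structured test image (blobs + gradient + edges).
structured_image <- function(n, seed = 1) {
  set.seed(seed)
  ii <- matrix(rep(seq_len(n), n), n, n); jj <- t(ii)
  x <- 0.3 * ii / n + 0.2 * sin(jj / 2) + 0.2 * (ii > n / 2) +
    0.15 * matrix(runif(n * n), n, n)
  (x - min(x)) / (max(x) - min(x))
}

# Parameters with every kernel and bias zeroed.
zero_params <- function(seed = 0) {
  p <- init_params(seed)
  for (nm in names(p$layers)) {
    p$layers[[nm]]$w[] <- 0
    p$layers[[nm]]$b[] <- 0
  }
  p
}

# A 4-channel toy Res2Net block (groups of one channel) with small
# random kernels, for direct comparison against the formula oracle.
toy_block_params <- function(seed = 7) {
  set.seed(seed)
  mk <- function(kh, cin, cout, pad, act = "relu")
    list(w = array(runif(kh * kh * cin * cout, -0.5, 0.5),
                   c(kh, kh, cin, cout)),
         b = runif(cout, -0.1, 0.1), pad = pad, act = act)
  list(layers = list(block_in = mk(1, 4, 4, 0),
                     block_g2 = mk(3, 1, 1, 1),
                     block_g3 = mk(3, 1, 1, 1),
                     block_g4 = mk(3, 1, 1, 1),
                     block_out = mk(1, 4, 4, 0)),
       group_conv_depth = 1L)
}
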