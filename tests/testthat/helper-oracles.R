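# Independent brute-force oracles, deliberately written with different
# algorithms/code paths than the implementations they check.

# Even-odd point-in-polygon via parametric edge intersection with the
# rightward ray, half-open in y; separate on-segment test.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    p <- c(px[i], py[i])
    crossings <- 0L
    on_edge <- FALSE
    for (e in seq_len(n)) {
      a <- poly[e, ]
      b <- poly[if (e == n) 1L else e + 1L, ]
      # on-segment?
      d <- b - a
      len2 <- sum(d^2)
      if (len2 > 0) {
        t_on <- sum((p - a) * d) / len2
        if (t_on >= -1e-12 && t_on <= 1 + 1e-12) {
          perp <- (p - a) - t_on * d
          if (sqrt(sum(perp^2)) < 1e-9) on_edge <- TRUE
        }
        # ray crossing, half-open in y to avoid double-counting vertices
        if ((a[2] <= p[2] && b[2] > p[2]) || (b[2] <= p[2] && a[2] > p[2])) {
          t_c <- (p[2] - a[2]) / (b[2] - a[2])
          if (a[1] + t_c * (b[1] - a[1]) > p[1]) crossings <- crossings + 1L
        }
      }
    }
    on_edge || (crossings %% 2L == 1L)
  }, logical(1))
}

# direct (non-separable) 2-D Gaussian convolution with edge-duplicating
# reflection, on the float scale; returns the unquantized array
oracle_gauss2d <- function(img, sigma) {
  r <- floor(4 * sigma)
  t0 <- (-r):r
  k1 <- exp(-t0^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  d <- dim(img)
  refl <- function(i, n) {
    p <- 2 * n
    j <- ((i - 1) %% p + p) %% p
    ifelse(j < n, j + 1, p - j)
  }
  out <- array(0, d)
  for (ch in 1:3) {
    m <- matrix(as.double(img[, , ch]), d[1], d[2])
    for (y in seq_len(d[1])) {
      ry <- refl(y + t0, d[1])
      for (x in seq_len(d[2])) {
        rx <- refl(x + t0, d[2])
        out[y, x, ch] <- sum(K * m[ry, rx])
      }
    }
  }
  out
}

# full-histogram top-k by explicit sort of a string-keyed table
oracle_top_k <- function(pixels, k) {
  key <- sprintf("%03d_%03d_%03d", pixels[, 1], pixels[, 2], pixels[, 3])
  tb <- table(key)
  df <- data.frame(key = names(tb), count = as.integer(tb))
  df <- df[order(-df$count, df$key), ]
  df <- head(df, k)
  parts <- do.call(rbind, strsplit(df$key, "_"))
  data.frame(r = as.integer(parts[, 1]), g = as.integer(parts[, 2]),
             b = as.integer(parts[, 3]), count = df$count)
}

# two-sided Mann-Whitney p by enumeration of all splits of the pooled data
oracle_mw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(ia) {
    r <- rank(pooled)
    sum(r[ia]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  splits <- combn(length(pooled), na)
  us <- apply(splits, 2, function(ia) {
    r <- rank(pooled)
    sum(r[ia]) - na * (na + 1) / 2
  })
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# explicit normal-equations least-squares solution for the 3x3 correction
oracle_normal_equations <- function(measured, target) {
  t(solve(t(measured) %*% measured) %*% t(measured) %*% target)
}

# random simple (star-shaped) polygon around a center
random_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# random well-conditioned distortion near the identity
random_distortion_matrix <- function() {
  repeat {
    M <- diag(3) + matrix(runif(9, -0.15, 0.15), 3)
    d <- svd(M, nu = 0, nv = 0)$d
    if (max(d) / min(d) < 20) return(M)
  }
}

# as above, but additionally requiring the distorted chart colors to stay
# strictly inside the 8-bit gamut (a clipped patch biases its mean, as it
# would on a real over-exposed chart)
random_ingamut_distortion <- function(targets) {
  repeat {
    M <- random_distortion_matrix()
    meas <- targets %*% t(solve(M))
    if (all(meas > 1) && all(meas < 254)) return(M)
  }
}

# a phantom whose petal ROIs have exactly-known bright color compositions:
# n_rois rectangles of 14 x 15 = 210 px, each painted with 20 distinct
# colors at pixel counts 1..20 (the integer partition of 210)
make_palette_phantom <- function(n_rois = 20, n_colors = 20) {
  stopifnot(n_colors == 20)  # counts 1..20 sum to the 210-px ROI exactly
  specs <- lapply(seq_len(n_rois), function(i) {
    row <- (i - 1) %/% 5
    col <- (i - 1) %% 5
    poly <- rect_polygon(8 + col * 20, 30 + row * 20, 14, 15)
    cols <- cbind(r = 150 + i + seq_len(n_colors),
                  g = 140 + (seq_len(n_colors) * 3) %% 40,
                  b = 150 + ((i + seq_len(n_colors)) * 7) %% 60)
    stopifnot(!anyDuplicated(cols))
    list(polygon = poly, colors = cols, weights = seq_len(n_colors))
  })
  simulate_scene(chart = chart_spec(),
                 distortion = distortion_model(diag(3), noise_sd = 0),
                 petal_spec = specs, width = 120, height = 120)
}
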