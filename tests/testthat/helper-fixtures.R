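# Shared fixtures and independent oracles. Expensive objects (full-size
# backbone, pretrained state, synthetic cohorts) are built once per test
# run and cached in this environment.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, builder(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# full ResNet-34 backbone at a fixed seed (random-initialization extractor)
full_net <- function() cached("full_net", function() {
  build_network(resnet_spec(), seed = 1L)
})

# small backbone with 64x64 input for fast pipeline plumbing tests
tiny64_net <- function() cached("tiny64_net", function() {
  build_network(resnet_spec(widths = c(4L, 8L), blocks = c(1L, 1L),
                            stem_filters = 4L, input_size = 64L,
                            n_classes = 4L), seed = 2L)
})

# very small network for training-machinery tests (16x16 input)
tiny16_spec <- function() resnet_spec(widths = c(4L, 8L), blocks = c(1L, 1L),
                                      stem_filters = 4L, input_size = 16L,
                                      n_classes = 3L)

# a small ellipsoid-mask case on a given grid
toy_case <- function(shape = 24L, seed = 1L, modalities = c("MRI", "PET", "CT")) {
  set.seed(seed)
  shape <- rep(shape, length.out = 3)
  ctr <- shape / 2 + runif(3, -2, 2)
  semi <- runif(3, 3, 6)
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - ctr[a]) / semi[a])^2)
  m <- array(as.numeric(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1),
             shape)
  vols <- lapply(modalities, function(mod)
    volume3d(array(rnorm(prod(shape), mean = 100, sd = 10), shape),
             modality = mod))
  names(vols) <- modalities
  load_case(vols, voi_mask(m), label = "SZF", case_id = paste0("toy", seed))
}

# smooth random 64^3 cube (low-frequency content so interpolation error is
# well-behaved), built by trilinear upsampling of a random coarse grid
smooth_cube <- function(seed = 1L, coarse = 8L) {
  set.seed(seed)
  g <- resample_volume(array(runif(coarse^3), rep(coarse, 3)), rep(64L, 3L))
  cube64(g, array(as.numeric(g > stats::median(g)), rep(64L, 3L)))
}

# ----- independent oracles ------------------------------------------------

# brute-force plane sampler: nested loops, scalar trilinear interpolation,
# no vectorized slicing; edge-clamped like the declared geometry
bf_sample_plane <- function(grid, point, u, v, nu, nv) {
  d <- dim(grid)
  out <- matrix(0, nu, nv)
  for (a in seq_len(nu)) {
    for (b in seq_len(nv)) {
      p <- point + (a - 1 - (nu - 1) / 2) * u + (b - 1 - (nv - 1) / 2) * v
      p <- pmax(pmin(p, d - 1), 0)
      i0 <- pmax(pmin(floor(p), d - 2), 0)
      f <- p - i0
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) f[1] else 1 - f[1]) *
             (if (dy) f[2] else 1 - f[2]) *
             (if (dz) f[3] else 1 - f[3])
        acc <- acc + w * grid[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
      }
      out[a, b] <- acc
    }
  }
  out
}

# brute-force bilinear resize matching the pixel-centre convention
bf_resize <- function(img, out_dim) {
  d <- dim(img)
  out <- matrix(0, out_dim[1], out_dim[2])
  for (a in seq_len(out_dim[1])) {
    for (b in seq_len(out_dim[2])) {
      x <- (a - 0.5) * d[1] / out_dim[1] - 0.5
      y <- (b - 0.5) * d[2] / out_dim[2] - 0.5
      x0 <- max(min(floor(x), d[1] - 2), 0); y0 <- max(min(floor(y), d[2] - 2), 0)
      fx <- min(max(x - x0, 0), 1); fy <- min(max(y - y0, 0), 1)
      out[a, b] <- img[x0 + 1, y0 + 1] * (1 - fx) * (1 - fy) +
                   img[x0 + 2, y0 + 1] * fx * (1 - fy) +
                   img[x0 + 1, y0 + 2] * (1 - fx) * fy +
                   img[x0 + 2, y0 + 2] * fx * fy
    }
  }
  out
}

# exhaustive concordant-pair AUC
bf_auc <- function(scores, labels) {
  y <- ifelse(as.character(labels) == "SZF", 1, -1)
  pos <- scores[y == 1]; neg <- scores[y == -1]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force placement-based DeLong oracle (double loops throughout)
bf_delong <- function(sa, sb, labels) {
  y <- ifelse(as.character(labels) == "SZF", 1, -1)
  ip <- which(y == 1); im <- which(y == -1)
  m <- length(ip); n <- length(im)
  plc <- function(s) {
    v10 <- numeric(m); v01 <- numeric(n)
    for (a in seq_len(m)) for (b in seq_len(n)) {
      ps <- (s[ip[a]] > s[im[b]]) + 0.5 * (s[ip[a]] == s[im[b]])
      v10[a] <- v10[a] + ps / n
      v01[b] <- v01[b] + ps / m
    }
    list(v10 = v10, v01 = v01, auc = sum(v10) / m)
  }
  pa <- plc(sa); pb <- plc(sb)
  cv <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  var_diff <- (cv(pa$v10, pa$v10) + cv(pb$v10, pb$v10) - 2 * cv(pa$v10, pb$v10)) / m +
              (cv(pa$v01, pa$v01) + cv(pb$v01, pb$v01) - 2 * cv(pa$v01, pb$v01)) / n
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_1 = pa$auc, auc_2 = pb$auc, var_diff = var_diff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# fast synthetic-cohort profile used in properties: modest grid, smaller
# lesions, everything else at generator defaults
test_cohort_config <- function(n_szf, n_szr, effect, seed, shape = 64L) {
  synthetic_config(n_per_class = c(SZF = n_szf, SZR = n_szr), shape = shape,
                   lesion_radius = c(5, 12), effect_size = effect, seed = seed)
}
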