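#' Configuration for the synthetic multimodal lesion-phantom cohort
#'
#' Each case carries co-registered MRI/PET/CT volumes sharing one
#' ellipsoidal lesion mask (the stand-in for the surgical target VOI).
#' Backgrounds are smooth correlated Gaussian fields. Seizure-recurrence
#' (SZR) cases receive an additive class effect of
#' `effect_size * modality_weight * sigma` *inside* the mask (negative in
#' PET, mimicking focal hypometabolism; positive in MRI/CT), so the
#' attention mechanism has a signal confined to the VOI to protect.
#' Label-independent "clutter" ellipsoids outside the mask are added to
#' both classes to make the no-mask condition strictly harder.
#'
#' @param n_per_class Cases per class, named `SZF`/`SZR` (default 40+40; a
#'   cohort shaped like the clinical study uses `c(SZF = 79, SZR = 62)`).
#' @param shape Volume grid (default 96^3).
#' @param modalities Modalities to simulate.
#' @param lesion_radius Range of ellipsoid semi-axes in voxels.
#' @param effect_size Class-conditional mean shift inside the lesion, in
#'   units of the background noise SD (0 = null cohort).
#' @param modality_weight Per-modality multiplier on the effect; PET
#'   carries the largest effect by default.
#' @param texture_scale Gaussian smoothing sigma of the background field
#'   (voxels).
#' @param n_clutter Clutter ellipsoids per case (outside the mask).
#' @param clutter_amplitude Max |shift| of a clutter ellipsoid, in noise-SD
#'   units.
#' @param seed Mandatory integer seed; all randomness (geometry, noise,
#'   effects) flows from it through named substreams.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(SZF = 40L, SZR = 40L),
                             shape = c(96L, 96L, 96L),
                             modalities = c("MRI", "PET", "CT"),
                             lesion_radius = c(6, 14),
                             effect_size = 1.0,
                             modality_weight = c(MRI = 0.7, PET = 1.0, CT = 0.5),
                             texture_scale = 3,
                             n_clutter = 2L,
                             clutter_amplitude = 1.5,
                             seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("config error: an integer seed is mandatory", call. = FALSE)
  if (!all(c("SZF", "SZR") %in% names(n_per_class)) || any(n_per_class < 2))
    stop("config error: need >= 2 cases per class, named SZF/SZR", call. = FALSE)
  if (effect_size < 0) stop("config error: effect_size must be >= 0", call. = FALSE)
  shape <- as.integer(rep(shape, length.out = 3))
  if (any(shape < 4 * max(lesion_radius)))
    stop("config error: volume too small for the lesion size range", call. = FALSE)
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  structure(list(n_per_class = n_per_class, shape = shape,
                 modalities = modalities, lesion_radius = lesion_radius,
                 effect_size = effect_size,
                 modality_weight = modality_weight[modalities],
                 texture_scale = texture_scale,
                 n_clutter = as.integer(n_clutter),
                 clutter_amplitude = clutter_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# substream seeding: one base seed, named streams, per-case offsets
stream_seed <- function(seed, stream, case = 0L) {
  offs <- c(geometry = 11L, noise = 29L, effect = 47L, clutter = 73L,
            corpus = 97L)
  (as.integer(seed) * 2017L + offs[[stream]] * 30011L + case * 613L) %% 2147483647L
}

# separable Gaussian smoothing by banded matrix products along each axis
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    half <- max(1L, ceiling(3 * sigma))
    kern <- exp(-((-half):half)^2 / (2 * sigma^2))
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + (-half):half, 1), n)
      for (kk in seq_along(j)) S[i, j[kk]] <- S[i, j[kk]] + kern[kk]
    }
    S <- S / rowSums(S)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- S %*% matrix(a, da[1])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

# unit-SD smooth background field
smooth_noise <- function(shape, sigma) {
  f <- smooth3d(array(rnorm(prod(shape)), shape), sigma)
  (f - mean(f)) / sd(f)
}

ellipsoid_mask <- function(shape, center, semi_axes) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / semi_axes[a])^2)
  g <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  array(as.numeric(g <= 1), shape)
}

MODALITY_BASE <- c(MRI = 300, PET = 5, CT = 40)
MODALITY_SD <- c(MRI = 60, PET = 1, CT = 15)

#' Generate a synthetic multimodal cohort
#'
#' Fully seed-reproducible; every case passes [load_case()] validation and
#' the on-disk layout written by [write_cohort()] is exactly what
#' [load_cohort()] consumes.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_cohort`: `cases` (list of
#'   `multimodal_case`), `truth` (per-case lesion geometry and applied
#'   shifts), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- cohort_labels(config)
  n <- length(labels)
  cases <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    gen <- generate_case(config, i, labels[i])
    cases[[i]] <- gen$case
    truth[[i]] <- gen$truth
  }
  structure(list(cases = cases, truth = truth, config = config),
            class = "synthetic_cohort")
}

cohort_labels <- function(config) {
  rep(c("SZF", "SZR"), times = config$n_per_class[c("SZF", "SZR")])
}

# one case, fully determined by (seed, case index, label): cohorts can be
# generated case-by-case without holding the rest in memory
generate_case <- function(config, i, label) {
  shape <- config$shape
  set.seed(stream_seed(config$seed, "geometry", i))
    semi <- runif(3, config$lesion_radius[1], config$lesion_radius[2])
    ctr <- runif(3, 0.35, 0.65) * shape
    mask <- ellipsoid_mask(shape, ctr, semi)
    set.seed(stream_seed(config$seed, "clutter", i))
    clut <- list()
    for (k in seq_len(config$n_clutter)) {
      csemi <- runif(3, config$lesion_radius[1], config$lesion_radius[2]) * 0.8
      # place clutter off-centre so it rarely overlaps the lesion
      cctr <- runif(3, 0.1, 0.9) * shape
      cmask <- ellipsoid_mask(shape, cctr, csemi) * (1 - mask)
      camp <- runif(length(config$modalities), -config$clutter_amplitude,
                    config$clutter_amplitude)
      names(camp) <- config$modalities
      clut[[k]] <- list(mask = cmask, amp = camp)
    }
    vols <- list()
    shifts <- numeric(0)
    for (mod in config$modalities) {
      set.seed(stream_seed(config$seed, "noise", i) + match(mod, MODALITIES))
      sdv <- MODALITY_SD[[mod]]
      field <- MODALITY_BASE[[mod]] + sdv * smooth_noise(shape, config$texture_scale)
      for (cl in clut) field <- field + sdv * cl$amp[[mod]] * cl$mask
      shift <- 0
      if (label == "SZR" && config$effect_size > 0) {
        dirn <- if (mod == "PET") -1 else 1  # PET: focal hypometabolism
        shift <- dirn * config$effect_size * config$modality_weight[[mod]] * sdv
        field <- field + shift * mask
      }
      vols[[mod]] <- volume3d(field, modality = mod)
      shifts[mod] <- shift
  }
  case <- load_case(vols, voi_mask(mask, affine = vols[[1]]$affine),
                    label = label, case_id = sprintf("case_%03d", i))
  list(case = case,
       truth = list(case_id = case$case_id, label = label, center = ctr,
                    semi_axes = semi, shifts = shifts,
                    noise_sd = MODALITY_SD[config$modalities]))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases (%s), effect %.2f, seed %d\n",
              length(x$cases),
              paste(names(x$config$n_per_class), x$config$n_per_class,
                    sep = "=", collapse = ", "),
              x$config$effect_size, x$config$seed))
  invisible(x)
}

#' Write a cohort to NIfTI volumes and a label table
#'
#' Emits `<case_id>_<modality>.nii.gz`, `<case_id>_mask.nii.gz` and
#' `labels.csv` (columns `case_id`, `label`, `mask`, one per modality) in
#' the layout [load_cohort()] reads. Given a [synthetic_config()] instead
#' of a generated cohort, cases are generated and written one at a time so
#' a large cohort never needs to fit in memory.
#'
#' @param cohort A [generate_cohort()] result, a list of cases, or a
#'   [synthetic_config()] (streamed generation).
#' @param dir Output directory (created if needed).
#' @return Path of the label table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(cs) {
    row <- list(case_id = cs$case_id, label = cs$label)
    mfile <- paste0(cs$case_id, "_mask.nii.gz")
    write_volume(cs$mask, file.path(dir, mfile))
    row$mask <- mfile
    for (mod in names(cs$volumes)) {
      vfile <- paste0(cs$case_id, "_", mod, ".nii.gz")
      write_volume(cs$volumes[[mod]], file.path(dir, vfile))
      row[[mod]] <- vfile
    }
    as.data.frame(row)
  }
  rows <- if (inherits(cohort, "synthetic_config")) {
    labels <- cohort_labels(cohort)
    lapply(seq_along(labels), function(i) {
      r <- write_one(generate_case(cohort, i, labels[i])$case)
      invisible(gc(FALSE))
      r
    })
  } else {
    cases <- if (inherits(cohort, "synthetic_cohort")) cohort$cases else cohort
    lapply(cases, write_one)
  }
  tab <- do.call(rbind, rows)
  path <- file.path(dir, "labels.csv")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Generate a procedural grayscale pretraining corpus
#'
#' A desk-scale labelled image-classification corpus: each class is a
#' texture family (oriented gratings, checkerboards, Gaussian blob fields)
#' with class-specific parameter ranges, 64x64 grayscale in `[0, 1]`.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images per class.
#' @param seed Integer seed.
#' @return List with `images` (64 x 64 x N array), `labels` (integer),
#'   `class_tag` (character description per class).
#' @export
generate_pretrain_corpus <- function(n_classes = 10L, n_per_class = 200L,
                                     seed = 1L) {
  if (n_classes < 2L)
    stop("validation error: corpus needs >= 2 classes", call. = FALSE)
  n <- n_classes * n_per_class
  imgs <- array(0, c(64, 64, n))
  labels <- integer(n)
  xy <- expand.grid(x = (0:63) / 63, y = (0:63) / 63)
  tags <- character(n_classes)
  idx <- 0L
  for (cl in seq_len(n_classes)) {
    fam <- (cl - 1L) %% 3L
    tags[cl] <- c("grating", "checker", "blobs")[fam + 1L]
    set.seed(stream_seed(seed, "corpus", cl))
    for (r in seq_len(n_per_class)) {
      idx <- idx + 1L
      labels[idx] <- cl
      if (fam == 0L) {            # oriented grating; class sets freq band
        f <- 2 + 2.5 * ((cl - 1) %/% 3) + runif(1)
        th <- runif(1, 0, pi)
        ph <- runif(1, 0, 2 * pi)
        img <- 0.5 + 0.4 * sin(2 * pi * f * (xy$x * cos(th) + xy$y * sin(th)) + ph)
      } else if (fam == 1L) {     # checkerboard; class sets cell size
        cell <- 3 + 2 * ((cl - 1) %/% 3) + sample(0:1, 1)
        ox <- runif(1, 0, cell); oy <- runif(1, 0, cell)
        img <- 0.2 + 0.6 * (((floor((xy$x * 63 + ox) / cell) +
                              floor((xy$y * 63 + oy) / cell)) %% 2))
      } else {                    # blob field; class sets count/width
        k <- 3 + 2 * ((cl - 1) %/% 3)
        w <- 0.05 + 0.02 * ((cl - 1) %/% 3)
        img <- rep(0.15, nrow(xy))
        for (b in seq_len(k)) {
          cx <- runif(1); cy <- runif(1)
          img <- img + 0.8 * exp(-((xy$x - cx)^2 + (xy$y - cy)^2) / (2 * w^2))
        }
      }
      img <- img + rnorm(length(img), sd = 0.05)
      imgs[, , idx] <- matrix(pmin(pmax(img, 0), 1), 64, 64)
    }
  }
  list(images = imgs, labels = labels, class_tag = tags)
}
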