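#' @useDynLib voipredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var predict
#' @importFrom utils read.csv write.csv head
NULL

MODALITIES <- c("MRI", "PET", "CT")
LABEL_LEVELS <- c("SZF", "SZR")  # positive class first: SZF = Engel I
AFFINE_TOL <- 1e-3

#' Construct a 3-D intensity volume
#'
#' A `volume3d` holds one co-registered modality image on a regular voxel
#' grid together with its voxel-to-world affine. Registration across
#' modalities is assumed to have been done upstream; this type only
#' validates its output (congruent grids and affines).
#'
#' @param grid 3-D numeric array of voxel intensities (all finite).
#' @param spacing Positive voxel size per axis in mm (length 3). Ignored if
#'   `affine` is given.
#' @param origin World coordinates of voxel (0,0,0) (length 3).
#' @param modality One of `"MRI"`, `"PET"`, `"CT"`.
#' @param affine Optional 4x4 voxel-to-world affine; overrides
#'   `spacing`/`origin`.
#' @return An object of class `volume3d` with fields `grid`, `affine`,
#'   `modality`.
#' @export
volume3d <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = "MRI", affine = NULL) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array", call. = FALSE)
  if (any(dim(grid) < 1L)) stop("grid dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(grid))) stop("volume intensities must be finite", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  } else {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
    if (any(abs(diag(affine)[1:3]) <= 0) && all(affine[1:3, 1:3] == 0))
      stop("degenerate affine", call. = FALSE)
  }
  structure(list(grid = grid, affine = affine, modality = modality),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s  %s  spacing %s mm\n", x$modality,
              paste(dim(x$grid), collapse = "x"),
              paste(signif(volume_spacing(x), 3), collapse = "x")))
  invisible(x)
}

volume_spacing <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Construct a binary volume-of-interest mask
#'
#' The surgical target VOI delineated on the co-registered grid. Values must
#' be 0/1 and at least one voxel must be foreground.
#'
#' @param grid 3-D array with values in \{0, 1\}.
#' @param affine 4x4 voxel-to-world affine (defaults to identity spacing).
#' @return Object of class `voi_mask` with fields `grid`, `affine`,
#'   `voxel_count`.
#' @export
voi_mask <- function(grid, affine = NULL) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array", call. = FALSE)
  u <- unique(as.vector(grid))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  vc <- sum(grid)
  if (vc < 1) stop("mask is empty: voxel_count must be >= 1", call. = FALSE)
  if (is.null(affine)) affine <- diag(4)
  structure(list(grid = grid, affine = as.matrix(affine),
                 voxel_count = as.integer(vc)),
            class = "voi_mask")
}

#' Read a NIfTI volume from disk
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param modality Modality tag to attach.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = "MRI") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim = dim(img)),
           affine = unclass(RNifti::xform(img)), modality = modality)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param x A [volume3d()] or [voi_mask()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$grid)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask from NIfTI
#'
#' @inheritParams read_volume
#' @return A [voi_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  g <- array(as.numeric(img), dim = dim(img))
  g[g != 0] <- 1
  voi_mask(g, affine = unclass(RNifti::xform(img)))
}

#' Assemble and validate one patient case
#'
#' Bundles 1-3 co-registered modality volumes, the surgical-target mask and
#' the outcome label into a validated unit. Grids must be congruent and
#' affines must agree within `1e-3`; a violated check raises a registration
#' error rather than silently proceeding.
#'
#' @param volumes Named list of [volume3d()] (names from MRI/PET/CT), or a
#'   named character vector of NIfTI paths.
#' @param mask A [voi_mask()] or a NIfTI path.
#' @param label `"SZF"` (seizure-free, Engel I; the positive class) or
#'   `"SZR"` (recurrence, Engel II-IV). May be `NA` for prediction-only
#'   cases.
#' @param case_id Case identifier string.
#' @return Object of class `multimodal_case`.
#' @export
load_case <- function(volumes, mask, label = NA_character_, case_id = "case") {
  if (is.character(volumes)) {
    if (is.null(names(volumes))) stop("volume paths must be named by modality", call. = FALSE)
    volumes <- mapply(function(p, m) read_volume(p, m), volumes, names(volumes),
                      SIMPLIFY = FALSE)
  }
  if (length(volumes) < 1L || length(volumes) > 3L)
    stop("a case needs 1-3 modality volumes", call. = FALSE)
  if (is.null(names(volumes)) || !all(names(volumes) %in% MODALITIES))
    stop("volumes must be named with modalities ", paste(MODALITIES, collapse = "/"),
         call. = FALSE)
  if (is.character(mask)) mask <- read_mask(mask)
  ref <- volumes[[1L]]
  for (m in names(volumes)) {
    v <- volumes[[m]]
    if (!identical(dim(v$grid), dim(ref$grid)))
      stop("registration error: grid shape mismatch for ", m, call. = FALSE)
    if (max(abs(v$affine - ref$affine)) > AFFINE_TOL)
      stop("registration error: affine mismatch for ", m, call. = FALSE)
  }
  if (!identical(dim(mask$grid), dim(ref$grid)))
    stop("registration error: mask grid shape mismatch", call. = FALSE)
  if (max(abs(mask$affine - ref$affine)) > AFFINE_TOL)
    stop("registration error: mask affine mismatch", call. = FALSE)
  if (!is.na(label)) label <- match.arg(label, LABEL_LEVELS)
  structure(list(case_id = as.character(case_id), volumes = volumes,
                 mask = mask, label = label),
            class = "multimodal_case")
}

#' @export
print.multimodal_case <- function(x, ...) {
  cat(sprintf("<multimodal_case> %s  [%s]  label %s  VOI %d voxels\n",
              x$case_id, paste(names(x$volumes), collapse = ","),
              x$label, x$mask$voxel_count))
  invisible(x)
}

#' Load a cohort from a label table
#'
#' The label table is a CSV with columns `case_id`, `label` (SZF/SZR),
#' `mask` and one column per modality holding NIfTI paths (relative to
#' `data_root` unless absolute).
#'
#' @param label_csv Path to the label table.
#' @param data_root Directory that relative paths are resolved against.
#' @return List of [load_case()] results.
#' @export
load_cohort <- function(label_csv, data_root = dirname(label_csv)) {
  tab <- read.csv(label_csv, stringsAsFactors = FALSE)
  need <- c("case_id", "label", "mask")
  if (!all(need %in% names(tab)))
    stop("label table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  mods <- intersect(MODALITIES, names(tab))
  if (length(mods) == 0L) stop("label table has no modality path columns", call. = FALSE)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(data_root, p))
  lapply(seq_len(nrow(tab)), function(i) {
    paths <- vapply(mods, function(m) resolve(tab[[m]][i]), character(1))
    load_case(paths, resolve(tab$mask[i]), label = tab$label[i],
              case_id = tab$case_id[i])
  })
}

mask_bounding_box <- function(mask_grid) {
  idx <- which(mask_grid != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))  # 1-based inclusive
}

#' Crop the minimum circumscribed cube around the VOI
#'
#' The cube side equals the largest extent of the mask bounding box plus
#' `2 * margin`, centred on the bounding-box centre (the extra voxel of an
#' odd padding difference goes to the high side). Where the cube extends
#' past the image border it is padded with the volume's minimum intensity,
#' so the VOI is always completely contained in the returned cube.
#'
#' @param volume A [volume3d()].
#' @param mask A [voi_mask()] on the same grid.
#' @param margin Non-negative integer margin in voxels added on every side.
#' @return List with `subvolume` (3-D array, cubic), `submask` (0/1 array,
#'   same shape), `side`, and `box` (0-based half-open `[lo, hi)` start
#'   indices per axis in the source grid).
#' @export
crop_min_cube <- function(volume, mask, margin = 0L) {
  stopifnot(inherits(volume, "volume3d"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$grid), dim(mask$grid)))
    stop("registration error: volume and mask shapes differ", call. = FALSE)
  margin <- as.integer(margin)
  stopifnot(margin >= 0L)
  bb <- mask_bounding_box(mask$grid)
  ext <- bb$hi - bb$lo + 1L
  side <- max(ext) + 2L * margin
  pad <- side - ext
  lo0 <- (bb$lo - 1L) - pad %/% 2L        # 0-based start, may be negative
  dims <- dim(volume$grid)
  fill <- min(volume$grid)
  sub <- array(fill, dim = rep(side, 3L))
  subm <- array(0, dim = rep(side, 3L))
  # overlap of [lo0, lo0+side) with [0, dims)
  src_lo <- pmax(lo0, 0L)
  src_hi <- pmin(lo0 + side, dims)        # exclusive
  if (any(src_hi <= src_lo)) stop("crop box does not intersect volume", call. = FALSE)
  dst_lo <- src_lo - lo0
  si <- lapply(1:3, function(a) (src_lo[a] + 1L):src_hi[a])
  di <- lapply(1:3, function(a) (dst_lo[a] + 1L):(dst_lo[a] + (src_hi[a] - src_lo[a])))
  sub[di[[1]], di[[2]], di[[3]]] <- volume$grid[si[[1]], si[[2]], si[[3]]]
  subm[di[[1]], di[[2]], di[[3]]] <- mask$grid[si[[1]], si[[2]], si[[3]]]
  list(subvolume = sub, submask = subm, side = side, box = as.integer(lo0))
}

# Pixel-centre coordinate mapping for resampling: output index i (0-based)
# samples input coordinate (i + 0.5) * n_in / n_out - 0.5. Identity when
# n_in == n_out.
resample_coords <- function(n_in, n_out) {
  (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
}

#' Trilinear resample of a 3-D array to a target shape
#'
#' Pixel-centre aligned; coordinates are clamped at the boundary so no
#' value outside the input range can be produced.
#'
#' @param arr 3-D numeric array.
#' @param out_dim Length-3 integer target shape.
#' @param nearest If `TRUE`, nearest-neighbour instead of trilinear (for
#'   masks).
#' @return Resampled 3-D array.
#' @export
resample_volume <- function(arr, out_dim, nearest = FALSE) {
  d <- dim(arr)
  cs <- lapply(1:3, function(a) resample_coords(d[a], out_dim[a]))
  if (nearest) {
    idx <- lapply(1:3, function(a) pmin(pmax(round(cs[[a]]) + 1, 1), d[a]))
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(cs[[a]]), 0), d[a] - 1))
  fr <- lapply(1:3, function(a) pmin(pmax(cs[[a]] - lo[[a]], 0), 1))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
  l <- lapply(lo, function(v) v + 1)  # 1-based
  h <- lapply(hi, function(v) v + 1)
  g <- function(i, j, k) arr[l[[1]] * (1 - i) + h[[1]] * i,
                             l[[2]] * (1 - j) + h[[2]] * j,
                             l[[3]] * (1 - k) + h[[3]] * k, drop = FALSE]
  fx <- array(rep(fr[[1]], times = out_dim[2] * out_dim[3]), out_dim)
  fy <- array(rep(rep(fr[[2]], each = out_dim[1]), times = out_dim[3]), out_dim)
  fz <- array(rep(fr[[3]], each = out_dim[1] * out_dim[2]), out_dim)
  (g(0,0,0) * (1-fx) + g(1,0,0) * fx) * (1-fy) * (1-fz) +
  (g(0,1,0) * (1-fx) + g(1,1,0) * fx) * fy     * (1-fz) +
  (g(0,0,1) * (1-fx) + g(1,0,1) * fx) * (1-fy) * fz +
  (g(0,1,1) * (1-fx) + g(1,1,1) * fx) * fy     * fz
}

#' Resample a cropped cube to the canonical 64^3 grid
#'
#' Trilinear interpolation for intensities, nearest-neighbour for the mask.
#'
#' @param subvolume Cubic 3-D array (output of [crop_min_cube()]).
#' @param submask Matching 0/1 array.
#' @param provenance Optional list recording source case/modality/crop box.
#' @return A `cube64` object: fields `grid` and `mask_grid`, both 64^3.
#' @export
resample_to_64 <- function(subvolume, submask, provenance = list()) {
  d <- dim(subvolume)
  if (length(unique(d)) != 1L)
    stop("contract error: input to resample_to_64 must be cubic", call. = FALSE)
  if (!identical(dim(submask), d))
    stop("contract error: submask shape differs from subvolume", call. = FALSE)
  out <- rep(64L, 3L)
  cube64(resample_volume(subvolume, out),
         resample_volume(submask, out, nearest = TRUE),
         provenance = provenance)
}

#' Construct a 64^3 cube (intensities + resampled mask)
#'
#' @param grid 64x64x64 numeric array.
#' @param mask_grid 64x64x64 0/1 array.
#' @param provenance Optional provenance list.
#' @return Object of class `cube64`.
#' @export
cube64 <- function(grid, mask_grid, provenance = list()) {
  if (!identical(dim(grid), rep(64L, 3L)) || !identical(dim(mask_grid), rep(64L, 3L)))
    stop("contract error: cube64 grids must be exactly 64x64x64", call. = FALSE)
  if (!all(mask_grid %in% c(0, 1)))
    stop("cube64 mask_grid must be binary", call. = FALSE)
  structure(list(grid = grid, mask_grid = mask_grid, provenance = provenance),
            class = "cube64")
}

#' Normalize cube intensities to [0, 1]
#'
#' Min-max rescaling over the cube. CT is first clipped to a Hounsfield
#' window (default \[-100, 300\] HU) to suppress bone/air extremes before
#' rescaling; MRI and PET are min-max only. A constant cube maps to all
#' zeros.
#'
#' @param cube A [cube64()].
#' @param modality Modality tag controlling the clipping policy.
#' @param ct_window Length-2 HU clipping window applied when
#'   `modality == "CT"`.
#' @return A [cube64()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(cube, modality = "MRI", ct_window = c(-100, 300)) {
  stopifnot(inherits(cube, "cube64"))
  g <- cube$grid
  if (!all(is.finite(g))) stop("intensities must be finite", call. = FALSE)
  if (match.arg(modality, MODALITIES) == "CT") {
    g <- pmin(pmax(g, ct_window[1]), ct_window[2])
    dim(g) <- dim(cube$grid)
  }
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else array(0, dim(g))
  cube64(g, cube$mask_grid, cube$provenance)
}
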