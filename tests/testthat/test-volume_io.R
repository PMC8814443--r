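test_that("NIfTI round-trip preserves grid, spacing and affine", {
  set.seed(10)
  g <- array(rnorm(20^3), rep(20, 3))
  v <- volume3d(g, spacing = c(1.25, 2, 0.8), origin = c(-7, 3, 12),
                modality = "CT")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f, "CT")
  expect_equal(v2$grid, g, tolerance = 1e-6)
  expect_lt(max(abs(v2$affine - v$affine)), 1e-5)
  m <- voi_mask(array(as.numeric(g > 0), dim(g)), affine = v$affine)
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  expect_equal(read_mask(fm)$grid, m$grid)
})

test_that("load_case validates congruence, mask content and labels", {
  cs <- toy_case(shape = 16L, seed = 3)
  expect_s3_class(cs, "multimodal_case")
  expect_length(cs$volumes, 3)
  expect_gte(cs$mask$voxel_count, 1)

  vols <- cs$volumes
  # all-zero mask is rejected before a case can be formed
  expect_error(voi_mask(array(0, rep(16, 3))), "empty")
  # shape mismatch
  bad <- volume3d(array(0, rep(8, 3)), modality = "PET")
  expect_error(load_case(c(vols[1], list(PET = bad)), cs$mask),
               "registration error")
  # affine mismatch beyond tolerance
  shifted <- vols[[1]]
  shifted$affine[1, 4] <- shifted$affine[1, 4] + 0.5
  expect_error(load_case(list(MRI = shifted, PET = vols[[2]]), cs$mask),
               "registration error")
  # non-binary mask
  expect_error(voi_mask(array(2, rep(4, 3))), "0 or 1")
  # missing file
  expect_error(read_volume("no/such/file.nii.gz"), "not found")
})

test_that("cohort label table round-trips through write_cohort/load_cohort", {
  cfg <- synthetic_config(n_per_class = c(SZF = 2L, SZR = 2L), shape = 28L,
                          lesion_radius = c(3, 6), seed = 42)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(file.path(dir, "labels.csv"))
  expect_length(back, 4)
  expect_equal(vapply(back, function(x) x$label, character(1)),
               vapply(co$cases, function(x) x$label, character(1)))
  expect_equal(back[[1]]$volumes$PET$grid, co$cases[[1]]$volumes$PET$grid,
               tolerance = 1e-6)
  expect_equal(back[[3]]$mask$grid, co$cases[[3]]$mask$grid)
})

test_that("crop_min_cube side equals max bounding-box extent plus margins", {
  m <- array(0, c(40, 40, 40))
  m[6:15, 11:30, 21:35] <- 1  # extents 10, 20, 15
  v <- volume3d(array(runif(40^3), rep(40, 3)))
  cr <- crop_min_cube(v, voi_mask(m))
  expect_equal(cr$side, 20)
  expect_equal(dim(cr$subvolume), rep(20L, 3))
  cr2 <- crop_min_cube(v, voi_mask(m), margin = 3)
  expect_equal(cr2$side, 26)
})

test_that("crop of a full-volume mask reproduces the (padded) volume", {
  g <- array(runif(10 * 20 * 15), c(10, 20, 15))
  v <- volume3d(g)
  cr <- crop_min_cube(v, voi_mask(array(1, dim(g))))
  expect_equal(cr$side, 20)
  # the original volume appears intact inside the padded cube
  idx <- which(cr$submask == 1, arr.ind = TRUE)
  expect_equal(sum(cr$submask), length(g))
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  expect_equal(cr$subvolume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], g)
  # padding uses the volume minimum
  expect_equal(sort(unique(cr$subvolume[cr$submask == 0]))[1], min(g))
})

test_that("every mask voxel lands inside the crop, any geometry (brute force)", {
  for (seed in 1:4) {
    cs <- toy_case(shape = c(30L, 24L, 36L)[1 + seed %% 3], seed = seed)
    v <- cs$volumes[[1]]
    cr <- crop_min_cube(v, cs$mask, margin = 2)
    # exhaustive containment scan over all mask voxels
    idx <- which(cs$mask$grid == 1, arr.ind = TRUE)
    inside <- 0L
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ] - 1L - cr$box  # position in cube coordinates (0-based)
      if (all(p >= 0) && all(p < cr$side)) inside <- inside + 1L
    }
    expect_equal(inside, nrow(idx))
    expect_equal(sum(cr$submask), nrow(idx))
  }
})

test_that("resample_to_64 is exact on identity, constants and linear ramps", {
  g64 <- array(runif(64^3), rep(64, 3))
  m64 <- array(round(runif(64^3)), rep(64, 3))
  out <- resample_to_64(g64, m64)
  expect_equal(out$grid, g64)
  expect_equal(out$mask_grid, m64)

  const <- array(7.5, rep(20, 3))
  outc <- resample_to_64(const, array(1, rep(20, 3)))
  expect_true(all(outc$grid == 7.5))

  ramp <- array(rep(seq(0, 1, length.out = 32), times = 32 * 32), rep(32, 3))
  outr <- resample_to_64(ramp, array(1, rep(32, 3)))
  # centre of the output grid sits at ramp midpoint
  expect_equal(mean(outr$grid[32:33, 32, 32]), 0.5, tolerance = 0.02)
  expect_gte(min(outr$grid), min(ramp))  # no overshoot
  expect_lte(max(outr$grid), max(ramp))

  expect_error(resample_to_64(array(0, c(10, 12, 10)), array(1, c(10, 12, 10))),
               "cubic")
})

test_that("resampling never loses mask foreground", {
  for (seed in 1:5) {
    cs <- toy_case(shape = 20L + 4L * seed, seed = seed + 10)
    cr <- crop_min_cube(cs$volumes[[1]], cs$mask)
    out <- resample_to_64(cr$subvolume, cr$submask)
    expect_gt(sum(out$mask_grid), 0)
    expect_true(all(out$mask_grid %in% c(0, 1)))
  }
})

test_that("normalize_intensity maps to [0,1], honours the CT window", {
  g <- array(runif(64^3, 100, 300), rep(64, 3))
  cube <- cube64(g, array(1, rep(64, 3)))
  nm <- normalize_intensity(cube, "MRI")
  expect_equal(nm$grid, (g - min(g)) / (max(g) - min(g)))

  const <- cube64(array(42, rep(64, 3)), array(1, rep(64, 3)))
  expect_true(all(normalize_intensity(const, "PET")$grid == 0))

  ct <- cube64(array(runif(64^3, -1000, 2000), rep(64, 3)),
               array(1, rep(64, 3)))
  out <- normalize_intensity(ct, "CT", ct_window = c(-100, 300))
  expect_true(all(out$grid >= 0 & out$grid <= 1))  # exhaustive range check
  # values beyond the window are saturated, so the extremes collapse
  expect_gt(mean(out$grid == 0), 0.2)
  expect_gt(mean(out$grid == 1), 0.2)
})
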