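#' Preprocess one modality of a case into a normalized 64^3 cube
#'
#' Crop the minimum circumscribed cube around the VOI, resample to 64^3
#' (trilinear intensities, nearest-neighbour mask), min-max normalize
#' (with CT Hounsfield clipping), and optionally apply mask attention.
#'
#' @param case A [load_case()] result.
#' @param modality Which modality volume to process.
#' @param attention `NULL`/`FALSE` for no attention, `TRUE` for the default
#'   [attention_config()], or an `attention_config`.
#' @param margin Crop margin in voxels (default 0).
#' @param ct_window CT clipping window in HU.
#' @return A [cube64()].
#' @export
case_to_cube <- function(case, modality, attention = TRUE, margin = 0L,
                         ct_window = c(-100, 300)) {
  stopifnot(inherits(case, "multimodal_case"))
  if (!modality %in% names(case$volumes))
    stop("case ", case$case_id, " has no ", modality, " volume", call. = FALSE)
  cr <- crop_min_cube(case$volumes[[modality]], case$mask, margin = margin)
  cube <- resample_to_64(cr$subvolume, cr$submask,
                         provenance = list(case_id = case$case_id,
                                           modality = modality, box = cr$box,
                                           side = cr$side))
  cube <- normalize_intensity(cube, modality = modality, ct_window = ct_window)
  if (isTRUE(attention)) attention <- attention_config()
  if (inherits(attention, "attention_config"))
    cube <- apply_mask_attention(cube, attention)
  cube
}

#' Extract per-modality deep-feature matrices for a whole cohort
#'
#' For every case and modality: preprocess to a cube ([case_to_cube()]),
#' extract the nine views, and run them through the backbone in one
#' batched forward pass. Rows are cases, columns the 4,608 concatenated
#' per-view features.
#'
#' @param cohort A `synthetic_cohort`, a list of `multimodal_case`, or a
#'   list of zero-argument loader functions each returning one case
#'   (cases then stream through memory one chunk at a time).
#' @param extractor A `pretrain_state` or `resnet_net` (random
#'   initialization is a supported extractor when no pretraining corpus is
#'   available).
#' @param modalities Modalities to extract (default: all present in the
#'   first case).
#' @param attention As in [case_to_cube()].
#' @param margin Crop margin in voxels.
#' @return Object of class `feature_cohort`: `features` (named list of
#'   n x 4608 matrices with attributes `modality`, `view_order`,
#'   `extractor_fingerprint`), `labels`, `case_ids`, `attention` flag.
#' @export
extract_cohort_features <- function(cohort, extractor, modalities = NULL,
                                    attention = TRUE, margin = 0L) {
  cases <- if (inherits(cohort, "synthetic_cohort")) cohort$cases else cohort
  stopifnot(length(cases) >= 1L)
  net <- as_network(extractor)
  # an element of `cases` may be a loader closure (returning the case when
  # called), so large cohorts stream from disk one chunk at a time
  materialize <- function(x) if (is.function(x)) x() else x
  if (is.null(modalities)) modalities <- names(materialize(cases[[1]])$volumes)
  fp <- network_fingerprint(net)
  n <- length(cases)
  feat_dim <- network_audit(net)$feature_dim
  mats <- lapply(modalities, function(m) matrix(NA_real_, n, 9L * feat_dim))
  names(mats) <- modalities
  labels <- character(n)
  case_ids <- character(n)
  # forward several cases per call: large batches use the GEMM much better
  vpc <- 9L * length(modalities)
  chunk <- max(1L, 108L %/% vpc)
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    views_all <- list()
    for (i in ii) {
      cs <- materialize(cases[[i]])
      labels[i] <- cs$label
      case_ids[i] <- cs$case_id
      for (mod in modalities) {
        cube <- case_to_cube(cs, mod, attention = attention, margin = margin)
        views_all <- c(views_all, extract_nine_views(cube)$views)
      }
    }
    F <- forward_views(net, views_all)  # (vpc * length(ii)) x feat_dim
    for (ci in seq_along(ii)) {
      for (j in seq_along(modalities)) {
        r0 <- (ci - 1L) * vpc + 9L * (j - 1L)
        mats[[j]][ii[ci], ] <-
          as.vector(t(F[(r0 + 1L):(r0 + 9L), , drop = FALSE]))
      }
    }
  }
  for (m in modalities) {
    attr(mats[[m]], "modality") <- m
    attr(mats[[m]], "view_order") <- VIEW_ORDER_TAG
    attr(mats[[m]], "extractor_fingerprint") <- fp
  }
  structure(list(features = mats, labels = labels, case_ids = case_ids,
                 attention = !isFALSE(attention) && !is.null(attention)),
            class = "feature_cohort")
}

#' Run the full LOOCV pipeline on a cohort
#'
#' Convenience wrapper: feature extraction (all modalities, mask attention
#' by default) followed by fused-kernel leave-one-out evaluation.
#'
#' @inheritParams extract_cohort_features
#' @param ... Passed to [loocv()].
#' @return An `evaluation_report`.
#' @export
run_pipeline <- function(cohort, extractor, modalities = NULL,
                         attention = TRUE, ...) {
  fc <- extract_cohort_features(cohort, extractor, modalities = modalities,
                                attention = attention)
  tag <- if (length(fc$features) > 1L) "Multi-Kernel" else names(fc$features)[1]
  if (fc$attention) tag <- paste0(tag, "+Mask")
  loocv(fc$features, fc$labels, method_tag = tag, ...)
}

#' Compare all single-modality and fused methods, with and without mask
#'
#' Extracts features twice (attention on and off) and delegates to
#' [compare_methods()], reproducing the structure of the headline
#' comparison (8 methods for three modalities, all pairwise DeLong tests).
#'
#' @inheritParams extract_cohort_features
#' @param ... Passed to [loocv()].
#' @return A `method_comparison`.
#' @export
compare_pipeline <- function(cohort, extractor, modalities = NULL, ...) {
  fc_mask <- extract_cohort_features(cohort, extractor, modalities = modalities,
                                     attention = TRUE)
  fc_plain <- extract_cohort_features(cohort, extractor, modalities = modalities,
                                      attention = FALSE)
  compare_methods(fc_mask$features, fc_plain$features, fc_plain$labels, ...)
}
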