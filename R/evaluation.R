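#' Confusion counts and derived rates at a score threshold
#'
#' The positive class is SZF (seizure-free). Scores strictly above
#' `threshold` predict SZF. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n, reported as percentages
#' rounded to 2 decimals. A rate whose denominator is 0 is reported as
#' `NA`, not 0.
#'
#' @param scores Numeric decision scores (higher = more SZF-like).
#' @param labels `"SZF"`/`"SZR"` labels (or -1/1 numeric, 1 = SZF).
#' @param threshold Decision threshold on the score (default 0).
#' @return List with counts `tp`, `fn`, `tn`, `fp` and percentages
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0) {
  stopifnot(length(scores) == length(labels))
  y <- to_pm1(labels)
  pred <- ifelse(scores > threshold, 1, -1)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == -1 & y == 1)
  tn <- sum(pred == -1 & y == -1); fp <- sum(pred == 1 & y == -1)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = pct(tp + tn, length(y)),
       sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp))
}

#' ROC curve and area under it
#'
#' The AUC equals the Mann-Whitney statistic with midrank tie handling:
#' `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @inheritParams confusion_metrics
#' @return List with `points` (data frame of `fpr`, `tpr` including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- to_pm1(labels)
  m <- sum(y == 1); n <- sum(y == -1)
  if (m == 0 || n == 0)
    stop("validation error: both classes must be present for ROC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)  # last index of each tie group
  pts <- data.frame(fpr = c(0, fp[keep] / n), tpr = c(0, tp[keep] / m))
  list(points = pts, auc = auc)
}

delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Placement-based estimator for two score vectors on the same cases: the
#' per-positive and per-negative placement values give an empirical
#' covariance estimate `S10/m + S01/n` of the AUC difference, from which a
#' z statistic and two-sided normal p-value are computed.
#'
#' @param scores_a,scores_b Two score vectors for the same cases.
#' @param labels Shared `"SZF"`/`"SZR"` labels.
#' @return Object of class `delong_result`: `auc_1`, `auc_2`, `var_diff`,
#'   `z`, `p_value`, `degenerate` (TRUE when the variance is 0, in which
#'   case p is reported as 1).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("contract error: score vectors and labels must have equal length",
         call. = FALSE)
  y <- to_pm1(labels)
  m <- sum(y == 1); n <- sum(y == -1)
  if (m == 0 || n == 0)
    stop("validation error: both classes must be present", call. = FALSE)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff <= 0
  z <- if (degenerate) 0 else (pa$auc - pb$auc) / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(auc_1 = pa$auc, auc_2 = pb$auc, var_diff = max(var_diff, 0),
                 z = z, p_value = p, degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.4f vs %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_1, x$auc_2, x$z, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without continuity correction, df = 1, upper-tail p-value (wraps
#' `stats::chisq.test(correct = FALSE)`).
#'
#' @param table 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop("contract error: expected a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("validation error: all margins must be positive", call. = FALSE)
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

# inner k-fold CV accuracy for a (weights, C) candidate on training kernels
inner_cv_score <- function(Ks, y, weights, C, folds) {
  correct <- 0L
  for (f in unique(folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[tr])) < 2L) next
    Kf <- Reduce(`+`, Map(function(K, w) w * K[tr, tr, drop = FALSE],
                          Ks, as.list(weights)))
    Kc <- Reduce(`+`, Map(function(K, w) w * K[te, tr, drop = FALSE],
                          Ks, as.list(weights)))
    mdl <- mksvm_train(Kf, y[tr], C = C, sigf = 7)
    correct <- correct + sum(sign(mksvm_predict(mdl, Kc)) == y[te])
  }
  correct
}

simplex_grid <- function(m, step = 0.1) {
  ticks <- round(1 / step)
  grid <- expand.grid(rep(list(0:ticks), m - 1))
  grid <- grid[rowSums(grid) <= ticks, , drop = FALSE]
  out <- cbind(grid, ticks - rowSums(grid)) * step
  unname(as.matrix(out))
}

#' Leave-one-out cross-validation of the kernel-fusion classifier
#'
#' For each case, a model is trained on the remaining n-1 cases:
#' standardization statistics, per-modality kernels, kernel weights and C
#' are all computed strictly inside the training fold (no leakage), the
#' held-out case is scored through the fold's cross-kernel, and the n
#' out-of-fold scores are summarized (confusion at threshold 0, ROC, AUC).
#'
#' @param features A cases x features matrix, or a named list of such
#'   matrices (one per modality) fused by convex kernel combination.
#' @param labels `"SZF"`/`"SZR"` labels (positive class SZF).
#' @param kernel `"linear"` (default) or `"rbf"` per-modality kernel.
#' @param gamma RBF bandwidth (default `1/p`).
#' @param C Soft-margin cost (default 1); ignored when `C_grid` is given.
#' @param weights Fixed fusion weights (`"uniform"` default) or `"grid"`
#'   for selection over the simplex (step 0.1) by inner 5-fold CV, or a
#'   numeric vector.
#' @param C_grid Optional numeric grid for inner-CV selection of C.
#' @param inner_k Inner CV fold count for hyperparameter selection.
#' @param method_tag Label attached to the report.
#' @return Object of class `evaluation_report`: out-of-fold `scores`,
#'   `labels`, confusion counts and rates, `roc`, `auc`, `method_tag`,
#'   `n`.
#' @export
loocv <- function(features, labels, kernel = c("linear", "rbf"), gamma = NULL,
                  C = 1, weights = "uniform", C_grid = NULL, inner_k = 5L,
                  method_tag = "fused") {
  kernel <- match.arg(kernel)
  if (is.matrix(features) || is.data.frame(features))
    features <- list(all = as.matrix(features))
  features <- lapply(features, as.matrix)
  n <- nrow(features[[1]])
  if (n < 3L) stop("validation error: LOOCV needs n >= 3", call. = FALSE)
  y <- to_pm1(labels)
  if (length(y) != n) stop("labels length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("validation error: single-class cohort", call. = FALSE)
  m <- length(features)
  fixed_w <- if (is.numeric(weights)) weights
             else if (identical(weights, "uniform")) rep(1 / m, m)
             else NULL
  select <- is.null(fixed_w) || !is.null(C_grid)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Ks <- list(); Kc <- list()
    for (mod in names(features)) {
      sc <- scaler_fit(features[[mod]][tr, , drop = FALSE])
      xt <- scaler_apply(sc, features[[mod]][tr, , drop = FALSE])
      xe <- scaler_apply(sc, features[[mod]][i, , drop = FALSE])
      km <- compute_kernel(xt, kind = kernel, gamma = gamma, modality_tag = mod)
      Ks[[mod]] <- km$matrix
      Kc[[mod]] <- compute_cross_kernel(xe, xt, km, gamma = gamma)
    }
    w <- fixed_w
    Ci <- C
    if (select) {
      folds <- rep_len(seq_len(inner_k), length(tr))
      wgrid <- if (is.null(fixed_w)) simplex_grid(m, 0.1) else matrix(fixed_w, 1)
      cgrid <- if (is.null(C_grid)) C else C_grid
      best <- -1L
      for (ci in cgrid) for (r in seq_len(nrow(wgrid))) {
        sc_cv <- inner_cv_score(Ks, y[tr], wgrid[r, ], ci, folds)
        if (sc_cv > best) { best <- sc_cv; w <- wgrid[r, ]; Ci <- ci }
      }
    }
    Kf <- Reduce(`+`, Map(function(K, wt) wt * K, Ks, as.list(w)))
    Kcf <- Reduce(`+`, Map(function(K, wt) wt * K, Kc, as.list(w)))
    mdl <- mksvm_train(Kf, y[tr], C = Ci)
    scores[i] <- mksvm_predict(mdl, Kcf)
  }
  evaluation_report(scores, labels, method_tag)
}

#' Build an evaluation report from out-of-fold scores
#'
#' @param scores Out-of-fold decision scores.
#' @param labels True labels.
#' @param method_tag Method label (modality set x attention on/off).
#' @return An `evaluation_report` (see [loocv()]).
#' @export
evaluation_report <- function(scores, labels, method_tag = "method") {
  cm <- confusion_metrics(scores, labels)
  rc <- roc_auc(scores, labels)
  structure(c(list(scores = scores,
                   labels = as.character(to_labels(labels)),
                   method_tag = method_tag, n = length(scores)),
              cm, list(roc = rc$points, auc = rc$auc)),
            class = "evaluation_report")
}

to_labels <- function(y) {
  if (is.numeric(y)) ifelse(y > 0, "SZF", "SZR") else as.character(y)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (n = %d; positive class SZF)\n",
              x$method_tag, x$n))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Serialize an evaluation report to JSON (and ROC to CSV)
#'
#' @param report An `evaluation_report`.
#' @param json_path Output JSON path.
#' @param roc_path Optional CSV path for the ROC points.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, roc_path = NULL) {
  obj <- unclass(report)
  obj$roc <- NULL
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_path)) write.csv(report$roc, roc_path, row.names = FALSE)
  invisible(json_path)
}

#' Compare prediction methods as in the headline performance table
#'
#' Runs LOOCV for every single-modality kernel and the fused multi-kernel,
#' each with and without mask attention (8 methods when three modalities
#' are available), and computes all pairwise DeLong comparisons of the
#' out-of-fold score vectors.
#'
#' @param features_mask Named list of per-modality feature matrices
#'   extracted *with* mask attention.
#' @param features_nomask Same, extracted *without* attention.
#' @param labels Case labels.
#' @param ... Passed to [loocv()] (kernel, C, ...).
#' @return Object of class `method_comparison`: `table` (one row per
#'   method: accuracy/sensitivity/specificity/AUC), `delong` (one row per
#'   method pair), `reports` (named list of `evaluation_report`s).
#' @export
compare_methods <- function(features_mask, features_nomask, labels, ...) {
  mods <- names(features_nomask)
  reports <- list()
  for (mod in mods)
    reports[[mod]] <- loocv(features_nomask[[mod]], labels,
                            method_tag = mod, ...)
  if (length(mods) > 1L)
    reports[["Multi-Kernel"]] <- loocv(features_nomask, labels,
                                       method_tag = "Multi-Kernel", ...)
  if (!is.null(features_mask)) {
    for (mod in names(features_mask))
      reports[[paste0(mod, "+Mask")]] <-
        loocv(features_mask[[mod]], labels,
              method_tag = paste0(mod, "+Mask"), ...)
    if (length(features_mask) > 1L)
      reports[["Multi-Kernel+Mask"]] <-
        loocv(features_mask, labels, method_tag = "Multi-Kernel+Mask", ...)
  }
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(method = r$method_tag, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               auc = round(r$auc, 4))))
  rownames(tab) <- NULL
  pairs <- utils::combn(names(reports), 2)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dl <- delong_test(reports[[a]]$scores, reports[[b]]$scores, labels)
    data.frame(method_1 = a, method_2 = b, auc_1 = dl$auc_1, auc_2 = dl$auc_2,
               z = dl$z, p_value = dl$p_value)
  }))
  structure(list(table = tab, delong = delong, reports = reports),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Prediction performance by method (LOOCV, positive class SZF):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
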