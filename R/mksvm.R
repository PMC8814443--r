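#' Fit feature standardization statistics
#'
#' Column means and standard deviations computed on training rows only
#' (leave-one-out folds each refit these, so the held-out case never leaks
#' into the scaling). Zero-variance columns are dropped from
#' standardization rather than causing failure; their indices are recorded.
#'
#' @param x Numeric feature matrix (cases x features).
#' @return Object of class `feature_scaler` with `center`, `scale`, `keep`.
#' @export
scaler_fit <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- colMeans(x)
  sds <- sqrt(pmax(colMeans(x^2) - ctr^2, 0) * n / max(n - 1, 1))
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < ncol(x) && isTRUE(getOption("voipredict.verbose", FALSE)))
    message(sprintf("dropping %d zero-variance feature column(s)",
                    ncol(x) - length(keep)))
  structure(list(center = ctr[keep], scale = sds[keep], keep = keep,
                 p = ncol(x)),
            class = "feature_scaler")
}

#' Apply fitted standardization
#'
#' @param scaler A [scaler_fit()] result.
#' @param x Feature matrix with the same column count the scaler saw.
#' @return Standardized matrix restricted to the retained columns.
#' @export
scaler_apply <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != scaler$p) stop("feature width differs from scaler", call. = FALSE)
  sweep(sweep(x[, scaler$keep, drop = FALSE], 2, scaler$center, "-"),
        2, scaler$scale, "/")
}

new_kernel_matrix <- function(K, modality_tag, normalization_tag, factor = 1) {
  K <- (K + t(K)) / 2  # enforce exact symmetry against float round-off
  structure(list(matrix = K, modality_tag = modality_tag,
                 normalization_tag = normalization_tag,
                 trace_factor = factor),
            class = "kernel_matrix")
}

#' Compute a per-modality case similarity kernel
#'
#' Linear (inner products) or Gaussian RBF (`exp(-gamma * ||x - y||^2)`,
#' default `gamma = 1/p`) on standardized features, followed by trace
#' normalization `K <- n * K / trace(K)` so that no modality dominates the
#' fused kernel by scale. The applied trace factor is stored so that
#' cross-kernels for new cases can be normalized consistently.
#'
#' @param x Standardized feature matrix (cases x features).
#' @param kind `"linear"` or `"rbf"`.
#' @param gamma RBF bandwidth (ignored for linear; default `1/ncol(x)`).
#' @param modality_tag Label stored on the kernel.
#' @return Object of class `kernel_matrix`: fields `matrix` (n x n,
#'   symmetric PSD), `modality_tag`, `normalization_tag`, `trace_factor`.
#' @export
compute_kernel <- function(x, kind = c("linear", "rbf"), gamma = NULL,
                           modality_tag = "modality") {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (kind == "linear") {
    K <- tcrossprod(x)
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    sq <- rowSums(x^2)
    D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
    K <- exp(-gamma * D2)
  }
  tr <- sum(diag(K))
  fac <- if (tr > 0) nrow(K) / tr else 1
  new_kernel_matrix(K * fac, modality_tag, paste0(kind, "+trace"), fac)
}

#' Cross-kernel between new cases and training cases
#'
#' Uses the training kernel's stored trace factor, so the scores of new
#' cases live on the same scale as the training kernel.
#'
#' @param x_new Standardized features of the new cases (rows).
#' @param x_train Standardized training features (the rows the model saw).
#' @param train_kernel The [compute_kernel()] result fit on `x_train`.
#' @param gamma RBF bandwidth; must match the training kernel's.
#' @return Numeric matrix (new cases x training cases).
#' @export
compute_cross_kernel <- function(x_new, x_train, train_kernel, gamma = NULL) {
  kind <- sub("\\+trace$", "", train_kernel$normalization_tag)
  x_new <- matrix(as.numeric(x_new), ncol = ncol(as.matrix(x_train)))
  if (kind == "linear") {
    K <- x_new %*% t(as.matrix(x_train))
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(as.matrix(x_train))
    D2 <- pmax(outer(rowSums(x_new^2), rowSums(as.matrix(x_train)^2), "+") -
                 2 * x_new %*% t(as.matrix(x_train)), 0)
    K <- exp(-gamma * D2)
  }
  K * train_kernel$trace_factor
}

#' Convex combination of per-modality kernels
#'
#' Element-wise fusion `sum_m beta_m K_m` with nonnegative weights summing
#' to 1. A convex combination of positive semidefinite kernels is positive
#' semidefinite.
#'
#' @param kernels List of [compute_kernel()] results on the same cases in
#'   the same order.
#' @param weights Nonnegative numeric vector summing to 1 (length matching
#'   `kernels`); default uniform.
#' @return A fused `kernel_matrix` with `modality_tag = "fused"`.
#' @export
combine_kernels <- function(kernels, weights = NULL) {
  m <- length(kernels)
  stopifnot(m >= 1L)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("kernel weights must be nonnegative and sum to 1", call. = FALSE)
  n <- nrow(kernels[[1]]$matrix)
  for (k in kernels)
    if (!identical(dim(k$matrix), dim(kernels[[1]]$matrix)))
      stop("contract error: kernels have mismatched case sets", call. = FALSE)
  K <- matrix(0, n, n)
  for (i in seq_len(m)) K <- K + weights[i] * kernels[[i]]$matrix
  out <- new_kernel_matrix(K, "fused", "convex-combination")
  out$weights <- weights
  out
}

#' Check symmetry and positive semidefiniteness of a kernel
#'
#' @param K A `kernel_matrix` or plain matrix.
#' @param tol Eigenvalue tolerance (default `-1e-6`).
#' @return `TRUE` invisibly; stops if violated.
#' @export
check_psd <- function(K, tol = 1e-6) {
  if (inherits(K, "kernel_matrix")) K <- K$matrix
  if (max(abs(K - t(K))) > 1e-8) stop("kernel is not symmetric", call. = FALSE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop("kernel is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

#' Train a soft-margin SVM on a precomputed kernel
#'
#' Solves the C-SVM dual
#' `max sum(alpha) - 0.5 t(alpha*y) K (alpha*y)` subject to
#' `0 <= alpha <= C`, `sum(alpha * y) = 0`, with an interior-point
#' quadratic-program solver on the precomputed kernel, and recovers the
#' bias from the on-margin support vectors (KKT midpoint if none). The
#' decision function is `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; positive
#' scores predict the positive class (SZF when labels are outcome labels).
#'
#' @param K Training kernel: a `kernel_matrix` or plain symmetric matrix
#'   (train x train).
#' @param y Binary labels: a factor/character with positive class `"SZF"`,
#'   or a numeric vector in \{-1, 1\}.
#' @param C Soft-margin cost (default 1).
#' @param sigf Significant figures of dual convergence for the QP solver.
#' @return Object of class `mksvm_model`: `alpha_y` (signed dual
#'   coefficients, length n_train), `b`, `support` (indices with
#'   `alpha > 0`), `C`, `y`, `train_scores`.
#' @export
mksvm_train <- function(K, y, C = 1, sigf = 9) {
  if (inherits(K, "kernel_matrix")) K <- K$matrix
  K <- as.matrix(K)
  n <- nrow(K)
  stopifnot(ncol(K) == n, C > 0)
  yy <- to_pm1(y)
  if (length(yy) != n) stop("labels length differs from kernel size", call. = FALSE)
  if (length(unique(yy)) < 2L)
    stop("validation error: both classes must be present for training", call. = FALSE)
  H <- (yy %o% yy) * K
  # fold-wise column centering puts the all-ones vector in the kernel's
  # null space, which is exactly the equality-constraint direction, so the
  # interior-point Newton system can be singular; retry with a growing
  # ridge (the subsequent active-set polish solves the exact un-ridged
  # KKT system anyway)
  qp <- NULL
  for (ridge in c(0, 1e-8, 1e-4, 1e-2, 1)) {
    qp <- tryCatch(
      kernlab::ipop(c = matrix(-1, n, 1),
                    H = H + diag(ridge * mean(diag(K)), n),
                    A = matrix(yy, 1), b = 0, l = matrix(0, n, 1),
                    u = matrix(C, n, 1), r = 0, sigf = sigf, maxiter = 400),
      error = function(e) NULL)
    if (!is.null(qp)) break
  }
  if (is.null(qp)) stop("SVM dual solver failed to converge", call. = FALSE)
  a <- pmin(pmax(as.vector(kernlab::primal(qp)), 0), C)
  eps <- 1e-6 * C
  a[a < eps] <- 0
  a[a > C - eps] <- C
  # active-set polish: with the support structure fixed by the QP solution,
  # the free (on-margin) dual coefficients and the bias satisfy an exact
  # linear KKT system; solving it removes the interior-point residual
  free <- which(a > eps & a < C - eps)
  if (length(free) > 0) {
    cb <- a * yy
    cb[free] <- 0
    rhs <- c(yy[free] - as.vector(K[free, , drop = FALSE] %*% cb), -sum(cb))
    A <- rbind(cbind(K[free, free, drop = FALSE], 1), c(rep(1, length(free)), 0))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      cf <- sol[seq_along(free)]
      af <- cf * yy[free]
      if (all(af > -eps & af < C + eps)) a[free] <- pmin(pmax(af, 0), C)
    }
  }
  f0 <- as.vector(K %*% (a * yy))
  on_margin <- which(a > eps & a < C - eps)
  b <- if (length(on_margin) > 0) {
    mean(yy[on_margin] - f0[on_margin])
  } else {
    # all alphas at a bound: b lies in the KKT interval; take its midpoint.
    # e_i = y_i - f0_i; lower bounds come from correctly-classified
    # positives (a = 0) and bound negatives (a = C), upper bounds from the
    # mirror sets.
    e <- yy - f0
    lo_set <- e[(yy == 1 & a <= eps) | (yy == -1 & a >= C - eps)]
    up_set <- e[(yy == 1 & a >= C - eps) | (yy == -1 & a <= eps)]
    lo <- if (length(lo_set)) max(lo_set) else -Inf
    up <- if (length(up_set)) min(up_set) else Inf
    if (is.finite(lo) && is.finite(up)) (lo + up) / 2
    else if (is.finite(lo)) lo else if (is.finite(up)) up else 0
  }
  structure(list(alpha_y = a * yy, b = b, support = which(a > eps),
                 C = C, y = yy, n_train = n,
                 train_scores = f0 + b),
            class = "mksvm_model")
}

to_pm1 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1/1", call. = FALSE)
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (all(y %in% LABEL_LEVELS)) return(ifelse(y == "SZF", 1, -1))
  lv <- sort(unique(y))
  if (length(lv) != 2L) stop("need exactly two classes", call. = FALSE)
  ifelse(y == lv[1], 1, -1)
}

#' Decision scores for new cases against a trained model
#'
#' `f(x) = K_cross %*% (alpha * y) + b`, reproducible bit-compatibly from
#' the stored coefficients. The cross kernel must be computed with the
#' model's kernel recipe and the training-fold standardization statistics.
#'
#' @param model A [mksvm_train()] result.
#' @param k_cross Numeric matrix (new cases x n_train).
#' @return Numeric vector of continuous decision scores; sign gives the
#'   predicted class, magnitude feeds the ROC.
#' @export
mksvm_predict <- function(model, k_cross) {
  k_cross <- matrix(as.numeric(k_cross), ncol = model$n_train)
  if (ncol(k_cross) != model$n_train)
    stop("contract error: cross-kernel has wrong training width", call. = FALSE)
  as.vector(k_cross %*% model$alpha_y + model$b)
}

#' Export a kernel matrix as delimited text with case IDs
#'
#' @param kernel A `kernel_matrix`.
#' @param case_ids Character vector of case identifiers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_kernel <- function(kernel, case_ids, path) {
  K <- kernel$matrix
  stopifnot(length(case_ids) == nrow(K))
  out <- data.frame(case_id = case_ids, K)
  names(out)[-1] <- case_ids
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
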