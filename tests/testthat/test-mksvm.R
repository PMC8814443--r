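test_that("standardization drops zero-variance columns instead of failing", {
  set.seed(1)
  x <- cbind(matrix(rnorm(40), 10, 4), 7)  # constant 5th column
  sc <- scaler_fit(x)
  expect_equal(sc$keep, 1:4)
  z <- scaler_apply(sc, x)
  expect_equal(ncol(z), 4)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_error(scaler_apply(sc, x[, 1:3]), "width")
})

test_that("linear kernel matches a brute-force double loop", {
  set.seed(2)
  x <- matrix(rnorm(6 * 20), 6, 20)
  km <- compute_kernel(x, "linear")
  raw <- km$matrix / km$trace_factor
  bf <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) bf[i, j] <- sum(x[i, ] * x[j, ])
  expect_lt(max(abs(raw - bf)), 1e-10)
  # trace normalization: trace equals n afterwards
  expect_equal(sum(diag(km$matrix)), 6, tolerance = 1e-10)
  expect_silent(check_psd(km))
})

test_that("orthonormal rows give the identity kernel; rbf limits behave", {
  x <- diag(4)  # orthonormal feature rows
  km <- compute_kernel(x, "linear")
  expect_equal(km$matrix / km$trace_factor, diag(4), tolerance = 1e-12)
  set.seed(3)
  y <- matrix(rnorm(5 * 8), 5, 8)
  k0 <- compute_kernel(y, "rbf", gamma = 1e-12)
  expect_true(all(abs(k0$matrix / k0$trace_factor - 1) < 1e-9))
  krbf <- compute_kernel(y, "rbf", gamma = 0.07)
  bf <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    bf[i, j] <- exp(-0.07 * sum((y[i, ] - y[j, ])^2))
  expect_lt(max(abs(krbf$matrix / krbf$trace_factor - bf)), 1e-10)
})

test_that("kernel fusion is a convex combination that preserves PSD", {
  set.seed(4)
  xs <- lapply(1:3, function(i) matrix(rnorm(8 * 10), 8, 10))
  ks <- lapply(xs, compute_kernel, kind = "linear")
  expect_equal(combine_kernels(ks, c(1, 0, 0))$matrix, ks[[1]]$matrix)
  same <- combine_kernels(list(ks[[1]], ks[[1]], ks[[1]]))
  expect_equal(same$matrix, ks[[1]]$matrix, tolerance = 1e-12)
  mix <- combine_kernels(ks[1:2], c(0.4, 0.6))
  ev <- eigen(mix$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-6)
  expect_error(combine_kernels(ks, c(0.5, 0.6, 0.2)), "sum to 1")
  expect_error(combine_kernels(ks, c(-0.1, 0.6, 0.5)), "nonnegative")
  k_small <- compute_kernel(matrix(rnorm(30), 5, 6), "linear")
  expect_error(combine_kernels(list(ks[[1]], k_small)), "contract error")
})

test_that("a separable toy problem is classified perfectly", {
  x <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  y <- c("SZR", "SZR", "SZF", "SZF")
  km <- compute_kernel(x, "linear")
  mdl <- mksvm_train(km, y, C = 10)
  expect_true(all(sign(mdl$train_scores) == c(-1, -1, 1, 1)))
  expect_error(mksvm_train(km, rep("SZF", 4)), "validation error")
})

test_that("the precomputed-kernel path equals the explicit-feature path", {
  set.seed(6)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- factor(rep(c("SZF", "SZR"), each = 15), levels = c("SZF", "SZR"))
  x[y == "SZF", 1] <- x[y == "SZF", 1] + 1.2
  K <- tcrossprod(x)  # un-normalized linear kernel for exact comparison
  mdl <- mksvm_train(K, y, C = 1)
  mine <- mksvm_predict(mdl, K)
  # explicit-feature route: w = X' (alpha * y), scores = X w + b; agreement
  # validates the whole kernel plumbing (inner products, cross-kernel, bias)
  w <- crossprod(x, mdl$alpha_y)
  explicit <- as.vector(x %*% w) + mdl$b
  expect_lt(max(abs(mine - explicit)), 1e-6)
  # the solution itself is at the dual optimum: KKT residual on free SVs
  free <- abs(mdl$alpha_y) > 1e-6 & abs(mdl$alpha_y) < 1 - 1e-6
  expect_lt(max(abs(mdl$y[free] * mine[free] - 1)), 1e-9)
  expect_lt(abs(sum(mdl$alpha_y)), 1e-9)
  # and matches an independent solver on raw features at that solver's
  # convergence tolerance
  ref <- kernlab::ksvm(x, y, type = "C-svc", C = 1, kernel = "vanilladot",
                       kpar = list(), scaled = FALSE, tol = 1e-9)
  theirs <- as.vector(kernlab::predict(ref, x, type = "decision"))
  s <- sign(stats::cor(mine, theirs))  # kernlab orients by first label
  expect_lt(max(abs(mine - s * theirs)), 1e-4)
  expect_equal(sort(kernlab::SVindex(ref)), which(abs(mdl$alpha_y) > 1e-6))
})

test_that("flipping the labels negates the decision function", {
  set.seed(7)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(c(1, -1), 10)
  K <- tcrossprod(x)
  m1 <- mksvm_train(K, y, C = 1, sigf = 10)
  m2 <- mksvm_train(K, -y, C = 1, sigf = 10)
  expect_lt(max(abs(mksvm_predict(m1, K) + mksvm_predict(m2, K))), 1e-5)
})

test_that("prediction is consistent, deterministic and weight-continuous", {
  set.seed(8)
  xs <- lapply(1:2, function(i) {
    x <- matrix(rnorm(24 * 6), 24, 6)
    x[1:12, i] <- x[1:12, i] + 1
    x
  })
  y <- rep(c("SZF", "SZR"), each = 12)
  ks <- lapply(xs, function(x) compute_kernel(scale(x), "linear"))
  # training case scored against its own model reproduces train_scores
  mdl <- mksvm_train(ks[[1]], y)
  expect_equal(mksvm_predict(mdl, ks[[1]]$matrix[3, , drop = FALSE]),
               mdl$train_scores[3], tolerance = 1e-10)
  # duplicate test rows give duplicate scores
  two <- ks[[1]]$matrix[c(5, 5), ]
  sc <- mksvm_predict(mdl, two)
  expect_identical(sc[1], sc[2])
  # scores vary continuously along the fusion-weight path
  prev <- NULL
  for (w in seq(0, 1, by = 0.1)) {
    Kf <- combine_kernels(ks, c(w, 1 - w))
    m <- mksvm_train(Kf, y)
    s <- mksvm_predict(m, Kf$matrix)
    expect_true(all(is.finite(s)))
    if (!is.null(prev)) expect_lt(max(abs(s - prev)), 1.0)
    prev <- s
  }
})

test_that("kernel export writes a readable case-labelled table", {
  set.seed(9)
  km <- compute_kernel(matrix(rnorm(12), 4, 3), "linear")
  f <- withr::local_tempfile(fileext = ".csv")
  export_kernel(km, paste0("case_", 1:4), f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$case_id, paste0("case_", 1:4))
  expect_equal(as.matrix(back[, -1]), km$matrix, tolerance = 1e-8,
               ignore_attr = TRUE)
})
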