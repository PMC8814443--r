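test_that("confusion metrics reproduce the headline arithmetic", {
  # 76/3 true/missed SZF and 53/9 true/missed SZR
  scores <- c(rep(1, 76), rep(-1, 3), rep(-1, 53), rep(1, 9))
  labels <- c(rep("SZF", 79), rep("SZR", 62))
  cm <- confusion_metrics(scores, labels)
  expect_equal(cm$tp, 76); expect_equal(cm$fn, 3)
  expect_equal(cm$tn, 53); expect_equal(cm$fp, 9)
  expect_equal(cm$accuracy, 91.49)
  expect_equal(cm$sensitivity, 96.20)
  expect_equal(cm$specificity, 85.48)
})

test_that("confusion metrics: perfection, symmetry and missing classes", {
  y <- rep(c("SZF", "SZR"), each = 5)
  s <- c(rep(2, 5), rep(-2, 5))
  cm <- confusion_metrics(s, y)
  expect_equal(c(cm$accuracy, cm$sensitivity, cm$specificity), rep(100, 3))
  # inverting labels with negated scores swaps sensitivity and specificity
  s2 <- c(rep(1, 3), rep(-1, 2), rep(-1, 4), rep(1, 1))
  cm_a <- confusion_metrics(s2, y)
  cm_b <- confusion_metrics(-s2, rev(sort(y)))  # relabel: SZF <-> SZR
  expect_equal(cm_a$sensitivity, cm_b$specificity)
  expect_equal(cm_a$specificity, cm_b$sensitivity)
  # a class absent: its rate is NA, not 0
  cm_na <- confusion_metrics(c(1, -1), c("SZF", "SZF"))
  expect_true(is.na(cm_na$specificity))
  expect_false(is.na(cm_na$sensitivity))
})

test_that("AUC equals the concordant-pair count, including ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("SZR", "SZR", "SZF", "SZF"))$auc, 0.75)
  expect_equal(roc_auc(c(-1, -2, 3, 4), c("SZR", "SZR", "SZF", "SZF"))$auc, 1.0)
  expect_equal(roc_auc(rep(1.5, 8), rep(c("SZF", "SZR"), 4))$auc, 0.5)
  # exhaustive pairwise oracle on random instances with heavy ties
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(c(10, 50, 200), 1)
    y <- ifelse(runif(n) < 0.45, "SZF", "SZR")
    if (length(unique(y)) < 2) y[1:2] <- c("SZF", "SZR")
    s <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties
    expect_identical(roc_auc(s, y)$auc, bf_auc(s, y))
  }
  expect_error(roc_auc(1:3, rep("SZF", 3)), "validation error")
})

test_that("ROC points trace the empirical curve endpoints", {
  rc <- roc_auc(c(0.9, 0.8, 0.4, 0.2), c("SZF", "SZR", "SZF", "SZR"))
  expect_equal(rc$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(rc$points[nrow(rc$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
})

test_that("DeLong matches the brute-force placement oracle exactly", {
  # 3 positives + 3 negatives hand case
  labels <- c(rep("SZF", 3), rep("SZR", 3))
  sa <- c(2.1, 0.4, 1.7, -0.3, 0.5, -1.2)
  sb <- c(1.0, 0.8, 0.2, 0.9, -0.7, -0.2)
  dl <- delong_test(sa, sb, labels)
  bf <- bf_delong(sa, sb, labels)
  expect_equal(dl$auc_1, bf$auc_1, tolerance = 1e-10)
  expect_equal(dl$auc_2, bf$auc_2, tolerance = 1e-10)
  expect_equal(dl$var_diff, bf$var_diff, tolerance = 1e-10)
  expect_equal(dl$z, bf$z, tolerance = 1e-10)
  expect_equal(dl$p_value, bf$p, tolerance = 1e-10)
  # antisymmetry
  dl2 <- delong_test(sb, sa, labels)
  expect_equal(dl2$z, -dl$z, tolerance = 1e-12)
  expect_equal(dl2$p_value, dl$p_value, tolerance = 1e-12)
  # identical scores: degenerate, p = 1
  dl0 <- delong_test(sa, sa, labels)
  expect_true(dl0$degenerate)
  expect_equal(dl0$p_value, 1)
  expect_equal(dl0$auc_1, dl0$auc_2)
  expect_error(delong_test(sa, sb[1:5], labels), "contract error")
})

test_that("DeLong agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  n <- 60
  y <- rep(c("SZF", "SZR"), each = n / 2)
  base <- rnorm(n) + (y == "SZF")
  sa <- base + rnorm(n, sd = 0.5)
  sb <- base + rnorm(n, sd = 0.8)
  dl <- delong_test(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, levels = c("SZR", "SZF"),
                                  direction = "<", quiet = TRUE),
                        pROC::roc(y, sb, levels = c("SZR", "SZF"),
                                  direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(unname(dl$z), unname(ref$statistic), tolerance = 1e-8)
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("the DeLong z statistic is near-standard-normal under the null", {
  set.seed(99)
  zs <- replicate(150, {
    y <- rep(c("SZF", "SZR"), each = 40)
    delong_test(rnorm(80), rnorm(80), y)$z
  })
  expect_gt(mean(abs(zs) < 1.96), 0.90)
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(sd(zs), 0.75); expect_lt(sd(zs), 1.3)
})

test_that("chi-square on 2x2 tables matches hand-computed cases", {
  res <- chi_square_test(matrix(c(34, 45, 31, 31), 2, byrow = TRUE))
  expect_equal(round(res$statistic, 3), 0.678)
  expect_equal(res$df, 1)
  expect_equal(chi_square_test(matrix(c(20, 30, 40, 60), 2,
                                      byrow = TRUE))$statistic, 0)
  # all |O-E| = 5 with E = 5 in each cell: chi-square = 4 * 25/5 = 20
  expect_equal(chi_square_test(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(chi_square_test(matrix(1:6, 2)), "contract error")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("LOOCV scores every case exactly once and is leakage-safe by construction", {
  set.seed(12)
  n <- 24
  y <- rep(c("SZF", "SZR"), each = n / 2)
  feats <- list(
    A = matrix(rnorm(n * 15), n, 15) + 0.8 * (y == "SZF"),
    B = matrix(rnorm(n * 10), n, 10))
  rep1 <- loocv(feats, y)
  expect_length(rep1$scores, n)
  expect_equal(rep1$tp + rep1$fn, sum(y == "SZF"))
  expect_equal(rep1$tn + rep1$fp, sum(y == "SZR"))
  expect_equal(rep1$accuracy, round(100 * (rep1$tp + rep1$tn) / n, 2))
  expect_gte(rep1$auc, 0); expect_lte(rep1$auc, 1)
  # deterministic
  expect_identical(rep1$scores, loocv(feats, y)$scores)
  # a single feature matrix works the same way
  rep2 <- loocv(feats$A, y, method_tag = "A")
  expect_equal(rep2$method_tag, "A")
  expect_error(loocv(feats, rep("SZF", n)), "validation error")
  expect_error(loocv(feats$A[1:2, ], y[1:2]), "n >= 3")
})

test_that("inner-CV hyperparameter selection runs inside the training fold", {
  set.seed(13)
  n <- 18
  y <- rep(c("SZF", "SZR"), each = n / 2)
  feats <- list(good = matrix(rnorm(n * 8), n, 8) + 1.2 * (y == "SZF"),
                noise = matrix(rnorm(n * 8), n, 8))
  rep_grid <- loocv(feats, y, weights = "grid", inner_k = 3)
  expect_length(rep_grid$scores, n)
  # the informative modality should dominate: grid fusion beats noise alone
  rep_noise <- loocv(feats$noise, y)
  expect_gte(rep_grid$auc, rep_noise$auc - 0.15)
  rep_c <- loocv(feats$good, y, C_grid = c(0.1, 1))
  expect_length(rep_c$scores, n)
})

test_that("reports serialize to JSON with ROC CSV", {
  set.seed(14)
  y <- rep(c("SZF", "SZR"), 8)
  r <- evaluation_report(rnorm(16) + (y == "SZF"), y, "demo")
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_report(r, jf, cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$auc, r$auc, tolerance = 1e-12)
  expect_equal(back$method_tag, "demo")
  expect_equal(nrow(read.csv(cf)), nrow(r$roc))
})

test_that("compare_methods yields the 8-method table and all pairwise DeLong rows", {
  set.seed(15)
  n <- 20
  y <- rep(c("SZF", "SZR"), each = n / 2)
  mkf <- function(shift) {
    lapply(c(MRI = 1, PET = 2, CT = 3), function(i)
      matrix(rnorm(n * 10), n, 10) + shift * i / 3 * (y == "SZF"))
  }
  cmp <- compare_methods(mkf(1.0), mkf(0.6), y)
  expect_equal(nrow(cmp$table), 8)
  expect_setequal(cmp$table$method,
                  c("MRI", "PET", "CT", "Multi-Kernel", "MRI+Mask",
                    "PET+Mask", "CT+Mask", "Multi-Kernel+Mask"))
  expect_equal(nrow(cmp$delong), choose(8, 2))
  expect_true(all(cmp$delong$p_value >= 0 & cmp$delong$p_value <= 1))
})
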