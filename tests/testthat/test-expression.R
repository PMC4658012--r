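sim_design <- function(n, p, seed = 1) {
  m <- affinityscan:::with_seed(seed, matrix(rnorm(n * p), n, p))
  dimnames(m) <- list(sprintf("g%04d", seq_len(n)), sprintf("pwm%02d", seq_len(p)))
  m
}

test_that("expression normalization adds the smallest nonzero value and log2s", {
  out <- normalize_expression(c(g1 = 0, g2 = 1, g3 = 3))
  expect_equal(unname(out), c(0, 1, 2))        # log2(1), log2(2), log2(4)
  v <- c(a = 7, b = 7)
  expect_equal(unname(normalize_expression(v)), rep(log2(14), 2))
  x <- c(5, 0, 2, 9, 0.4)
  expect_true(all(diff(normalize_expression(sort(x))) >= 0))
  expect_error(normalize_expression(c(0, 0)), "all expression values")
  expect_error(normalize_expression(c(-1, 2)), "non-negative")
  # per-column pseudo-counts for matrices
  m <- cbind(l1 = c(0, 1, 3), l2 = c(0, 2, 6))
  nm <- normalize_expression(m)
  expect_equal(unname(nm[, 1]), c(0, 1, 2))
  expect_equal(unname(nm[, 2]), c(1, 2, 3))
})

test_that("noise-free linear data is recovered exactly with adjusted R2 of 1", {
  X <- sim_design(100, 5)
  cc <- c(2, -1, 0.5, 0, 3)
  y <- setNames(drop(X %*% cc) + 4, rownames(X))
  fit <- fit_linear(X, y)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[-1]), cc, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), 4, tolerance = 1e-6)
  expect_equal(unname(predict(fit, X)), unname(y), tolerance = 1e-6)
  expect_equal(sum(residuals(fit)^2), 0, tolerance = 1e-12)
})

test_that("permuted expression yields near-zero adjusted R2 and calibrated p", {
  X <- sim_design(300, 5, seed = 2)
  set.seed(3)
  ps <- replicate(100, fit_linear(X, setNames(rnorm(300), rownames(X)))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  r2s <- replicate(20, fit_linear(X, setNames(rnorm(300), rownames(X)))$adj_r2)
  expect_lt(mean(r2s), 0.05)
})

test_that("R2 at a set signal-to-noise ratio matches the analytic value", {
  X <- sim_design(4000, 3, seed = 4)
  cc <- c(1, 1, 1)
  signal <- drop(X %*% cc)
  noise_sd <- stats::sd(signal)            # SNR 1 -> R2 = 0.5
  set.seed(5)
  y <- setNames(signal + rnorm(4000, 0, noise_sd), rownames(X))
  fit <- fit_linear(X, y)
  expect_equal(fit$r2, 0.5, tolerance = 0.05)
  expect_gte(fit$r2, fit$adj_r2)
})

test_that("genes with missing or -Inf affinities are dropped and reported", {
  X <- sim_design(50, 3, seed = 6)
  X[3, 2] <- NA
  X[7, 1] <- -Inf
  y <- setNames(drop(replace(X, !is.finite(X), 0) %*% c(1, 1, 1)),
                rownames(X))
  fit <- fit_linear(X, y)
  expect_setequal(fit$dropped, c("g0003", "g0007"))
  expect_equal(fit$n_genes, 48)
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- sim_design(40, 2, seed = 7)
  X <- cbind(X, dup = X[, 1] * 2)
  y <- setNames(rnorm(40), rownames(X))
  expect_error(fit_linear(X, y), "collinear.*dup")
})

test_that("explained variance is invariant under invertible predictor change of basis", {
  X <- sim_design(200, 6, seed = 8)
  set.seed(9)
  y <- setNames(drop(X %*% rnorm(6)) + rnorm(200), rownames(X))
  A <- affinityscan:::with_seed(10, matrix(rnorm(36), 6, 6))
  while (abs(det(A)) < 1e-3) A <- A + diag(6)
  XB <- X %*% A
  colnames(XB) <- colnames(X)
  f1 <- fit_linear(X, y)
  f2 <- fit_linear(XB, y)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-9)
  # also invariant under affine rescaling of one column
  X3 <- X; X3[, 2] <- 5 * X3[, 2] + 7
  expect_equal(fit_linear(X3, y)$r2, f1$r2, tolerance = 1e-9)
})

test_that("cross-validated R2 is deterministic, near 1 noise-free, near 0 on noise", {
  X <- sim_design(200, 5, seed = 11)
  y_clean <- setNames(drop(X %*% rep(1, 5)) + 2, rownames(X))
  expect_gt(crossval_r2(X, y_clean, seed = 1), 0.999)
  expect_identical(crossval_r2(X, y_clean, seed = 3),
                   crossval_r2(X, y_clean, seed = 3))
  set.seed(12)
  y_noise <- setNames(rnorm(200), rownames(X))
  cv <- crossval_r2(X, y_noise, seed = 1)
  ins <- fit_linear(X, y_noise)$r2
  expect_lt(cv, 0.05)
  expect_gt(ins, cv)   # the overfitting gap
  expect_error(crossval_r2(X[1:5, ], y_clean[1:5], folds = 10), "folds")
})

test_that("lasso recovers a sparse support and obeys its penalty limits", {
  X <- sim_design(400, 25, seed = 13)
  true_idx <- 1:5
  cc <- rep(0, 25); cc[true_idx] <- c(3, -3, 2.5, 2, -2)
  set.seed(14)
  y <- setNames(drop(X %*% cc) + rnorm(400, 0, 1), rownames(X))
  las <- fit_lasso(X, y, seed = 15)
  expect_true(all(colnames(X)[true_idx] %in% las$selected))
  expect_lte(length(setdiff(las$selected, colnames(X)[true_idx])), 12)
  expect_equal(sort(names(which(las$coefficients[-1] != 0))),
               sort(las$selected))
  expect_gt(las$cv_r2, 0.8)
  expect_lte(las$cv_r2, fit_linear(X, y)$r2 + 0.02)
  # penalty extremes against glmnet's own path
  gfit <- las$cvfit$glmnet.fit
  co_big <- glmnet::coef.glmnet(gfit, s = max(las$cvfit$lambda) * 100)
  expect_equal(sum(abs(co_big[-1])), 0, tolerance = 1e-8)
  co_small <- as.numeric(glmnet::coef.glmnet(gfit, s = 1e-6, exact = FALSE))
  ols <- unname(coef(fit_linear(X, y)))
  expect_equal(co_small, ols, tolerance = 0.05)
})

test_that("shuffled-PWM control: shuffling length-1 PWMs changes nothing", {
  pwms <- list(a = fixture_pwm(91, 1), b = fixture_pwm(92, 1))
  recs <- lapply(1:40, function(i) fixture_seq(900 + i, 120))
  names(recs) <- vapply(recs, `[[`, "", "id")
  set.seed(16)
  y <- setNames(rnorm(40), names(recs))
  res <- shuffled_pwm_control(pwms, recs, y, seed = 5)
  expect_equal(unname(res$r2_real), unname(res$r2_shuffled),
               tolerance = 1e-12)
})

test_that("expression generated from real-PWM TBA favours real over shuffled PWMs", {
  pwms <- lapply(1:4, function(i) make_pwm(500 + i, 8, 1.2))
  names(pwms) <- sprintf("m%d", 1:4)
  recs <- lapply(1:120, function(i) fixture_seq(3000 + i, 200))
  names(recs) <- vapply(recs, `[[`, "", "id")
  design <- score_matrix(pwms, recs, mode = "tba")
  set.seed(17)
  y <- setNames(drop(design %*% c(2, -2, 1.5, 1)) +
                  rnorm(120, 0, 0.5 * stats::sd(design %*% c(2, -2, 1.5, 1))),
                rownames(design))
  res <- shuffled_pwm_control(pwms, recs, y, seed = 18)
  expect_gt(unname(res$r2_real), unname(res$r2_shuffled))
  # shuffle seed changes the shuffled fit, not the real one
  res2 <- shuffled_pwm_control(pwms, recs, y, seed = 19)
  expect_equal(unname(res$r2_real), unname(res2$r2_real), tolerance = 1e-12)
})

test_that("composition features count CpG dinucleotides as a fraction of positions", {
  f <- composition_features(list(sequence_record("x", "CGCG")))
  expect_equal(unname(f[1, "CpG"]), 2 / 3)
  expect_equal(unname(f[1, c("A", "C", "G")]), c(0, 0.5, 0.5))
  f2 <- composition_features(list(sequence_record("y", "AATT")))
  expect_equal(unname(f2[1, "CpG"]), 0)
})

test_that("a GC-driven expression signal is captured by the composition baseline", {
  recs <- lapply(1:150, function(i) fixture_seq(5000 + i, 150))
  names(recs) <- vapply(recs, `[[`, "", "id")
  feats <- composition_features(recs)
  gc <- feats[, "C"] + feats[, "G"]
  set.seed(20)
  y <- setNames(3 * gc + rnorm(150, 0, 0.3 * stats::sd(3 * gc)), names(recs))
  fit <- composition_baseline(recs, y)
  expect_gt(fit$adj_r2, 0.5)
  # constant-composition sequences make the design degenerate
  const <- lapply(1:20, function(i)
    sequence_record(sprintf("c%d", i), strrep("ACGT", 10)))
  yc <- setNames(rnorm(20), sprintf("c%d", 1:20))
  expect_error(composition_baseline(const, yc), "collinear")
})
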