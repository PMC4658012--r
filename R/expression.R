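#' Log-linear modelling of gene expression on affinity profiles
#'
#' Expression of gene g is modelled as
#' \deqn{e_g = \sum_i c_i a_g(i) + b + r_g}
#' where \eqn{a_g(i)} is the affinity (TBA or occupancy) of gene g's
#' regulatory region for PWM i, \eqn{c_i} and b are fitted, and \eqn{r_g} is
#' the residual.  The model quality metric is the adjusted R-squared; the
#' whole-model p-value is the F-test against the intercept-only model.
#' Companions: 10-fold cross-validation, lasso selection with the
#' CV-error-minimizing penalty, a shuffled-PWM control, and a base/CpG
#' composition baseline.
#'
#' @name expression_model
NULL

#' Normalize raw expression values
#'
#' Adds a pseudo-count -- by default the smallest nonzero value of the table
#' -- to every value and log2-transforms.  With a matrix (one column per
#' cell line) the pseudo-count is computed per column.
#'
#' @param x non-negative numeric vector or matrix of raw expression values.
#' @param pseudocount optional explicit pseudo-count overriding the default.
#' @return log2-transformed values, same shape and names as `x`.
#' @examples
#' normalize_expression(c(g1 = 0, g2 = 1, g3 = 3))  # pseudo-count 1
#' @export
normalize_expression <- function(x, pseudocount = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(apply(x, 2, normalize_expression, pseudocount = pseudocount))
  }
  if (any(x < 0, na.rm = TRUE)) stopf("expression values must be non-negative")
  nz <- x[!is.na(x) & x > 0]
  if (length(nz) == 0L) stopf("all expression values are zero")
  pc <- pseudocount %||% min(nz)
  log2(x + pc)
}

# align design rows with expression names; drop genes with non-finite cells
align_design <- function(design, expr) {
  design <- as.matrix(design)
  if (!is.null(names(expr)) && !is.null(rownames(design))) {
    common <- intersect(rownames(design), names(expr))
    if (length(common) == 0L) stopf("no genes shared by design and expression")
    design <- design[common, , drop = FALSE]
    expr <- expr[common]
  } else if (nrow(design) != length(expr)) {
    stopf("design has %d rows but expression has %d values",
          nrow(design), length(expr))
  }
  ok <- stats::complete.cases(design) & apply(is.finite(design), 1, all) &
    is.finite(expr)
  dropped <- if (!is.null(rownames(design))) rownames(design)[!ok] else
    which(!ok)
  list(design = design[ok, , drop = FALSE], expr = expr[ok],
       dropped = dropped)
}

#' Fit the log-linear expression model
#'
#' Ordinary least squares of expression on the affinity design matrix.
#' Genes with missing or non-finite affinities (for instance an occupancy of
#' `-Inf`, meaning no site passed the cutoff) are dropped listwise and
#' reported in the fit object.
#'
#' @param design numeric matrix (genes x PWMs), e.g. a [score_matrix()].
#' @param expr named numeric vector of normalized (log2) expression.
#' @return An object of class `affinity_lm`: list with the underlying `lm`
#'   fit, `r2`, `adj_r2`, `p` (overall F-test vs intercept-only),
#'   `n_genes`, `n_predictors`, `dropped` gene ids.
#' @seealso [crossval_r2()], [fit_lasso()], [composition_baseline()]
#' @export
fit_linear <- function(design, expr) {
  al <- align_design(design, expr)
  X <- al$design; y <- al$expr
  if (nrow(X) <= ncol(X))
    stopf("need more genes (%d) than predictors (%d)", nrow(X), ncol(X))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    collinear <- setdiff(seq_len(ncol(X) + 1L), piv) - 1L
    stopf("rank-deficient design; collinear column(s): %s",
          paste(colnames(X)[collinear], collapse = ", "))
  }
  df <- data.frame(.e = y, X, check.names = FALSE)
  fit <- stats::lm(.e ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(fit = fit, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 p = p, n_genes = nrow(X), n_predictors = ncol(X),
                 dropped = al$dropped),
            class = "affinity_lm")
}

#' @export
print.affinity_lm <- function(x, ...) {
  cat(sprintf(
    "Affinity model of expression: %d genes, %d PWMs\n  R2 = %.4f  adjusted R2 = %.4f  model p = %.3g\n",
    x$n_genes, x$n_predictors, x$r2, x$adj_r2, x$p))
  if (length(x$dropped))
    cat(sprintf("  %d gene(s) dropped (missing/non-finite affinity)\n",
                length(x$dropped)))
  invisible(x)
}

#' @export
summary.affinity_lm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.affinity_lm <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.affinity_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.affinity_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  X <- as.matrix(newdata)
  co <- stats::coef(object$fit)
  slope_names <- names(co)[-1]
  if (!is.null(colnames(X))) {
    missing_cols <- setdiff(slope_names, colnames(X))
    if (length(missing_cols))
      stopf("newdata lacks column(s): %s", paste(missing_cols, collapse = ", "))
    X <- X[, slope_names, drop = FALSE]
  }
  drop(co[1] + X %*% co[-1])
}

#' Held-out R-squared by k-fold cross-validation
#'
#' Splits genes into `folds` folds (deterministically given `seed`), fits
#' the OLS model on each training set and measures R-squared on the held-out
#' genes; returns the mean over folds.  Persistently lower CV values than
#' the in-sample R-squared indicate overfitting.
#'
#' @inheritParams fit_linear
#' @param folds number of folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @return Mean held-out R-squared.
#' @export
crossval_r2 <- function(design, expr, folds = 10, seed = 1) {
  al <- align_design(design, expr)
  X <- al$design; y <- al$expr
  n <- nrow(X)
  if (folds > n) stopf("more folds (%d) than genes (%d)", folds, n)
  assign_ <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  r2 <- vapply(seq_len(folds), function(k) {
    tr <- assign_ != k
    fit <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])
    co <- fit$coefficients
    co[is.na(co)] <- 0
    pred <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% co)
    yt <- y[!tr]
    1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
  }, 0)
  mean(r2)
}

#' Lasso regression with CV-chosen penalty
#'
#' L1-penalized fit of the same model; the penalty is chosen to minimize
#' 10-fold cross-validation error.  Predictors are standardized internally;
#' coefficients are reported on the original scale.
#'
#' @inheritParams crossval_r2
#' @param nfolds folds for the internal CV (default 10).
#' @return Object of class `affinity_lasso`: list with `coefficients`
#'   (named, original scale, including intercept), `selected` (PWMs with
#'   nonzero coefficient), `penalty` (chosen lambda), `cv_r2`, and the
#'   underlying `cv.glmnet` fit.
#' @export
fit_lasso <- function(design, expr, seed = 1, nfolds = 10) {
  al <- align_design(design, expr)
  X <- al$design; y <- al$expr
  cvfit <- with_seed(seed,
    glmnet::cv.glmnet(X, y, alpha = 1, nfolds = nfolds, standardize = TRUE))
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
  selected <- names(co)[-1][co[-1] != 0]
  cv_r2 <- 1 - min(cvfit$cvm) / mean((y - mean(y))^2)
  structure(list(coefficients = co, selected = selected,
                 penalty = cvfit$lambda.min, cv_r2 = cv_r2,
                 n_genes = nrow(X), n_predictors = ncol(X), cvfit = cvfit),
            class = "affinity_lasso")
}

#' @export
print.affinity_lasso <- function(x, ...) {
  cat(sprintf(
    "Lasso affinity model: %d of %d PWMs selected (lambda = %.4g, CV R2 = %.4f)\n",
    length(x$selected), x$n_predictors, x$penalty, x$cv_r2))
  invisible(x)
}

#' @export
coef.affinity_lasso <- function(object, ...) object$coefficients

#' Shuffled-PWM negative control
#'
#' Refits the expression model after column-shuffling every PWM (preserving
#' base composition, destroying positional preference) and recomputing the
#' TBA design.  How much predictive power survives shuffling measures the
#' share of the model's R-squared owed to generic composition rather than
#' motif-specific binding.
#'
#' @param pwms named list of [pwm()] objects.
#' @param records list of [sequence_record()]s (the regulatory regions).
#' @param expr normalized expression: named vector, or matrix with one
#'   column per cell line (paired test across columns is then reported).
#' @param bg a [background()] vector.
#' @param seed integer; shuffle i uses seed `seed + i`.
#' @return List with `r2_real`, `r2_shuffled` (vectors over cell lines) and
#'   `p` (paired Wilcoxon; NA with a single expression column).
#' @export
shuffled_pwm_control <- function(pwms, records, expr, bg = background(),
                                 seed = 1) {
  shuf <- lapply(seq_along(pwms), function(i)
    shuffle_pwm(pwms[[i]], seed + i))
  names(shuf) <- names(pwms)
  d_real <- score_matrix(pwms, records, bg, mode = "tba")
  d_shuf <- score_matrix(shuf, records, bg, mode = "tba")
  e <- if (is.matrix(expr)) expr else
    matrix(expr, ncol = 1, dimnames = list(names(expr), "expr"))
  r2_real <- apply(e, 2, function(y)
    fit_linear(d_real, setNames(y, rownames(e)))$adj_r2)
  r2_shuf <- apply(e, 2, function(y)
    fit_linear(d_shuf, setNames(y, rownames(e)))$adj_r2)
  p <- if (ncol(e) < 2) NA_real_ else {
    delta <- r2_real - r2_shuf
    if (all(delta == 0)) 1 else
      suppressWarnings(stats::wilcox.test(delta, exact = length(delta) <= 25,
                                          correct = TRUE)$p.value)
  }
  list(r2_real = r2_real, r2_shuffled = r2_shuf, p = p)
}

#' Per-sequence base and CpG composition features
#'
#' Frequencies of A, C and G (T is implied) and of the CpG dinucleotide
#' (count of "CG" over the number of dinucleotide positions).
#'
#' @param records list of [sequence_record()]s.
#' @return Numeric matrix (sequences x 4) with columns A, C, G, CpG.
#' @export
composition_features <- function(records) {
  if (is.sequence_record(records)) records <- list(records)
  feats <- t(vapply(records, function(r) {
    v <- strsplit(r$bases, "", fixed = TRUE)[[1]]
    n <- sum(v %in% BASES)
    freq <- vapply(c("A", "C", "G"), function(b) sum(v == b) / n, 0)
    di <- paste0(v[-length(v)], v[-1])
    cpg <- sum(di == "CG") / (length(v) - 1L)
    c(freq, CpG = cpg)
  }, numeric(4)))
  rownames(feats) <- vapply(records, `[[`, "", "id")
  feats
}

#' Composition-only baseline model
#'
#' Fits expression on base and CpG composition alone -- no PWM information.
#' The gap between this baseline and the affinity model bounds how much of
#' the affinity model's power is attributable to crude sequence composition.
#'
#' @inheritParams shuffled_pwm_control
#' @param expr named numeric vector of normalized expression.
#' @return An `affinity_lm` fit on the composition design.
#' @export
composition_baseline <- function(records, expr) {
  fit_linear(composition_features(records), expr)
}
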