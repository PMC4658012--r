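#' Evaluating affinity scores as binding predictors
#'
#' Given affinity scores for TF-bound (ChIP-seq peak) and control sequences,
#' these functions measure discrimination by the area under the ROC curve,
#' computed exactly from ranks (equivalently, the normalized Mann-Whitney U
#' statistic), with ties -- including ties among `-Inf` "no site" occupancy
#' values -- contributing 1/2.  A cutoff sweep produces one AUC for total
#' binding affinity and one per occupancy cutoff, the comparison at the
#' heart of the cutoff-free-vs-discrete-sites question.
#'
#' @name binding_eval
NULL

#' Area under the ROC curve
#'
#' @param positives,negatives numeric score vectors (\code{-Inf} allowed) for
#'   the bound and control classes.
#' @return AUC in \[0, 1\]: the probability that a random positive outranks a
#'   random negative, ties counting 1/2.
#' @examples
#' roc_auc(c(3, 1), c(2, 0))  # 3 of 4 pairs correctly ordered -> 0.75
#' @export
roc_auc <- function(positives, negatives) {
  n1 <- length(positives); n2 <- length(negatives)
  if (n1 == 0L || n2 == 0L) stopf("both score classes must be non-empty")
  if (anyNA(positives) || anyNA(negatives)) stopf("scores must not be NA")
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Two-sided Mann-Whitney test on two score classes
#'
#' Rank-sum test with tie correction (normal approximation), as used to
#' attach a significance value to each AUC.
#'
#' @inheritParams roc_auc
#' @return Two-sided p-value.
#' @export
mann_whitney_p <- function(positives, negatives) {
  if (length(unique(c(positives, negatives))) == 1L) return(1)
  p <- suppressWarnings(stats::wilcox.test(positives, negatives,
                                           exact = FALSE,
                                           correct = TRUE)$p.value)
  if (is.na(p)) 1 else p
}

# score every record under every predictor of the sweep:
# matrix n_records x (1 + length(grid)); column 1 = tba
sweep_scores <- function(pwm, records, bg, grid) {
  smax <- s_max(pwm, bg)
  thr <- occupancy_threshold(smax, as.numeric(grid))
  out <- matrix(NA_real_, length(records), 1L + length(grid))
  for (i in seq_along(records)) {
    s <- window_scores_impl(pwm, records[[i]], bg)
    s <- s[!is.na(s)]
    if (length(s) == 0L) next
    out[i, 1] <- logsumexp(s)
    for (k in seq_along(thr)) out[i, 1 + k] <- logsumexp(s[s >= thr[k]])
  }
  out
}

#' AUC sweep over the occupancy cutoff grid
#'
#' For every (experiment, PWM) pair computes one AUC for TBA and one for
#' occupancy at each grid cutoff (11 values with the default 10-point grid),
#' each with its Mann-Whitney p-value.  Window scores are computed once per
#' sequence and reused across cutoffs.
#'
#' @param pwms named list of [pwm()] objects.
#' @param experiments either a single `list(positives =, negatives =)` of
#'   [sequence_record()] lists, or a named list of such experiments.
#' @param bg a [background()] vector.
#' @param grid a [cutoff_grid()].
#' @return Data frame with columns `experiment`, `pwm`, `predictor`
#'   (`"tba"` or `"occupancy@C"`), `cutoff` (NA for TBA), `auc`, `p`.
#' @export
cutoff_sweep <- function(pwms, experiments, bg = background(),
                         grid = cutoff_grid()) {
  if (is.pwm(pwms)) pwms <- setNames(list(pwms), pwms$name)
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, `[[`, "", "name")
  if (!is.null(experiments$positives)) experiments <- list(exp1 = experiments)
  predictors <- c("tba", sprintf("occupancy@%g", as.numeric(grid)))
  cutoffs <- c(NA_real_, as.numeric(grid))
  rows <- list()
  for (en in names(experiments)) {
    ex <- experiments[[en]]
    if (is.null(ex$positives) || is.null(ex$negatives) ||
        length(ex$positives) == 0L || length(ex$negatives) == 0L)
      stopf("experiment '%s' needs non-empty positives and negatives", en)
    for (pn in names(pwms)) {
      sp <- sweep_scores(pwms[[pn]], ex$positives, bg, grid)
      sn <- sweep_scores(pwms[[pn]], ex$negatives, bg, grid)
      for (k in seq_along(predictors)) {
        pos <- sp[, k]; neg <- sn[, k]
        ok_pos <- !is.na(pos); ok_neg <- !is.na(neg)
        if (!any(ok_pos) || !any(ok_neg)) {
          rows[[length(rows) + 1L]] <-
            data.frame(experiment = en, pwm = pn, predictor = predictors[k],
                       cutoff = cutoffs[k], auc = NA_real_, p = NA_real_,
                       reason = "no scorable sequence")
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(experiment = en, pwm = pn, predictor = predictors[k],
                     cutoff = cutoffs[k],
                     auc = roc_auc(pos[ok_pos], neg[ok_neg]),
                     p = mann_whitney_p(pos[ok_pos], neg[ok_neg]),
                     reason = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Drop (experiment, PWM) pairs with no predictive power
#'
#' Removes pairs whose AUC is below 0.5 for every predictor in the sweep
#' (neither TBA nor any occupancy cutoff does better than chance), a sign of
#' a mismatched PWM or problematic experiment.
#'
#' @param records data frame from [cutoff_sweep()].
#' @return Filtered data frame; `attr(., "n_dropped")` counts removed pairs.
#' @export
filter_uninformative <- function(records) {
  key <- interaction(records$experiment, records$pwm, drop = TRUE)
  bad <- tapply(records$auc, key, function(a) all(!is.na(a) & a < 0.5))
  drop_keys <- names(bad)[bad]
  out <- records[!(key %in% drop_keys), , drop = FALSE]
  attr(out, "n_dropped") <- length(drop_keys)
  if (length(drop_keys))
    message(length(drop_keys),
            " experiment/PWM pair(s) dropped (AUC < 0.5 at every cutoff)")
  out
}

#' Per-PWM AUC averaged over experiments
#'
#' @param records data frame from [cutoff_sweep()].
#' @return Data frame pwm x predictor with the unweighted mean AUC.
#' @export
average_auc <- function(records) {
  agg <- stats::aggregate(auc ~ pwm + predictor, data = records,
                          FUN = mean, na.action = stats::na.omit)
  agg
}

#' Paired Wilcoxon test on per-PWM AUC differences
#'
#' Compares two predictors over a common PWM set by the signed-rank test on
#' per-PWM AUC differences (exact for 25 or fewer pairs, normal
#' approximation with continuity correction above).
#'
#' @param a,b named numeric vectors of AUC per PWM (same PWM set).
#' @return List with `p` (two-sided p-value) and `deltas` (`a - b`, named).
#' @export
paired_wilcoxon_auc_delta <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)))
    stopf("the two AUC vectors must be named by the same PWM set")
  b <- b[names(a)]
  delta <- a - b
  p <- if (all(delta == 0)) 1 else
    suppressWarnings(stats::wilcox.test(delta,
                                        exact = length(delta) <= 25,
                                        correct = TRUE)$p.value)
  list(p = p, deltas = delta)
}
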