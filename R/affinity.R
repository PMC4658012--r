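#' Total binding affinity, window scores and cutoff occupancy
#'
#' The total binding affinity (TBA) of a sequence for a PWM is the log of
#' the sum, over every length-l window of the sequence, of the larger of the
#' two strand-orientation likelihood ratios of the PWM model against the
#' background model.  It is a cutoff-free, thermodynamically motivated
#' sequence-level affinity: strong sites dominate the sum but arbitrarily
#' weak sites still contribute.  The cutoff *occupancy* restricts the same
#' sum to windows whose log-likelihood score reaches a fraction `C` of the
#' maximum achievable score, recovering the classical discrete-binding-site
#' picture as `C` grows.  All scores use natural logarithms.
#'
#' @name affinity
NULL

# per-window log-likelihood-ratio scores (max over the two orientations);
# NA for windows covering an N or masked position
window_scores_impl <- function(pwm, record, bg) {
  l <- pwm$length
  code <- encode_dna(record$bases)
  if (length(record$mask)) code[record$mask] <- NA_integer_
  L <- length(code)
  nw <- L - l + 1L
  if (nw < 1L) return(numeric(0))
  logM <- log(pwm$matrix)                      # 4 x l
  logB <- log(unclass(bg))                     # 4
  # reverse orientation: matrix position l-j+1 read on the complementary base
  comp <- c(4L, 3L, 2L, 1L)
  logMrc <- logM[comp, rev(seq_len(l)), drop = FALSE]
  per_pos_f <- logM[code, , drop = FALSE] - logB[code]   # L x l
  per_pos_r <- logMrc[code, , drop = FALSE] - logB[code]
  idx <- outer(seq_len(nw) - 1L, seq_len(l), "+")        # nw x l positions
  lin <- idx + matrix((seq_len(l) - 1L) * L, nw, l, byrow = TRUE)
  lin <- as.vector(lin)
  fwd <- rowSums(matrix(per_pos_f[lin], nw, l))
  rev_ <- rowSums(matrix(per_pos_r[lin], nw, l))
  pmax(fwd, rev_)
}

#' Per-window scores of a sequence under a PWM
#'
#' @param pwm a [pwm()] object.
#' @param record a [sequence_record()] (or a plain DNA string).
#' @param bg a [background()] vector.
#' @return Numeric vector of length `L - l + 1`: the log-likelihood-ratio
#'   score of each window (max over the two orientations), `NA` where the
#'   window covers an N or masked base.
#' @export
window_scores <- function(pwm, record, bg = background()) {
  stopifnot(is.pwm(pwm))
  if (!is.sequence_record(record)) record <- sequence_record("seq", record)
  window_scores_impl(pwm, record, bg)
}

#' Score a single window
#'
#' @param pwm a [pwm()] object.
#' @param window DNA string exactly `pwm$length` long, no N.
#' @param bg a [background()] vector.
#' @return The window's log-likelihood-ratio score (natural log; max of the
#'   forward and reverse orientation).
#' @export
window_score <- function(pwm, window, bg = background()) {
  stopifnot(is.pwm(pwm))
  if (nchar(window) != pwm$length)
    stopf("window length %d does not match PWM length %d",
          nchar(window), pwm$length)
  s <- window_scores_impl(pwm, sequence_record("w", window), bg)
  if (is.na(s)) stopf("unscorable window (contains N): '%s'", window)
  s
}

#' Maximum achievable window score of a PWM
#'
#' The best score any window can reach: per position the most favourable
#' base is chosen, separately for the two orientations, and the better
#' orientation is kept.  Under a strand-symmetric background the two
#' orientations coincide.
#'
#' @param pwm a [pwm()] object.
#' @param bg a [background()] vector.
#' @return Scalar maximum score (natural log).
#' @export
s_max <- function(pwm, bg = background()) {
  stopifnot(is.pwm(pwm))
  logM <- log(pwm$matrix)
  logB <- log(unclass(bg))
  fwd <- sum(apply(logM - logB, 2, max))
  # reverse orientation pairs matrix base b with plus-strand base comp(b)
  logB_comp <- logB[c(4L, 3L, 2L, 1L)]
  rev_ <- sum(apply(logM - logB_comp, 2, max))
  max(fwd, rev_)
}

affinity_value <- function(value, n_windows_used, n_sites_passing = NA_integer_) {
  structure(list(value = value, n_windows_used = as.integer(n_windows_used),
                 n_sites_passing = as.integer(n_sites_passing)),
            class = "affinity_value")
}

#' @export
print.affinity_value <- function(x, ...) {
  cat(sprintf("affinity %.6g  (windows used: %d%s)\n", x$value,
              x$n_windows_used,
              if (is.na(x$n_sites_passing)) ""
              else sprintf(", sites passing cutoff: %d", x$n_sites_passing)))
  invisible(x)
}

#' @export
as.numeric.affinity_value <- function(x, ...) x$value

usable_scores <- function(pwm, record, bg) {
  if (!is.sequence_record(record)) record <- sequence_record("seq", record)
  s <- window_scores_impl(pwm, record, bg)
  if (length(s) == 0L)
    stopf("sequence '%s' (%d bp) is shorter than the PWM (%d bp)",
          record$id, nchar(record$bases), pwm$length)
  s[!is.na(s)]
}

#' Total binding affinity of a sequence
#'
#' @param pwm a [pwm()] object.
#' @param record a [sequence_record()] or DNA string.
#' @param bg a [background()] vector.
#' @return An `affinity_value` whose `value` is
#'   `log(sum(exp(window scores)))` over all scorable windows.
#' @seealso [occupancy()], [window_scores()], [score_matrix()]
#' @export
tba <- function(pwm, record, bg = background()) {
  stopifnot(is.pwm(pwm))
  s <- usable_scores(pwm, record, bg)
  if (length(s) == 0L)
    stopf("no scorable window (all windows cover N or masked bases)")
  affinity_value(logsumexp(s), length(s))
}

#' Cutoff occupancy of a sequence
#'
#' Like [tba()], but only windows scoring at least `cutoff * s_max(pwm, bg)`
#' contribute (comparison made with a 1e-9 relative tolerance so the top
#' site always passes at `cutoff = 1`).  With no passing window the value is
#' `-Inf`, a legitimate "no site" result, never an error.
#'
#' @inheritParams tba
#' @param cutoff fraction of the maximum score, in (0, 1].
#' @return An `affinity_value` with `n_sites_passing` filled in.
#' @export
occupancy <- function(pwm, record, bg = background(), cutoff) {
  stopifnot(is.pwm(pwm))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stopf("cutoff must be a single value in (0, 1]")
  s <- usable_scores(pwm, record, bg)
  if (length(s) == 0L)
    stopf("no scorable window (all windows cover N or masked bases)")
  thr <- occupancy_threshold(s_max(pwm, bg), cutoff)
  pass <- s >= thr
  affinity_value(logsumexp(s[pass]), length(s), sum(pass))
}

occupancy_threshold <- function(smax, cutoff) {
  cutoff * smax - 1e-9 * max(1, abs(smax))
}

#' Sum of above-cutoff window scores
#'
#' The score a site-enumeration tool assigns to a whole sequence: the
#' arithmetic sum of the (log) scores of all windows passing the cutoff.
#' Unlike [occupancy()], the scores are not exponentiated before summing,
#' so weak sites are weighted on the log scale rather than the affinity
#' scale.  Returns 0 when no window passes.
#'
#' @inheritParams occupancy
#' @return Scalar sum of passing window scores.
#' @export
sum_of_scores <- function(pwm, record, bg = background(), cutoff) {
  stopifnot(is.pwm(pwm))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stopf("cutoff must be a single value in (0, 1]")
  s <- usable_scores(pwm, record, bg)
  thr <- occupancy_threshold(s_max(pwm, bg), cutoff)
  sum(s[s >= thr])
}

#' Cutoff grid for occupancy sweeps
#'
#' @param values strictly increasing cutoffs in (0, 1]; default the 10
#'   equally spaced values 0.1, 0.2, ..., 1.
#' @return Numeric vector of class `cutoff_grid`.
#' @export
cutoff_grid <- function(values = seq(0.1, 1, by = 0.1)) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(values <= 0) || any(values > 1))
    stopf("cutoffs must lie in (0, 1]")
  if (any(diff(values) <= 0)) stopf("cutoffs must be strictly increasing")
  structure(values, class = "cutoff_grid")
}

# ---- score matrix ---------------------------------------------------------

#' Region-by-PWM score matrix
#'
#' Applies one scoring mode to every (sequence, PWM) pair, producing the
#' design matrix used downstream for binding evaluation and expression
#' regression.  Cells whose sequence has no scorable window are `NA`, with
#' the reason recorded in `attr(x, "missing")`.
#'
#' @param pwms named list of [pwm()] objects.
#' @param records list of [sequence_record()] objects.
#' @param bg a [background()] vector.
#' @param mode `"tba"`, `"occupancy"` or `"sum_of_scores"`.
#' @param cutoff required for the two cutoff-based modes.
#' @return Numeric matrix (rows = sequence ids, columns = PWM names) of
#'   class `score_matrix`, with attributes `mode`, `cutoff` and `missing`
#'   (data frame of seq/pwm/reason for NA cells).
#' @export
score_matrix <- function(pwms, records, bg = background(),
                         mode = c("tba", "occupancy", "sum_of_scores"),
                         cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.pwm(pwms)) pwms <- list(pwms)
  if (is.sequence_record(records)) records <- list(records)
  if (length(pwms) == 0L) stopf("empty PWM list")
  if (length(records) == 0L) stopf("empty sequence list")
  if (mode != "tba" && is.null(cutoff))
    stopf("mode '%s' needs a cutoff", mode)
  pnames <- names(pwms) %||% vapply(pwms, `[[`, "", "name")
  if (is.null(names(pwms))) names(pwms) <- pnames
  snames <- vapply(records, `[[`, "", "id")
  out <- matrix(NA_real_, length(records), length(pwms),
                dimnames = list(snames, pnames))
  miss <- list()
  for (j in seq_along(pwms)) {
    pw <- pwms[[j]]
    smax <- s_max(pw, bg)
    thr <- if (mode == "tba") -Inf else occupancy_threshold(smax, cutoff)
    for (i in seq_along(records)) {
      s <- window_scores_impl(pw, records[[i]], bg)
      s <- s[!is.na(s)]
      if (length(s) == 0L) {
        miss[[length(miss) + 1L]] <-
          data.frame(seq = snames[i], pwm = pnames[j],
                     reason = "no scorable window")
        next
      }
      out[i, j] <- switch(mode,
        tba = logsumexp(s),
        occupancy = logsumexp(s[s >= thr]),
        sum_of_scores = sum(s[s >= thr]))
    }
  }
  structure(out, mode = mode, cutoff = cutoff,
            missing = if (length(miss)) do.call(rbind, miss) else
              data.frame(seq = character(), pwm = character(),
                         reason = character()),
            class = c("score_matrix", "matrix", "array"))
}

#' Write a score matrix as TSV
#'
#' First column `seq_id`, one column per PWM; `-Inf` is serialized as
#' `-inf`, `NA` as `NA`.
#'
#' @param x a [score_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  chr <- lapply(df, function(col) {
    out <- format(col, digits = 12, trim = TRUE, scientific = FALSE)
    out[is.na(col)] <- "NA"
    out[col == -Inf] <- "-inf"
    out
  })
  df <- cbind(seq_id = rownames(x), as.data.frame(chr, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path TSV file.
#' @return Numeric matrix with sequence ids as rownames.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rn <- df[[1]]
  num <- suppressWarnings(apply(m, 2, function(col) {
    col[col == "-inf"] <- "-Inf"
    as.numeric(col)
  }))
  num <- matrix(num, nrow = nrow(df), dimnames = list(rn, colnames(m)))
  structure(num, class = c("score_matrix", "matrix", "array"))
}
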