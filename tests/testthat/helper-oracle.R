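# Brute-force reference implementations with explicit loops.  Deliberately
# slow and simple; used only to cross-check the vectorized scoring code.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_complement <- function(b) {
  switch(b, A = "T", C = "G", G = "C", T = "A", "N")
}

# forward/reverse likelihood-ratio products of one window; NA if unscorable
oracle_window_ratio <- function(pwm, chars, bg) {
  l <- pwm$length
  stopifnot(length(chars) == l)
  if (any(!chars %in% ORACLE_BASES)) return(NA_real_)
  fwd <- 1; rev_ <- 1
  for (j in seq_len(l)) {
    bj <- chars[j]
    cj <- oracle_complement(bj)
    fwd <- fwd * pwm$matrix[bj, j] / bg[[bj]]
    rev_ <- rev_ * pwm$matrix[cj, l - j + 1] / bg[[bj]]
  }
  max(fwd, rev_)
}

oracle_window_score <- function(pwm, window, bg) {
  log(oracle_window_ratio(pwm, strsplit(window, "")[[1]], bg))
}

# all per-window ratios of a record, masked/N windows as NA
oracle_all_ratios <- function(pwm, record, bg) {
  chars <- strsplit(record$bases, "")[[1]]
  if (length(record$mask)) chars[record$mask] <- "N"
  l <- pwm$length
  n <- length(chars) - l + 1
  if (n < 1) return(numeric(0))
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- oracle_window_ratio(pwm, chars[i:(i + l - 1)], bg)
  out
}

oracle_tba <- function(pwm, record, bg) {
  r <- oracle_all_ratios(pwm, record, bg)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("oracle: no scorable window")
  log(sum(r))
}

# s_max by explicit per-position maximization over both orientations
oracle_s_max <- function(pwm, bg) {
  l <- pwm$length
  fwd <- 0; rev_ <- 0
  for (j in seq_len(l)) {
    best_f <- -Inf; best_r <- -Inf
    for (b in ORACLE_BASES) {
      best_f <- max(best_f, log(pwm$matrix[b, j] / bg[[b]]))
      cb <- oracle_complement(b)
      best_r <- max(best_r, log(pwm$matrix[cb, l - j + 1] / bg[[b]]))
    }
    fwd <- fwd + best_f; rev_ <- rev_ + best_r
  }
  max(fwd, rev_)
}

oracle_occupancy <- function(pwm, record, bg, cutoff) {
  r <- oracle_all_ratios(pwm, record, bg)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("oracle: no scorable window")
  thr <- cutoff * oracle_s_max(pwm, bg) - 1e-9 * max(1, abs(oracle_s_max(pwm, bg)))
  keep <- log(r) >= thr
  if (!any(keep)) return(-Inf)
  log(sum(r[keep]))
}
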