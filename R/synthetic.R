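#' Synthetic benchmarks for affinity scoring and expression modelling
#'
#' Generators for every input the package consumes: random PWMs with a
#' target information content, background sequence, positive sequences with
#' planted motif sites (mimicking the structure of ChIP-seq peak vs control
#' sets), chromatin-state segmentations, and expression simulated forward
#' from the log-linear model.  Everything is deterministic given its seed.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param seed integer seed driving every random draw.
#' @param n_pos,n_neg numbers of positive / negative sequences.
#' @param L sequence length (bp).
#' @param k planted sites per positive sequence.
#' @param site_strength site-sampling temperature: 1 draws sites faithfully
#'   from the PWM column distributions, 0 always inserts the consensus;
#'   values between interpolate (sharper than the PWM).
#' @param bg a [background()] for the random sequence.
#' @param expr optional list for expression simulation: `c` (coefficients),
#'   `b` (intercept), `sd` (residual standard deviation), and optionally
#'   `pseudocount`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_pos = 300, n_neg = 300, L = 500, k = 3,
                       site_strength = 1, bg = background(), expr = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1, L >= 1, k >= 0,
            site_strength >= 0, site_strength <= 1)
  if (!is.null(expr)) stopifnot(is.numeric(expr$c), expr$sd >= 0)
  structure(list(seed = as.integer(seed), n_pos = n_pos, n_neg = n_neg,
                 L = L, k = k, site_strength = site_strength, bg = bg,
                 expr = expr),
            class = "sim_config")
}

position_ic <- function(p) 2 + sum(p * log2(p))

anneal_column <- function(p, t) {
  q <- p^t
  q / sum(q)
}

#' Random PWM with a target information content
#'
#' Columns are drawn from a flat Dirichlet and annealed with a common
#' temperature chosen so the mean per-position information content (against
#' a uniform background) matches the target within 0.1 bits.
#'
#' @param seed integer seed.
#' @param l motif length (positions).
#' @param ic_target mean per-position information content in bits; must be
#'   below 2 (2 bits needs zero-probability entries, which PWMs here never
#'   contain).
#' @return A [pwm()] named `simpwm_<seed>`.
#' @export
make_pwm <- function(seed, l, ic_target = 1) {
  stopifnot(l >= 1)
  if (ic_target < 0 || ic_target >= 1.99)
    stopf("information-content target must lie in [0, 1.99) bits")
  cols <- with_seed(seed, {
    g <- matrix(stats::rgamma(4 * l, shape = 1), 4, l)
    sweep(g, 2, colSums(g), "/")
  })
  mean_ic <- function(t) mean(apply(cols, 2, function(p)
    position_ic(anneal_column(p, t))))
  f <- function(t) mean_ic(t) - ic_target
  t_hi <- 2
  while (f(t_hi) < 0 && t_hi < 4096) t_hi <- t_hi * 2
  if (f(t_hi) < 0)
    stopf("information-content target %.2f bits unreachable for this draw",
          ic_target)
  t_star <- if (f(0) >= 0) 0 else
    stats::uniroot(f, c(0, t_hi), tol = 1e-8)$root
  m <- apply(cols, 2, anneal_column, t = t_star)
  pwm(matrix(m, 4, l), name = sprintf("simpwm_%d", seed))
}

#' Random background sequences
#'
#' @param n number of sequences.
#' @param L length of each (bp).
#' @param bg a [background()] vector.
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return Named list of [sequence_record()]s.
#' @export
random_sequences <- function(n, L, bg = background(), seed = 1,
                             prefix = "seq") {
  seqs <- with_seed(seed, replicate(n, paste(
    sample(BASES, L, replace = TRUE, prob = unclass(bg)), collapse = "")))
  ids <- sprintf("%s_%03d", prefix, seq_len(n))
  recs <- mapply(sequence_record, ids, seqs, SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}

# draw one site string from the PWM at the configured temperature
draw_site <- function(pwm, site_strength) {
  vapply(seq_len(pwm$length), function(j) {
    p <- pwm$matrix[, j]
    if (site_strength == 0) BASES[which.max(p)]
    else sample(BASES, 1, prob = anneal_column(p, 1 / site_strength))
  }, "")
}

#' Planted-motif binding benchmark
#'
#' Negatives are i.i.d. background sequences; positives are background
#' sequences with `k` non-overlapping sites inserted, each drawn from the
#' PWM (orientation random per site).  This mirrors the structure of a
#' ChIP-seq peak set against length-matched controls.
#'
#' @param cfg a [sim_config()].
#' @param pwm the [pwm()] whose sites are planted.
#' @return List with `positives`, `negatives` (lists of
#'   [sequence_record()]s) and `sites` (data frame: seq id, 1-based start,
#'   end, strand of every planted site).
#' @export
make_binding_benchmark <- function(cfg, pwm) {
  stopifnot(inherits(cfg, "sim_config"), is.pwm(pwm))
  l <- pwm$length
  if (cfg$k * l > cfg$L)
    stopf("%d sites of %d bp cannot fit in %d bp", cfg$k, l, cfg$L)
  with_seed(cfg$seed, {
    neg <- lapply(seq_len(cfg$n_neg), function(i) sequence_record(
      sprintf("neg_%03d", i),
      paste(sample(BASES, cfg$L, replace = TRUE, prob = unclass(cfg$bg)),
            collapse = "")))
    names(neg) <- vapply(neg, `[[`, "", "id")
    sites <- list()
    pos <- lapply(seq_len(cfg$n_pos), function(i) {
      b <- sample(BASES, cfg$L, replace = TRUE, prob = unclass(cfg$bg))
      starts <- integer(0)
      if (cfg$k > 0) {
        for (try in seq_len(10000)) {
          starts <- sort(sample.int(cfg$L - l + 1L, cfg$k))
          if (cfg$k == 1L || all(diff(starts) >= l)) break
          starts <- integer(0)
        }
        if (length(starts) == 0L)
          stopf("could not place %d non-overlapping sites in %d bp",
                cfg$k, cfg$L)
        for (s in starts) {
          site <- draw_site(pwm, cfg$site_strength)
          strand <- sample(c("+", "-"), 1)
          if (strand == "-")
            site <- strsplit(reverse_complement(paste(site, collapse = "")),
                             "", fixed = TRUE)[[1]]
          b[s:(s + l - 1L)] <- site
          sites[[length(sites) + 1L]] <<-
            data.frame(seq = sprintf("pos_%03d", i), start = s,
                       end = s + l - 1L, strand = strand)
        }
      }
      sequence_record(sprintf("pos_%03d", i), paste(b, collapse = ""))
    })
    names(pos) <- vapply(pos, `[[`, "", "id")
    list(positives = pos, negatives = neg,
         sites = if (length(sites)) do.call(rbind, sites) else
           data.frame(seq = character(), start = integer(),
                      end = integer(), strand = character()))
  })
}

#' Simulate expression from an affinity design matrix
#'
#' Draws log2 expression as `design %*% c + b + Normal(0, sd)` and maps it
#' back to the raw scale as `2^e - pseudocount` floored at 0, so that
#' [normalize_expression()] (given the same pseudo-count) recovers the
#' simulated log2 values.
#'
#' @param design numeric genes x PWMs matrix (e.g. a TBA [score_matrix()]).
#' @param cfg a [sim_config()] whose `expr` holds `c`, `b`, `sd` and
#'   optionally `pseudocount` (default: the smallest simulated raw value
#'   `2^e`, which puts exactly one gene at raw 0).
#' @return List with `raw` (named vector), `log2` (named vector of the
#'   simulated log2 values) and `pseudocount`.
#' @export
make_expression <- function(design, cfg) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$expr))
  X <- as.matrix(design)
  cc <- cfg$expr$c
  if (length(cc) != ncol(X))
    stopf("coefficient vector length %d does not match %d design columns",
          length(cc), ncol(X))
  b <- cfg$expr$b %||% 0
  e <- drop(X %*% cc) + b +
    with_seed(cfg$seed, stats::rnorm(nrow(X), 0, cfg$expr$sd))
  names(e) <- rownames(X)
  q <- cfg$expr$pseudocount %||% min(2^e)
  raw <- pmax(2^e - q, 0)
  list(raw = raw, log2 = e, pseudocount = q)
}

#' Random chromatin-state segmentation
#'
#' Tiles `[0, chrom_len)` with segments of exponentially distributed length;
#' each segment is closed with probability `closed_fraction` (one of the two
#' closed labels of the shipped 15-state map) and otherwise gets one of the
#' 13 open labels, so closed states cover about `closed_fraction` of the
#' chromosome.
#'
#' @param seed integer seed.
#' @param chrom_len chromosome length (bp).
#' @param mean_seg_len mean segment length (bp).
#' @param closed_fraction target fraction of closed sequence, in \[0, 1\].
#' @param chrom chromosome name.
#' @return A `chromatin_segments` data frame tiling the chromosome exactly.
#' @export
make_chromatin <- function(seed, chrom_len, mean_seg_len = 500,
                           closed_fraction = 0.3, chrom = "chr1") {
  stopifnot(chrom_len >= mean_seg_len, closed_fraction >= 0,
            closed_fraction <= 1)
  map <- read_state_map()
  open_labels <- names(map)[map == "open"]
  closed_labels <- names(map)[map == "closed"]
  with_seed(seed, {
    lens <- integer(0)
    while (sum(lens) < chrom_len)
      lens <- c(lens, pmax(1L, round(stats::rexp(50, 1 / mean_seg_len))))
    cum <- cumsum(lens)
    lens <- lens[seq_len(which(cum >= chrom_len)[1])]
    lens[length(lens)] <- chrom_len - sum(lens[-length(lens)])
    closed <- stats::runif(length(lens)) < closed_fraction
    states <- ifelse(closed,
                     sample(closed_labels, length(lens), replace = TRUE),
                     sample(open_labels, length(lens), replace = TRUE))
    ends <- cumsum(lens)
    chromatin_segments(
      data.frame(chrom = chrom, start = c(0L, ends[-length(ends)]),
                 end = ends, state = states),
      map)
  })
}
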