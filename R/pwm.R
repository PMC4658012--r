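#' Position weight matrices and background base frequencies
#'
#' A PWM is stored as a 4 x l probability matrix (rows A, C, G, T; columns
#' are binding-site positions).  Every entry is strictly positive and each
#' column sums to 1, so likelihood ratios against a background are always
#' well defined.  Matrices can be built from JASPAR-style count matrices
#' (zero counts are replaced by one before normalization) or from
#' probability matrices (zero probabilities receive a 1e-6 pseudocount and
#' the column is renormalized).
#'
#' @param matrix numeric 4 x l matrix of per-position base probabilities.
#' @param name identifier for the matrix.
#' @param source_kind `"counts"` or `"probabilities"`, recording how the
#'   probabilities were obtained.
#' @return An object of class `pwm`: a list with elements `name`, `matrix`
#'   (4 x l, rownames A/C/G/T), `length` and `source_kind`.
#' @examples
#' m <- matrix(c(.97, .01, .01, .01,
#'               .01, .97, .01, .01), nrow = 4)
#' pwm(m, name = "toy")
#' @export
pwm <- function(matrix, name = "pwm", source_kind = "probabilities") {
  if (!is.matrix(matrix) || nrow(matrix) != 4L)
    stopf("a PWM needs a 4-row matrix (rows A, C, G, T); got %s rows",
          if (is.matrix(matrix)) nrow(matrix) else "a non-matrix")
  if (ncol(matrix) < 1L) stopf("PWM '%s' has no positions", name)
  storage.mode(matrix) <- "double"
  rownames(matrix) <- BASES
  obj <- structure(list(name = as.character(name), matrix = matrix,
                        length = ncol(matrix),
                        source_kind = match.arg(source_kind,
                                                c("counts", "probabilities"))),
                   class = "pwm")
  validate_pwm(obj)
  obj
}

validate_pwm <- function(x) {
  m <- x$matrix
  if (any(!is.finite(m)) || any(m <= 0))
    stopf("PWM '%s': entries must be finite and strictly positive", x$name)
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9))
    stopf("PWM '%s': column(s) %s do not sum to 1",
          x$name, paste(which(abs(cs - 1) > 1e-9), collapse = ", "))
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d positions, from %s)\n", x$name, x$length,
              x$source_kind))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @export
#' @rdname pwm
is.pwm <- function(x) inherits(x, "pwm")

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a [pwm()] object.
#' @return A character string of length `x$length`.
#' @export
consensus <- function(x) {
  stopifnot(is.pwm(x))
  paste(BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

# ---- file parsing ---------------------------------------------------------

# Strip JASPAR row decoration: "A  [ 10  0  3 ]" -> "10 0 3"
strip_row <- function(line) {
  line <- sub("^\\s*[ACGTacgt]\\s*", "", line)
  gsub("[][]", " ", line)
}

parse_numeric_row <- function(line, path, lineno) {
  txt <- strsplit(trimws(strip_row(line)), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(txt))
  if (length(vals) == 0L || anyNA(vals))
    stopf("%s: line %d is not a numeric matrix row: '%s'", path, lineno, line)
  vals
}

# Read the 4 matrix rows (plus optional '>' header) of a JASPAR-style file.
# Rows may be labelled A/C/G/T (any order noted by label) or unlabelled
# (assumed A, C, G, T).
read_matrix_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  lines <- lines[keep]
  header <- grepl("^>", lines)
  name <- if (any(header)) sub("^>\\s*", "", lines[which(header)[1]]) else
    tools::file_path_sans_ext(basename(path))
  name <- strsplit(name, "\\s+")[[1]][1]
  rows <- lines[!header]
  linenos <- keep[!header]
  if (length(rows) != 4L)
    stopf("%s: expected 4 matrix rows, found %d", path, length(rows))
  labs <- toupper(sub("^\\s*([A-Za-z]).*$", "\\1", rows))
  labelled <- all(labs %in% BASES) && !anyDuplicated(labs)
  vals <- mapply(parse_numeric_row, rows, linenos,
                 MoreArgs = list(path = path), SIMPLIFY = FALSE)
  if (length(unique(lengths(vals))) != 1L)
    stopf("%s: matrix rows have unequal lengths", path)
  m <- do.call(rbind, vals)
  rownames(m) <- if (labelled) labs else BASES
  m <- m[BASES, , drop = FALSE]
  list(name = name, matrix = m)
}

#' Read a JASPAR-style count matrix
#'
#' Parses a position frequency matrix of integer counts ('>' header line
#' optional; rows with or without `A [ ... ]` decoration).  Zero counts are
#' replaced by one before the column is normalized to probabilities, so the
#' resulting PWM never assigns probability zero to a base.
#'
#' @param path path to the count-matrix file.
#' @return A [pwm()] with `source_kind = "counts"`.
#' @export
read_pwm_counts <- function(path) {
  parsed <- read_matrix_file(path)
  m <- parsed$matrix
  if (any(m < 0))
    stopf("%s: negative counts in row(s) %s", path,
          paste(BASES[unique(which(m < 0, arr.ind = TRUE)[, 1])], collapse = ", "))
  if (any(abs(m - round(m)) > 1e-6))
    warnf("%s: non-integer counts; treating as counts anyway", path)
  m[m == 0] <- 1
  m <- sweep(m, 2, colSums(m), "/")
  pwm(m, name = parsed$name, source_kind = "counts")
}

#' Read a probability matrix
#'
#' Parses a 4 x l probability matrix (TSV rows labelled A/C/G/T, or
#' JASPAR-like layout).  Zero entries receive a pseudocount of 1e-6 and the
#' affected columns are renormalized.  A warning is raised when 1e-6 is not
#' smaller than the smallest nonzero probability, since the pseudocount is
#' then not negligible relative to the data.
#'
#' @param path path to the probability-matrix file.
#' @param pseudocount value substituted for exact zeros (default `1e-6`).
#' @return A [pwm()] with `source_kind = "probabilities"`.
#' @export
read_pwm_probs <- function(path, pseudocount = 1e-6) {
  parsed <- read_matrix_file(path)
  m <- parsed$matrix
  if (any(m < 0) || any(m > 1))
    stopf("%s: probabilities must lie in [0, 1]", path)
  bad <- abs(colSums(m) - 1) > 0.01
  if (any(bad))
    stopf("%s: column(s) %s do not sum to 1 (tolerance 0.01)", path,
          paste(which(bad), collapse = ", "))
  nz <- m[m > 0]
  if (length(nz) && min(nz) <= pseudocount)
    warnf("%s: pseudocount %g is not smaller than the smallest nonzero probability (%g)",
          path, pseudocount, min(nz))
  m[m == 0] <- pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  pwm(m, name = parsed$name, source_kind = "probabilities")
}

#' Read every PWM file in a directory
#'
#' @param dir directory of matrix files.
#' @param kind `"counts"` or `"probabilities"`; chooses the per-file reader.
#' @param pattern filename regexp (default: any file).
#' @return Named list of [pwm()] objects, ordered by file name.
#' @export
read_pwm_dir <- function(dir, kind = c("counts", "probabilities"),
                         pattern = NULL) {
  kind <- match.arg(kind)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stopf("no PWM files found in %s", dir)
  reader <- if (kind == "counts") read_pwm_counts else read_pwm_probs
  pwms <- lapply(files, reader)
  names(pwms) <- vapply(pwms, `[[`, "", "name")
  pwms
}

#' Column-shuffle a PWM
#'
#' Randomly permutes the positions (columns) of the matrix, preserving its
#' overall base composition while destroying the positional binding
#' preference.  Used as a negative control: affinities computed with
#' shuffled matrices retain composition effects but not motif specificity.
#'
#' @param pwm a [pwm()] object.
#' @param seed integer seed making the permutation reproducible.
#' @return A [pwm()] with the same columns in permuted order; the name gains
#'   a `_shuf` suffix.
#' @export
shuffle_pwm <- function(pwm, seed) {
  stopifnot(is.pwm(pwm))
  perm <- with_seed(seed, sample.int(pwm$length))
  out <- pwm
  out$matrix <- pwm$matrix[, perm, drop = FALSE]
  out$name <- paste0(pwm$name, "_shuf")
  out
}

# ---- background -----------------------------------------------------------

#' Background base frequencies
#'
#' The background model is a single mononucleotide frequency vector
#' (A, C, G, T).  In genome-scale work it is estimated from intergenic
#' sequence; the uniform default keeps affinities well defined when no
#' genome is at hand.
#'
#' @param freqs numeric vector of 4 strictly positive frequencies
#'   (A, C, G, T order); normalized to sum to 1.
#' @return An object of class `background`: a named numeric vector.
#' @examples
#' background()                   # uniform
#' background(c(.3, .2, .2, .3))  # AT-rich
#' @export
background <- function(freqs = c(0.25, 0.25, 0.25, 0.25)) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(!is.finite(freqs)) || any(freqs <= 0))
    stopf("background needs 4 strictly positive frequencies (A, C, G, T)")
  freqs <- freqs / sum(freqs)
  structure(setNames(freqs, BASES), class = "background")
}

#' @export
print.background <- function(x, ...) {
  cat("Background base frequencies:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Estimate background frequencies from FASTA sequence
#'
#' Counts A/C/G/T (case-insensitive) over every record, skipping N and other
#' ambiguity codes.  A base never observed is floored at one count so the
#' background stays strictly positive.
#'
#' @param path FASTA file, typically of intergenic sequence.
#' @return A [background()] vector.
#' @export
background_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("%s: no FASTA records", path)
  freq <- colSums(Biostrings::alphabetFrequency(seqs)[, BASES, drop = FALSE])
  if (sum(freq) == 0) stopf("%s: no unambiguous A/C/G/T bases found", path)
  freq[freq == 0] <- 1
  background(freq / sum(freq))
}
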