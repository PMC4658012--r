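#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# log(sum(exp(x))) without overflow; -Inf for empty or all--Inf input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# DNA string -> integer codes 1..4 (A,C,G,T), NA for anything else (N, gaps)
encode_dna <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(v, BASES)
}

decode_dna <- function(code) {
  out <- rep("N", length(code))
  ok <- !is.na(code)
  out[ok] <- BASES[code[ok]]
  paste(out, collapse = "")
}

reverse_complement <- function(x) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                         collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
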