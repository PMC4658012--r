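#' Regulatory regions: promoters and chromatin-state refinement
#'
#' Regions are stranded sets of disjoint half-open genomic intervals
#' (0-based, BED convention) attached to a gene.  The basic region is the
#' proximal promoter, 1500 bp upstream and 500 bp downstream of the TSS.
#' Given a chromatin-state segmentation, a promoter is refined by removing
#' positions in closed states and extending each end that falls inside an
#' open state to that state's boundary, yielding cell-type-dependent
#' regulatory regions.
#'
#' @name regions
NULL

new_region <- function(gene_id, chrom, intervals, strand,
                       provenance = "fixed_promoter", fully_closed = FALSE) {
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 2)
  colnames(intervals) <- c("start", "end")
  if (nrow(intervals)) {
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals[, 2] <= intervals[, 1]))
      stopf("region '%s': empty or inverted interval", gene_id)
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stopf("region '%s': overlapping intervals", gene_id)
  } else if (!fully_closed) {
    stopf("region '%s' has no intervals and is not flagged fully closed",
          gene_id)
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 intervals = intervals, strand = match.arg(strand, c("+", "-")),
                 provenance = provenance, fully_closed = fully_closed),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region '%s'> %s%s (%s)%s\n", x$gene_id, x$chrom, x$strand,
              x$provenance, if (x$fully_closed) " [fully closed]" else ""))
  if (nrow(x$intervals))
    cat(paste(sprintf("  [%d, %d)", x$intervals[, 1], x$intervals[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}

#' @export
#' @rdname regions
is.region <- function(x) inherits(x, "region")

region_width <- function(x) sum(x$intervals[, 2] - x$intervals[, 1])

#' Fixed promoter around a transcription start site
#'
#' Builds the interval covering `up` bases 5' of the TSS and `down` bases
#' starting at the TSS, oriented by strand and clipped at position 0.  The
#' TSS is the 0-based position of the first transcribed base.
#'
#' @param tss list or one-row data frame with `gene_id`, `chrom`, `tss`
#'   (0-based position), `strand`.
#' @param up,down bases upstream / downstream of the TSS (defaults 1500 and
#'   500, the proximal-promoter window used throughout the package).
#' @return A `region` with provenance `"fixed_promoter"`.
#' @examples
#' promoter_from_tss(list(gene_id = "g1", chrom = "chr1", tss = 10000,
#'                        strand = "+"))
#' @export
promoter_from_tss <- function(tss, up = 1500, down = 500) {
  pos <- as.numeric(tss$tss)
  if (is.na(pos) || pos < 0) stopf("gene '%s': invalid TSS", tss$gene_id)
  if (tss$strand == "+") {
    start <- pos - up; end <- pos + down
  } else {
    start <- pos - down; end <- pos + up
  }
  start <- max(0, start)
  if (end <= start) stopf("gene '%s': promoter clipped to nothing", tss$gene_id)
  new_region(tss$gene_id, tss$chrom, c(start, end), tss$strand)
}

#' Read a BED6-like TSS table
#'
#' Columns: chrom, start, end, gene_id, score, strand.  The TSS is taken as
#' `start` on the + strand and `end - 1` on the - strand.
#'
#' @param path TSV/BED file (no header).
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopf("%s: expected 6 BED columns", path)
  names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  data.frame(gene_id = df$gene_id, chrom = df$chrom,
             tss = ifelse(df$strand == "+", df$start, df$end - 1),
             strand = df$strand, stringsAsFactors = FALSE)
}

# ---- chromatin states -----------------------------------------------------

#' Read a chromatin-state label map
#'
#' Two-column TSV (no header): state label, `open` or `closed`.  The default
#' map shipped with the package classifies the standard 15-state histone-
#' modification HMM segmentation, with the Polycomb-repressed and
#' heterochromatin/low-signal states closed and the remaining 13 open.
#'
#' @param path map file; default the shipped 15-state map.
#' @return Named character vector label -> "open"/"closed".
#' @export
read_state_map <- function(path = system.file("extdata",
                                              "chromhmm15_state_map.tsv",
                                              package = "affinityscan")) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) != 2) stopf("%s: expected 2 columns (label, open|closed)", path)
  if (!all(df[[2]] %in% c("open", "closed")))
    stopf("%s: second column must be 'open' or 'closed'", path)
  setNames(df[[2]], df[[1]])
}

#' Read a BED4 chromatin segmentation
#'
#' @param path BED4 file: chrom, start, end, state label.
#' @param state_map named vector from [read_state_map()]; every label in the
#'   segmentation must be present.
#' @return Data frame chrom/start/end/state/openness of class
#'   `chromatin_segments`.
#' @export
read_segmentation_bed <- function(path, state_map = read_state_map()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4) stopf("%s: expected 4 BED columns", path)
  names(df)[1:4] <- c("chrom", "start", "end", "state")
  chromatin_segments(df[1:4], state_map)
}

#' Attach open/closed calls to a segmentation table
#'
#' @param df data frame with chrom, start, end, state.
#' @param state_map named vector label -> "open"/"closed".
#' @return The table with an `openness` column, sorted, class
#'   `chromatin_segments`.
#' @export
chromatin_segments <- function(df, state_map = read_state_map()) {
  unknown <- setdiff(unique(df$state), names(state_map))
  if (length(unknown))
    stopf("segmentation states missing from the state map: %s",
          paste(unknown, collapse = ", "))
  df$openness <- unname(state_map[df$state])
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (any(df$end <= df$start)) stopf("segmentation has empty intervals")
  structure(df, class = c("chromatin_segments", "data.frame"))
}

#' Refine a region with chromatin-state information
#'
#' Positions overlapping closed states are removed; if an end of the
#' original region falls inside an open state, the region is extended to
#' that state's boundary (both ends, independently).  A promoter entirely in
#' closed states becomes an empty region flagged fully closed.
#'
#' @param region a `region` (typically from [promoter_from_tss()]).
#' @param segments a `chromatin_segments` table tiling the region's
#'   chromosome without overlaps.
#' @return A `region` with provenance `"chromatin_refined"`.
#' @export
refine_with_chromatin <- function(region, segments) {
  stopifnot(is.region(region))
  seg <- segments[segments$chrom == region$chrom, , drop = FALSE]
  if (nrow(seg) == 0L)
    stopf("chromosome '%s' absent from the segmentation", region$chrom)
  seg <- seg[order(seg$start), , drop = FALSE]
  if (region$fully_closed) return(region)
  span_l <- region$intervals[1, 1]
  span_r <- region$intervals[nrow(region$intervals), 2]
  seg_at <- function(pos) which(seg$start <= pos & pos < seg$end)[1]
  il <- seg_at(span_l); ir <- seg_at(span_r - 1)
  if (!is.na(il) && seg$openness[il] == "open") span_l <- seg$start[il]
  if (!is.na(ir) && seg$openness[ir] == "open") span_r <- seg$end[ir]
  open <- seg[seg$openness == "open", , drop = FALSE]
  span_ir <- IRanges::IRanges(start = span_l + 1L, end = span_r)
  open_ir <- IRanges::reduce(IRanges::IRanges(start = open$start + 1L,
                                              end = open$end))
  kept <- IRanges::intersect(span_ir, open_ir)
  # keep only pieces that intersect the refined span and original coverage
  if (length(kept) == 0L)
    return(new_region(region$gene_id, region$chrom,
                      matrix(numeric(0), ncol = 2), region$strand,
                      provenance = "chromatin_refined", fully_closed = TRUE))
  ints <- cbind(start = IRanges::start(kept) - 1L, end = IRanges::end(kept))
  new_region(region$gene_id, region$chrom, ints, region$strand,
             provenance = "chromatin_refined")
}

#' Extract region sequences from a genome
#'
#' Multi-interval regions are concatenated in genomic order with one masked
#' junction base inserted between consecutive intervals, so no scoring
#' window can span a gap.  Sequences are reported on the + strand (total
#' binding affinity is strand-symmetric).  Fully closed regions are skipped
#' and listed in `attr(result, "skipped")`.
#'
#' @param regions list of `region` objects.
#' @param genome named character vector / list of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @return Named list of [sequence_record()]s (one per non-empty region).
#' @export
extract_sequences <- function(regions, genome) {
  if (is.region(regions)) regions <- list(regions)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
    genome <- setNames(as.character(genome), nm)
  }
  genome <- unlist(as.list(genome))
  out <- list(); skipped <- character()
  for (rg in regions) {
    if (rg$fully_closed || nrow(rg$intervals) == 0L) {
      skipped <- c(skipped, rg$gene_id)
      next
    }
    chrom_seq <- genome[[rg$chrom]]
    if (is.null(chrom_seq))
      stopf("region '%s': chromosome '%s' not in genome", rg$gene_id, rg$chrom)
    clen <- nchar(chrom_seq)
    if (any(rg$intervals[, 2] > clen))
      stopf("region '%s': interval exceeds length of %s (%d bp)",
            rg$gene_id, rg$chrom, clen)
    pieces <- substring(chrom_seq, rg$intervals[, 1] + 1, rg$intervals[, 2])
    bases <- paste(pieces, collapse = "N")
    mask <- if (length(pieces) > 1)
      cumsum(nchar(pieces[-length(pieces)]) + 1L) else integer()
    out[[rg$gene_id]] <- sequence_record(rg$gene_id, bases, mask)
  }
  if (length(skipped))
    message(length(skipped), " fully closed region(s) skipped: ",
            paste(utils::head(skipped, 10), collapse = ", "),
            if (length(skipped) > 10) ", ..." else "")
  attr(out, "skipped") <- skipped
  out
}
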