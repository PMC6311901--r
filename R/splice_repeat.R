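#' Exon/intron (splicing) features of a transcript
#'
#' Lengths and GC content of the transcript and of its first exon/intron:
#' `txLen`, `exonCount`, `longestELen`, `fELen` (first exon length),
#' `fEgc` (first exon GC), `fILen` (first intron length, `NA` for
#' single-exon transcripts), `fIgc` (first intron GC, requires the genome
#' sequence and is `NA` otherwise), plus total/mean exon and intron
#' lengths and whole-transcript GC.
#'
#' @param t A [transcript].
#' @param genome Optional named list/character of chromosome sequences for
#'   intron GC (rarely available; `NA` otherwise).
#' @return A one-row `data.frame` of splice features.
#' @export
splice_features <- function(t, genome = NULL) {
  el <- t$exon_lengths; il <- t$intron_lengths
  first_exon <- substr(t$seq, 1L, el[1])
  figc <- NA_real_
  if (!is.null(genome) && length(il) >= 1 && !is.null(t$genome_intervals)) {
    gi <- t$genome_intervals
    chrom <- gi$chrom[1]
    if (chrom %in% names(genome)) {
      # first intron in transcript order lies between the first two exons
      if (gi$strand[1] == "-") {
        iv <- c(gi$end[2] + 1L, gi$start[1] - 1L)
      } else {
        iv <- c(gi$end[1] + 1L, gi$start[2] - 1L)
      }
      if (iv[1] <= iv[2]) figc <- gc_content(substr(genome[[chrom]], iv[1], iv[2]))
    }
  }
  data.frame(txLen = nchar(t$seq),
             txGc = gc_content(t$seq),
             exonCount = length(el),
             longestELen = max(el),
             meanELen = mean(el),
             fELen = el[1],
             fEgc = gc_content(first_exon),
             fILen = if (length(il)) il[1] else NA_integer_,
             fIgc = figc,
             totalILen = if (length(il)) sum(il) else NA_integer_,
             meanILen = if (length(il)) mean(il) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read repeat-element annotation
#'
#' `read_repeat_bed()` reads a BED file whose name (4th) column carries the
#' repeat class; `read_repeatmasker()` parses RepeatMasker `.out` format
#' and maps `repClass/repFamily` (column 11, e.g. `LINE/L1`, `SINE/Alu`)
#' into class labels: both the class and, for `Alu`/`SINEB2`, the family
#' are emitted as separate rows so either granularity can be flagged.
#'
#' @param path Annotation path.
#' @return `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   closed), `class`.
#' @export
read_repeat_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]), class = df[[4]],
             stringsAsFactors = FALSE)
}

#' @rdname read_repeat_bed
#' @export
read_repeatmasker <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]    # banner
  lines <- trimws(lines[nzchar(trimws(lines))])
  fields <- strsplit(lines, "\\s+")
  rows <- lapply(fields, function(f) {
    cls <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    labels <- unique(c(cls[1], if (length(cls) > 1) cls[2]))
    data.frame(chrom = f[5], start = as.integer(f[6]), end = as.integer(f[7]),
               class = labels, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Repeat classes dropped before flagging (non-TE annotation).
.repeat_exclude <- c("Simple_repeat", "Low_complexity", "ncRNA", "RNA",
                     "rRNA", "tRNA", "snRNA", "scRNA", "srpRNA")

#' Repeat-element overlap flags
#'
#' One binary flag per repeat class: 1 iff any exon genomic interval of the
#' transcript overlaps (>= 1 bp) a repeat of that class, after removing
#' repeats annotated as simple repeats, low complexity, or non-coding RNA.
#' Transcripts without genomic intervals get all-`NA` flags.
#'
#' @param t A [transcript] with `genome_intervals`.
#' @param repeats Repeat annotation from [read_repeat_bed()] /
#'   [read_repeatmasker()] (same assembly as the transcript intervals).
#' @param classes Flag namespace (default LTR, LINE, SINE, Alu, SINEB2).
#' @return A one-row `data.frame` of 0/1 (or `NA`) flags named by class.
#' @export
repeat_flags <- function(t, repeats,
                         classes = c("LTR", "LINE", "SINE", "Alu", "SINEB2")) {
  flags <- setNames(rep(NA_integer_, length(classes)), classes)
  gi <- t$genome_intervals
  if (!is.null(gi) && nrow(gi) > 0) {
    flags[] <- 0L
    if (!is.null(repeats) && nrow(repeats) > 0) {
      rep_keep <- repeats[!(repeats$class %in% .repeat_exclude), , drop = FALSE]
      if (nrow(rep_keep) > 0) {
        ex <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start, gi$end))
        rg <- GenomicRanges::GRanges(rep_keep$chrom,
                                     IRanges::IRanges(rep_keep$start, rep_keep$end))
        hits <- GenomicRanges::findOverlaps(ex, rg, minoverlap = 1L)
        hit_classes <- unique(rep_keep$class[S4Vectors::subjectHits(hits)])
        flags[classes %in% hit_classes] <- 1L
      }
    }
  }
  as.data.frame(as.list(flags), stringsAsFactors = FALSE)
}
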