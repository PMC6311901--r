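#' Transcript objects
#'
#' A `transcript` is a lightweight S3 record holding the mature (spliced,
#' sense-strand) sequence of one lncRNA together with its exon/intron
#' structure and, optionally, the genomic intervals of its exons.  All
#' transcript coordinates in this package are 1-based and closed.
#'
#' @param id Transcript identifier (unique within a set).
#' @param seq Mature transcript sequence.  Normalized to the uppercase DNA
#'   alphabet: `U` becomes `T`, any other non-ACGTN symbol becomes `N`.
#' @param exon_lengths Ordered exon lengths, 5'->3' in transcript order.
#'   Their sum must equal `nchar(seq)`.
#' @param intron_lengths Ordered lengths of the genomic introns between
#'   consecutive exons; empty for single-exon transcripts.
#' @param genome_intervals Optional `data.frame` with columns `chrom`,
#'   `start`, `end`, `strand` (1-based closed genomic exon intervals, in
#'   transcript order), used only for repeat-element overlap.
#'
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, seq, exon_lengths = NULL, intron_lengths = NULL,
                       genome_intervals = NULL) {
  seq <- normalize_seq(seq)
  if (is.null(exon_lengths)) exon_lengths <- nchar(seq)
  if (is.null(intron_lengths)) {
    intron_lengths <- if (length(exon_lengths) > 1) rep(0L, length(exon_lengths) - 1L) else integer(0)
  }
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (any(exon_lengths <= 0)) stop("transcript '", id, "': all exon lengths must be positive")
  if (sum(exon_lengths) != nchar(seq)) {
    stop("transcript '", id, "': exon lengths sum to ", sum(exon_lengths),
         " but sequence length is ", nchar(seq))
  }
  if (length(intron_lengths) != max(0L, length(exon_lengths) - 1L)) {
    stop("transcript '", id, "': need ", max(0L, length(exon_lengths) - 1L),
         " intron lengths, got ", length(intron_lengths))
  }
  if (any(intron_lengths < 0)) stop("transcript '", id, "': intron lengths must be >= 0")
  structure(list(id = as.character(id), seq = seq, exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths, genome_intervals = genome_intervals),
            class = "transcript")
}

#' @exportS3Method base::print
print.transcript <- function(x, ...) {
  cat("<transcript> ", x$id, ": ", nchar(x$seq), " nt, ",
      length(x$exon_lengths), " exon(s)\n", sep = "")
  invisible(x)
}

#' @export
length.transcript <- function(x) nchar(x$seq)

# Uppercase; RNA -> DNA; anything outside ACGTN -> N.
normalize_seq <- function(s) {
  s <- toupper(as.character(s))
  s <- chartr("U", "T", s)
  gsub("[^ACGTN]", "N", s)
}

#' Read transcripts from FASTA (and optional exon annotation)
#'
#' Builds one [transcript] per FASTA record.  When a GTF (exon features
#' grouped by `transcript_id`) or BED12 annotation is supplied, exon and
#' intron lengths are taken from it, in 5'->3' transcript order (minus-strand
#' exon blocks are reversed); records without an annotation entry become
#' single-exon transcripts.  The FASTA is assumed to hold the sense-strand
#' mature sequence.
#'
#' @param fasta_path Path to a FASTA file of mature transcript sequences.
#' @param annotation_path Optional path to a GTF (`.gtf`/`.gff`) or BED12
#'   (`.bed`) file describing exon structure for a subset of the FASTA ids.
#' @return A named list of [transcript] objects, in FASTA order.
#' @export
read_transcripts <- function(fasta_path, annotation_path = NULL) {
  # BStringSet: tolerate RNA/ambiguity/stray symbols, normalized below
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ann <- if (!is.null(annotation_path)) read_exon_annotation(annotation_path) else list()
  unknown <- setdiff(names(ann), ids)
  if (length(unknown)) stop("annotation ids absent from FASTA: ",
                            paste(head(unknown, 5), collapse = ", "))
  errors <- character(0)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- as.character(seqs[[i]])
    a <- ann[[ids[i]]]
    if (is.null(a)) {
      out[[i]] <- transcript(ids[i], s)
    } else if (sum(a$exon_lengths) != nchar(s)) {
      errors <- c(errors, paste0(ids[i], ": annotation exon sum ", sum(a$exon_lengths),
                                 " != sequence length ", nchar(s)))
    } else {
      out[[i]] <- transcript(ids[i], s, a$exon_lengths, a$intron_lengths, a$genome_intervals)
    }
  }
  if (length(errors)) stop("annotation/sequence length mismatch:\n  ",
                           paste(errors, collapse = "\n  "))
  names(out) <- ids
  out
}

# Parse a GTF or BED12 exon annotation into per-transcript exon/intron
# lengths plus genomic intervals.  Dispatch on file extension.
read_exon_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    g <- rtracklayer::import(path, format = "gtf")
    g[S4Vectors::mcols(g)$type == "exon"]
  } else if (ext == "bed") {
    bed12_to_exons(rtracklayer::import(path, format = "bed"))
  } else {
    stop("unsupported annotation format: .", ext, " (use GTF or BED12)")
  }
  tx <- S4Vectors::mcols(gr)$transcript_id
  if (is.null(tx)) tx <- S4Vectors::mcols(gr)$name
  parts <- split(seq_along(gr), as.character(tx))
  lapply(parts, function(idx) {
    e <- gr[idx]
    e <- e[order(GenomicRanges::start(e))]
    minus <- as.character(GenomicRanges::strand(e)[1]) == "-"
    il <- if (length(e) > 1) {
      GenomicRanges::start(e)[-1] - GenomicRanges::end(e)[-length(e)] - 1L
    } else integer(0)
    gi <- data.frame(chrom = as.character(GenomicRanges::seqnames(e)),
                     start = GenomicRanges::start(e), end = GenomicRanges::end(e),
                     strand = as.character(GenomicRanges::strand(e)),
                     stringsAsFactors = FALSE)
    if (minus) { # 5'->3' order on the minus strand is descending genomic
      gi <- gi[rev(seq_len(nrow(gi))), , drop = FALSE]
      rownames(gi) <- NULL
      il <- rev(il)
    }
    list(exon_lengths = as.integer(gi$end - gi$start + 1L),
         intron_lengths = as.integer(il), genome_intervals = gi)
  })
}

# Expand BED12 records into one GRanges exon per block (named by record).
bed12_to_exons <- function(gr) {
  if (is.null(S4Vectors::mcols(gr)$blocks)) { # plain BED: one exon per record
    S4Vectors::mcols(gr)$transcript_id <- S4Vectors::mcols(gr)$name
    return(gr)
  }
  blocks <- S4Vectors::mcols(gr)$blocks
  res <- lapply(seq_along(gr), function(i) {
    b <- IRanges::shift(blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], b,
                           strand = GenomicRanges::strand(gr)[i],
                           transcript_id = S4Vectors::mcols(gr)$name[i])
  })
  do.call(c, res)
}

#' Write transcripts to FASTA and BED12
#'
#' Inverse of [read_transcripts()]: emits the mature sequences as FASTA and
#' the exon structure as BED12.  Transcripts without genomic intervals are
#' written on a pseudo-chromosome named after the transcript, preserving
#' exon/intron lengths.
#'
#' @param ts Named list of [transcript] objects.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, the input `ts`.
#' @export
write_transcripts <- function(ts, fasta_path, bed_path = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(ts, `[[`, "", "seq"))
  names(seqs) <- vapply(ts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    rows <- vapply(ts, function(t) {
      gi <- t$genome_intervals
      if (is.null(gi)) {
        starts <- cumsum(c(1L, t$exon_lengths[-length(t$exon_lengths)] +
                             t$intron_lengths))
        gi <- data.frame(chrom = t$id, start = starts,
                         end = starts + t$exon_lengths - 1L, strand = "+")
      }
      g <- gi[order(gi$start), , drop = FALSE] # BED blocks are genomic-ascending
      chrom_start <- min(g$start) - 1L
      paste(g$chrom[1], chrom_start, max(g$end), t$id, 0, gi$strand[1],
            chrom_start, chrom_start, "0,0,0", nrow(g),
            paste0(paste(g$end - g$start + 1L, collapse = ","), ","),
            paste0(paste(g$start - 1L - chrom_start, collapse = ","), ","),
            sep = "\t")
    }, "")
    writeLines(rows, bed_path)
  }
  invisible(ts)
}

#' GC content of a DNA string
#'
#' Fraction (G + C) / (A + C + G + T); `N` is excluded from both numerator
#' and denominator.  Returns `NA` for empty or all-`N` input.
#'
#' @param s DNA string.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_content <- function(s) {
  s <- normalize_seq(s)
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0) return(NA_real_)
  nchar(gsub("[^GC]", "", s)) / acgt
}

#' Partition a transcript into 5'UTR / ORF / 3'UTR regions
#'
#' For each ORF present in `orfs` (primary, first, upstream), returns the
#' three intervals `five_utr = [1, start-1]`, `orf = [start, end]`,
#' `three_utr = [end+1, len]` in transcript coordinates.  A region is empty
#' (zero width, `start > end`) when the ORF touches a transcript end; a kind
#' whose ORF is absent maps to `NULL` and all downstream features of its
#' regions are treated as missing.
#'
#' @param t A [transcript].
#' @param orfs An `orf_set` from [find_orf_set()].
#' @return A list with entries `porf`, `forf`, `uorf`; each present entry is
#'   a list of intervals `five_utr`, `orf`, `three_utr` (`c(start, end)`).
#' @export
extract_regions <- function(t, orfs) {
  len <- nchar(t$seq)
  one <- function(o) {
    if (is.null(o)) return(NULL)
    if (o$start < 1 || o$end > len) {
      stop("ORF interval [", o$start, ", ", o$end, "] outside transcript of length ", len)
    }
    list(five_utr = c(1L, o$start - 1L),
         orf = c(o$start, o$end),
         three_utr = c(o$end + 1L, len))
  }
  list(porf = one(orfs$porf), forf = one(orfs$forf), uorf = one(orfs$uorf))
}

# Interval helpers: intervals are c(start, end), 1-based closed; empty iff
# start > end.
interval_width <- function(iv) max(0L, iv[2] - iv[1] + 1L)
interval_seq <- function(s, iv) if (interval_width(iv) == 0) "" else substr(s, iv[1], iv[2])
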