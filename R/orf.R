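#' Enumerate putative open reading frames
#'
#' Scans every occurrence of a start codon from `starts` and extends it to
#' the first in-frame stop codon (`TAG`, `TGA`, `TAA`) wholly inside the
#' sequence.  Start codons with no in-frame stop yield no ORF: every
#' reported ORF is terminated.  Codons containing `N` never match.
#'
#' @param seq DNA string (mature transcript, sense strand).
#' @param starts Character vector of start codons (default `"ATG"`).
#' @return A `data.frame` with columns `start`, `end` (1-based closed, width
#'   divisible by 3) and `start_codon`, ordered by `start`.
#' @export
enumerate_orfs <- function(seq, starts = "ATG") {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      start_codon = character(0), stringsAsFactors = FALSE)
  if (n < 6) return(empty)
  codons <- substring(seq, 1:(n - 2), 3:n)
  start_pos <- which(codons %in% starts)
  stop_pos <- which(codons %in% c("TAG", "TGA", "TAA"))
  if (!length(start_pos) || !length(stop_pos)) return(empty)
  # first in-frame stop strictly downstream of each start
  res <- lapply(start_pos, function(p) {
    sp <- stop_pos[stop_pos > p & (stop_pos - p) %% 3 == 0]
    if (!length(sp)) return(NULL)
    c(p, sp[1] + 2L)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(empty)
  m <- do.call(rbind, res)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             start_codon = substring(seq, m[, 1], m[, 1] + 2L),
             stringsAsFactors = FALSE)
}

orf_record <- function(row, kind) {
  if (is.null(row) || nrow(row) == 0) return(NULL)
  list(start = row$start[1], end = row$end[1],
       start_codon = row$start_codon[1], kind = kind)
}

#' Primary ORF: the longest ATG-initiated ORF
#'
#' Ties on length are broken toward the 5'-most start.
#'
#' @inheritParams enumerate_orfs
#' @return A list (`start`, `end`, `start_codon`, `kind`) or `NULL` when the
#'   sequence has no terminated ATG ORF.
#' @export
primary_orf <- function(seq) {
  o <- enumerate_orfs(seq, "ATG")
  if (nrow(o) == 0) return(NULL)
  len <- o$end - o$start + 1L
  o <- o[order(-len, o$start), , drop = FALSE]
  orf_record(o[1, , drop = FALSE], "primary")
}

#' First ORF: the 5'-most ATG-initiated ORF
#'
#' @inheritParams enumerate_orfs
#' @return A list as in [primary_orf()], or `NULL`.
#' @export
first_orf <- function(seq) {
  o <- enumerate_orfs(seq, "ATG")
  if (nrow(o) == 0) return(NULL)
  orf_record(o[which.min(o$start), , drop = FALSE], "first")
}

#' Upstream ORF: near-cognate ORF wholly 5' of the primary ORF
#'
#' Considers ORFs initiated at the near-cognate start codons `CTG`, `GTG`,
#' `TTG` whose entire interval lies upstream of (or abuts) the primary ORF
#' start; candidates overlapping the primary ORF are excluded.  Among the
#' survivors the longest is returned (ties toward the 5'-most), mirroring
#' the primary-ORF convention.
#'
#' @inheritParams enumerate_orfs
#' @param porf The primary ORF (must be present).
#' @return A list as in [primary_orf()], or `NULL`.
#' @export
upstream_orf <- function(seq, porf) {
  if (is.null(porf)) stop("upstream_orf() requires a primary ORF")
  o <- enumerate_orfs(seq, c("CTG", "GTG", "TTG"))
  o <- o[o$end < porf$start, , drop = FALSE]
  if (nrow(o) == 0) return(NULL)
  len <- o$end - o$start + 1L
  o <- o[order(-len, o$start), , drop = FALSE]
  orf_record(o[1, , drop = FALSE], "upstream")
}

#' The primary / first / upstream ORF triple of a transcript
#'
#' Only these three selected ORFs feed the feature set; other ORFs inside or
#' downstream of the primary ORF are ignored.  The upstream ORF is defined
#' only when a primary ORF exists.
#'
#' @inheritParams enumerate_orfs
#' @return An object of class `orf_set`: list with entries `porf`, `forf`,
#'   `uorf` (each an ORF record or `NULL`).
#' @export
find_orf_set <- function(seq) {
  p <- primary_orf(seq)
  structure(list(porf = p,
                 forf = first_orf(seq),
                 uorf = if (is.null(p)) NULL else upstream_orf(seq, p)),
            class = "orf_set")
}

#' @exportS3Method base::print
print.orf_set <- function(x, ...) {
  fmt <- function(o, lab) {
    if (is.null(o)) cat(" ", lab, ": absent\n", sep = "")
    else cat(" ", lab, ": [", o$start, ", ", o$end, "] ", o$start_codon, "\n", sep = "")
  }
  cat("<orf_set>\n"); fmt(x$porf, "pORF"); fmt(x$forf, "fORF"); fmt(x$uorf, "uORF")
  invisible(x)
}

#' Tabulate ORF sets for a collection of transcripts
#'
#' @param ts Named list of [transcript] objects.
#' @return `data.frame` with columns `id`, `kind`, `start`, `end`,
#'   `start_codon` (one row per present ORF).
#' @export
orf_table <- function(ts) {
  rows <- lapply(ts, function(t) {
    os <- find_orf_set(t$seq)
    keep <- Filter(Negate(is.null), unclass(os))
    if (!length(keep)) return(NULL)
    data.frame(id = t$id,
               kind = vapply(keep, `[[`, "", "kind"),
               start = vapply(keep, `[[`, 0L, "start"),
               end = vapply(keep, `[[`, 0L, "end"),
               start_codon = vapply(keep, `[[`, "", "start_codon"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(0), kind = character(0),
                                      start = integer(0), end = integer(0),
                                      start_codon = character(0))
  rownames(out) <- NULL
  out
}
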