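#' Build reference frequency tables for context / trimer / hexamer scores
#'
#' From a set of coding sequences (each starting at its start codon, length
#' divisible by 3), builds three frequency-table pairs: the "active"
#' frequencies `F` come from the CDS set itself and the "inactive" `F'`
#' from a uniform per-sequence nucleotide shuffle of the same set
#' (seeded).  The context table is position-specific over a window of
#' offsets around each sequence start (default -6..+3, the start-codon A at
#' offset 0); trimer and hexamer tables count in-frame units stepping by 3
#' codons/bi-codons.  A pseudocount is added to every cell before
#' normalization so that every queryable unit has `F > 0` and `F' > 0`.
#' Offsets upstream of the sequence start have no observations and are
#' pseudocount-uniform in both tables (hence contribute 0 to scores).
#'
#' @param cds Character vector of CDS-like sequences (length >= 9,
#'   divisible by 3).
#' @param seed Integer seed for the shuffle.
#' @param pseudocount Count added to every table cell (default 0.5).
#' @param context_offsets Integer offsets of the context window relative to
#'   the first base of the start codon (default `-6:3`; use `-6:1` for the
#'   narrower window variant).
#' @return A list of three `frequency_table` objects:
#'   `context`, `trimer`, `hexamer`.
#' @export
build_reference_tables <- function(cds, seed = 1L, pseudocount = 0.5,
                                   context_offsets = -6:3) {
  if (!length(cds)) stop("empty CDS set")
  cds <- vapply(cds, normalize_seq, "", USE.NAMES = FALSE)
  if (any(nchar(cds) < 9) || any(nchar(cds) %% 3 != 0)) {
    stop("each CDS must have length >= 9 and divisible by 3")
  }
  shuffled <- with_seed(seed, vapply(cds, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
  mk <- function(kind, f, fp) {
    structure(list(unit_kind = kind, F = f, F_prime = fp,
                   pseudocount = pseudocount,
                   context_offsets = context_offsets),
              class = "frequency_table")
  }
  list(context = mk("context_position",
                    context_counts(cds, context_offsets, pseudocount),
                    context_counts(shuffled, context_offsets, pseudocount)),
       trimer = mk("trimer",
                   unit_counts(cds, 3L, pseudocount),
                   unit_counts(shuffled, 3L, pseudocount)),
       hexamer = mk("hexamer",
                    unit_counts(cds, 6L, pseudocount),
                    unit_counts(shuffled, 6L, pseudocount)))
}

#' @exportS3Method base::print
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> ", x$unit_kind, ", ",
      if (is.matrix(x$F)) paste(nrow(x$F), "positions") else paste(length(x$F), "units"),
      ", pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

# Position-specific nucleotide frequencies (rows = offsets, cols = ACGT),
# window anchored at the first base of each sequence; out-of-range or N
# positions contribute nothing (pseudocount only).
context_counts <- function(seqs, offsets, pseudocount) {
  nts <- c("A", "C", "G", "T")
  m <- matrix(pseudocount, nrow = length(offsets), ncol = 4,
              dimnames = list(as.character(offsets), nts))
  for (s in seqs) {
    pos <- 1L + offsets           # start base is offset 0
    ok <- pos >= 1L & pos <= nchar(s)
    ch <- substring(s, pos[ok], pos[ok])
    keep <- ch %in% nts
    rows <- which(ok)[keep]
    cols <- match(ch[keep], nts)
    for (r in seq_along(rows)) m[rows[r], cols[r]] <- m[rows[r], cols[r]] + 1
  }
  sweep(m, 1, rowSums(m), "/")    # frequencies sum to 1 per position
}

# In-frame unit frequencies over all 4^k units; step 3 (codons for k = 3,
# overlapping bi-codons for k = 6); units containing N are skipped.
unit_counts <- function(seqs, k, pseudocount) {
  units <- all_units(k)
  cnt <- setNames(rep(pseudocount, length(units)), units)
  for (s in seqs) {
    u <- inframe_units(s, k)
    u <- u[!grepl("N", u, fixed = TRUE)]
    if (length(u)) {
      tb <- table(u)
      cnt[names(tb)] <- cnt[names(tb)] + as.numeric(tb)
    }
  }
  cnt / sum(cnt)
}

all_units <- function(k) {
  nts <- c("A", "C", "G", "T")
  u <- nts
  for (i in seq_len(k - 1)) u <- as.vector(outer(u, nts, paste0))
  sort(u)
}

inframe_units <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = 3L)
  substring(s, starts, starts + k - 1L)
}

#' Context (Kozak-like) score of an ORF start
#'
#' Mean natural-log frequency ratio `log(F/F')` of the nucleotides at the
#' window offsets around the ORF start (default -6..+3, the first base of
#' the start codon at offset 0).  The window must fit inside the
#' transcript; otherwise the score is missing (`NA`).  Positions holding
#' `N` are skipped and reduce `n`.
#'
#' @param seq Transcript sequence.
#' @param orf_start 1-based position of the first base of the start codon.
#' @param tables Table list from [build_reference_tables()] (or a single
#'   context `frequency_table`).
#' @return A list (`value` in nats, `n_units`), or value `NA` when the
#'   window is truncated.
#' @export
context_score <- function(seq, orf_start, tables) {
  tab <- if (inherits(tables, "frequency_table")) tables else tables$context
  offsets <- tab$context_offsets
  seq <- normalize_seq(seq)
  pos <- orf_start + offsets
  if (any(pos < 1L) || any(pos > nchar(seq))) {
    return(list(value = NA_real_, n_units = 0L))
  }
  ch <- substring(seq, pos, pos)
  keep <- ch %in% c("A", "C", "G", "T")
  if (!any(keep)) return(list(value = NA_real_, n_units = 0L))
  i <- match(as.character(offsets[keep]), rownames(tab$F))
  j <- match(ch[keep], colnames(tab$F))
  lr <- log(tab$F[cbind(i, j)] / tab$F_prime[cbind(i, j)])
  list(value = mean(lr), n_units = sum(keep))
}

# Shared scorer for trimer/hexamer: mean log(F/F') over in-frame units.
unit_score <- function(orf_seq, tab, k) {
  orf_seq <- normalize_seq(orf_seq)
  if (nchar(orf_seq) < k || nchar(orf_seq) %% 3 != 0) {
    return(list(value = NA_real_, n_units = 0L))
  }
  u <- inframe_units(orf_seq, k)
  u <- u[!grepl("N", u, fixed = TRUE)]
  if (!length(u)) return(list(value = NA_real_, n_units = 0L))
  lr <- log(tab$F[u] / tab$F_prime[u])
  list(value = mean(lr), n_units = length(u))
}

#' Trimer (codon-usage) score of an ORF
#'
#' Mean natural-log frequency ratio of the ORF's in-frame codons between
#' the active and shuffled reference tables.  A positive score indicates
#' codon usage resembling the active (CDS-like) reference.
#'
#' @param orf_seq ORF sequence (length divisible by 3).
#' @param tables Table list from [build_reference_tables()] (or a single
#'   trimer `frequency_table`).
#' @return A list (`value` in nats, `n_units`).
#' @export
trimer_score <- function(orf_seq, tables) {
  tab <- if (inherits(tables, "frequency_table")) tables else tables$trimer
  unit_score(orf_seq, tab, 3L)
}

#' Hexamer (bi-codon usage) score of an ORF
#'
#' As [trimer_score()], over in-frame hexamers stepping by 3 (overlapping
#' codon pairs), the unit also used for coding-potential assessment in
#' CPAT-style models.  ORFs shorter than 6 nt score missing.
#'
#' @inheritParams trimer_score
#' @return A list (`value` in nats, `n_units`).
#' @export
hexamer_score <- function(orf_seq, tables) {
  tab <- if (inherits(tables, "frequency_table")) tables else tables$hexamer
  unit_score(orf_seq, tab, 6L)
}

#' Write / read frequency tables as TSV
#'
#' Serialization: one row per unit (or per position:nucleotide for the
#' context table) with columns `unit`, `F`, `F_prime`.
#'
#' @param tab A `frequency_table`.
#' @param path Output / input path.
#' @return `write_frequency_table()` returns `tab` invisibly;
#'   `read_frequency_table()` returns a `frequency_table`.
#' @export
write_frequency_table <- function(tab, path) {
  if (is.matrix(tab$F)) {
    grid <- expand.grid(pos = rownames(tab$F), nt = colnames(tab$F),
                        stringsAsFactors = FALSE)
    df <- data.frame(unit = paste0(grid$pos, ":", grid$nt),
                     F = tab$F[cbind(grid$pos, grid$nt)],
                     F_prime = tab$F_prime[cbind(grid$pos, grid$nt)])
  } else {
    df <- data.frame(unit = names(tab$F), F = unname(tab$F),
                     F_prime = unname(tab$F_prime))
  }
  hdr <- paste0("# unit_kind=", tab$unit_kind, " pseudocount=", tab$pseudocount,
                if (!is.null(tab$context_offsets))
                  paste0(" offsets=", paste(tab$context_offsets, collapse = ",")) else "")
  writeLines(c(hdr, paste(colnames(df), collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))), path)
  invisible(tab)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  hdr <- readLines(path, n = 1)
  kind <- sub(".*unit_kind=(\\S+).*", "\\1", hdr)
  ps <- as.numeric(sub(".*pseudocount=(\\S+).*", "\\1", hdr))
  offs <- if (grepl("offsets=", hdr)) {
    as.integer(strsplit(sub(".*offsets=(\\S+).*", "\\1", hdr), ",")[[1]])
  } else NULL
  df <- read.delim(path, skip = 1)
  if (kind == "context_position") {
    parts <- strsplit(df$unit, ":", fixed = TRUE)
    pos <- vapply(parts, `[[`, "", 1); nt <- vapply(parts, `[[`, "", 2)
    upos <- as.character(sort(unique(as.integer(pos)))); unt <- c("A", "C", "G", "T")
    f <- fp <- matrix(NA_real_, length(upos), 4, dimnames = list(upos, unt))
    f[cbind(pos, nt)] <- df$F; fp[cbind(pos, nt)] <- df$F_prime
  } else {
    f <- setNames(df$F, df$unit); fp <- setNames(df$F_prime, df$unit)
  }
  structure(list(unit_kind = kind, F = f, F_prime = fp, pseudocount = ps,
                 context_offsets = offs), class = "frequency_table")
}
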