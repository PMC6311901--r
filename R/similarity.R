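#' Pairwise sequence similarity as coverage of the shorter sequence
#'
#' Computes the percentage of the shorter sequence covered by local
#' alignment blocks against the longer one, using an internal seeded
#' routine: exact k-mer seeds (default `k = 11`) are extended along their
#' diagonal into maximal exact runs and then greedily extended across
#' mismatches while block identity stays at or above `min_identity`.
#' Coverage is the union of shorter-sequence positions inside qualifying
#' blocks.  This plays the role a local aligner (e.g. BLAST) plays in
#' duplicate removal; seed length and identity floor are configurable.
#'
#' @param a,b [transcript] objects (or plain DNA strings).
#' @param k Seed length (exact match) for block discovery.
#' @param min_identity Identity floor for a block after mismatch extension.
#' @return A list (`id_a`, `id_b`, `coverage_of_shorter` in `[0, 100]`).
#' @export
pairwise_similarity <- function(a, b, k = 11L, min_identity = 0.8) {
  ga <- function(x, d) if (is.character(x)) list(id = d, seq = normalize_seq(x)) else x
  a <- ga(a, "a"); b <- ga(b, "b")
  if (!nchar(a$seq) || !nchar(b$seq)) stop("pairwise_similarity: empty sequence")
  list(id_a = a$id, id_b = b$id,
       coverage_of_shorter = similarity_coverage(a$seq, b$seq, k, min_identity))
}

# Coverage (%) of the shorter of s1/s2 by seeded local blocks vs the other.
similarity_coverage <- function(s1, s2, k = 11L, min_identity = 0.8) {
  if (nchar(s1) <= nchar(s2)) { s <- s1; l <- s2 } else { s <- s2; l <- s1 }
  ns <- nchar(s); nl <- nchar(l)
  if (ns < k) { # degenerate: fall back to exact containment
    return(if (grepl(s, l, fixed = TRUE)) 100 else 0)
  }
  sc <- strsplit(s, "")[[1]]
  lc <- strsplit(l, "")[[1]]
  lk <- substring(l, 1:(nl - k + 1L), k:nl)
  idx <- split(seq_len(nl - k + 1L), lk)
  sk <- substring(s, 1:(ns - k + 1L), k:ns)
  hit_i <- which(sk %in% names(idx))
  if (!length(hit_i)) return(0)
  # diagonals (offset of l relative to s) holding at least one seed
  diags <- unique(unlist(lapply(hit_i, function(i) idx[[sk[i]]] - i)))
  covered <- logical(ns)
  for (d in diags) {
    i0 <- max(1L, 1L - d); i1 <- min(ns, nl - d)       # valid s-range on diagonal
    if (i1 - i0 + 1L < k) next
    match_v <- sc[i0:i1] == lc[(i0 + d):(i1 + d)]
    r <- rle(match_v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seed_runs <- which(r$values & r$lengths >= k)
    for (j in seed_runs) {
      b0 <- starts[j]; b1 <- ends[j]; m <- r$lengths[j]   # matches in block
      repeat { # absorb flanking mismatch run + next match run while identity holds
        grew <- FALSE
        jr <- which(starts > b1 & r$values)
        if (length(jr)) {
          nb1 <- ends[jr[1]]; nm <- m + r$lengths[jr[1]]
          if (nm / (nb1 - b0 + 1L) >= min_identity) { b1 <- nb1; m <- nm; grew <- TRUE }
        }
        jl <- which(ends < b0 & r$values)
        if (length(jl)) {
          jl <- jl[length(jl)]
          nb0 <- starts[jl]; nm <- m + r$lengths[jl]
          if (nm / (b1 - nb0 + 1L) >= min_identity) { b0 <- nb0; m <- nm; grew <- TRUE }
        }
        if (!grew) break
      }
      covered[(i0 + b0 - 1L):(i0 + b1 - 1L)] <- TRUE
    }
  }
  100 * sum(covered) / ns
}

#' Remove transcripts sharing high sequence similarity
#'
#' Greedy longest-first pass: transcripts are visited in order of
#' decreasing length (ties: input order) and a candidate is discarded iff
#' its coverage-of-shorter against any already-retained transcript exceeds
#' `threshold` percent — i.e. of a highly similar pair, the shorter one is
#' discarded.  The retained set is returned in the original input order.
#'
#' @param ts Named list of [transcript] objects with unique ids.
#' @param threshold Coverage percentage above which a pair counts as highly
#'   similar (default 60, of the shorter sequence).
#' @param hits Optional precomputed pairwise hits `data.frame`
#'   (`id_a`, `id_b`, `coverage`) — e.g. parsed from a BLAST run — used in
#'   place of the internal similarity routine.
#' @param ... Passed to [pairwise_similarity()].
#' @return The retained subset of `ts` (input order), with the discarded
#'   ids in attribute `"discarded"`.
#' @export
deduplicate <- function(ts, threshold = 60, hits = NULL, ...) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100) {
    stop("threshold must be in (0, 100]")
  }
  ids <- vapply(ts, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  lens <- vapply(ts, function(t) nchar(t$seq), 0L)
  ord <- order(-lens, seq_along(ts))
  lookup <- NULL
  if (!is.null(hits)) {
    lookup <- c(setNames(hits$coverage, paste(hits$id_a, hits$id_b)),
                setNames(hits$coverage, paste(hits$id_b, hits$id_a)))
  }
  cov_fun <- function(a, b) {
    if (!is.null(lookup)) {
      v <- lookup[paste(a$id, b$id)]
      return(if (is.na(v)) 0 else unname(v))
    }
    pairwise_similarity(a, b, ...)$coverage_of_shorter
  }
  retained <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (j in retained) {
      if (cov_fun(ts[[i]], ts[[j]]) > threshold) { hit <- TRUE; break }
    }
    if (!hit) retained <- c(retained, i)
  }
  keep <- sort(retained)
  out <- ts[keep]
  attr(out, "discarded") <- unname(ids[setdiff(seq_along(ts), keep)])
  out
}
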