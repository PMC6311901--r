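#' Predict m6A sites from the DRACH consensus
#'
#' Default motif-only backend: scans the transcript for the DRACH consensus
#' (`D` in A/G/T, `R` in A/G, then `A`, `C`, `H` in A/C/T) and reports the
#' central `A` of every (possibly overlapping) match with score 1.
#' Externally predicted site tables imported with [read_site_table()] take
#' precedence over this backend in the feature pipeline.
#'
#' @param seq DNA string or [transcript].
#' @return `data.frame` with columns `kind` (`"m6A"`), `start`, `end`
#'   (single base), `score`.
#' @export
predict_m6a <- function(seq) {
  if (inherits(seq, "transcript")) seq <- seq$seq
  seq <- normalize_seq(seq)
  hits <- gregexpr("(?=[AGT][AG]AC[ACT])", seq, perl = TRUE)[[1]]
  pos <- if (hits[1] == -1) integer(0) else as.integer(hits) + 2L
  data.frame(kind = rep("m6A", length(pos)), start = pos, end = pos,
             score = rep(1, length(pos)), stringsAsFactors = FALSE)
}

#' G-quadruplex scoring constants
#'
#' QGRS-style search constraints and G-score constants: candidates are four
#' G-runs of equal length `g >= min_run`, loops of `loop_range` bases,
#' total span at most `max_total`.  The G-score rewards more/longer G-runs
#' (`run_weight * (g - 1)`) and penalizes uneven loops (minus the mean
#' pairwise absolute loop-length difference, `even_weight` per base).
#'
#' @param min_run Minimum G-run length (tetrad size), default 2.
#' @param loop_range Allowed loop lengths, default `c(0, 36)`.
#' @param max_total Maximum candidate span in nt, default 30.
#' @param run_weight Score per unit of `g - 1`.
#' @param even_weight Penalty per base of mean pairwise loop difference.
#' @return Parameter list for [detect_g4()].
#' @export
g4_params <- function(min_run = 2L, loop_range = c(0L, 36L), max_total = 30L,
                      run_weight = 21, even_weight = 1) {
  list(min_run = as.integer(min_run), loop_range = as.integer(loop_range),
       max_total = as.integer(max_total), run_weight = run_weight,
       even_weight = even_weight)
}

g4_score <- function(g, loops, params) {
  d <- abs(c(loops[1] - loops[2], loops[1] - loops[3], loops[2] - loops[3]))
  params$run_weight * (g - 1) - params$even_weight * mean(d)
}

#' Detect stable G-quadruplex segments
#'
#' Enumerates QGRS-style candidates (four equal-length G-runs with bounded
#' loops and total span, see [g4_params()]), scores them, keeps those with
#' G-score at or above `min_gscore` (the stability threshold), and resolves
#' overlaps greedily by descending score (ties: 5'-most start, then
#' shorter).
#'
#' @param seq DNA string or [transcript].
#' @param min_gscore Stability threshold (default 30).
#' @param params Constants from [g4_params()].
#' @return `data.frame` with columns `kind` (`"G4"`), `start`, `end`,
#'   `score`, non-overlapping, ordered by `start`.
#' @export
detect_g4 <- function(seq, min_gscore = 30, params = g4_params()) {
  if (inherits(seq, "transcript")) seq <- seq$seq
  seq <- normalize_seq(seq)
  cand <- g4_candidates(seq, params)
  cand <- cand[cand$score >= min_gscore, , drop = FALSE]
  resolve_g4_overlaps(cand)
}

# All candidate quadruplets (run-based enumeration).
g4_candidates <- function(seq, params) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  ch <- strsplit(seq, "")[[1]]
  is_g <- ch == "G"
  out <- list()
  gmax <- max(rle(is_g)$lengths[rle(is_g)$values], 0)
  for (g in params$min_run:max(params$min_run, gmax)) {
    if (g * 4 > params$max_total) break
    # positions where a run of >= g G's starts
    runs <- which(vapply(seq_len(n - g + 1L),
                         function(p) all(is_g[p:(p + g - 1L)]), TRUE))
    if (length(runs) < 4) next
    for (a in runs) {
      if (a + 4L * g - 1L > n) next
      b_ok <- runs[runs >= a + g + params$loop_range[1] &
                   runs <= a + g + params$loop_range[2]]
      for (b in b_ok) {
        c_ok <- runs[runs >= b + g + params$loop_range[1] &
                     runs <= b + g + params$loop_range[2]]
        for (cc in c_ok) {
          d_ok <- runs[runs >= cc + g + params$loop_range[1] &
                       runs <= cc + g + params$loop_range[2]]
          for (dd in d_ok) {
            end <- dd + g - 1L
            if (end - a + 1L > params$max_total) next
            loops <- c(b - (a + g), cc - (b + g), dd - (cc + g))
            out[[length(out) + 1L]] <- c(a, end,
                                         g4_score(g, loops, params))
          }
        }
      }
    }
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             score = m[, 3])
}

# Greedy non-overlapping selection by score desc, then start asc, then
# shorter span; shared by detector and test oracle contract.
resolve_g4_overlaps <- function(cand) {
  if (nrow(cand) == 0) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  }
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ov <- any(cand$start[i] <= cand$end[keep] & cand$end[i] >= cand$start[keep])
    if (!length(keep) || !ov) keep <- c(keep, i)
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  data.frame(kind = rep("G4", nrow(res)), start = res$start, end = res$end,
             score = res$score, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a site-annotation table (TSV)
#'
#' Import path for externally predicted sites (e.g. SRAMP m6A predictions
#' or QGRS G4 calls): columns `kind`, `transcript_id`, `start`, `end`
#' (optional, defaults to `start`), `score`.
#'
#' @param path TSV path.
#' @return Named list (by transcript id) of site `data.frame`s.
#' @export
read_site_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "transcript_id", "start", "score") %in% colnames(df)))
  if (is.null(df$end)) df$end <- df$start
  lapply(split(df, df$transcript_id), function(d) {
    data.frame(kind = d$kind, start = as.integer(d$start),
               end = as.integer(d$end), score = d$score,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Site-to-anchor distance features
#'
#' For each site kind (m6A, G4), picks one representative site — highest
#' score, ties broken toward the 5'-most — and measures its distance to
#' the transcript anchors: TIS (5' end), TTS (3' end), and the start/end
#' of each of the upstream/first/primary ORFs.  Two measures per anchor:
#' direct distance `log10(1 + |site - anchor|)` (bases, log scale) and
#' relative distance `100 * |site - anchor| / length` (percent of the
#' transcript).  Absent sites or absent anchor ORFs yield `NA`.
#'
#' @param t A [transcript].
#' @param orfs Its `orf_set` (see [find_orf_set()]).
#' @param sites `data.frame` of sites on `t` (columns `kind`, `start`,
#'   `end`, `score`), e.g. from [predict_m6a()] / [detect_g4()].
#' @return `data.frame` with columns `kind`, `anchor`, `direct`,
#'   `relative` (one row per kind/anchor combination, `NA` when missing).
#' @export
site_distance_features <- function(t, orfs, sites) {
  len <- nchar(t$seq)
  anchors <- list(TIS = 1L, TTS = len,
                  uOrfStart = orfs$uorf$start, uOrfEnd = orfs$uorf$end,
                  fOrfStart = orfs$forf$start, fOrfEnd = orfs$forf$end,
                  pOrfStart = orfs$porf$start, pOrfEnd = orfs$porf$end)
  anchor_names <- c("TIS", "TTS", "uOrfStart", "uOrfEnd", "fOrfStart",
                    "fOrfEnd", "pOrfStart", "pOrfEnd")
  kinds <- c("m6A", "G4")
  rows <- list()
  for (k in kinds) {
    sk <- sites[sites$kind == k, , drop = FALSE]
    rep_pos <- NA_integer_
    if (nrow(sk)) {
      sk <- sk[order(-sk$score, sk$start), , drop = FALSE]
      rep_pos <- sk$start[1]
    }
    for (a in anchor_names) {
      ap <- anchors[[a]]
      if (is.na(rep_pos) || is.null(ap)) {
        direct <- relative <- NA_real_
      } else {
        d <- abs(rep_pos - ap)
        direct <- log10(1 + d)
        relative <- 100 * d / len
      }
      rows[[length(rows) + 1L]] <- data.frame(kind = k, anchor = a,
                                              direct = direct,
                                              relative = relative,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
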