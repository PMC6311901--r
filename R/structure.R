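#' Stem-probability model parameters
#'
#' Per-pair Boltzmann weights of the internal nested partition function
#' (weight `exp(-E/kT)` with energies in kT units: GC stronger than AU
#' stronger than GU wobble), the minimum hairpin-loop length, and the span
#' cap applied to long transcripts.
#'
#' @param wGC,wAU,wGU Boltzmann weights of the canonical pairs.
#' @param minloop Minimum number of unpaired bases inside a hairpin loop.
#' @param long_cap Span cap substituted for very long (> `long_threshold`
#'   nt) transcripts.
#' @param long_threshold Length above which `long_cap` replaces the
#'   all-pairs default span.
#' @param guard_cap,guard_threshold Complexity guard: transcripts longer
#'   than `guard_threshold` have their span capped at `guard_cap` because
#'   the partition function costs O(N * span^2).  Set
#'   `guard_threshold = Inf` to disable.
#' @return A list of parameters for [stem_profile()].
#' @export
stem_params <- function(wGC = exp(3), wAU = exp(2), wGU = exp(1), minloop = 3L,
                        long_cap = 200L, long_threshold = 9500L,
                        guard_cap = 200L, guard_threshold = 2000L) {
  list(wGC = wGC, wAU = wAU, wGU = wGU, minloop = as.integer(minloop),
       long_cap = as.integer(long_cap), long_threshold = as.integer(long_threshold),
       guard_cap = as.integer(guard_cap), guard_threshold = guard_threshold)
}

#' Per-base stem probabilities of a transcript
#'
#' Probability that each base is paired in the thermodynamic ensemble of
#' nested secondary structures, restricted to pairs `(i, j)` with
#' `|j - i| <= max_span`.  The default span is `N - 1` (all pairs), falling
#' back to 200 for very long (> 9500 nt) transcripts; independently, a
#' complexity guard caps the span at 200 for transcripts over 2000 nt
#' (both configurable via [stem_params()]).  `N` bases never pair.
#'
#' @param seq DNA/RNA string (a [transcript]'s `seq` is accepted too).
#' @param max_span Maximum pairing distance; `NULL` for the defaults above.
#' @param params Model parameters from [stem_params()].
#' @return An object of class `stem_profile`: list with `probs` (one value
#'   in `[0, 1]` per base) and `max_span`.
#' @export
stem_profile <- function(seq, max_span = NULL, params = stem_params()) {
  if (inherits(seq, "transcript")) seq <- seq$seq
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < 1) stop("stem_profile: empty sequence")
  if (is.null(max_span)) {
    max_span <- if (n > params$long_threshold) params$long_cap else n - 1L
  }
  if (n > params$guard_threshold) max_span <- min(max_span, params$guard_cap)
  max_span <- max(1L, min(as.integer(max_span), n - 1L))
  enc <- encode_dna(seq)
  probs <- .stem_pair_probs_cpp(enc, max_span, params$wAU, params$wGC,
                                params$wGU, params$minloop)
  structure(list(probs = as.numeric(probs), max_span = max_span),
            class = "stem_profile")
}

encode_dna <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L
  m - 1L
}

#' @exportS3Method base::print
print.stem_profile <- function(x, ...) {
  cat("<stem_profile> ", length(x$probs), " bases, max_span ", x$max_span,
      ", mean ", round(mean(x$probs), 3), "\n", sep = "")
  invisible(x)
}

#' Mean stem probability over a region
#'
#' @param profile A `stem_profile` (or bare numeric probability vector).
#' @param interval `c(start, end)`, 1-based closed; empty (`start > end`)
#'   intervals yield `NA`.
#' @return Arithmetic mean probability, or `NA_real_`.
#' @export
region_mean_stem <- function(profile, interval) {
  p <- if (inherits(profile, "stem_profile")) profile$probs else profile
  if (is.null(interval) || interval_width(interval) == 0) return(NA_real_)
  if (interval[1] < 1 || interval[2] > length(p)) {
    stop("interval [", interval[1], ", ", interval[2], "] outside profile of length ",
         length(p))
  }
  mean(p[interval[1]:interval[2]])
}

#' Ratio of UTR to ORF mean stem probability
#'
#' Quantifies the secondary-structure change between a UTR and its ORF.
#' Missing inputs, or an ORF mean below `eps`, propagate `NA`.
#'
#' @param utr_mean,orf_mean Region means from [region_mean_stem()].
#' @param eps Guard against division by (near-)zero.
#' @return `utr_mean / orf_mean`, or `NA_real_`.
#' @export
stem_ratio <- function(utr_mean, orf_mean, eps = 1e-6) {
  if (is.na(utr_mean) || is.na(orf_mean) || orf_mean < eps) return(NA_real_)
  utr_mean / orf_mean
}

#' Import / export per-base stem probabilities as TSV
#'
#' The import path accepts externally computed per-base probability tables
#' (columns `transcript_id`, `position`, `stem_prob`), which take
#' precedence over the internal backend when supplied to the feature
#' pipeline.
#'
#' @param profiles Named list of `stem_profile` objects.
#' @param path TSV path.
#' @return `read_stem_profiles()` returns a named list of `stem_profile`s.
#' @export
write_stem_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    data.frame(transcript_id = id,
               position = seq_along(profiles[[id]]$probs),
               stem_prob = profiles[[id]]$probs)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(profiles)
}

#' @rdname write_stem_profiles
#' @export
read_stem_profiles <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("transcript_id", "position", "stem_prob") %in% colnames(df)))
  out <- lapply(split(df, df$transcript_id), function(d) {
    d <- d[order(d$position), ]
    if (any(d$stem_prob < 0 | d$stem_prob > 1)) {
      stop("stem probabilities outside [0, 1] for ", d$transcript_id[1])
    }
    structure(list(probs = d$stem_prob, max_span = NA_integer_),
              class = "stem_profile")
  })
  out
}
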