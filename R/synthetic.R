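#' Default codon usage (approximate human)
#'
#' Relative usage of the 61 sense codons, normalized to sum to 1, from the
#' commonly cited human codon-usage frequencies.  Used as the default
#' "active" codon model of [generate_cds_reference()].
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
default_codon_usage <- function() {
  u <- c(TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
         CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
         ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
         GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
         TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
         CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
         ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
         GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
         TAT = 12.2, TAC = 15.3,
         CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
         AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
         GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
         TGT = 10.6, TGC = 12.6, TGG = 13.2,
         CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
         AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
         GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
  u / sum(u)
}

#' Generate a CDS reference set with codon-usage bias
#'
#' Each sequence is `ATG` + i.i.d. sense codons drawn from `codon_usage` +
#' one stop codon; lengths are divisible by 3 and uniform over
#' `length_range`.  Serves as the "active ORF" reference for
#' [build_reference_tables()].
#'
#' @param n Number of sequences.
#' @param codon_usage Named probabilities over the 61 sense codons
#'   (must sum to 1).
#' @param length_range Total length range in nt (inclusive).
#' @param seed Integer seed.
#' @return Character vector of CDS sequences.
#' @export
generate_cds_reference <- function(n, codon_usage = default_codon_usage(),
                                   length_range = c(150, 600), seed = 1L) {
  if (length(codon_usage) != 61 || abs(sum(codon_usage) - 1) > 1e-6) {
    stop("codon_usage must be 61 sense-codon probabilities summing to 1")
  }
  stops <- c("TAA", "TGA", "TAG")
  if (any(names(codon_usage) %in% stops)) stop("codon_usage must exclude stops")
  lens <- 3L * (seq.int(ceiling(length_range[1] / 3), floor(length_range[2] / 3)))
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      total <- sample(lens, 1)
      k <- total / 3L - 2L                       # internal codons
      body <- sample(names(codon_usage), k, replace = TRUE, prob = codon_usage)
      paste0("ATG", paste(body, collapse = ""),
             sample(stops, 1, prob = c(0.30, 0.47, 0.23)))
    }, "")
  })
}

#' Configuration of a synthetic labeled lncRNA cohort
#'
#' Defines the statistical structure of a two-class cohort: cohort sizes,
#' a log-normal transcript length distribution, a categorical exon-count
#' distribution, background GC, per-kind site implant rates, repeat
#' insertion probabilities, and the planted class effects (named signed
#' shifts; the sign is the direction of the ribosome-associated class).
#' Effects on `fEgc`, `fELen`, `fILen`, repeat flags, and the k-mer score
#' features are realized mechanistically in the sequences; any other
#' requested feature is realized by direct value injection into the
#' extracted feature matrix (see [apply_planted_injections()]).
#'
#' @param n_ribo,n_noribo Class sizes.
#' @param length_meanlog,length_sdlog,length_range Log-normal transcript
#'   length parameters (nt) and clipping range.
#' @param exon_count_probs Named probabilities of exon counts.
#' @param base_gc Background GC fraction.
#' @param planted_effects Named signed shifts (e.g.
#'   `c(fEgc = 0.1, fELen = -0.1)`).
#' @param orf_prob Probability a transcript carries an embedded CDS-like
#'   ORF.
#' @param site_rates Poisson implant rates per transcript for `m6A` and
#'   `G4` motifs.
#' @param repeat_base_prob Baseline repeat insertion probability per class
#'   label (LTR/LINE/SINE/Alu/SINEB2).
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters.
#' @param seed Global cohort seed (fanned out to per-component streams).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_ribo = 500L, n_noribo = 500L,
                          length_meanlog = 6.3, length_sdlog = 0.6,
                          length_range = c(200L, 10000L),
                          exon_count_probs = c("1" = 0.20, "2" = 0.35,
                                               "3" = 0.25, "4" = 0.12,
                                               "5" = 0.08),
                          base_gc = 0.45,
                          planted_effects = c(fEgc = 0.1, fELen = -0.1,
                                              fILen = 0.1, LTR = 0.1),
                          orf_prob = 0.8,
                          site_rates = c(m6A = 2, G4 = 0.7),
                          repeat_base_prob = c(LTR = 0.15, LINE = 0.15,
                                               SINE = 0.15, Alu = 0.10,
                                               SINEB2 = 0.05),
                          intron_meanlog = 6.5, intron_sdlog = 1.0,
                          seed = 1L) {
  cfg <- list(n_ribo = as.integer(n_ribo), n_noribo = as.integer(n_noribo),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              length_range = as.integer(length_range),
              exon_count_probs = exon_count_probs, base_gc = base_gc,
              planted_effects = planted_effects, orf_prob = orf_prob,
              site_rates = site_rates, repeat_base_prob = repeat_base_prob,
              intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  pe <- cfg$planted_effects
  if (length(pe)) {
    if (any(abs(pe) > 1)) stop("infeasible planted effect (|shift| > 1): ",
                               paste(names(pe)[abs(pe) > 1], collapse = ", "))
    if ("fEgc" %in% names(pe)) {
      g <- cfg$base_gc + pe[["fEgc"]]
      if (g < 0 || g > 1) stop("fEgc shift pushes GC outside [0, 1]")
    }
    rep_planted <- intersect(names(pe), names(cfg$repeat_base_prob))
    for (r in rep_planted) {
      p <- cfg$repeat_base_prob[[r]] + pe[[r]]
      if (p < 0 || p > 1) stop(r, " shift pushes insertion probability outside [0, 1]")
    }
  }
  if (abs(sum(cfg$exon_count_probs) - 1) > 1e-6) stop("exon_count_probs must sum to 1")
  invisible(cfg)
}

# Features whose planted effects generate_cohort() realizes in sequence.
.mechanistic_features <- function(cfg) {
  c("fEgc", "fELen", "fILen", names(cfg$repeat_base_prob),
    grep("OrfSeqTrimer$|OrfSeqHexamer$|OrfContext$",
         feature_registry()$name, value = TRUE))
}

#' Ground truth of a planted cohort
#'
#' Deterministic (seed-independent) listing of the planted discriminative
#' features with their signs, magnitudes, and realization path.
#'
#' @param cfg A [cohort_config()].
#' @return `data.frame` with columns `feature`, `sign`, `magnitude`,
#'   `mechanism` (`"mechanistic"` or `"injected"`).
#' @export
planted_truth <- function(cfg) {
  pe <- cfg$planted_effects
  if (!length(pe)) {
    return(data.frame(feature = character(0), sign = character(0),
                      magnitude = numeric(0), mechanism = character(0)))
  }
  data.frame(feature = names(pe),
             sign = ifelse(pe > 0, "+", "-"),
             magnitude = abs(unname(pe)),
             mechanism = ifelse(names(pe) %in% .mechanistic_features(cfg),
                                "mechanistic", "injected"),
             stringsAsFactors = FALSE)
}

rand_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Overwrite `insert` into `seq` starting at 1-based `at` (must fit).
splice_into <- function(seq, insert, at) {
  paste0(substr(seq, 1, at - 1), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Generate a labeled synthetic lncRNA cohort
#'
#' Emits a two-class cohort of transcripts with realistic exon/intron
#' structure and the configured planted class effects: class-dependent
#' first-exon GC, first-exon and first-intron length scaling, embedded
#' CDS-like ORFs (with class-dependent codon source when a k-mer score
#' effect is planted), implanted m6A/G4 motifs, and repeat intervals
#' inserted with class-dependent probabilities.  All randomness derives
#' from `cfg$seed` via documented per-component streams, so any output is
#' bit-reproducible.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Optional directory; when given, writes
#'   `transcripts.fa`, `transcripts.bed` (BED12), `repeats.bed`,
#'   `sites.tsv`, `labels.tsv`, and `truth.json`.
#' @return List with `transcripts` (named list of [transcript]),
#'   `labels` (named 0/1 vector), `repeats` (`data.frame`), `sites`
#'   (long `data.frame` of implanted sites), `truth`
#'   (see [planted_truth()]), and `config`.
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  validate_cohort_config(cfg)
  n <- cfg$n_ribo + cfg$n_noribo
  labels <- c(rep(1L, cfg$n_ribo), rep(0L, cfg$n_noribo))
  ids <- sprintf("tx%04d", seq_len(n))
  names(labels) <- ids
  pe <- cfg$planted_effects
  eff <- function(f) if (f %in% names(pe)) pe[[f]] else 0
  kmer_effect <- any(grepl("OrfSeq|OrfContext", names(pe)))
  usage <- default_codon_usage()
  uniform_usage <- setNames(rep(1 / 61, 61), names(usage))
  rep_classes <- names(cfg$repeat_base_prob)

  transcripts <- vector("list", n)
  rep_rows <- list()
  site_rows <- list()
  chrom_cursor <- 1L

  with_seed(derive_seed(cfg$seed, "cohort"), {
    for (i in seq_len(n)) {
      lab <- labels[i]
      L <- as.integer(round(rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)))
      L <- max(cfg$length_range[1], min(cfg$length_range[2], L))
      k <- as.integer(sample(names(cfg$exon_count_probs), 1,
                             prob = cfg$exon_count_probs))
      # first-exon length: ~30% of the transcript, class-scaled
      f_mult <- exp(2 * eff("fELen") * lab)
      f_len <- max(30L, min(L - 20L * (k - 1L),
                            as.integer(round(0.3 * L * f_mult))))
      if (k > 1) {
        w <- rgamma(k - 1L, 2, 1); w <- w / sum(w)
        rest <- as.integer(round((L - f_len) * w))
        rest[k - 1L] <- L - f_len - sum(rest[-(k - 1L)])
        rest <- pmax(rest, 1L)
        exon_lengths <- c(f_len, rest)
        exon_lengths[k] <- exon_lengths[k] + (L - sum(exon_lengths))
        i_mult <- exp(2 * eff("fILen") * lab)
        introns <- pmax(30L, round(rlnorm(k - 1L, cfg$intron_meanlog,
                                          cfg$intron_sdlog)))
        introns[1] <- max(30L, round(introns[1] * i_mult))
      } else {
        f_len <- L                           # the whole transcript is exon 1
        exon_lengths <- L
        introns <- integer(0)
      }
      # collect implants first (ORF, site motifs); preferentially placed
      # downstream of the first exon so they do not dilute a planted fEgc
      # shift, with GC compensation of the first-exon background when an
      # implant has to overlap it
      implants <- list()
      place <- function(width) {
        lo <- f_len + 3L; hi <- L - width - 2L
        if (hi >= lo) sample(lo:hi, 1) else sample(seq(3L, max(3L, L - width - 2L)), 1)
      }
      if (runif(1) < cfg$orf_prob && L >= 160) {
        orf_len <- 3L * sample(30:min(100, floor((L - 60) / 3)), 1)
        src <- usage
        if (kmer_effect) {
          neg <- any(pe[grepl("OrfSeq|OrfContext", names(pe))] < 0)
          if ((lab == 1 && neg) || (lab == 0 && !neg)) src <- uniform_usage
        }
        body <- sample(names(src), orf_len / 3L - 2L, replace = TRUE, prob = src)
        implants[[length(implants) + 1L]] <-
          list(seq = paste0("ATG", paste(body, collapse = ""), "TGA"),
               at = place(orf_len))
      }
      n_m6a <- min(rpois(1, cfg$site_rates[["m6A"]]), L %/% 10)
      if (n_m6a > 0 && L > 20) {
        for (p in vapply(seq_len(n_m6a), function(.) place(5L), 0L)) {
          implants[[length(implants) + 1L]] <- list(seq = "GGACT", at = p)
          site_rows[[length(site_rows) + 1L]] <-
            data.frame(kind = "m6A", transcript_id = ids[i],
                       start = p + 2L, end = p + 2L, score = 1)
        }
      }
      n_g4 <- min(rpois(1, cfg$site_rates[["G4"]]), 3L)
      if (n_g4 > 0 && L > 60) {
        motif <- "GGGAGGGAGGGAGGG"
        for (p in vapply(seq_len(n_g4), function(.) place(nchar(motif)), 0L)) {
          implants[[length(implants) + 1L]] <- list(seq = motif, at = p)
          site_rows[[length(site_rows) + 1L]] <-
            data.frame(kind = "G4", transcript_id = ids[i],
                       start = p, end = p + nchar(motif) - 1L, score = 42)
        }
      }
      # first-exon background GC, compensated for implant overlap
      gc_target <- cfg$base_gc + eff("fEgc") * lab
      imp_nt <- 0L; imp_gc_nt <- 0
      for (im in implants) {
        ov <- min(im$at + nchar(im$seq) - 1L, f_len) - im$at + 1L
        if (ov > 0) {
          part <- substr(im$seq, 1L, ov)
          imp_nt <- imp_nt + ov
          imp_gc_nt <- imp_gc_nt + ov * gc_content(part)
        }
      }
      n_bg <- f_len - imp_nt
      gc_bg <- if (n_bg > 0) {
        min(0.98, max(0.02, (gc_target * f_len - imp_gc_nt) / n_bg))
      } else gc_target
      seq <- paste0(rand_dna(f_len, gc_bg), rand_dna(L - f_len, cfg$base_gc))
      for (im in implants) seq <- splice_into(seq, im$seq, im$at)
      # genomic placement on one simulated chromosome
      starts <- as.integer(chrom_cursor + cumsum(c(0L, exon_lengths[-k] + introns)))
      gi <- data.frame(chrom = "chrSim", start = starts,
                       end = as.integer(starts + exon_lengths - 1L),
                       strand = "+", stringsAsFactors = FALSE)
      chrom_cursor <- max(gi$end) + 10000L
      # repeat insertions overlapping a random exon
      for (rc in rep_classes) {
        p_ins <- min(1, max(0, cfg$repeat_base_prob[[rc]] + eff(rc) * lab))
        if (runif(1) < p_ins) {
          e <- sample(k, 1)
          w <- max(20L, min(150L, exon_lengths[e] - 1L))
          s0 <- gi$start[e] + sample.int(max(1L, exon_lengths[e] - w), 1) - 1L
          rep_rows[[length(rep_rows) + 1L]] <-
            data.frame(chrom = "chrSim", start = s0, end = s0 + w - 1L,
                       class = rc, stringsAsFactors = FALSE)
        }
      }
      # excluded-class decoy near (not overlapping) the transcript
      if (runif(1) < 0.2) {
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(chrom = "chrSim", start = max(gi$end) + 500L,
                     end = max(gi$end) + 700L, class = "Simple_repeat",
                     stringsAsFactors = FALSE)
      }
      transcripts[[i]] <- transcript(ids[i], seq, exon_lengths, introns, gi)
    }
  })
  names(transcripts) <- ids
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               class = character(0))
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(kind = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0), score = numeric(0))
  truth <- planted_truth(cfg)
  out <- list(transcripts = transcripts, labels = labels, repeats = repeats,
              sites = sites, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# Write every cohort artifact in its interchange format.
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_transcripts(cohort$transcripts, fp("transcripts.fa"), fp("transcripts.bed"))
  rep_bed <- cohort$repeats
  write.table(data.frame(rep_bed$chrom, rep_bed$start - 1L, rep_bed$end,
                         rep_bed$class),
              fp("repeats.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cohort$sites, fp("sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(id = names(cohort$labels), label = cohort$labels),
              fp("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, fp("truth.json"), dataframe = "rows")
  invisible(out_dir)
}

#' Inject planted effects not realized in sequence
#'
#' Adds the configured shift to the class-1 rows of every planted feature
#' whose mechanism is `"injected"` (see [planted_truth()]).  No-op when
#' all planted effects are mechanistic.
#'
#' @param m A labeled [feature_matrix] extracted from a cohort.
#' @param cohort The cohort object from [generate_cohort()].
#' @return The adjusted [feature_matrix].
#' @export
apply_planted_injections <- function(m, cohort) {
  tr <- cohort$truth
  inj <- tr[tr$mechanism == "injected", , drop = FALSE]
  for (k in seq_len(nrow(inj))) {
    f <- inj$feature[k]
    if (!f %in% colnames(m$X)) {
      warning("injected feature not in matrix: ", f)
      next
    }
    delta <- inj$magnitude[k] * ifelse(inj$sign[k] == "+", 1, -1)
    m$X[m$y == 1, f] <- m$X[m$y == 1, f] + delta
  }
  m
}

#' Simulate a feature-space cohort with planted effects
#'
#' Direct feature-value generation (the injection path): every feature is
#' Gaussian noise around 0.5; planted features get a class-conditional
#' mean shift of +/- `delta / 2` whose sign encodes the direction of
#' association with the ribosome-associated class.  Used for
#' feature-selection recovery experiments where exact effect sizes matter.
#'
#' @param n_per_class Samples per class.
#' @param n_features Total features (named `feat01`, `feat02`, ...).
#' @param planted Named signs (`+1`/`-1`) of the planted features; default
#'   plants 4 of the features (2 positive, 2 negative).
#' @param delta Class mean difference on the feature scale.
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed.
#' @return A labeled [feature_matrix] with attribute `"truth"`
#'   (`data.frame`: `feature`, `sign`, `magnitude`).
#' @export
simulate_feature_matrix <- function(n_per_class = 400L, n_features = 24L,
                                    planted = NULL, delta = 0.1,
                                    noise_sd = 0.05, seed = 1L) {
  nm <- sprintf("feat%02d", seq_len(n_features))
  if (is.null(planted)) {
    planted <- setNames(c(1, 1, -1, -1), nm[1:4])
  }
  stopifnot(all(names(planted) %in% nm), all(planted %in% c(-1, 1)))
  n <- 2L * n_per_class
  y <- c(rep(1L, n_per_class), rep(0L, n_per_class))
  X <- with_seed(seed, {
    X <- matrix(rnorm(n * n_features, 0.5, noise_sd), n, n_features,
                dimnames = list(NULL, nm))
    for (f in names(planted)) {
      X[, f] <- X[, f] + ifelse(y == 1, 1, -1) * planted[[f]] * delta / 2
    }
    X
  })
  m <- feature_matrix(X, y = y, ids = sprintf("s%04d", seq_len(n)))
  attr(m, "truth") <- data.frame(feature = names(planted),
                                 sign = ifelse(planted > 0, "+", "-"),
                                 magnitude = delta, stringsAsFactors = FALSE)
  m
}
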