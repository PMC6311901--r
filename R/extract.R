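#' Canonical feature registry
#'
#' The documented feature set extracted by [extract_features()], grouped by
#' mechanism: RNA splicing (lengths/GC of transcript, first exon and first
#' intron), putative ORFs (lengths and transcript coverage of the
#' primary/first/upstream ORF and their UTRs), k-mer scores (Kozak-like
#' context, codon and bi-codon usage per ORF), RNA secondary structure
#' (region mean stem probabilities and UTR/ORF ratios), site distances
#' (m6A and G4 to TIS/TTS/ORF boundaries, direct log10 and relative
#' percent), and repeat-element flags.
#'
#' @param repeat_classes Repeat flag namespace.
#' @return `data.frame` with columns `name`, `group`.
#' @export
feature_registry <- function(repeat_classes = c("LTR", "LINE", "SINE", "Alu",
                                                "SINEB2")) {
  splice <- c("txLen", "txGc", "exonCount", "longestELen", "meanELen",
              "fELen", "fEgc", "fILen", "totalILen", "meanILen")
  orf <- unlist(lapply(c("p", "f", "u"), function(x) {
    paste0(x, c("OrfLen", "Orf5utrLen", "Orf3utrLen", "OrfCov", "Orf5utrCov",
                "Orf3utrCov", "OrfContext", "OrfSeqTrimer", "OrfSeqHexamer"))
  }))
  struct <- c("txStem", "pOrf5utrStem", "pOrfStem", "pOrf3utrStem",
              "stemRatio5utr", "stemRatio3utr")
  anchors <- c("Tis", "Tts", "UOrfStart", "UOrfEnd", "FOrfStart", "FOrfEnd",
               "POrfStart", "POrfEnd")
  sites <- c(paste0("m6a", rep(anchors, each = 2), c("Dist", "Rel")),
             paste0("g4", rep(anchors, each = 2), c("Dist", "Rel")))
  data.frame(name = c(splice, orf, struct, sites, repeat_classes),
             group = c(rep("splice", length(splice)), rep("orf", length(orf)),
                       rep("structure", length(struct)),
                       rep("site", length(sites)),
                       rep("repeat", length(repeat_classes))),
             stringsAsFactors = FALSE)
}

# Feature block for one ORF kind: lengths, coverages, k-mer scores.
orf_feature_row <- function(t, kind_letter, orf, regions, tables) {
  nm <- function(suffix) paste0(kind_letter, suffix)
  len <- nchar(t$seq)
  cols <- setNames(rep(NA_real_, 9),
                   c(nm("OrfLen"), nm("Orf5utrLen"), nm("Orf3utrLen"),
                     nm("OrfCov"), nm("Orf5utrCov"), nm("Orf3utrCov"),
                     nm("OrfContext"), nm("OrfSeqTrimer"), nm("OrfSeqHexamer")))
  if (!is.null(orf)) {
    w5 <- interval_width(regions$five_utr)
    w3 <- interval_width(regions$three_utr)
    wo <- orf$end - orf$start + 1L
    cols[nm("OrfLen")] <- wo
    cols[nm("Orf5utrLen")] <- w5
    cols[nm("Orf3utrLen")] <- w3
    cols[nm("OrfCov")] <- wo / len
    cols[nm("Orf5utrCov")] <- w5 / len
    cols[nm("Orf3utrCov")] <- w3 / len
    if (!is.null(tables)) {
      orf_seq <- substr(t$seq, orf$start, orf$end)
      cols[nm("OrfContext")] <- context_score(t$seq, orf$start, tables)$value
      cols[nm("OrfSeqTrimer")] <- trimer_score(orf_seq, tables)$value
      cols[nm("OrfSeqHexamer")] <- hexamer_score(orf_seq, tables)$value
    }
  }
  as.data.frame(as.list(cols))
}

#' Extract the canonical feature set for a transcript collection
#'
#' Runs every feature module over each transcript: ORF discovery, k-mer
#' scores against the supplied reference tables, stem-probability profile
#' (internal backend, or imported profiles when given), m6A/G4 site
#' detection (or imported site tables, which take precedence), splice
#' features, and repeat flags.  Features whose prerequisites are absent
#' (no ORF, no site, single exon, no genomic intervals) are `NA` and are
#' handled downstream by mean imputation.
#'
#' @param ts Named list of [transcript] objects.
#' @param tables Reference tables from [build_reference_tables()] (`NULL`
#'   drops the k-mer score features).
#' @param repeats Optional repeat annotation (see [repeat_flags()]);
#'   `NULL` drops the repeat flags.
#' @param site_tables Optional imported site annotations (named list by
#'   transcript id, see [read_site_table()]); detected sites are used for
#'   transcripts absent from the list.
#' @param stem_profiles Optional imported stem profiles (named list, see
#'   [read_stem_profiles()]).
#' @param max_span Pairing-span constraint for [stem_profile()].
#' @param stem_pars,g4_pars,min_gscore Backend parameters.
#' @param labels Optional labels passed through to [assemble()].
#' @param verbose Print progress every 200 transcripts.
#' @return A labeled [feature_matrix].
#' @export
extract_features <- function(ts, tables = NULL, repeats = NULL,
                             site_tables = NULL, stem_profiles = NULL,
                             max_span = NULL, stem_pars = stem_params(),
                             g4_pars = g4_params(), min_gscore = 30,
                             labels = NULL, verbose = FALSE) {
  rows <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    t <- ts[[i]]
    orfs <- find_orf_set(t$seq)
    regions <- extract_regions(t, orfs)
    len <- nchar(t$seq)

    splice <- splice_features(t)
    splice$fIgc <- NULL                      # needs genome sequence; not extracted here

    orf_cols <- cbind(orf_feature_row(t, "p", orfs$porf, regions$porf, tables),
                      orf_feature_row(t, "f", orfs$forf, regions$forf, tables),
                      orf_feature_row(t, "u", orfs$uorf, regions$uorf, tables))

    prof <- if (!is.null(stem_profiles) && t$id %in% names(stem_profiles)) {
      stem_profiles[[t$id]]
    } else {
      stem_profile(t$seq, max_span = max_span, params = stem_pars)
    }
    p5 <- if (!is.null(regions$porf)) region_mean_stem(prof, regions$porf$five_utr) else NA_real_
    po <- if (!is.null(regions$porf)) region_mean_stem(prof, regions$porf$orf) else NA_real_
    p3 <- if (!is.null(regions$porf)) region_mean_stem(prof, regions$porf$three_utr) else NA_real_
    struct <- data.frame(txStem = mean(prof$probs), pOrf5utrStem = p5,
                         pOrfStem = po, pOrf3utrStem = p3,
                         stemRatio5utr = stem_ratio(p5, po),
                         stemRatio3utr = stem_ratio(p3, po))

    sites <- if (!is.null(site_tables) && t$id %in% names(site_tables)) {
      site_tables[[t$id]]
    } else {
      rbind(predict_m6a(t$seq),
            detect_g4(t$seq, min_gscore = min_gscore, params = g4_pars))
    }
    dist_df <- site_distance_features(t, orfs, sites)
    site_cols <- site_features_wide(dist_df)

    rep_cols <- if (!is.null(repeats)) repeat_flags(t, repeats) else NULL

    row <- cbind(data.frame(id = t$id, stringsAsFactors = FALSE),
                 splice, orf_cols, struct, site_cols)
    if (!is.null(rep_cols)) row <- cbind(row, rep_cols)
    rows[[i]] <- row
    if (verbose && i %% 200 == 0) message("  features: ", i, "/", length(ts))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(tables)) { # k-mer score columns are all-NA placeholders: drop
    df <- df[, !grepl("OrfContext$|OrfSeqTrimer$|OrfSeqHexamer$", colnames(df)),
             drop = FALSE]
  }
  suppressWarnings(assemble(list(df), labels = labels))
}

# Long site-distance table -> one wide row with canonical names.
site_features_wide <- function(dist_df) {
  pre <- ifelse(dist_df$kind == "m6A", "m6a", "g4")
  an <- sub("^(.)", "\\U\\1", dist_df$anchor, perl = TRUE)
  an <- sub("^TIS$", "Tis", an); an <- sub("^TTS$", "Tts", an)
  vals <- c(rbind(dist_df$direct, dist_df$relative))
  names(vals) <- c(rbind(paste0(pre, an, "Dist"), paste0(pre, an, "Rel")))
  as.data.frame(as.list(vals))
}
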