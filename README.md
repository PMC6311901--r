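# ribolnc

Which sequence features distinguish ribosome-associated (ribo) from
ribosome-free (noribo) long noncoding RNAs?  `ribolnc` is an R package
for researchers who have lncRNA transcripts with binary ribosome-
association labels (e.g. from ribosome profiling) and want a reusable,
tested pipeline that

1. extracts a documented set of ~80 sequence-derived features per
   transcript — splicing structure (lengths/GC of the transcript, first
   exon, first intron), putative ORFs (primary = longest ATG ORF,
   first = 5'-most ATG ORF, upstream = near-cognate CTG/GTG/TTG ORF 5'
   of the primary), Kozak-like context and codon/bi-codon usage scores,
   per-region RNA stem probabilities, m6A (DRACH) and G-quadruplex
   (QGRS-style) site distances to TIS/TTS/ORF boundaries, and
   repeat-element overlap flags;
2. removes near-duplicate sequences (>60% coverage of the shorter
   sequence), mean-imputes and min-max scales the feature matrix, prunes
   redundant features (|Pearson r| > 0.8), and ranks features by
   two-sample Kolmogorov–Smirnov importance (−log10 p); and
3. selects a sparse joint feature set with L1-regularized logistic
   regression, minimizing

   ‖w‖₁ + C Σᵢ log(1 + exp(−yᵢ(Xᵢᵀw + c))),  yᵢ ∈ {−1, +1},

   over a sweep of the inverse regularization strength C on a stratified
   80:20 split, choosing the smallest C within ε of the maximal held-out
   accuracy.  Nonzero coefficients, signed by direction of association
   with the ribo class and ranked by |w|, are the selected features.

A synthetic-cohort generator with planted, known-sign class effects makes
every stage testable end to end without external data or binaries.

## Worked example

```r
library(ribolnc)

# a labeled synthetic cohort of 500 transcripts, plus CDS reference
# tables for the k-mer scores
cohort <- generate_cohort(cohort_config(n_ribo = 250, n_noribo = 250, seed = 1))
tables <- build_reference_tables(generate_cds_reference(500, seed = 2), seed = 3)

res <- run_pipeline(cohort, tables = tables, max_span = 100, split_seed = 4)

res$pruned
#> <feature_matrix> 500 transcripts x 59 features (250 ribo / 250 noribo); 0 missing

head(res$ks, 5)
#>        feature     D             p importance
#> 1         fEgc 0.852 1.000000e-300 300.000000
#> 2         txGc 0.436 1.000000e-300 300.000000
#> 3       txStem 0.236  1.794377e-06   5.746086
#> 4 pOrf5utrStem 0.236  1.794377e-06   5.746086
#> 5      uOrfCov 0.176  8.666695e-04   3.062146

res$selection$chosen_C
#> [1] 0.51
res$selection$accuracy
#> [1] 0.95
res$report
#>   rank          feature       coef sign
#> 1    1             fEgc 17.4390675    +
#> 2    2             SINE -0.2256257    -
#> 3    3              LTR  0.1785399    +
#> 4    4 m6aFOrfStartDist  0.1315952    +
```

Reading: 21 of the 80 extracted features were pruned as redundant
(|r| > 0.8).  The KS ranking puts first-exon GC (`fEgc`) far ahead of
everything else — this cohort plants a +0.1 GC shift in the ribo class,
and `txGc` tags along because whole-transcript GC partially contains the
first exon.  The C sweep selects C = 0.51 with 95% held-out accuracy; the
model keeps `fEgc` (positive: higher first-exon GC associates with
ribosome binding) and the planted positive `LTR` repeat flag, with small
additional terms.  On real data the same calls apply unchanged:
`read_transcripts()` (FASTA + GTF/BED12), `read_repeatmasker()` /
`read_repeat_bed()`, `read_site_table()` for external m6A/G4 predictions,
and a labels table.

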