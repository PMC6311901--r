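test_that("generated CDS are structurally valid and seeded", {
  cds <- generate_cds_reference(200, seed = 21, length_range = c(90, 300))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substring(cds, nchar(cds) - 2) %in% c("TAA", "TGA", "TAG")))
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(nchar(cds) >= 90 & nchar(cds) <= 300))
  expect_identical(cds, generate_cds_reference(200, seed = 21,
                                               length_range = c(90, 300)))
  expect_false(identical(cds[1], generate_cds_reference(1, seed = 22,
                                                        length_range = c(90, 300))))
})

test_that("empirical codon frequencies track the requested usage", {
  usage <- default_codon_usage()
  cds <- generate_cds_reference(5000, seed = 23, length_range = c(150, 300))
  internal <- unlist(lapply(cds, function(s) {
    n <- nchar(s)
    starts <- seq(4, n - 5, by = 3)          # skip ATG and the stop
    substring(s, starts, starts + 2)
  }))
  emp <- table(factor(internal, levels = names(usage))) / length(internal)
  expect_lt(max(abs(as.numeric(emp) - unname(usage))), 0.01)
})

test_that("cohort labels and ids are as configured", {
  cfg <- cohort_config(n_ribo = 30, n_noribo = 20, seed = 31,
                       planted_effects = c(fEgc = 0.1))
  cohort <- generate_cohort(cfg)
  expect_length(cohort$transcripts, 50)
  expect_equal(sum(cohort$labels == 1), 30)
  expect_equal(sum(cohort$labels == 0), 20)
  expect_identical(names(cohort$transcripts), names(cohort$labels))
  # reproducibility from the single seed
  cohort2 <- generate_cohort(cfg)
  expect_identical(vapply(cohort$transcripts, `[[`, "", "seq"),
                   vapply(cohort2$transcripts, `[[`, "", "seq"))
  expect_identical(cohort$repeats, cohort2$repeats)
})

test_that("planted first-exon GC shift is realized at the stated size", {
  cfg <- cohort_config(n_ribo = 500, n_noribo = 500, seed = 32,
                       planted_effects = c(fEgc = 0.1))
  cohort <- generate_cohort(cfg)
  fegc <- vapply(cohort$transcripts, function(t) {
    gc_content(substr(t$seq, 1, t$exon_lengths[1]))
  }, 0)
  diff <- mean(fegc[cohort$labels == 1]) - mean(fegc[cohort$labels == 0])
  expect_equal(diff, 0.1, tolerance = 0.02)
})

test_that("planted truth lists exactly the requested effects", {
  cfg <- cohort_config(planted_effects = c(fEgc = 0.1, fELen = -0.1),
                       seed = 33)
  tr <- planted_truth(cfg)
  expect_setequal(tr$feature, c("fEgc", "fELen"))
  expect_equal(tr$sign[tr$feature == "fEgc"], "+")
  expect_equal(tr$sign[tr$feature == "fELen"], "-")
  expect_true(all(tr$mechanism == "mechanistic"))
  # truth is seed-invariant
  cfg2 <- cohort_config(planted_effects = c(fEgc = 0.1, fELen = -0.1),
                        seed = 99)
  expect_identical(tr, planted_truth(cfg2))
  # empty plan, empty truth
  expect_equal(nrow(planted_truth(cohort_config(planted_effects = numeric(0)))),
               0L)
  # unknown features go through the injection path
  cfg3 <- cohort_config(planted_effects = c(stemRatio5utr = 0.2))
  expect_equal(planted_truth(cfg3)$mechanism, "injected")
})

test_that("infeasible planted effects are rejected", {
  expect_error(cohort_config(planted_effects = c(fEgc = 1.5)), "infeasible")
  expect_error(cohort_config(base_gc = 0.95,
                             planted_effects = c(fEgc = 0.1)), "GC outside")
  expect_error(cohort_config(planted_effects = c(LTR = 0.9)), "probability")
})

test_that("emitted cohort files round-trip through the reader modules", {
  cfg <- cohort_config(n_ribo = 15, n_noribo = 15, seed = 34,
                       length_range = c(200L, 1500L))
  dir <- tempfile()
  cohort <- generate_cohort(cfg, out_dir = dir)
  ts <- read_transcripts(file.path(dir, "transcripts.fa"),
                         file.path(dir, "transcripts.bed"))
  expect_length(ts, 30)
  expect_identical(vapply(ts, `[[`, "", "seq"),
                   vapply(cohort$transcripts, `[[`, "", "seq"))
  expect_identical(lapply(ts, `[[`, "exon_lengths"),
                   lapply(cohort$transcripts, `[[`, "exon_lengths"))
  reps <- read_repeat_bed(file.path(dir, "repeats.bed"))
  expect_identical(reps$start, cohort$repeats$start)
  labs <- read.delim(file.path(dir, "labels.tsv"))
  expect_equal(sum(labs$label), 15)
  if (nrow(cohort$sites)) {
    sites <- read_site_table(file.path(dir, "sites.tsv"))
    expect_true(all(names(sites) %in% labs$id))
  }
})

test_that("null cohorts produce uniform-ish KS p-values", {
  m <- simulate_feature_matrix(n_per_class = 200, n_features = 24,
                               planted = c(feat01 = 1), delta = 0,  # no effect
                               noise_sd = 0.05, seed = 35)
  r <- ks_rank(m)
  expect_gte(mean(r$p > 0.01), 0.95)
})

test_that("injection path shifts only the class-1 rows of injected features", {
  cfg <- cohort_config(n_ribo = 10, n_noribo = 10, seed = 36,
                       planted_effects = c(txStem = 0.2))
  X <- matrix(0.5, 20, 2, dimnames = list(NULL, c("txStem", "other")))
  m <- feature_matrix(X, y = c(rep(1, 10), rep(0, 10)),
                      ids = sprintf("tx%04d", 1:20))
  cohort <- list(truth = planted_truth(cfg))
  m2 <- apply_planted_injections(m, cohort)
  expect_equal(unname(m2$X[m$y == 1, "txStem"]), rep(0.7, 10))
  expect_equal(unname(m2$X[m$y == 0, "txStem"]), rep(0.5, 10))
  expect_equal(m2$X[, "other"], m$X[, "other"])
})
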