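test_that("reference tables are seeded-deterministic and strictly positive", {
  cds <- generate_cds_reference(20, seed = 4)
  t1 <- build_reference_tables(cds, seed = 11)
  t2 <- build_reference_tables(cds, seed = 11)
  expect_identical(t1, t2)
  t3 <- build_reference_tables(cds, seed = 12)
  expect_false(identical(t1$trimer$F_prime, t3$trimer$F_prime))
  expect_gt(min(t1$trimer$F_prime), 0)
  expect_gt(min(t1$hexamer$F_prime), 0)
  expect_gt(min(t1$context$F_prime), 0)
  # normalization: context rows and unit tables each sum to 1
  expect_equal(unname(rowSums(t1$context$F)), rep(1, 10), tolerance = 1e-9)
  expect_equal(sum(t1$trimer$F), 1, tolerance = 1e-9)
  expect_equal(sum(t1$hexamer$F_prime), 1, tolerance = 1e-9)
  expect_error(build_reference_tables(character(0)), "empty")
  expect_error(build_reference_tables("ATGAA"), "divisible|length")
})

test_that("in-frame trimer frequencies match hand counts", {
  tabs <- build_reference_tables(rep("ATGAAATAG", 7), seed = 1, pseudocount = 0)
  expect_equal(unname(tabs$trimer$F[c("ATG", "AAA", "TAG")]), rep(1 / 3, 3))
  expect_equal(sum(tabs$trimer$F > 0), 3L)
})

test_that("scores are zero when F equals F' (identity case)", {
  tabs <- build_reference_tables(generate_cds_reference(30, seed = 2), seed = 3)
  same <- lapply(tabs, function(tb) { tb$F_prime <- tb$F; tb })
  set.seed(21)
  for (i in 1:100) {
    orf_len <- 3 * sample(3:40, 1)
    orf <- paste0("ATG", random_dna(orf_len - 6), "TAA")
    expect_equal(trimer_score(orf, same)$value, 0)
    expect_equal(hexamer_score(orf, same)$value, 0)
    s <- paste0(random_dna(10), orf, random_dna(5))
    expect_equal(context_score(s, 11, same)$value, 0)
  }
})

test_that("uniform log-ratio e scores exactly 1 (worked 3-codon example)", {
  tabs <- build_reference_tables(rep("ATGAAATAG", 3), seed = 1)
  toy <- tabs$trimer
  toy$F[] <- 1 / 64; toy$F_prime[] <- 1 / 64
  toy$F[c("ATG", "AAA", "TAG")] <- exp(1) / 64
  sc <- trimer_score("ATGAAATAG", toy)
  expect_equal(sc$value, 1.0)
  expect_equal(sc$n_units, 3L)
  ctx <- tabs$context
  ctx$F_prime <- ctx$F / exp(1)              # ratio e at every position
  expect_equal(context_score(paste0("AAAAAA", "ATGAAATAG"), 7, ctx)$value, 1.0)
})

test_that("a two-position toy window with ratios e^2 and e^-2 scores 0", {
  tabs <- build_reference_tables(rep("ATGAAATAG", 3), seed = 1,
                                 context_offsets = c(-1L, 0L))
  ctx <- tabs$context
  ctx$F[] <- 0.25; ctx$F_prime[] <- 0.25
  ctx$F["-1", "A"] <- 0.25 * exp(2); ctx$F["0", "A"] <- 0.25 * exp(-2)
  expect_equal(context_score("AATG", 2, ctx)$value, 0)
})

test_that("window truncation and unit minimums give missing scores", {
  tabs <- build_reference_tables(generate_cds_reference(10, seed = 5), seed = 6)
  expect_true(is.na(context_score("ATGAAATAG", 1, tabs)$value))  # no -6 context
  expect_true(is.na(context_score(paste0("AAAAAA", "ATG"), 7, tabs)$value)) # no +3
  expect_true(is.na(trimer_score("AT", tabs)$value))
  expect_true(is.na(hexamer_score("TAG", tabs)$value))
  expect_equal(hexamer_score("ATGAAATAG", tabs)$n_units, 2L)  # ATGAAA, AAATAG
  # units containing N are skipped, reducing n
  expect_equal(trimer_score("ATGNNNTAG", tabs)$n_units, 2L)
})

test_that("swapping F and F' negates every score", {
  set.seed(31)
  tabs <- build_reference_tables(generate_cds_reference(25, seed = 7), seed = 8)
  swap <- lapply(tabs, function(tb) {
    tmp <- tb$F; tb$F <- tb$F_prime; tb$F_prime <- tmp; tb
  })
  for (i in 1:50) {
    orf <- paste0("ATG", random_dna(3 * sample(2:30, 1)), "TGA")
    s <- paste0(random_dna(8), orf)
    expect_equal(trimer_score(orf, swap)$value, -trimer_score(orf, tabs)$value,
                 tolerance = 1e-12)
    expect_equal(hexamer_score(orf, swap)$value, -hexamer_score(orf, tabs)$value,
                 tolerance = 1e-12)
    expect_equal(context_score(s, 9, swap)$value, -context_score(s, 9, tabs)$value,
                 tolerance = 1e-12)
  }
})

test_that("CDS-like ORFs outscore their shuffles on average", {
  cds <- generate_cds_reference(400, seed = 41)
  tabs <- build_reference_tables(cds, seed = 42)
  probe <- generate_cds_reference(500, seed = 43, length_range = c(90, 240))
  set.seed(44)
  sc_active <- vapply(probe, function(s) trimer_score(s, tabs)$value, 0)
  sc_shuffled <- vapply(probe, function(s) {
    trimer_score(paste(sample(strsplit(s, "")[[1]]), collapse = ""), tabs)$value
  }, 0)
  expect_gt(mean(sc_active), 0)
  expect_lt(mean(sc_shuffled), 0)
  # pairwise: actives beat their own shuffles in expectation
  expect_gt(mean(sc_active - sc_shuffled), 0)
})

test_that("frequency tables round-trip through TSV", {
  tabs <- build_reference_tables(generate_cds_reference(10, seed = 9), seed = 10)
  for (kind in names(tabs)) {
    p <- tempfile(fileext = ".tsv")
    write_frequency_table(tabs[[kind]], p)
    back <- read_frequency_table(p)
    expect_equal(back$unit_kind, tabs[[kind]]$unit_kind)
    expect_equal(back$F, tabs[[kind]]$F, tolerance = 1e-12)
    expect_equal(back$F_prime, tabs[[kind]]$F_prime, tolerance = 1e-12)
  }
})
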