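test_that("assemble column-joins tables and validates ids/names", {
  t1 <- data.frame(id = c("a", "b", "c"), f1 = 1:3, f2 = 4:6)
  t2 <- data.frame(id = c("c", "a", "b"), f3 = 7:9, f4 = 0.1, f5 = NA_real_)
  m <- assemble(list(t1, t2)) |> suppressWarnings()
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(m$X["a", "f3"], 8)            # id-aligned join
  expect_warning(assemble(list(t1, t2)), "no transcript")
  t_dup <- data.frame(id = c("a", "b", "c"), f1 = 1:3)
  expect_error(assemble(list(t1, t_dup)), "duplicate")
  t_bad <- data.frame(id = c("a", "b", "x"), f9 = 1:3)
  expect_error(assemble(list(t1, t_bad)), "inconsistent")
})

test_that("labels attach by id and must be complete 0/1", {
  t1 <- data.frame(id = c("a", "b"), f1 = c(1, 2))
  m <- assemble(list(t1), labels = c(b = 1, a = 0))
  expect_equal(m$y, c(0L, 1L))
  expect_error(assemble(list(t1), labels = c(a = 0)), "missing")
})

test_that("mean imputation fills exactly the missing cells", {
  m <- feature_matrix(cbind(a = c(1, NA, 3), b = c(5, NA, NA), c = 1:3))
  mi <- impute_mean(m)
  expect_equal(unname(mi$X[, "a"]), c(1, 2, 3))
  expect_equal(unname(mi$X[, "b"]), c(5, 5, 5))
  expect_false(any(is.na(mi$X)))
  expect_equal(sum(mi$mask), 3L)             # mask remembers original holes
  m2 <- feature_matrix(cbind(a = c(1, 2), b = c(NA_real_, NA_real_)))
  expect_error(impute_mean(m2), "all-missing")
  m3 <- feature_matrix(cbind(a = c(1, 2)))
  expect_identical(impute_mean(m3)$X, m3$X)  # no missing: identity
})

test_that("min-max scaling maps each column to [0, 1]", {
  m <- feature_matrix(cbind(a = c(2, 4, 6), b = c(7, 7, 7), c = c(0, 0.25, 1)))
  ms <- minmax_scale(m)
  expect_equal(unname(ms$X[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(ms$X[, "b"]), c(0, 0, 0))   # constant -> 0
  expect_equal(unname(ms$X[, "c"]), c(0, 0.25, 1)) # already spanning: unchanged
})

test_that("redundancy pruning removes duplicates and negated duplicates", {
  set.seed(81)
  x <- rnorm(50)
  m <- feature_matrix(cbind(x1 = x, x2 = x, y1 = rnorm(50)))
  pr <- prune_redundant(m)
  expect_equal(ncol(pr$matrix$X), 2L)
  expect_true("y1" %in% colnames(pr$matrix$X))
  expect_equal(pr$log$removed, "x2")         # later of the tied pair
  m2 <- feature_matrix(cbind(x1 = x, x1neg = -x, y1 = rnorm(50)))
  pr2 <- prune_redundant(m2)
  expect_equal(ncol(pr2$matrix$X), 2L)       # |r| = 1 counts despite sign
})

test_that("triangle of mutually correlated features loses two members", {
  set.seed(82)
  base <- rnorm(100)
  m <- feature_matrix(cbind(a = base + rnorm(100, 0, 0.1),
                            b = base + rnorm(100, 0, 0.1),
                            c = base + rnorm(100, 0, 0.1),
                            d = rnorm(100)))
  stopifnot(min(abs(cor(m$X[, 1:3]))) > 0.8)
  pr <- prune_redundant(m)
  expect_equal(ncol(pr$matrix$X), 2L)
  expect_true("d" %in% colnames(pr$matrix$X))
  expect_equal(nrow(pr$log), 2L)
})

test_that("no surviving pair exceeds the threshold on random matrices", {
  set.seed(83)
  for (i in 1:10) {
    n <- 60
    k <- sample(5:12, 1)
    X <- matrix(rnorm(n * k), n, k)
    # implant correlated clusters
    X[, 2] <- X[, 1] + rnorm(n, 0, 0.05)
    if (k > 4) X[, 4] <- -X[, 3] + rnorm(n, 0, 0.1)
    colnames(X) <- paste0("f", seq_len(k))
    pr <- prune_redundant(feature_matrix(X), threshold = 0.8)
    r <- cor(pr$matrix$X); diag(r) <- 0
    expect_lte(max(abs(r)), 0.8)
  }
})

test_that("scaling commutes with pruning (Pearson r is affine-invariant)", {
  set.seed(84)
  X <- matrix(rnorm(300), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 2] <- 3 * X[, 1] + rnorm(50, 0, 0.1) + 10
  m <- feature_matrix(X)
  a <- prune_redundant(minmax_scale(m))$matrix
  b <- minmax_scale(prune_redundant(m)$matrix)
  expect_identical(colnames(a$X), colnames(b$X))
})

test_that("KS statistic and exact permutation p match full enumeration", {
  # identical multisets: D = 0, p = 1
  m <- feature_matrix(cbind(f = c(0.3, 0.7, 0.3, 0.7)), y = c(0, 0, 1, 1))
  r <- ks_rank(m)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  # fully separated pairs: D = 1, exact p = 2/6
  m2 <- feature_matrix(cbind(f = c(0.1, 0.2, 0.8, 0.9)), y = c(0, 0, 1, 1))
  r2 <- ks_rank(m2)
  expect_equal(r2$D, 1)
  expect_equal(r2$p, 2 / 6)
  expect_equal(r2$importance, -log10(2 / 6))
  expect_error(ks_rank(feature_matrix(cbind(f = c(1, 2)), y = c(1, 1))),
               "class|labels|samples")
})

test_that("KS ranking is invariant to strictly monotone transforms", {
  set.seed(85)
  x <- c(rnorm(40, 0), rnorm(40, 0.8))
  y <- c(rep(0, 40), rep(1, 40))
  m1 <- feature_matrix(cbind(f = x), y = y)
  m2 <- feature_matrix(cbind(f = exp(x)), y = y)     # monotone transform
  r1 <- ks_rank(m1); r2 <- ks_rank(m2)
  expect_equal(r1$D, r2$D)
  expect_equal(r1$p, r2$p)
})

test_that("a planted-effect feature outranks pure noise almost always", {
  wins <- 0L
  for (rep in 1:20) {
    m <- simulate_feature_matrix(n_per_class = 100, n_features = 10,
                                 planted = c(feat01 = 1), delta = 0.1,
                                 noise_sd = 0.05, seed = 1000 + rep)
    r <- ks_rank(m)
    if (r$feature[1] == "feat01") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("feature matrices round-trip through TSV", {
  m <- feature_matrix(cbind(a = c(1.5, 2.5), b = c(NA, 4)), y = c(0, 1),
                      ids = c("t1", "t2"))
  p <- tempfile(fileext = ".tsv")
  write_feature_matrix(m, p)
  back <- read_feature_matrix(p)
  expect_equal(back$X, m$X)
  expect_equal(back$y, m$y)
  expect_equal(back$ids, m$ids)
})

test_that("the canonical registry names match extracted features", {
  set.seed(86)
  cds <- generate_cds_reference(15, seed = 1)
  tabs <- build_reference_tables(cds, seed = 2)
  ts <- list(t1 = transcript("t1", paste0(random_dna(40), cds[1], random_dna(40))),
             t2 = transcript("t2", random_dna(150)))
  reps <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), class = character(0))
  m <- extract_features(ts, tables = tabs, repeats = reps)
  reg <- feature_registry()
  expect_setequal(colnames(m$X), reg$name)
})
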