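# Independent brute-force oracles used to validate the package's
# implementations on small inputs.  These deliberately use naive
# algorithms (position-by-position scans, exhaustive enumeration) rather
# than the package's code paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- ORFs: scan every position, walk codon by codon to the first stop ----
oracle_enumerate_orfs <- function(seq, starts) {
  n <- nchar(seq)
  out <- NULL
  for (p in seq_len(max(0, n - 5))) {
    if (!substr(seq, p, p + 2) %in% starts) next
    q <- p + 3
    while (q + 2 <= n) {
      if (substr(seq, q, q + 2) %in% c("TAG", "TGA", "TAA")) {
        out <- rbind(out, data.frame(start = p, end = q + 2,
                                     start_codon = substr(seq, p, p + 2)))
        break
      }
      q <- q + 3
    }
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               start_codon = character(0))
  else out
}

oracle_primary <- function(seq) {
  o <- oracle_enumerate_orfs(seq, "ATG")
  if (nrow(o) == 0) return(NULL)
  len <- o$end - o$start + 1
  o <- o[order(-len, o$start), ]
  as.list(o[1, ])
}

oracle_first <- function(seq) {
  o <- oracle_enumerate_orfs(seq, "ATG")
  if (nrow(o) == 0) return(NULL)
  as.list(o[which.min(o$start), ])
}

oracle_upstream <- function(seq, porf) {
  o <- oracle_enumerate_orfs(seq, c("CTG", "GTG", "TTG"))
  o <- o[o$end < porf$start, ]
  if (nrow(o) == 0) return(NULL)
  len <- o$end - o$start + 1
  o <- o[order(-len, o$start), ]
  as.list(o[1, ])
}

# --- stem probabilities: exhaustive enumeration of nested structures ----
oracle_stem <- function(seq, span, wGC = exp(3), wAU = exp(2), wGU = exp(1),
                        minloop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  pw <- function(a, b) {
    p <- paste0(ch[a], ch[b])
    if (p %in% c("GC", "CG")) wGC
    else if (p %in% c("AT", "TA")) wAU
    else if (p %in% c("GT", "TG")) wGU
    else 0
  }
  structs <- function(lo, hi) {
    if (lo > hi) return(list(list(pairs = matrix(nrow = 0, ncol = 2), w = 1)))
    out <- list()
    for (s in structs(lo + 1, hi)) out[[length(out) + 1]] <- s
    for (k in (lo + minloop + 1):hi) {
      if (k > hi || k - lo <= minloop || k - lo > span) next
      w <- pw(lo, k)
      if (w == 0) next
      for (inner in structs(lo + 1, k - 1)) {
        for (outer in structs(k + 1, hi)) {
          out[[length(out) + 1]] <- list(
            pairs = rbind(c(lo, k), inner$pairs, outer$pairs),
            w = w * inner$w * outer$w)
        }
      }
    }
    out
  }
  if (n < minloop + 2) return(rep(0, n))
  ss <- structs(1, n)
  Z <- sum(vapply(ss, `[[`, 0, "w"))
  probs <- rep(0, n)
  for (s in ss) {
    if (nrow(s$pairs)) {
      for (r in seq_len(nrow(s$pairs))) {
        probs[s$pairs[r, ]] <- probs[s$pairs[r, ]] + s$w
      }
    }
  }
  probs / Z
}

# --- G4: brute force over all G-run quadruplet placements ----------------
oracle_g4 <- function(seq, min_gscore = 30, params = g4_params()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  run_ok <- function(p, g) p >= 1 && p + g - 1 <= n && all(ch[p:(p + g - 1)] == "G")
  cand <- NULL
  for (g in params$min_run:floor(params$max_total / 4)) {
    for (a in 1:n) {
      if (!run_ok(a, g)) next
      for (b in (a + g):(n)) {
        l1 <- b - (a + g)
        if (l1 < params$loop_range[1]) next
        if (l1 > params$loop_range[2]) break
        if (!run_ok(b, g)) next
        for (cc in (b + g):n) {
          l2 <- cc - (b + g)
          if (l2 < params$loop_range[1]) next
          if (l2 > params$loop_range[2]) break
          if (!run_ok(cc, g)) next
          for (dd in (cc + g):n) {
            l3 <- dd - (cc + g)
            if (l3 < params$loop_range[1]) next
            if (l3 > params$loop_range[2]) break
            if (!run_ok(dd, g)) next
            end <- dd + g - 1
            if (end - a + 1 > params$max_total) break
            d <- abs(c(l1 - l2, l1 - l3, l2 - l3))
            score <- params$run_weight * (g - 1) - params$even_weight * mean(d)
            cand <- rbind(cand, data.frame(start = a, end = end, score = score))
          }
        }
      }
    }
  }
  if (is.null(cand)) cand <- data.frame(start = integer(0), end = integer(0),
                                        score = numeric(0))
  cand <- cand[cand$score >= min_gscore, , drop = FALSE]
  # same published selection rule: greedy by score desc, start asc, shorter
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ov <- any(cand$start[i] <= cand$end[keep] & cand$end[i] >= cand$start[keep])
    if (!length(keep) || !ov) keep <- c(keep, i)
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# --- KS: D and permutation p by full enumeration -------------------------
oracle_ks_D <- function(x0, x1) {
  pts <- sort(unique(c(x0, x1)))
  max(abs(vapply(pts, function(v) mean(x0 <= v) - mean(x1 <= v), 0)))
}

oracle_ks_perm_p <- function(x0, x1) {
  pool <- c(x0, x1)
  d_obs <- oracle_ks_D(x0, x1)
  idx <- combn(length(pool), length(x0))
  mean(vapply(seq_len(ncol(idx)), function(k) {
    oracle_ks_D(pool[idx[, k]], pool[-idx[, k]]) >= d_obs - 1e-12
  }, TRUE))
}

# Small labeled matrix for L1 tests: one strong feature + noise.
toy_labeled_matrix <- function(n_per_class = 60, seed = 99, n_noise = 3) {
  set.seed(seed)
  y <- c(rep(1, n_per_class), rep(0, n_per_class))
  X <- cbind(sig = ifelse(y == 1, 0.8, 0.2) + rnorm(2 * n_per_class, 0, 0.05),
             matrix(runif(2 * n_per_class * n_noise), ncol = n_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  feature_matrix(X, y = y, ids = sprintf("t%03d", seq_len(2 * n_per_class)))
}
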