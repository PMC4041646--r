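# Independent brute-force oracles used to pin expected values.
# Everything here is deliberately naive and shares no code with the package.

# -- Smith-Waterman local alignment score (affine gaps: a run of L gaps
#    costs open + L * extend), Gotoh recursion over full matrices.
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  M <- matrix(0, n + 1, m + 1)     # best ending in a substitution
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# -- fitting alignment (shorter global, longer local, linear gap cost):
#    maximum score over all placements of `shorter` inside `longer`
oracle_fitting_score <- function(shorter, longer, match = 1, mismatch = -1,
                                 gap = 2) {
  sv <- strsplit(shorter, "")[[1]]
  lv <- strsplit(longer, "")[[1]]
  n <- length(sv)
  m <- length(lv)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -gap * (0:n)
  D[1, ] <- 0                        # free prefix of the longer
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (sv[i - 1] == lv[j - 1]) match else mismatch
      D[i, j] <- max(D[i - 1, j - 1] + s, D[i - 1, j] - gap,
                     D[i, j - 1] - gap)
    }
  }
  max(D[n + 1, ])                    # free suffix of the longer
}

# -- Cramer-von Mises two-sample statistic by direct ECDF double loop
oracle_cvm_stat <- function(x, y) {
  pooled <- c(x, y)
  fx <- vapply(pooled, function(z) mean(x <= z), 0)
  fy <- vapply(pooled, function(z) mean(y <= z), 0)
  length(x) * length(y) / (length(x) + length(y))^2 * sum((fx - fy)^2)
}

# -- exact permutation p-value by enumerating all relabellings
oracle_cvm_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  t_obs <- oracle_cvm_stat(x, y)
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(idx) {
    oracle_cvm_stat(pooled[idx], pooled[-idx])
  })
  mean(stats >= t_obs - 1e-12)
}

# -- Kruskal-Wallis H with tie correction, from mean ranks by hand
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  N <- length(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  R <- tapply(r, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(R^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# -- per-base coverage by looping positions
oracle_coverage <- function(starts, ends, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    for (p in (starts[i] + 1):ends[i]) depth[p] <- depth[p] + 1L
  }
  depth
}

# -- k-mer counts by dictionary scan (skipping non-ACGT windows)
oracle_kmer_counts <- function(seqs, k) {
  out <- new.env()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      out[[w]] <- (out[[w]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- entropy from a naive substring table
oracle_entropy <- function(s, k) {
  n <- nchar(s)
  tab <- table(substring(s, 1:(n - k + 1), k:n))
  p <- tab / sum(tab)
  -sum(p * log2(p))
}

# -- quality-clean prefix by exhaustive window scan: cut at the start of
#    the first window whose mean falls below the threshold
oracle_quality_keep <- function(phred, window, threshold) {
  n <- length(phred)
  if (n < window) return(n)
  for (s in 1:(n - window + 1)) {
    if (mean(phred[s:(s + window - 1)]) < threshold) return(s - 1L)
  }
  n
}

gini_coefficient <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
}

# small shared fixtures -------------------------------------------------

toy_reads <- function(bases, q = 35) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(bases)),
                 bases = bases,
                 quals = vapply(nchar(bases),
                                function(l) phred_to_qual(rep(q, l)), ""),
                 mid = NA_character_)
}
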