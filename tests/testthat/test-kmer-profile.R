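test_that("k-mer counting matches a naive dictionary scan", {
  p <- count_kmers("ACGTAC", k = 6)
  expect_identical(p$total, 1L)
  expect_identical(unname(p$counts[["ACGTAC"]]), 1L)

  set.seed(1)
  seqs <- random_dna(100, 40)
  prof <- count_kmers(seqs, k = 3)
  expect_identical(prof$total, sum(pmax(0L, nchar(seqs) - 3L + 1L)))
  oracle <- oracle_kmer_counts(seqs, 3)
  for (w in ls(oracle)) {
    expect_identical(unname(prof$counts[[w]]), oracle[[w]])
  }
  expect_identical(sum(prof$counts > 0), length(ls(oracle)))

  ## windows containing non-ACGT symbols are skipped
  with_n <- count_kmers("ACGNACGT", k = 3)
  expect_identical(with_n$total, 3L)   # ACG (pos 1), ACG (pos 5), CGT (pos 6)
  expect_identical(unname(with_n$counts[["ACG"]]), 2L)

  ## additivity
  a <- count_kmers(seqs[1:50], k = 3, label = "a")
  b <- count_kmers(seqs[51:100], k = 3, label = "b")
  expect_identical((a + b)$counts, prof$counts)

  ## canonical counting pools reverse complements
  can <- count_kmers("AAAAAA", k = 3, canonical = TRUE)
  expect_identical(unname(can$counts[["TTT"]]),
                   unname(can$counts[["AAA"]]))
  expect_error(count_kmers("ACGT", k = 1), "k")
})

test_that("gamma moments fit recovers known shape and is scale invariant", {
  for (s in 1:50) {
    set.seed(s)
    ab <- rgamma(4096, shape = 2, scale = 0.001)
    counts <- round(ab / sum(ab) * 2e6)
    prof <- structure(list(label = "syn", k = 6L, counts = counts,
                           total = sum(counts)), class = "kmer_profile")
    fit <- fit_gamma(prof)
    expect_lt(abs(fit$shape - 2) / 2, 0.15)
  }

  uniform <- structure(list(label = "u", k = 6L,
                            counts = rep(5L, 4096), total = 5L * 4096L),
                       class = "kmer_profile")
  expect_error(fit_gamma(uniform), "variance")

  set.seed(60)
  ab <- rgamma(4096, 2, scale = 0.001)
  c1 <- round(ab / sum(ab) * 1e6)
  p1 <- structure(list(label = "x", k = 6L, counts = c1, total = sum(c1)),
                  class = "kmer_profile")
  p10 <- structure(list(label = "x", k = 6L, counts = c1 * 10L,
                        total = sum(c1) * 10L), class = "kmer_profile")
  expect_equal(fit_gamma(p1)$shape, fit_gamma(p10)$shape,
               tolerance = 1e-12)
  expect_equal(fit_gamma(p1)$scale, fit_gamma(p10)$scale,
               tolerance = 1e-12)
})

test_that("profile distance is a correlation dissimilarity", {
  g <- generate_genome(20000, 0.5, seed = 2)
  p <- count_kmers(g$sequence, k = 6, label = "g")
  expect_equal(profile_distance(p, p), 0, tolerance = 1e-12)

  scaled <- structure(list(label = "s", k = 6L, counts = p$counts * 7L,
                           total = p$total * 7L), class = "kmer_profile")
  expect_equal(profile_distance(p, scaled), 0, tolerance = 1e-12)

  ## same-composition slices sit closer than a different-GC genome
  ec <- generate_genome(100000, 0.508, seed = 3)
  bs <- generate_genome(50000, 0.435, seed = 4, id = "bs")
  half1 <- count_kmers(substr(ec$sequence, 1, 50000), 6, "ec1")
  half2 <- count_kmers(substr(ec$sequence, 50001, 100000), 6, "ec2")
  other <- count_kmers(bs$sequence, 6, "bs")
  expect_lt(profile_distance(half1, half2),
            profile_distance(half1, other))
  expect_equal(profile_distance(half1, other),
               profile_distance(other, half1), tolerance = 1e-12)
})

test_that("bootstrap clustering pairs similar profiles with high support", {
  ec <- generate_genome(100000, 0.508, seed = 5)
  bs <- generate_genome(50000, 0.435, seed = 6, id = "far")
  p1 <- count_kmers(substr(ec$sequence, 1, 50000), 6, "near1")
  p2 <- count_kmers(substr(ec$sequence, 50001, 100000), 6, "near2")
  p3 <- count_kmers(bs$sequence, 6, "far")

  bh <- hclust_bootstrap(list(p1, p2, p3), n_boot = 200, seed = 7)
  expect_true(all(bh$support$support >= 0 & bh$support$support <= 100))
  expect_gte(clade_support(bh, c("near1", "near2")), 95)

  plain <- hclust_bootstrap(list(p1, p2, p3), n_boot = 0)
  expect_true(all(is.na(plain$support$support)))

  expect_error(hclust_bootstrap(list(p1, p2)), "3 profiles")

  nwk <- tempfile(fileext = ".nwk")
  write_newick(bh, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, c("near1", "near2", "far"))
})

test_that("correspondence analysis satisfies its matrix identities", {
  ## toy 3 x 4 table as three profiles over a 4-k-mer alphabet
  toy_profile <- function(label, counts) {
    structure(list(label = label, k = 1L,
                   counts = stats::setNames(as.integer(counts),
                                            c("A", "C", "G", "T")),
                   total = sum(counts)), class = "kmer_profile")
  }
  profs <- list(toy_profile("p1", c(10, 5, 3, 2)),
                toy_profile("p2", c(2, 8, 6, 4)),
                toy_profile("p3", c(4, 4, 9, 3)))
  ca <- correspondence_analysis(profs, dims = 2)

  X <- rbind(c(10, 5, 3, 2), c(2, 8, 6, 4), c(4, 4, 9, 3))
  chi <- suppressWarnings(chisq.test(X))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(X), tolerance = 1e-9)

  ## row coordinates reproduce inertias: sum_r mass * coord^2 = inertia_d
  for (d in 1:2) {
    coord <- ca$row_coords[[paste0("dim", d)]]
    expect_equal(sum(ca$row_coords$mass * coord^2), ca$inertias[d],
                 tolerance = 1e-9)
  }

  ## independent eigen-decomposition oracle (up to sign)
  P <- X / sum(X)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(S %*% t(S))
  expect_equal(ca$inertias, ev$values[1:2], tolerance = 1e-8)
  for (d in 1:2) {
    oracle_coord <- (diag(1 / sqrt(r)) %*% ev$vectors[, d]) *
      sqrt(ev$values[d])
    got <- ca$row_coords[[paste0("dim", d)]]
    expect_true(max(abs(got - oracle_coord)) < 1e-8 ||
                  max(abs(got + oracle_coord)) < 1e-8)
  }

  ## identical profiles: zero inertia, no dimensions
  same <- correspondence_analysis(list(toy_profile("a", c(5, 5, 5, 5)),
                                       toy_profile("b", c(10, 10, 10, 10))))
  expect_identical(same$total_inertia, 0)
  expect_identical(same$dims, 0L)
  expect_true(same$rank_deficient)

  gl <- glance(ca)
  expect_identical(gl$dims, 2L)
})

test_that("profile resampling equalises depth and preserves composition", {
  g <- generate_genome(30000, 0.45, seed = 8)
  p <- genome_profile(g)
  rs <- resample_profile(p, 10000, seed = 9)
  expect_identical(rs$total, 10000L)
  expect_gt(cor(rel_abundance(rs), rel_abundance(p)), 0.5)
  expect_identical(resample_profile(p, 10000, seed = 9)$counts, rs$counts)
})

test_that("unassigned reads are attributed to their true source", {
  gA <- generate_genome(40000, 0.45, seed = 10, id = "genomeA")
  gB <- generate_genome(40000, 0.51, seed = 11, id = "genomeB")
  nul <- generate_null_genome(40000, seed = 12)
  reads <- simulate_ds_reads(gA, 1200, seed = 13)$reads

  rep <- attribute_unassigned(reads, list(gA, gB), nul,
                              n_boot = 300, n_perm = 199, seed = 14)
  expect_identical(rep$best_candidate, "genomeA")
  expect_gte(rep$best_support, 90)
  ## the null and the wrong-GC candidate are both rejected
  cmp <- rep$comparisons
  expect_lt(cmp$cvm_p[cmp$role == "null"], 0.05)
  expect_lt(cmp$cvm_p[cmp$profile == "genomeB"], 0.05)

  ## reads genuinely from the null genome are not rejected against it
  set.seed(15)
  hits <- vapply(1:40, function(s) {
    r <- simulate_ds_reads(nul, 2000, seed = 100 + s)$reads
    pu <- count_kmers(r$bases, 6)
    pn <- genome_profile(nul)
    depth <- min(pu$total, pn$total)
    xu <- rel_abundance(resample_profile(pu, depth, seed = s))
    xn <- rel_abundance(resample_profile(pn, depth, seed = s + 1L))
    cvm_gof(xu, xn, n_perm = 99, seed = s)$p_value > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  ## single candidate: clustering skipped with notice, CvM still present
  single <- attribute_unassigned(reads[1:100, ], list(gA), nul,
                                 n_boot = 50, n_perm = 99, seed = 16)
  expect_null(single$clustering)
  expect_match(single$notice, "skipped")
  expect_identical(nrow(single$comparisons), 2L)
})
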