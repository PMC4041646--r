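test_that("generate_genome respects composition, alphabet and determinism", {
  g <- generate_genome(100000, gc = 0.508, seed = 3)
  expect_s3_class(g, "genome")
  expect_equal(gc_content(g), 0.508, tolerance = 0.02 / 0.508)
  expect_lt(abs(gc_content(g) - 0.508), 0.02)

  at_only <- generate_genome(10, gc = 0, seed = 4)
  expect_false(grepl("[GC]", at_only$sequence))

  expect_identical(generate_genome(500, 0.4, seed = 9)$sequence,
                   generate_genome(500, 0.4, seed = 9)$sequence)
  expect_error(generate_genome(0, 0.5, seed = 1), "length")
  expect_error(generate_genome(10, 1.2, seed = 1), "gc")
})

test_that("null genome is uniform over bases and hexamers", {
  g <- generate_null_genome(4^6 * 100, seed = 5)
  prof <- count_kmers(g$sequence, k = 6)
  expect_true(all(prof$counts > 0))          # all 4096 hexamers present
  expect_lt(max(abs(rel_abundance(prof) - 1 / 4096)), 5 / 4096)

  counts <- table(strsplit(generate_null_genome(100000, seed = 6)$sequence,
                           "")[[1]])
  purine_frac <- sum(counts[c("A", "G")]) / sum(counts)
  expect_lt(abs(purine_frac - 0.5), 0.02)

  expect_equal(nchar(generate_null_genome(1, seed = 7)$sequence), 1L)
  expect_error(generate_null_genome(0, seed = 1), "length")
})

test_that("DS simulation honours the fragment and read-length model", {
  g <- generate_genome(20000, 0.5, seed = 11)
  sim <- simulate_ds_reads(g, 400, seed = 12)
  lens <- nchar(sim$reads$bases)
  expect_true(all(lens >= 40))
  expect_true(all(lens <= fragment_model()$frag_max))
  expect_true(all(nchar(sim$reads$quals) == lens))
  expect_true(all(qual_to_phred(paste(sim$reads$quals, collapse = "")) %in%
                    2:41))

  fixed <- simulate_ds_reads(g, 50,
                             frag = fragment_model(700, 700, 700, 700, 0),
                             read_len_sd = 0, seed = 13)
  expect_length(unique(nchar(fixed$reads$bases)), 1L)

  expect_error(simulate_ds_reads(generate_genome(500, 0.5, seed = 1), 10),
               "frag_max")
})

test_that("DS coverage is near-uniform at the configured sequencing effort", {
  g <- generate_genome(100000, 0.5, seed = 21)
  pilot <- simulate_ds_reads(g, 500, seed = 22)
  mean_len <- mean(nchar(pilot$reads$bases))
  n <- round(0.76 * nchar(g$sequence) / mean_len)
  sim <- simulate_ds_reads(g, n, seed = 23)
  track <- coverage_from_truth(sim$truth, g)
  expect_equal(mean(track$depth), 0.76, tolerance = 0.1)

  ## Poisson fit of the depth histogram, checked at positions far enough
  ## apart to be independent (depths are autocorrelated within a fragment)
  big <- simulate_ds_reads(g, 5000, seed = 24)
  d <- coverage_from_truth(big$truth, g)$depth[seq(1500, 98500, by = 1000)]
  lam <- mean(d)
  k <- 0:max(d)
  obs <- tabulate(d + 1, max(d) + 1)
  p <- dpois(k, lam)
  p[length(p)] <- 1 - ppois(max(d) - 1, lam)
  grp <- pmin(pmax(k, floor(lam - 3 * sqrt(lam))),
              ceiling(lam + 3 * sqrt(lam)))
  og <- tapply(obs, grp, sum)
  eg <- tapply(p * length(d), grp, sum)
  chisq <- sum((og - eg)^2 / eg)
  expect_gt(pchisq(chisq, length(og) - 1, lower.tail = FALSE), 0.001)
})

test_that("simulation truth is conserved and classes follow the mix", {
  g <- generate_genome(30000, 0.5, seed = 31)
  cont <- generate_genome(30000, 0.43, seed = 32, id = "cont")
  mda <- simulate_mda_reads(g, 10000,
                            mda = mda_params(contaminant_genome = cont),
                            seed = 33)
  expect_identical(dplyr::n_distinct(mda$truth$read_id), 10000L)
  expect_identical(sort(unique(mda$reads$read_id)),
                   sort(unique(mda$truth$read_id)))

  per_read <- dplyr::count(mda$truth, read_id, class)
  expect_true(all(per_read$n[per_read$class == "target"] == 1))
  expect_true(all(per_read$n[per_read$class == "chimera"] == 2))
  expect_true(all(per_read$n[per_read$class == "concatemer"] == 1))

  cls <- dplyr::distinct(mda$truth, read_id, class)$class
  for (spec in list(c("chimera", 0.05), c("contaminant", 0.05),
                    c("concatemer", 0.55))) {
    n_obs <- sum(cls == spec[1])
    p <- as.numeric(spec[2])
    expect_gte(n_obs, qbinom(0.005, 10000, p))
    expect_lte(n_obs, qbinom(0.995, 10000, p))
  }

  ds <- simulate_ds_reads(g, 200, seed = 34)
  expect_identical(nrow(ds$truth), 200L)
  expect_true(all(ds$truth$class == "target"))
})

test_that("MDA coverage is skewed relative to DS at equal effort", {
  g <- generate_genome(50000, 0.5, seed = 41)
  cont <- generate_genome(50000, 0.43, seed = 42, id = "cont")
  ds <- simulate_ds_reads(g, 1000, seed = 43)
  mda <- simulate_mda_reads(g, 1000,
                            mda = mda_params(contaminant_genome = cont),
                            seed = 44)
  tr_ds <- coverage_from_truth(ds$truth, g)
  tr_mda <- coverage_from_truth(mda$truth, g)
  expect_gt(gini_coefficient(tr_mda$depth), gini_coefficient(tr_ds$depth))
  expect_gt(max(tr_mda$depth) / mean(tr_mda$depth),
            max(tr_ds$depth) / mean(tr_ds$depth))
})

test_that("degenerate MDA parameters collapse to the DS start distribution", {
  g <- generate_genome(100000, 0.5, seed = 51)
  mda <- simulate_mda_reads(
    g, 2000,
    mda = mda_params(priming_rate = 20, amplification_dispersion = 1e-6,
                     chimera_rate = 0, contaminant_fraction = 0,
                     concatemer_fraction = 0, window = 1000),
    seed = 52)
  ds <- simulate_ds_reads(g, 2000, seed = 53)
  res <- cvm_two_sample(mda$truth$start, ds$truth$start, n_perm = 499,
                        seed = 1)
  expect_gt(res$p_value, 0.01)
})

test_that("MDA simulation validates its parameters", {
  g <- generate_genome(5000, 0.5, seed = 61)
  expect_error(mda_params(chimera_rate = 0.5, contaminant_fraction = 0.4,
                          concatemer_fraction = 0.2,
                          contaminant_genome = g), "<= 1")
  expect_error(mda_params(contaminant_fraction = 0.1), "contaminant_genome")
  expect_error(
    simulate_mda_reads(g, 10, mda = structure(
      list(priming_rate = 1, amplification_dispersion = 1,
           chimera_rate = 0, contaminant_fraction = 0.5,
           concatemer_fraction = 0, contaminant_genome = NULL,
           window = 500), class = "mda_params"), seed = 1),
    "contaminant_genome")
})

test_that("adaptor attachment appends 3' adaptors and records the MID", {
  g <- generate_genome(20000, 0.5, seed = 71)
  sim <- simulate_ds_reads(g, 100, seed = 72)
  adaptor <- "CTGAGACTGCCAAGGCACACAGGGGATAGG"

  all_on <- attach_adaptors(sim$reads, adaptor, mid = "MID7",
                            attach_prob = 1, seed = 73)
  expect_true(all(endsWith(all_on$bases, adaptor)))
  expect_true(all(all_on$mid == "MID7"))
  expect_true(all(nchar(all_on$bases) == nchar(all_on$quals)))

  none <- attach_adaptors(sim$reads, adaptor, attach_prob = 0, seed = 74)
  expect_identical(none$bases, sim$reads$bases)
  expect_identical(none$quals, sim$reads$quals)

  ## round trip: the adaptor finder recovers the insertion coordinate
  hits <- find_adaptor(all_on, adaptor, min_score = 24)
  orig_len <- nchar(sim$reads$bases)
  recovered <- mean(hits$found & hits$start == orig_len &
                      hits$end == nchar(all_on$bases))
  expect_gte(recovered, 0.99)
})

test_that("FASTQ round-trips byte-identically and simulation is deterministic", {
  g <- generate_genome(20000, 0.5, seed = 81)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_ds_reads(g, 100, seed = 82)$reads, f1)
  write_fastq(simulate_ds_reads(g, 100, seed = 82)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_fastq(f1)
  orig <- simulate_ds_reads(g, 100, seed = 82)$reads
  expect_identical(back$read_id, orig$read_id)
  expect_identical(back$bases, orig$bases)
  expect_identical(back$quals, orig$quals)
})
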