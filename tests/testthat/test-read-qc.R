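test_that("quality trimming keeps the longest clean prefix", {
  good <- toy_reads("ACGTACGTACGTACGTACGT", q = 40)
  expect_identical(trim_quality(good)$bases, good$bases)

  ## Q2 tail: removed at the first failing window
  phred <- c(rep(38, 60), rep(2, 50))
  r <- tibble::tibble(read_id = "r1",
                      bases = strrep("ACGT", 110 / 4 + 1) |> substr(1, 110),
                      quals = phred_to_qual(phred), mid = NA)
  trimmed <- trim_quality(r, window = 10, threshold = 20)
  expect_identical(nchar(trimmed$bases),
                   oracle_quality_keep(phred, 10, 20))
  expect_lt(nchar(trimmed$bases), 70)

  all_bad <- toy_reads("ACGTACGTACGTACGT", q = 2)
  expect_identical(nchar(trim_quality(all_bad)$bases), 0L)

  ## random qualities agree with the exhaustive prefix scan
  set.seed(10)
  for (i in 1:40) {
    n <- sample(15:120, 1)
    phred <- sample(2:41, n, replace = TRUE)
    r <- tibble::tibble(read_id = "x", bases = random_dna(1, n),
                        quals = phred_to_qual(phred), mid = NA)
    expect_identical(nchar(trim_quality(r, 10, 20)$bases),
                     oracle_quality_keep(phred, 10, 20))
  }
})

test_that("adaptor search finds 3' adaptors and matches the DP oracle", {
  adaptor <- "CTGAGACTGCCAAGGCACAC"
  set.seed(20)
  insert <- random_dna(1, 150)
  r <- toy_reads(paste0(insert, adaptor))
  hit <- find_adaptor(r, adaptor, min_score = 24)
  expect_true(hit$found)
  expect_identical(hit$start, 150L)
  expect_identical(hit$end, 170L)
  expect_identical(hit$score, 40)          # 20 matches x 2

  ## two mismatches: score 18*2 - 2*3 = 30 still clears 24
  mutated <- adaptor
  substr(mutated, 3, 3) <- "A"
  substr(mutated, 12, 12) <- "T"
  hit2 <- find_adaptor(toy_reads(paste0(insert, mutated)), adaptor,
                       min_score = 24)
  expect_true(hit2$found)
  expect_identical(hit2$score, 30)

  ## null distribution: adaptor-free reads essentially never reach 30
  set.seed(21)
  null_reads <- toy_reads(random_dna(10000, 100))
  null_hits <- find_adaptor(null_reads, adaptor, min_score = 30)
  expect_gte(mean(!null_hits$found), 0.999)

  ## alignment score equals an independent Gotoh local-alignment oracle
  ## (reads kept within the 3'-most searched window so the whole read is
  ## in scope for both implementations)
  set.seed(22)
  for (i in 1:25) {
    read <- random_dna(1, sample(60:100, 1))
    if (i %% 2 == 0) {
      pos <- sample(10:(nchar(read) - 21), 1)
      substr(read, pos, pos + 19) <- adaptor
    }
    got <- find_adaptor(toy_reads(read), adaptor, min_score = 1)$score
    expect_identical(got, oracle_local_score(read, adaptor))
  }
})

test_that("adaptor trimming removes the hit through the read end", {
  adaptor <- "CTGAGACTGCCAAGGCACAC"
  set.seed(30)
  r <- toy_reads(random_dna(3, 80))
  no_hits <- find_adaptor(r, adaptor, min_score = 40)
  expect_identical(trim_adaptor(r, no_hits)$bases, r$bases)

  with_ad <- toy_reads(paste0(substr(r$bases, 1, 60), adaptor))
  hits <- find_adaptor(with_ad, adaptor, min_score = 24)
  trimmed <- trim_adaptor(with_ad, hits)
  expect_identical(nchar(trimmed$bases), rep(60L, 3))
  expect_identical(trimmed$bases, substr(r$bases, 1, 60))

  bad <- hits
  bad$start <- 999L
  expect_error(trim_adaptor(with_ad, bad), "bounds")

  ## composition with the simulator's attach step is the exact inverse
  g <- generate_genome(20000, 0.5, seed = 31)
  sim <- simulate_ds_reads(g, 80, seed = 32)
  att <- attach_adaptors(sim$reads, adaptor, attach_prob = 1, seed = 33)
  rec <- trim_adaptor(att, find_adaptor(att, adaptor, min_score = 24))
  expect_identical(rec$bases, sim$reads$bases)
})

test_that("sequence entropy matches the k-mer distribution definition", {
  expect_identical(sequence_entropy("AAAAAAAAAA", k = 3), 0)
  expect_equal(sequence_entropy("ACGTACGTACGT", k = 1), 2)
  set.seed(40)
  long <- random_dna(1, 10000)
  expect_equal(sequence_entropy(long, k = 3), 6, tolerance = 0.05 / 6)
  expect_error(sequence_entropy("AC", k = 3), "at least k")

  for (s in random_dna(20, 50)) {
    expect_equal(sequence_entropy(s, k = 3), oracle_entropy(s, 3),
                 tolerance = 1e-12)
  }
})

test_that("run_qc filters in fixed order and accounts for every read", {
  g <- generate_genome(30000, 0.5, seed = 51)
  sim <- simulate_ds_reads(g, 400, seed = 52)
  res <- run_qc(sim$reads)
  expect_gte(res$report$surviving / res$report$input, 0.95)
  rep <- res$report
  expect_identical(rep$removed_quality + rep$removed_length +
                     rep$removed_complexity + rep$surviving, rep$input)
  ## survivors satisfy all thresholds simultaneously
  expect_true(all(nchar(res$reads$bases) >= qc_config()$min_read_len))
  ent <- sequence_entropy(res$reads$bases, 3)
  max_ent <- log2(pmin(64, nchar(res$reads$bases) - 2))
  expect_true(all(ent >= 0.5 * max_ent))
  ## no stage increases read length
  expect_true(all(nchar(res$reads$bases) <=
                    nchar(sim$reads$bases[match(res$reads$read_id,
                                                sim$reads$read_id)])))

  homopolymers <- toy_reads(strrep(c("A", "T", "G"), 60))
  res_h <- run_qc(homopolymers)
  expect_identical(res_h$report$removed_complexity, 3L)
  expect_identical(res_h$report$surviving, 0L)

  empty <- run_qc(toy_reads(character(0)))
  expect_identical(empty$report$input, 0L)
  expect_identical(nrow(empty$reads), 0L)
})

test_that("run_qc with adaptors trims and counts adaptor-positive reads", {
  g <- generate_genome(30000, 0.5, seed = 61)
  adaptor <- "CTGAGACTGCCAAGGCACACAGGGGATAGG"
  sim <- simulate_ds_reads(g, 200, seed = 62)
  att <- attach_adaptors(sim$reads, adaptor, attach_prob = 0.5, seed = 63)
  res <- run_qc(att, adaptor = adaptor)
  expect_gt(res$report$adaptor_positive, 50)
  expect_lt(res$report$adaptor_positive, 150)
  expect_gte(res$report$trimmed, res$report$adaptor_positive)
})
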