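test_that("word index stores every overlapping k-mer position", {
  g <- genome("toy", "ACGTACGTACGT")
  idx <- build_index(g, word_size = 4)
  expect_identical(index_lookup(idx, "ACGT"), c(0L, 4L, 8L))
  expect_identical(index_lookup(idx, "CGTA"), c(1L, 5L))
  expect_identical(index_lookup(idx, "TTTT"), integer(0))

  n_pos <- sum(lengths(as.list(idx$env)))
  expect_identical(n_pos, nchar(g$sequence) - 4L + 1L)

  ## lookups equal a naive substring scan
  set.seed(1)
  big <- generate_genome(1000, 0.5, seed = 2)
  idx13 <- build_index(big, 13)
  starts <- sample(1:(1000 - 12), 100)
  for (s in starts) {
    kmer <- substr(big$sequence, s, s + 12)
    naive <- which(vapply(1:(1000 - 12), function(i) {
      substr(big$sequence, i, i + 12) == kmer
    }, TRUE)) - 1L
    expect_identical(index_lookup(idx13, kmer), naive)
  }

  expect_error(build_index(genome("t", "ACGT"), 13), "shorter")
  expect_error(build_index(big, 20), "word_size")
})

test_that("exact substrings map to their origin on either strand", {
  g <- generate_genome(20000, 0.5, seed = 11)
  idx <- build_index(g)
  sub <- substr(g$sequence, 5001, 5100)        # 0-based [5000, 5100)
  al <- map_reads(idx, toy_reads(sub))
  expect_true(al$mapped)
  expect_identical(al$ref_start, 5000L)
  expect_identical(al$ref_end, 5100L)
  expect_identical(al$strand, "+")
  expect_identical(al$identity, 1)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  al_rc <- map_reads(idx, toy_reads(rc))
  expect_identical(al_rc$ref_start, 5000L)
  expect_identical(al_rc$ref_end, 5100L)
  expect_identical(al_rc$strand, "-")

  ## deterministic: mapping twice yields identical rows
  expect_identical(map_reads(idx, toy_reads(c(sub, rc))),
                   map_reads(idx, toy_reads(c(sub, rc))))
})

test_that("simulated error-free reads map back to their truth intervals", {
  g <- generate_genome(100000, 0.508, seed = 21)
  sim <- simulate_ds_reads(g, 1000, seed = 22)
  idx <- build_index(g)
  al <- map_reads(idx, sim$reads)
  expect_true(all(al$identity[al$mapped] == 1))

  m <- dplyr::inner_join(al[al$mapped, ], sim$truth, by = "read_id")
  ok <- abs(m$ref_start - m$start) <= 2 & abs(m$ref_end - m$end) <= 2 &
    m$strand.x == m$strand.y
  expect_gte(sum(ok) / nrow(sim$reads), 0.99)
})

test_that("coverage tracks count interval membership exactly", {
  g <- generate_genome(100, 0.5, seed = 31)
  one <- tibble::tibble(ref_start = 10L, ref_end = 20L)
  tr <- coverage_track(one, g)
  expect_identical(sum(tr$depth), 10L)
  expect_identical(tr$depth[11:20], rep(1L, 10))
  expect_identical(tr$depth[10], 0L)

  two <- dplyr::bind_rows(one, one)
  expect_identical(coverage_track(two, g)$depth[15], 2L)

  set.seed(32)
  starts <- sample(0:90, 1000, replace = TRUE)
  ends <- pmin(starts + sample(1:10, 1000, replace = TRUE), 100L)
  many <- tibble::tibble(ref_start = starts, ref_end = ends)
  tr_many <- coverage_track(many, g)
  expect_identical(tr_many$depth, oracle_coverage(starts, ends, 100))
  expect_identical(sum(tr_many$depth), sum(ends - starts))

  expect_error(coverage_track(tibble::tibble(ref_start = -1L, ref_end = 5L),
                              g), "bounds")
  expect_error(coverage_track(tibble::tibble(ref_start = 10L,
                                             ref_end = 200L), g), "bounds")
})

test_that("coverage summaries report mean, max, breadth and histogram", {
  g <- generate_genome(500, 0.5, seed = 41)
  zero <- coverage_track(tibble::tibble(ref_start = integer(),
                                        ref_end = integer()), g)
  s <- coverage_summary(zero)
  expect_identical(c(s$mean, s$max, s$breadth), c(0, 0, 0))

  hist0 <- coverage_histogram(zero)
  expect_identical(sum(hist0$bases), 500L)

  ## Lander-Waterman: breadth ~ 1 - exp(-c) for uniform coverage
  big <- generate_genome(100000, 0.5, seed = 42)
  pilot <- simulate_ds_reads(big, 300, seed = 43)
  n <- round(0.77 * 100000 / mean(nchar(pilot$reads$bases)))
  sim <- simulate_ds_reads(big, n, seed = 44)
  tr <- coverage_from_truth(sim$truth, big)
  cs <- coverage_summary(tr)
  expect_lt(abs(cs$breadth - (1 - exp(-cs$mean))), 0.03)
  expect_identical(cs$mean * cs$ref_len, as.numeric(sum(tr$depth)))
  expect_identical(sum(coverage_histogram(tr)$bases), 100000L)
})

test_that("alignments and coverage round-trip through SAM, wiggle and BED", {
  g <- generate_genome(5000, 0.5, seed = 51)
  sim <- simulate_ds_reads(g, 50, seed = 52,
                           frag = fragment_model(400, 900, 400, 600, 100))
  idx <- build_index(g)
  al <- map_reads(idx, sim$reads)

  sam <- tempfile(fileext = ".sam")
  write_sam(al, idx, sam)
  lines <- readLines(sam)
  expect_identical(lines[1], "@HD\tVN:1.6\tSO:unknown")
  expect_match(lines[2], "^@SQ\tSN:sim_genome\tLN:5000$")
  body <- strsplit(lines[-(1:2)], "\t")
  expect_true(all(lengths(body) == 11L))
  mapped_rows <- body[vapply(body, function(x) x[2] != "4", TRUE)]
  expect_true(all(grepl("^[0-9]+M$",
                        vapply(mapped_rows, `[[`, "", 6))))

  tr <- coverage_track(al, g)
  wig <- tempfile(fileext = ".wig")
  write_wiggle(tr, wig)
  back <- read_wiggle(wig)
  expect_identical(back$depth, tr$depth)
  expect_identical(back$ref_id, tr$ref_id)

  bed <- tempfile(fileext = ".bed")
  write_covered_bed(tr, bed)
  intervals <- readr::read_tsv(bed, col_names = c("chrom", "start", "end"),
                               show_col_types = FALSE)
  covered_from_bed <- sum(intervals$end - intervals$start)
  expect_identical(as.integer(covered_from_bed), sum(tr$depth > 0))
})
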