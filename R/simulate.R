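#' Fragment-size model for shotgun library simulation
#'
#' Sonication of genomic DNA yields a broad fragment-size distribution and
#' small fragments are then removed by bead cleanup. We model the retained
#' distribution as a normal truncated to `[frag_min, frag_max]` with
#' fragments below `size_cutoff` rejected and redrawn, which makes the
#' effective lower bound `max(frag_min, size_cutoff)`.
#'
#' @param frag_min,frag_max Fragment size range in bp.
#' @param size_cutoff Fragments below this size are removed (bead cleanup).
#' @param target_mean,target_sd Mean and sd of the underlying normal law.
#'
#' @return A list of class `fragment_model`.
#' @export
fragment_model <- function(frag_min = 200, frag_max = 1000,
                           size_cutoff = 400, target_mean = 700,
                           target_sd = 150) {
  stopifnot(frag_min <= size_cutoff, size_cutoff <= target_mean,
            target_mean <= frag_max, target_sd >= 0)
  structure(list(frag_min = frag_min, frag_max = frag_max,
                 size_cutoff = size_cutoff, target_mean = target_mean,
                 target_sd = target_sd),
            class = "fragment_model")
}

#' Parameters of the MDA artifact model
#'
#' Multiple displacement amplification (MDA) is modelled mechanistically as
#' a set of priming sites laid down as a Poisson process along the genome,
#' each receiving a log-normal amplification weight; reads start
#' preferentially downstream of heavily amplified sites, which produces the
#' spiky, gap-ridden coverage characteristic of MDA. Reads may further be
#' chimeric (two joined half-fragments from independent sites), derive from
#' a contaminating genome carried in the amplification reagent, or be
#' template-free concatemers of random hexamer primers.
#'
#' @param priming_rate Expected priming sites per kb (> 0).
#' @param amplification_dispersion sdlog of the log-normal per-site
#'   amplification weights (> 0); larger values give spikier coverage.
#' @param chimera_rate Per-read probability of a chimeric read.
#' @param contaminant_fraction Per-read probability of a contaminant read.
#' @param concatemer_fraction Per-read probability of a hexamer-concatemer
#'   read.
#' @param contaminant_genome [genome()] acting as the contamination and
#'   hexamer source (the amplification reagent's host); required whenever
#'   `contaminant_fraction + concatemer_fraction > 0`.
#' @param window Width in bp of the downstream window after a priming site
#'   in which amplified fragments are anchored.
#'
#' @return A list of class `mda_params`.
#' @export
mda_params <- function(priming_rate = 0.1, amplification_dispersion = 3,
                       chimera_rate = 0.05, contaminant_fraction = 0.05,
                       concatemer_fraction = 0.55,
                       contaminant_genome = NULL, window = 500) {
  stopifnot(priming_rate > 0, amplification_dispersion > 0,
            chimera_rate >= 0, chimera_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            concatemer_fraction >= 0, concatemer_fraction <= 1,
            window >= 1)
  if (chimera_rate + contaminant_fraction + concatemer_fraction > 1) {
    stop("chimera_rate + contaminant_fraction + concatemer_fraction must be <= 1",
         call. = FALSE)
  }
  if (is.null(contaminant_genome) &&
      contaminant_fraction + concatemer_fraction > 0) {
    stop("contaminant_genome required when contaminant or concatemer reads are simulated",
         call. = FALSE)
  }
  structure(list(priming_rate = priming_rate,
                 amplification_dispersion = amplification_dispersion,
                 chimera_rate = chimera_rate,
                 contaminant_fraction = contaminant_fraction,
                 concatemer_fraction = concatemer_fraction,
                 contaminant_genome = contaminant_genome,
                 window = window),
            class = "mda_params")
}

## truncated-normal draw by rejection; sd = 0 collapses to clamped mean
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

## Phred+33 encoded quality strings for reads of the given lengths.
## Per-base Phred ~ round(Normal(mean, sd)) clamped to [2, 41].
sim_qual_strings <- function(lengths, qual_mean = 36, qual_sd = 3.5) {
  total <- sum(lengths)
  q <- pmin(pmax(round(stats::rnorm(total, qual_mean, qual_sd)), 2L), 41L)
  idx <- rep.int(seq_along(lengths), lengths)
  vapply(split(q + 33L, idx), intToUtf8, "", USE.NAMES = FALSE)
}

#' Convert between Phred+33 quality strings and integer scores
#'
#' @param qual A Phred+33 encoded quality string.
#' @param scores An integer vector of Phred scores.
#' @return `qual_to_phred()` returns an integer vector; `phred_to_qual()`
#'   a single string.
#' @export
qual_to_phred <- function(qual) utf8ToInt(qual) - 33L

#' @rdname qual_to_phred
#' @export
phred_to_qual <- function(scores) intToUtf8(scores + 33L)

new_read_tbl <- function(read_id, bases, quals, mid = NA_character_) {
  tibble::tibble(read_id = read_id, bases = bases, quals = quals, mid = mid)
}

new_truth_tbl <- function(read_id = character(), class = character(),
                          genome_id = character(), start = integer(),
                          end = integer(), strand = character()) {
  tibble::tibble(read_id = read_id, class = class, genome_id = genome_id,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

## Extract reads of given lengths from fragments [fs, fs+flen) of `seq`,
## taking the 5' prefix on the drawn strand. Returns bases plus the truth
## interval (0-based half-open, forward-strand coordinates).
extract_prefix_reads <- function(seq, fs, flen, read_len, strand) {
  fe <- fs + flen
  start <- ifelse(strand == "+", fs, fe - read_len)
  end <- start + read_len
  bases <- substring(seq, start + 1L, end)
  rev <- strand == "-"
  if (any(rev)) bases[rev] <- reverse_complement(bases[rev])
  list(bases = bases, start = start, end = end)
}

#' Simulate direct-sequencing (DS) reads
#'
#' Emulates shotgun sequencing of unamplified DNA: fragment start positions
#' are uniform over the genome (near-uniform coverage), fragment lengths
#' follow the [fragment_model()], and each read is the 5' prefix of its
#' fragment on a uniformly chosen strand, with read length
#' `min(fragment length, truncated Normal(read_len_mean, read_len_sd) >= 40)`.
#' Reads are error-free at the base level; per-base qualities follow a
#' clamped normal model.
#'
#' @param genome Source [genome()].
#' @param n_reads Number of reads (>= 1).
#' @param frag A [fragment_model()].
#' @param read_len_mean,read_len_sd Read-length law (nt); defaults match a
#'   typical pyrosequencing run (mean 230, sd 137).
#' @param seed Integer seed; output is reproducible.
#' @param run_label Prefix for read identifiers.
#' @param qual_mean,qual_sd Per-base quality model (Phred).
#'
#' @return A list with elements `reads` (tibble: `read_id`, `bases`,
#'   `quals`, `mid`) and `truth` (tibble: `read_id`, `class`, `genome_id`,
#'   `start`, `end`, `strand`; 0-based half-open forward-strand intervals).
#'   All DS reads have truth class `"target"`.
#' @export
simulate_ds_reads <- function(genome, n_reads, frag = fragment_model(),
                              read_len_mean = 230, read_len_sd = 137,
                              seed = 1L, run_label = "DS",
                              qual_mean = 36, qual_sd = 3.5) {
  stopifnot(inherits(genome, "genome"), n_reads >= 1,
            inherits(frag, "fragment_model"))
  L <- nchar(genome$sequence)
  if (L < frag$frag_max) {
    stop("genome shorter than frag_max", call. = FALSE)
  }
  withr::with_seed(seed, {
    flen <- round(rtrunc_norm(n_reads, frag$target_mean, frag$target_sd,
                              lower = max(frag$frag_min, frag$size_cutoff),
                              upper = frag$frag_max))
    fs <- floor(stats::runif(n_reads, 0, L - flen + 1))
    rl <- pmin(flen, round(rtrunc_norm(n_reads, read_len_mean, read_len_sd,
                                       lower = 40)))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    ex <- extract_prefix_reads(genome$sequence, fs, flen, rl, strand)
    quals <- sim_qual_strings(rl, qual_mean, qual_sd)
    ids <- sprintf("%s_%06d", run_label, seq_len(n_reads))
    list(
      reads = new_read_tbl(ids, ex$bases, quals),
      truth = new_truth_tbl(ids, "target", genome$id, ex$start, ex$end,
                            strand)
    )
  })
}

#' Simulate MDA-amplified reads with coverage bias and artifacts
#'
#' Reads are generated from the mechanistic amplification model described
#' in [mda_params()]: each read is, with the configured probabilities,
#' a chimera, a contaminant-genome read, a template-free hexamer concatemer,
#' or otherwise a target read anchored downstream of a weighted priming
#' site. Target reads therefore pile up around high-weight sites, giving
#' coverage spikes far above the mean and a large uncovered fraction.
#'
#' @inheritParams simulate_ds_reads
#' @param mda An [mda_params()] object.
#'
#' @return As [simulate_ds_reads()]. Truth classes are `"target"`,
#'   `"chimera"` (two origin-interval rows), `"contaminant"`, and
#'   `"concatemer"` (one row with `NA` interval).
#' @export
simulate_mda_reads <- function(genome, n_reads, frag = fragment_model(),
                               read_len_mean = 230, read_len_sd = 137,
                               mda = mda_params(), seed = 1L,
                               run_label = "MDA",
                               qual_mean = 36, qual_sd = 3.5) {
  stopifnot(inherits(genome, "genome"), n_reads >= 1,
            inherits(frag, "fragment_model"), inherits(mda, "mda_params"))
  L <- nchar(genome$sequence)
  if (L < frag$frag_max) {
    stop("genome shorter than frag_max", call. = FALSE)
  }
  if (is.null(mda$contaminant_genome) &&
      mda$contaminant_fraction + mda$concatemer_fraction > 0) {
    stop("contaminant_genome required when contaminant or concatemer reads are simulated",
         call. = FALSE)
  }

  withr::with_seed(seed, {
    ## priming sites: Poisson process along the genome
    n_sites <- max(1L, stats::rpois(1, mda$priming_rate * L / 1000))
    site_pos <- floor(stats::runif(n_sites, 0, L))
    site_w <- stats::rlnorm(n_sites, meanlog = 0,
                            sdlog = mda$amplification_dispersion)

    cls <- sample(c("chimera", "contaminant", "concatemer", "target"),
                  n_reads, replace = TRUE,
                  prob = c(mda$chimera_rate, mda$contaminant_fraction,
                           mda$concatemer_fraction,
                           1 - mda$chimera_rate - mda$contaminant_fraction -
                             mda$concatemer_fraction))
    rl <- round(rtrunc_norm(n_reads, read_len_mean, read_len_sd, lower = 40))
    ids <- sprintf("%s_%06d", run_label, seq_len(n_reads))

    bases <- character(n_reads)
    truth <- vector("list", n_reads)

    anchor_start <- function(n, len) {
      ## fragment start anchored in the window downstream of a priming site
      s <- sample.int(n_sites, n, replace = TRUE, prob = site_w)
      pmin(pmax(site_pos[s] + floor(stats::runif(n, 0, mda$window)), 0L),
           L - len)
    }

    is_t <- which(cls == "target")
    if (length(is_t) > 0L) {
      flen <- round(rtrunc_norm(length(is_t), frag$target_mean,
                                frag$target_sd,
                                lower = max(frag$frag_min, frag$size_cutoff),
                                upper = frag$frag_max))
      rlen <- pmin(flen, rl[is_t])
      rl[is_t] <- rlen
      fs <- anchor_start(length(is_t), flen)
      strand <- sample(c("+", "-"), length(is_t), replace = TRUE)
      ex <- extract_prefix_reads(genome$sequence, fs, flen, rlen, strand)
      bases[is_t] <- ex$bases
      truth[is_t] <- purrr::pmap(
        list(ids[is_t], ex$start, ex$end, strand),
        function(id, s, e, st) new_truth_tbl(id, "target", genome$id, s, e, st))
    }

    is_c <- which(cls == "chimera")
    if (length(is_c) > 0L) {
      h1 <- ceiling(rl[is_c] / 2)
      h2 <- rl[is_c] - h1
      s1 <- anchor_start(length(is_c), h1)
      s2 <- anchor_start(length(is_c), pmax(h2, 1L))
      st1 <- sample(c("+", "-"), length(is_c), replace = TRUE)
      st2 <- sample(c("+", "-"), length(is_c), replace = TRUE)
      e1 <- extract_prefix_reads(genome$sequence, s1, h1, h1, st1)
      e2 <- extract_prefix_reads(genome$sequence, s2, pmax(h2, 1L),
                                 pmax(h2, 1L), st2)
      half2 <- ifelse(h2 > 0L, e2$bases, "")
      bases[is_c] <- paste0(e1$bases, half2)
      truth[is_c] <- purrr::pmap(
        list(ids[is_c], e1$start, e1$end, st1, e2$start, e2$end, st2,
             h2 > 0L),
        function(id, a1, b1, x1, a2, b2, x2, has2) {
          t1 <- new_truth_tbl(id, "chimera", genome$id, a1, b1, x1)
          if (has2) {
            dplyr::bind_rows(t1, new_truth_tbl(id, "chimera", genome$id,
                                               a2, b2, x2))
          } else t1
        })
      rl[is_c] <- nchar(bases[is_c])
    }

    is_x <- which(cls == "contaminant")
    if (length(is_x) > 0L) {
      cg <- mda$contaminant_genome
      Lc <- nchar(cg$sequence)
      rlen <- pmin(rl[is_x], Lc)
      fs <- floor(stats::runif(length(is_x), 0, Lc - rlen + 1))
      strand <- sample(c("+", "-"), length(is_x), replace = TRUE)
      ex <- extract_prefix_reads(cg$sequence, fs, rlen, rlen, strand)
      bases[is_x] <- ex$bases
      rl[is_x] <- rlen
      truth[is_x] <- purrr::pmap(
        list(ids[is_x], ex$start, ex$end, strand),
        function(id, s, e, st) new_truth_tbl(id, "contaminant", cg$id, s, e, st))
    }

    is_k <- which(cls == "concatemer")
    if (length(is_k) > 0L) {
      cg <- mda$contaminant_genome
      hex <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAString(cg$sequence), width = 6)
      hex_names <- names(hex)
      hex_p <- as.numeric(hex)
      if (sum(hex_p) == 0) hex_p <- rep(1, length(hex_p))
      bases[is_k] <- vapply(rl[is_k], function(len) {
        n_hex <- ceiling(len / 6)
        substr(paste(sample(hex_names, n_hex, replace = TRUE,
                            prob = hex_p), collapse = ""), 1L, len)
      }, "")
      truth[is_k] <- purrr::map(ids[is_k], function(id) {
        new_truth_tbl(id, "concatemer", NA_character_, NA_integer_,
                      NA_integer_, NA_character_)
      })
    }

    quals <- sim_qual_strings(rl, qual_mean, qual_sd)
    list(
      reads = new_read_tbl(ids, bases, quals),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Append a 3' adaptor to simulated reads
#'
#' With probability `attach_prob` per read, the 3' Y-adaptor sequence is
#' appended to the read's 3' end (truncated if the combined read would
#' exceed `max_len`), and the multiplex identifier (MID) label is recorded
#' on every read. Qualities for appended bases follow the same clamped
#' normal model as the simulators.
#'
#' @param reads Read tibble (`read_id`, `bases`, `quals`, `mid`).
#' @param adaptor3 Adaptor sequence (non-empty DNA string).
#' @param mid MID label recorded on the reads.
#' @param attach_prob Per-read probability of carrying the adaptor.
#' @param seed Integer seed.
#' @param max_len Maximum combined read length; `Inf` keeps full adaptors.
#'
#' @return The read tibble with adaptors appended and an added logical
#'   column `adaptor_attached`.
#' @export
attach_adaptors <- function(reads, adaptor3, mid = "MID1", attach_prob = 1,
                            seed = 1L, max_len = Inf) {
  stopifnot(is.character(adaptor3), nchar(adaptor3) >= 1)
  withr::with_seed(seed, {
    hit <- stats::runif(nrow(reads)) < attach_prob
    out <- reads
    out$mid <- mid
    out$adaptor_attached <- hit
    if (any(hit)) {
      keep <- pmin(nchar(adaptor3),
                   pmax(0, max_len - nchar(reads$bases[hit])))
      app <- substr(rep(adaptor3, sum(hit)), 1L, keep)
      out$bases[hit] <- paste0(reads$bases[hit], app)
      aq <- sim_qual_strings(pmax(keep, 0))
      out$quals[hit] <- paste0(reads$quals[hit], aq)
    }
    out
  })
}

#' Read and write FASTQ (Sanger Phred+33)
#'
#' @param reads Read tibble with `read_id`, `bases`, `quals`.
#' @param path File path.
#' @return `read_fastq()` returns a read tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$bases),
    Biostrings::PhredQuality(reads$quals))
  names(seqs) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  new_read_tbl(sub("\\s.*$", "", names(x)),
               unname(as.character(x)),
               unname(as.character(Biostrings::quality(x))))
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth tibble from a simulator.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
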