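#' Read quality-control configuration
#'
#' Defaults: sliding-window quality trimming (window 10 nt, mean Phred 20),
#' 3' adaptor detection at local-alignment score >= 24 (roughly a 16-nt
#' exact match under the +2/-3 scoring), minimum surviving length 40 nt,
#' and a trimer-entropy low-complexity filter at half the attainable
#' entropy.
#'
#' @param qual_window Sliding window width in nt.
#' @param qual_threshold Minimum mean Phred per window.
#' @param min_read_len Minimum surviving read length in nt.
#' @param adaptor_min_score Minimum local-alignment score to call an
#'   adaptor hit.
#' @param entropy_k K-mer size of the complexity filter.
#' @param entropy_min Minimum entropy as a fraction of the maximum
#'   attainable for the read, in `[0, 1]`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(qual_window = 10, qual_threshold = 20,
                      min_read_len = 40, adaptor_min_score = 24,
                      entropy_k = 3, entropy_min = 0.5) {
  stopifnot(qual_window >= 1, qual_threshold > 0, min_read_len >= 1,
            adaptor_min_score > 0, entropy_k >= 1,
            entropy_min >= 0, entropy_min <= 1)
  structure(list(qual_window = qual_window, qual_threshold = qual_threshold,
                 min_read_len = min_read_len,
                 adaptor_min_score = adaptor_min_score,
                 entropy_k = entropy_k, entropy_min = entropy_min),
            class = "qc_config")
}

## keep-length of one read under the sliding-window rule: the read is cut
## at the start of the first window whose mean quality drops below the
## threshold, so every complete window in the kept prefix passes
quality_keep_length <- function(phred, window, threshold) {
  n <- length(phred)
  window <- as.integer(window)
  if (n < window) return(n)
  cs <- cumsum(c(0, phred))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  bad <- which(means < threshold)
  if (length(bad) == 0L) return(n)
  bad[1] - 1L
}

#' Quality-trim reads from the 3' end
#'
#' Each read is cut at the start of the first sliding window of `window`
#' bases whose mean Phred quality falls below `threshold`, so every
#' complete window in the kept prefix passes. Reads shorter than the
#' window are kept whole; a read may be trimmed to length zero.
#'
#' @param reads Read tibble (`read_id`, `bases`, `quals`, ...).
#' @param window Window width in nt (>= 1).
#' @param threshold Minimum mean Phred per window.
#' @return The read tibble with trimmed `bases` and `quals`.
#' @export
trim_quality <- function(reads, window = 10, threshold = 20) {
  stopifnot(window >= 1)
  keep <- vapply(reads$quals, function(q) {
    quality_keep_length(qual_to_phred(q), window, threshold)
  }, 0L, USE.NAMES = FALSE)
  dplyr::mutate(reads,
                bases = substr(.data$bases, 1L, keep),
                quals = substr(.data$quals, 1L, keep))
}

#' Locate a 3' adaptor in reads by local alignment
#'
#' The adaptor is aligned (Smith-Waterman; match +2, mismatch -3, gap open
#' -5, gap extend -2 per base) against the 3'-most
#' `max(100, 2 * nchar(adaptor))` nt of each read. A hit is reported when
#' the alignment score reaches `min_score`.
#'
#' @param reads Read tibble.
#' @param adaptor Adaptor sequence (>= 8 nt).
#' @param min_score Minimum alignment score.
#' @return Tibble with one row per read: `read_id`, `found`, `start`,
#'   `end` (0-based half-open read coordinates of the hit, `NA` if none)
#'   and `score`.
#' @export
find_adaptor <- function(reads, adaptor, min_score = 24) {
  stopifnot(nchar(adaptor) >= 8)
  n <- nrow(reads)
  out <- tibble::tibble(read_id = reads$read_id, found = FALSE,
                        start = NA_integer_, end = NA_integer_,
                        score = NA_real_)
  lens <- nchar(reads$bases)
  usable <- which(lens >= 1L)
  if (length(usable) == 0L) return(out)
  region_len <- pmin(lens[usable], max(100L, 2L * nchar(adaptor)))
  offset <- lens[usable] - region_len            # 0-based region origin
  regions <- substr(reads$bases[usable], offset + 1L, lens[usable])
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(regions),
    subject = Biostrings::DNAString(adaptor),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  sc <- Biostrings::score(al)
  hit <- sc >= min_score
  out$score[usable] <- sc
  out$found[usable] <- hit
  if (any(hit)) {
    pat <- Biostrings::pattern(al)
    out$start[usable[hit]] <- offset[hit] +
      BiocGenerics::start(pat)[hit] - 1L
    out$end[usable[hit]] <- offset[hit] + BiocGenerics::end(pat)[hit]
  }
  out
}

#' Trim reads at an adaptor hit
#'
#' Removes bases (and qualities) from the hit start to the read end, the
#' appropriate action for adaptor read-through at the 3' end. Reads whose
#' hit is `found = FALSE` are returned unchanged.
#'
#' @param reads Read tibble.
#' @param hits Hit tibble from [find_adaptor()] (matched by `read_id`).
#' @return The trimmed read tibble.
#' @export
trim_adaptor <- function(reads, hits) {
  m <- match(reads$read_id, hits$read_id)
  start <- hits$start[m]
  found <- !is.na(m) & hits$found[m] & !is.na(start)
  lens <- nchar(reads$bases)
  if (any(found & (start < 0 | start > lens), na.rm = TRUE)) {
    stop("adaptor interval out of read bounds", call. = FALSE)
  }
  cut <- ifelse(found, start, lens)
  dplyr::mutate(reads,
                bases = substr(.data$bases, 1L, cut),
                quals = substr(.data$quals, 1L, cut))
}

#' Shannon entropy of the k-mer composition of sequences
#'
#' Base-2 entropy of the empirical distribution of overlapping k-mers;
#' windows containing non-ACGT symbols are skipped. A homopolymer has
#' entropy 0; a maximally diverse sequence approaches
#' `log2(min(4^k, n_windows))` bits.
#'
#' @param bases Character vector of DNA strings, each of length >= `k`.
#' @param k K-mer size.
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' sequence_entropy(c("AAAAAAAAAA", "ACGTACGTACGT"), k = 3)
sequence_entropy <- function(bases, k = 3) {
  if (any(nchar(bases) < k)) {
    stop("all sequences must be at least k bases long", call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(bases), width = k, simplify.as = "matrix")
  apply(counts, 1L, function(x) {
    tot <- sum(x)
    if (tot == 0) return(0)
    p <- x[x > 0] / tot
    -sum(p * log2(p))
  })
}

#' Run the full read quality-control pipeline
#'
#' Stages run in fixed order: quality trimming, 3' adaptor trimming (when
#' an adaptor is supplied), length filtering, then the entropy
#' low-complexity filter (a read passes when its entropy is at least
#' `entropy_min` times the maximum attainable `log2(min(4^k, n_windows))`).
#' Every input read is accounted for exactly once in the report, by its
#' first failing stage.
#'
#' @param reads Read tibble.
#' @param cfg A [qc_config()].
#' @param adaptor Optional 3' adaptor sequence; `NULL` skips adaptor
#'   trimming.
#' @return A list with `reads` (surviving, trimmed read tibble) and
#'   `report` (one-row tibble: `input`, `trimmed`, `adaptor_positive`,
#'   `removed_quality`, `removed_length`, `removed_complexity`,
#'   `surviving`).
#' @export
run_qc <- function(reads, cfg = qc_config(), adaptor = NULL) {
  stopifnot(inherits(cfg, "qc_config"))
  input <- nrow(reads)
  if (input == 0L) {
    report <- tibble::tibble(input = 0L, trimmed = 0L, adaptor_positive = 0L,
                             removed_quality = 0L, removed_length = 0L,
                             removed_complexity = 0L, surviving = 0L)
    return(list(reads = reads, report = report))
  }
  len0 <- nchar(reads$bases)

  cur <- trim_quality(reads, cfg$qual_window, cfg$qual_threshold)
  emptied <- nchar(cur$bases) < 1L
  removed_quality <- sum(emptied)
  cur <- cur[!emptied, , drop = FALSE]

  adaptor_positive <- 0L
  if (!is.null(adaptor) && nrow(cur) > 0L) {
    hits <- find_adaptor(cur, adaptor, cfg$adaptor_min_score)
    adaptor_positive <- sum(hits$found)
    cur <- trim_adaptor(cur, hits)
  }

  short <- nchar(cur$bases) < cfg$min_read_len
  removed_length <- sum(short)
  cur <- cur[!short, , drop = FALSE]

  removed_complexity <- 0L
  if (nrow(cur) > 0L) {
    ent <- sequence_entropy(cur$bases, cfg$entropy_k)
    n_windows <- pmax(nchar(cur$bases) - cfg$entropy_k + 1L, 1L)
    max_ent <- log2(pmin(4^cfg$entropy_k, n_windows))
    low <- ent < cfg$entropy_min * max_ent
    removed_complexity <- sum(low)
    cur <- cur[!low, , drop = FALSE]
  }

  trimmed <- sum(nchar(cur$bases) < len0[match(cur$read_id, reads$read_id)]) +
    removed_quality
  report <- tibble::tibble(
    input = input, trimmed = as.integer(trimmed),
    adaptor_positive = as.integer(adaptor_positive),
    removed_quality = as.integer(removed_quality),
    removed_length = as.integer(removed_length),
    removed_complexity = as.integer(removed_complexity),
    surviving = nrow(cur))
  list(reads = cur, report = report)
}

#' Write a QC report as TSV
#'
#' @param report Report tibble from [run_qc()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
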