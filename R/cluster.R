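#' Pairwise identity and coverage of two sequences
#'
#' The shorter sequence is aligned globally against the longer with free
#' end gaps on the longer (match +1, mismatch -1, gap -2 per gapped
#' column). Identity is matches divided by the aligned columns of the
#' shorter's span; coverage is the shorter's aligned span on the longer
#' divided by the longer's length.
#'
#' @param a,b Non-empty DNA strings.
#' @return One-row tibble: `identity`, `coverage`, `score`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")  # identity 7/8
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  if (nchar(a) <= nchar(b)) {
    shorter <- a; longer <- b
  } else {
    shorter <- b; longer <- a
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(shorter),
    subject = Biostrings::DNAString(longer),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 2)
  ## when the shorter overhangs the longer's end, the overhang columns are
  ## outside the reported alignment but still part of the shorter's span
  overhang <- nchar(shorter) - Biostrings::width(Biostrings::pattern(al))
  cols <- Biostrings::nchar(al) + overhang
  tibble::tibble(
    identity = Biostrings::nmatch(al) / cols,
    coverage = Biostrings::width(Biostrings::subject(al)) / nchar(longer),
    score = Biostrings::score(al))
}

## multiset count of shared k-mers between two k-mer count tables
shared_kmer_count <- function(ta, tb) {
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0L) return(0L)
  sum(pmin(ta[common], tb[common]))
}

kmer_table <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  table(substring(s, 1:(n - k + 1L), k:n))
}

## conservative lower bound on shared k-mers for a pair that can still
## reach the identity threshold; never excludes a passing pair
prefilter_threshold <- function(len_short, len_long, k, identity_threshold) {
  ## the shorter is aligned globally, so aligned columns = len_short + c
  ## with c the gap columns in the shorter; every gap column is a
  ## non-match, hence e <= (1-t)(len_short + e), i.e. e <= (1-t)/t * Ls.
  ## Each non-match column destroys at most k of the shorter's k-mers.
  m_max <- floor((1 - identity_threshold) / identity_threshold * len_short)
  max(1L, (len_short - k + 1L) - k * m_max)
}

#' Greedy incremental identity clustering of reads
#'
#' CD-HIT-style greedy scheme: reads are sorted by length descending (ties
#' broken lexicographically by id); each read joins the first existing
#' cluster whose representative passes a shared-k-mer prefilter and whose
#' [pairwise_identity()] meets both the identity and coverage thresholds,
#' otherwise it founds a new cluster. Representatives are cluster founders
#' and hence the longest members. The prefilter is a conservative bound
#' derived from the identity threshold and never changes the result
#' relative to an unfiltered greedy pass.
#'
#' @param reads Read tibble (`read_id`, `bases`).
#' @param identity_threshold Identity threshold in `(0.5, 1]`.
#' @param coverage_threshold Minimum fraction of the representative's
#'   length the candidate must align over.
#' @param k_filter K-mer size of the prefilter.
#' @param use_prefilter Disable to force the brute-force greedy pass.
#' @return Tibble of class `cluster_set`: one row per read with
#'   `read_id`, `cluster`, `representative`, `is_representative`;
#'   attributes `identity_threshold`, `coverage_threshold`.
#' @export
greedy_cluster <- function(reads, identity_threshold,
                           coverage_threshold = 0.8, k_filter = 5,
                           use_prefilter = TRUE) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  empty <- tibble::tibble(read_id = character(), cluster = integer(),
                          representative = character(),
                          is_representative = logical())
  if (nrow(reads) == 0L) {
    attr(empty, "identity_threshold") <- identity_threshold
    attr(empty, "coverage_threshold") <- coverage_threshold
    class(empty) <- c("cluster_set", class(empty))
    return(empty)
  }
  o <- order(-nchar(reads$bases), reads$read_id)
  ids <- reads$read_id[o]
  seqs <- reads$bases[o]
  lens <- nchar(seqs)

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)

  rep_idx <- integer(0)          # indices (into sorted order) of founders
  rep_tabs <- list()
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    tab_i <- if (use_prefilter) kmer_table(seqs[i], k_filter) else NULL
    cand <- seq_along(rep_idx)
    if (use_prefilter && length(cand) > 0L) {
      pass <- vapply(cand, function(ci) {
        r <- rep_idx[ci]
        thr <- prefilter_threshold(lens[i], lens[r], k_filter,
                                   identity_threshold)
        shared_kmer_count(tab_i, rep_tabs[[ci]]) >= thr
      }, TRUE)
      cand <- cand[pass]
    }
    placed <- 0L
    if (length(cand) > 0L) {
      ## reads arrive in descending length order, so every representative
      ## is at least as long as read i: fit the read (global) into each
      ## candidate representative (local) in one vectorized call
      al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(seqs[rep_idx[cand]]),
        subject = Biostrings::DNAString(seqs[i]),
        type = "local-global", substitutionMatrix = sub_mat,
        gapOpening = 0, gapExtension = 2)
      overhang <- lens[i] - Biostrings::width(Biostrings::subject(al))
      identity <- Biostrings::nmatch(al) /
        (Biostrings::nchar(al) + overhang)
      coverage <- Biostrings::width(Biostrings::pattern(al)) /
        lens[rep_idx[cand]]
      ok <- identity >= identity_threshold & coverage >= coverage_threshold
      if (any(ok)) placed <- cand[which(ok)[1]]   # first-fit
    }
    if (placed == 0L) {
      rep_idx <- c(rep_idx, i)
      if (use_prefilter) rep_tabs[[length(rep_idx)]] <- tab_i
      placed <- length(rep_idx)
    }
    assign[i] <- placed
  }
  out <- tibble::tibble(
    read_id = ids,
    cluster = assign,
    representative = ids[rep_idx][assign],
    is_representative = seq_along(ids) %in% rep_idx)
  attr(out, "identity_threshold") <- identity_threshold
  attr(out, "coverage_threshold") <- coverage_threshold
  class(out) <- c("cluster_set", class(out))
  out
}

#' Cluster counts across a stringency sweep
#'
#' One [greedy_cluster()] run per identity threshold; lowering the
#' threshold coarsens the clustering, so amplified (duplicate-rich) read
#' sets show a steep drop in cluster count.
#'
#' @param reads Read tibble.
#' @param thresholds Identity thresholds, sorted descending.
#' @param coverage_threshold,k_filter Passed to [greedy_cluster()].
#' @return Tibble: `threshold`, `n_clusters`, `n_reads`,
#'   `largest_cluster`.
#' @export
cluster_curve <- function(reads, thresholds = c(0.99, 0.95, 0.9, 0.85, 0.8),
                          coverage_threshold = 0.8, k_filter = 5) {
  stopifnot(!is.unsorted(rev(thresholds)))
  purrr::map_dfr(thresholds, function(t) {
    cs <- greedy_cluster(reads, t, coverage_threshold, k_filter)
    tibble::tibble(
      threshold = t,
      n_clusters = if (nrow(cs) == 0L) 0L else max(cs$cluster),
      n_reads = nrow(cs),
      largest_cluster = if (nrow(cs) == 0L) 0L else max(table(cs$cluster)))
  })
}

#' Write clusters in CD-HIT-like .clstr text format
#'
#' @param clusters A [greedy_cluster()] result.
#' @param reads The read tibble that was clustered (for lengths).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, reads, path) {
  lens <- nchar(reads$bases)[match(clusters$read_id, reads$read_id)]
  lines <- character(0)
  for (cl in sort(unique(clusters$cluster))) {
    rows <- which(clusters$cluster == cl)
    lines <- c(lines, sprintf(">Cluster %d", cl - 1L))
    member <- 0L
    for (i in rows) {
      tag <- if (clusters$is_representative[i]) "*" else "at"
      lines <- c(lines, sprintf("%d\t%dnt, >%s... %s", member, lens[i],
                                clusters$read_id[i], tag))
      member <- member + 1L
    }
  }
  writeLines(lines, path)
  invisible(path)
}
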