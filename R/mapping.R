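#' Build a word-hash index of a reference genome
#'
#' Every overlapping k-mer of the forward strand is indexed to its sorted
#' 0-based start positions, the classic hash-lookup structure of
#' seed-and-extend read mappers (default word size 13).
#'
#' @param genome Reference [genome()].
#' @param word_size K-mer size (sensible mapping values lie in `[8, 16]`;
#'   smaller words are admitted for exploration and enumeration).
#' @return An object of class `word_index`.
#' @export
build_index <- function(genome, word_size = 13) {
  stopifnot(inherits(genome, "genome"),
            word_size >= 2, word_size <= 16)
  L <- nchar(genome$sequence)
  if (L <= word_size) stop("genome shorter than word_size", call. = FALSE)
  n <- L - word_size + 1L
  kmers <- substring(genome$sequence, 1:n, word_size:L)
  env <- list2env(split(0:(n - 1L), kmers), hash = TRUE)
  structure(list(word_size = as.integer(word_size), env = env,
                 ref_id = genome$id, ref_len = L,
                 ref_seq = genome$sequence),
            class = "word_index")
}

#' @export
print.word_index <- function(x, ...) {
  cat(sprintf("<word_index> %s: %s bp, word size %d, %s distinct words\n",
              x$ref_id, format(x$ref_len, big.mark = ","), x$word_size,
              format(length(x$env), big.mark = ",")))
  invisible(x)
}

#' Look up the reference positions of a k-mer
#'
#' @param index A [build_index()] object.
#' @param kmer A string of length `word_size`.
#' @return Integer vector of 0-based start positions (empty when absent).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "word_index"))
  hit <- get0(kmer, envir = index$env, inherits = FALSE)
  if (is.null(hit)) integer(0) else as.integer(hit)
}

## seeds of one strand: 0-based read positions and reference positions
collect_seeds <- function(index, seq) {
  k <- index$word_size
  n <- nchar(seq)
  if (n < k) return(NULL)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  hits <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
  lens <- lengths(hits)
  if (sum(lens) == 0L) return(NULL)
  list(read_pos = rep.int(0:(n - k), lens),
       ref_pos = as.integer(unlist(hits, use.names = FALSE)))
}

## best diagonal of one strand: most seeds, ties to the leftmost diagonal
best_diagonal <- function(seeds) {
  diag <- seeds$ref_pos - seeds$read_pos
  o <- order(diag)
  r <- rle(diag[o])
  i <- which(r$lengths == max(r$lengths))[1]   # leftmost among maxima
  d <- r$values[i]
  list(diag = d, n_seeds = r$lengths[i],
       seed_read_pos = sort(seeds$read_pos[diag == d]))
}

## greedy ungapped extension from the first seed block along a diagonal,
## one base at a time while the running identity stays >= min_identity
extend_diagonal <- function(match, a, b, min_identity) {
  n <- length(match)
  m <- sum(match[(a + 1):b])
  ## right
  j <- b
  while (j < n) {
    if ((m + match[j + 1]) / (j + 1 - a) < min_identity) break
    j <- j + 1L
    m <- m + match[j]
  }
  b <- j
  ## left
  j <- a
  while (j > 0) {
    if ((m + match[j]) / (b - j + 1) < min_identity) break
    m <- m + match[j]
    j <- j - 1L
  }
  list(a = j, b = b, matched = m)
}

map_one <- function(index, bases, rc, min_match_len, min_identity) {
  k <- index$word_size
  cand <- list()
  fwd <- collect_seeds(index, bases)
  if (!is.null(fwd)) cand[["+"]] <- best_diagonal(fwd)
  rev <- collect_seeds(index, rc)
  if (!is.null(rev)) cand[["-"]] <- best_diagonal(rev)
  if (length(cand) == 0L) return(NULL)
  strand <- if (length(cand) == 1L) {
    names(cand)
  } else if (cand[["-"]]$n_seeds > cand[["+"]]$n_seeds) {
    "-"
  } else if (cand[["+"]]$n_seeds > cand[["-"]]$n_seeds) {
    "+"
  } else if (cand[["-"]]$diag < cand[["+"]]$diag) {
    "-"
  } else "+"                                   # forward wins exact ties
  best <- cand[[strand]]
  seq <- if (strand == "+") bases else rc
  n <- nchar(seq)
  d <- best$diag
  j_lo <- max(0L, -d)
  j_hi <- min(n, index$ref_len - d)            # read positions [j_lo, j_hi)
  if (j_hi - j_lo < k) return(NULL)
  ref_sub <- substr(index$ref_seq, d + j_lo + 1L, d + j_hi)
  match <- utf8ToInt(substr(seq, j_lo + 1L, j_hi)) == utf8ToInt(ref_sub)
  rp0 <- best$seed_read_pos[1]
  ext <- extend_diagonal(match, a = rp0 - j_lo, b = rp0 + k - j_lo,
                         min_identity = min_identity)
  aligned_len <- ext$b - ext$a
  if (aligned_len < min_match_len) return(NULL)
  list(ref_start = d + j_lo + ext$a, ref_end = d + j_lo + ext$b,
       strand = strand, matched_bases = ext$matched,
       aligned_len = aligned_len,
       identity = ext$matched / aligned_len)
}

#' Map reads against a word-hash index
#'
#' Seed-and-extend mapping: k-mer seeds are collected for the read and its
#' reverse complement, voted by diagonal (`ref_pos - read_pos`), and the
#' best diagonal (most seeds; ties broken toward the leftmost reference
#' position, with the forward strand preferred on a strand tie) is extended
#' ungapped in both directions while the running identity stays at or above
#' `min_identity`. A single seed suffices to nominate a diagonal. Reads
#' whose best extension is shorter than `min_match_len` are unmapped.
#'
#' @param index A [build_index()] object.
#' @param reads Read tibble (`read_id`, `bases`, ...).
#' @param min_match_len Minimum aligned length to report.
#' @param min_identity Minimum running identity during extension.
#' @return Tibble with one row per read: `read_id`, `mapped`, `ref_id`,
#'   `ref_start`, `ref_end` (0-based half-open), `strand`,
#'   `matched_bases`, `aligned_len`, `identity`.
#' @export
map_reads <- function(index, reads, min_match_len = 10, min_identity = 0.9) {
  stopifnot(inherits(index, "word_index"))
  rc_all <- character(nrow(reads))
  ok <- nchar(reads$bases) > 0L
  rc_all[ok] <- reverse_complement(reads$bases[ok])
  res <- purrr::map2(reads$bases, rc_all, function(b, rc) {
    map_one(index, b, rc, min_match_len, min_identity)
  })
  mapped <- !vapply(res, is.null, TRUE)
  g <- function(f, default) {
    vapply(res, function(r) if (is.null(r)) default else r[[f]],
           default)
  }
  tibble::tibble(
    read_id = reads$read_id,
    mapped = mapped,
    ref_id = ifelse(mapped, index$ref_id, NA_character_),
    ref_start = as.integer(g("ref_start", NA_real_)),
    ref_end = as.integer(g("ref_end", NA_real_)),
    strand = g("strand", NA_character_),
    matched_bases = as.integer(g("matched_bases", NA_real_)),
    aligned_len = as.integer(g("aligned_len", NA_real_)),
    identity = g("identity", NA_real_)
  )
}

#' Per-base coverage track from alignments
#'
#' @param alignments Alignment tibble from [map_reads()] (unmapped rows
#'   are ignored) or any tibble with `ref_start`, `ref_end` 0-based
#'   half-open columns.
#' @param genome The reference [genome()] the alignments refer to.
#' @return An object of class `coverage_track` with `ref_id` and an
#'   integer `depth` vector of length `nchar(genome)`.
#' @export
coverage_track <- function(alignments, genome) {
  stopifnot(inherits(genome, "genome"))
  L <- nchar(genome$sequence)
  a <- alignments
  if ("mapped" %in% names(a)) a <- a[a$mapped, , drop = FALSE]
  if ("ref_id" %in% names(a)) a <- a[is.na(a$ref_id) | a$ref_id == genome$id, , drop = FALSE]
  s <- a$ref_start
  e <- a$ref_end
  if (length(s) > 0L &&
      (any(s < 0) || any(e > L) || any(s >= e))) {
    stop("alignment interval out of reference bounds", call. = FALSE)
  }
  depth <- integer(L)
  if (length(s) > 0L) {
    delta <- tabulate(s + 1L, nbins = L) - tabulate(e + 1L, nbins = L)
    depth <- cumsum(delta)
  }
  structure(list(ref_id = genome$id, depth = as.integer(depth)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %s bp, mean %.3fx, max %dx, breadth %.3f\n",
              x$ref_id, format(length(x$depth), big.mark = ","),
              mean(x$depth), max(x$depth), mean(x$depth > 0)))
  invisible(x)
}

#' Summary statistics of a coverage track
#'
#' @param track A [coverage_track()].
#' @return One-row tibble: `ref_id`, `ref_len`, `mean` (depth),
#'   `max`, `breadth` (fraction of positions covered at least once) and
#'   `total_depth`.
#' @export
coverage_summary <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  d <- track$depth
  tibble::tibble(ref_id = track$ref_id, ref_len = length(d),
                 mean = mean(d), max = max(d), breadth = mean(d > 0),
                 total_depth = sum(d))
}

#' Depth histogram of a coverage track
#'
#' @param track A [coverage_track()].
#' @return Tibble `depth`, `bases`; `sum(bases)` equals the reference
#'   length.
#' @export
coverage_histogram <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  tab <- table(track$depth)
  tibble::tibble(depth = as.integer(names(tab)),
                 bases = as.integer(tab))
}

#' Write alignments as minimal SAM
#'
#' Emits a valid header plus one line per read with an M-only CIGAR over
#' the aligned span (`SEQ`/`QUAL` omitted as `*`); mapped strand is
#' encoded in FLAG (0/16), unmapped reads as FLAG 4.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @param index The [build_index()] used for mapping (for the `@SQ` line).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, index, path) {
  stopifnot(inherits(index, "word_index"))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", index$ref_id, index$ref_len))
  body <- purrr::pmap_chr(alignments, function(read_id, mapped, ref_id,
                                               ref_start, ref_end, strand,
                                               matched_bases, aligned_len,
                                               identity, ...) {
    if (!mapped) {
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", read_id)
    } else {
      flag <- if (strand == "-") 16L else 0L
      sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
              read_id, flag, ref_id, ref_start + 1L, 60L, aligned_len)
    }
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write alignments as TSV
#'
#' @param alignments Alignment tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  readr::write_tsv(alignments, path)
  invisible(path)
}

#' Read and write coverage tracks as fixed-step wiggle
#'
#' Fixed-step, span-1 wiggle holding the full per-base depth vector.
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @return `read_wiggle()` returns a `coverage_track`; `write_wiggle()`
#'   returns `path` invisibly.
#' @export
write_wiggle <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  writeLines(c(sprintf("fixedStep chrom=%s start=1 step=1 span=1",
                       track$ref_id),
               format(track$depth, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' @rdname write_wiggle
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^fixedStep", lines[1]))
  ref_id <- sub(".*chrom=(\\S+).*", "\\1", lines[1])
  structure(list(ref_id = ref_id, depth = as.integer(lines[-1])),
            class = "coverage_track")
}

#' Write covered intervals as BED
#'
#' Maximal runs of positions with depth >= 1, as 0-based half-open BED
#' intervals.
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_covered_bed <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$depth > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  readr::write_tsv(
    tibble::tibble(chrom = track$ref_id, start = starts[keep],
                   end = ends[keep]),
    path, col_names = FALSE)
  invisible(path)
}
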